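test_that("constant descriptor columns are pruned, order preserved", {
  X <- cbind(a = 1:5, b = rep(0, 5), c = 5:1, d = rep(2, 5), e = c(1, 3, 2, 5, 4))
  out <- drop_constant_columns(X)
  expect_identical(colnames(out$x), c("a", "c", "e"))
  expect_identical(out$removed, c("b", "d"))
  expect_identical(drop_constant_columns(X[, c("a", "c")])$removed,
                   character(0))
  expect_error(drop_constant_columns(matrix(1, 3, 2)), "constant")
  # the scale of the real pruning problem: 1875 columns, 448 constant
  set.seed(1)
  big <- matrix(stats::runif(30 * 1875), 30, 1875)
  const <- sample(1875, 448)
  big[, const] <- matrix(rep(stats::runif(448), each = 30), 30)
  expect_equal(ncol(drop_constant_columns(big)$x), 1427)
})

test_that("autoscaling standardizes and is idempotent", {
  expect_equal(as.vector(autoscale(matrix(1:3))), c(-1, 0, 1))
  X <- matrix(stats::rnorm(40), 10)
  Xs <- autoscale(X)
  expect_equal(colMeans(Xs), rep(0, 4), tolerance = 1e-12)
  expect_equal(apply(Xs, 2, stats::sd), rep(1, 4), tolerance = 1e-12)
  expect_equal(unclass(autoscale(Xs))[, ], Xs[, ], tolerance = 1e-12)
  expect_error(autoscale(cbind(1:3, rep(1, 3))), "zero-variance")
  # the packaged calibration block scales cleanly
  cal <- qspr_dataset("calibration")
  expect_equal(mean(autoscale(cal$x)[, "ALogP"]), 0, tolerance = 1e-12)
  expect_equal(stats::sd(autoscale(cal$x)[, "ALogP"]), 1, tolerance = 1e-12)
})

test_that("OLS matches exact lines and the normal-equations oracle", {
  x <- matrix(1:5, dimnames = list(NULL, "x"))
  f <- qspr(x, 2 * (1:5) + 1, method = "ols")
  expect_equal(unname(f$coefficients), 2, tolerance = 1e-12)
  expect_equal(f$intercept, 1, tolerance = 1e-12)
  fc <- qspr(x, rep(4, 5), method = "ols")
  expect_equal(unname(fc$coefficients), 0, tolerance = 1e-12)
  expect_equal(fc$intercept, 4, tolerance = 1e-12)
  set.seed(10)
  X <- matrix(stats::rnorm(30), 10, 3)
  y <- stats::rnorm(10)
  fit <- qspr(X, y, method = "ols")
  Xd <- cbind(1, X)
  beta <- solve(t(Xd) %*% Xd, t(Xd) %*% y)  # brute-force normal equations
  expect_equal(unname(c(fit$intercept, fit$coefficients)), drop(beta),
               tolerance = 1e-8)
  expect_equal(unname(fit$bw),
               unname(fit$coefficients * apply(X, 2, stats::sd)))
})

test_that("rank-deficient problems fall back to the minimum-norm fit", {
  set.seed(2)
  X <- matrix(stats::rnorm(12), 3, 4)
  y <- stats::rnorm(3)
  expect_warning(f <- qspr(X, y, method = "ols"), "minimum-norm")
  expect_equal(unname(predict(f, X)), y, tolerance = 1e-8)
})

test_that("PCR reduces to OLS at full rank and to PC1 when constructed", {
  set.seed(3)
  X <- matrix(stats::rnorm(48), 12, 4,
              dimnames = list(NULL, paste0("d", 1:4)))
  y <- stats::rnorm(12)
  p_full <- qspr(X, y, method = "pcr", n_components = 4)
  p_ols <- qspr(X, y, method = "ols")
  expect_equal(predict(p_full, X), predict(p_ols, X), tolerance = 1e-8)
  # response generated from the first component only
  sv <- svd(autoscale(X))
  y1 <- 2 + 3 * sv$u[, 1] * sv$d[1]
  p1 <- qspr(X, y1, method = "pcr", n_components = 1)
  expect_lt(max(abs(p1$residuals)), 1e-10)
  expect_error(qspr(X, y, method = "pcr", n_components = 40),
               "n_components")
})

test_that("scaling a descriptor rescales OLS and leaves PCR unchanged", {
  set.seed(4)
  X <- matrix(stats::rnorm(60), 15, 4,
              dimnames = list(NULL, paste0("d", 1:4)))
  y <- stats::rnorm(15)
  X10 <- X; X10[, 2] <- 10 * X10[, 2]
  o1 <- qspr(X, y, "ols"); o2 <- qspr(X10, y, "ols")
  expect_equal(o2$coefficients[["d2"]], o1$coefficients[["d2"]] / 10,
               tolerance = 1e-8)
  p1 <- qspr(X, y, "pcr", 3); p2 <- qspr(X10, y, "pcr", 3)
  expect_equal(predict(p2, X10), predict(p1, X), tolerance = 1e-8)
})

test_that("leave-one-out equals an explicit refit loop", {
  set.seed(5)
  X <- matrix(stats::rnorm(36), 12, 3,
              dimnames = list(NULL, paste0("d", 1:3)))
  y <- drop(X %*% c(1, -2, 0.5)) + stats::rnorm(12, sd = 0.3)
  got <- loo_cv(X, y)
  manual <- vapply(seq_len(12), function(i) {
    m <- qspr(X[-i, ], y[-i], "ols")
    predict(m, X[i, , drop = FALSE])
  }, numeric(1))
  expect_equal(got$predictions, manual, tolerance = 0)
  expect_equal(got$rmsecv, sqrt(mean((manual - y)^2)), tolerance = 0)
  # collinear points fit exactly
  expect_equal(loo_cv(matrix(1:3, dimnames = list(NULL, "x")),
                      c(2, 4, 6))$rmsecv, 0, tolerance = 1e-10)
})

test_that("cross-validated error sits at the noise level", {
  set.seed(6)
  X <- matrix(stats::rnorm(90), 30, 3,
              dimnames = list(NULL, paste0("d", 1:3)))
  sigma <- 0.5
  y <- 1 + drop(X %*% c(2, -1, 3)) + stats::rnorm(30, sd = sigma)
  r <- loo_cv(X, y)$rmsecv
  expect_gt(r, 0.5 * sigma)
  expect_lt(r, 2 * sigma)
})

test_that("forward selection finds planted signal before noise", {
  set.seed(7)
  x <- matrix(stats::rnorm(100), 20, 5,
              dimnames = list(NULL, paste0("d", 1:5)))
  y <- 5 * x[, 3]  # one perfect correlate among noise
  sel <- forward_select(x, y)
  expect_identical(sel$selected[1], "d3")
  # three strong variables in a 20 x 50 problem
  d <- simulate_qspr(20, 50, informative = c("5" = 4, "17" = -3, "33" = 5),
                     noise_sd = 0.05, seed = 8)
  tr <- forward_select(d$x, d$y, max_vars = 6)
  expect_true(all(c("V5", "V17", "V33") %in% tr$selected[1:3]))
  expect_true(all(diff(tr$rmsecv_path) <= 0))
})

test_that("selection plus refit recovers a sparse generating model", {
  d <- simulate_qspr(40, 20, informative = c("2" = 1.5, "9" = -2, "14" = 1),
                     noise_sd = 0.01, seed = 9)
  tr <- forward_select(d$x, d$y, max_vars = 8)
  expect_true(all(c("V2", "V9", "V14") %in% tr$selected))
  est <- tr$model$coefficients[c("V2", "V9", "V14")]
  expect_equal(unname(est), c(1.5, -2, 1), tolerance = 0.05)
})

test_that("prediction aligns descriptors by name", {
  cal <- qspr_dataset("calibration")
  m <- qspr(cal$x, cal$y, "ols")
  expect_equal(predict(m, cal$x), m$fitted.values)
  perm <- cal$x[, rev(colnames(cal$x))]
  expect_equal(predict(m, perm), predict(m, cal$x))
  expect_error(predict(m, cal$x[, -1]), "missing descriptor")
  # external set lands in a physically plausible rate window
  prd <- qspr_dataset("prediction")
  pr <- predict(m, prd$x)
  expect_true(all(pr > 0 & pr < 50))
})

test_that("validation reports per-compound errors and aggregates", {
  v0 <- validate(c(1, 2), c(1, 2))
  expect_equal(v0$table$error_percent, c(0, 0))
  expect_equal(v0$rmsep, 0)
  v1 <- validate(1.231, 1.226)
  expect_equal(v1$table$error_percent, -0.406, tolerance = 0.01)
  expect_lt(abs(v1$table$error_percent - (-0.400)), 0.15)
  v2 <- validate(0.264, 0.228)
  expect_equal(v2$table$error_percent, -13.64, tolerance = 0.01)
  expect_lt(abs(v2$table$error_percent - (-13.662)), 0.15)
  expect_error(validate(1:3, 1:2), "length")
  expect_error(validate(c(-1, 1), c(1, 1)), "> 0")
})
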