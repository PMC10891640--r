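test_that("chemical rank is recovered from the singular value spectrum", {
  ser2 <- simulate_dhp_series(k1 = 1e-3, wavelengths = coarse_wl())
  expect_identical(estimate_rank(ser2), 2L)
  # rank one: single spectrum times a decay
  wl <- coarse_wl()
  s <- gaussian_spectrum(spectral_bands(360, 20, 1), wl)
  decay <- exp(-1e-3 * default_times())
  ser1 <- spectral_series(wl, default_times(), outer(decay, s))
  expect_identical(estimate_rank(ser1), 1L)
  # three species at 0.2% noise, trace second photoproduct
  ser3 <- simulate_dhp_series(k1 = 1e-3, k2 = 2e-4, scheme = "sequential",
                              relative_sd = 0.002, seed = 7,
                              wavelengths = coarse_wl())
  expect_identical(estimate_rank(ser3), 3L)
  zero <- spectral_series(wl, c(0, 60), matrix(0, 2, length(wl)))
  expect_error(estimate_rank(zero), "all-zero")
})

test_that("purest-variable initialization lands inside the true bands", {
  # well separated narrow bands
  ser <- simulate_dhp_series(k1 = 1e-3, band_width = 10,
                             wavelengths = coarse_wl())
  S0 <- init_purest(ser, 2)
  sel <- sort(attr(S0, "wavelengths"))
  expect_true(sel[1] >= 240 && sel[1] <= 300)
  expect_true(sel[2] >= 330 && sel[2] <= 390)
  # single component: just the purest column
  expect_silent(S1 <- init_purest(ser, 1))
  expect_equal(ncol(S1), 1)
  # overlapping bands: initial spectra still close to the truth
  ser2 <- simulate_dhp_series(k1 = 1.061e-4, band_width = 25,
                              wavelengths = coarse_wl())
  S2 <- init_purest(ser2, 2)
  for (j in 1:2)
    expect_gte(max(cosine(S2[, j], ser2$truth$S[, 1]),
                   cosine(S2[, j], ser2$truth$S[, 2])), 0.9)
  expect_error(init_purest(ser, 100), "exceeds")
})

test_that("fit metrics implement the lof / explained-variance formulas", {
  ser <- simulate_dhp_series(k1 = 1e-3, wavelengths = coarse_wl())
  D <- ser$absorbance
  m <- fit_metrics(D, ser$truth$C, ser$truth$S)
  expect_equal(unname(m), c(0, 100))
  m0 <- fit_metrics(D, 0 * ser$truth$C, ser$truth$S)
  expect_equal(unname(m0), c(100, 0))
  # residual sum of squares at exactly 1% of the data sum of squares
  sv <- svd(D)
  C <- sv$u %*% diag(sv$d) * 0.9
  m1 <- fit_metrics(D, C, sv$v)
  expect_equal(unname(m1["lof_percent"]), 10, tolerance = 1e-9)
  expect_equal(unname(m1["r2_percent"]), 99, tolerance = 1e-9)
  expect_error(fit_metrics(matrix(0, 2, 2), matrix(0, 2, 1),
                           matrix(0, 2, 1)), "all-zero")
})

test_that("exact data are a fixed point of the constrained ALS", {
  ser <- simulate_dhp_series(k1 = 4.435e-4, wavelengths = coarse_wl())
  m <- mcr_als(ser, 2, init = "provided", S_init = ser$truth$S)
  expect_lt(m$lof_percent, 1e-6)
  expect_true(m$converged)
})

test_that("recovered spectra match the generating spectra", {
  ser <- simulate_dhp_series(k1 = 1e-3, wavelengths = coarse_wl())
  m <- mcr_als(ser, 2)
  for (j in 1:2)
    expect_gte(cosine(m$S[, j], ser$truth$S[, j]), 0.99)
  # component order: parent peaks at t = 0
  expect_identical(which.max(m$C[, "parent"]), 1L)
})

test_that("algebraic and constraint invariants hold across runs", {
  for (seed in 1:3) {
    ser <- simulate_dhp_series(k1 = 1e-3, relative_sd = 0.004, seed = seed,
                               wavelengths = coarse_wl())
    m <- mcr_als(ser, 2)
    # identity r2 = 100 - lof^2/100
    expect_equal(m$r2_percent, 100 - m$lof_percent^2 / 100,
                 tolerance = 1e-9)
    # non-negativity exact
    expect_gte(min(m$C), 0)
    expect_gte(min(m$S), 0)
    # closure: every row at the t = 0 total
    expect_equal(rowSums(m$C), rep(sum(m$C[1, ]), nrow(m$C)),
                 tolerance = 1e-9)
    # no worse than the first iterate
    m1 <- suppressWarnings(mcr_als(ser, 2, max_iter = 1))
    expect_lte(m$lof_percent, m1$lof_percent + 1e-12)
  }
})

test_that("unconstrained ALS agrees with the truncated SVD", {
  ser <- simulate_dhp_series(k1 = 1e-3, relative_sd = 0.003, seed = 11,
                             wavelengths = coarse_wl())
  off <- list(nonneg_C = FALSE, nonneg_S = FALSE, unimodal_C = FALSE,
              closure_C = FALSE)
  m <- mcr_als(ser, 2, constraints = off, tol = 1e-12, max_iter = 2000)
  D <- ser$absorbance
  sv <- svd(D)
  D2 <- sv$u[, 1:2] %*% diag(sv$d[1:2]) %*% t(sv$v[, 1:2])
  expect_lt(norm(m$C %*% t(m$S) - D2, "F") / norm(D2, "F"), 1e-8)
})

test_that("parent profiles are recovered end to end at realistic noise", {
  for (seed in c(2, 9)) {
    ser <- simulate_dhp_series(k1 = 1e-3, relative_sd = 0.005, seed = seed,
                               wavelengths = coarse_wl())
    m <- mcr_als(ser, 2)
    expect_gte(stats::cor(m$C[, "parent"], ser$truth$C[, "parent"]), 0.999)
  }
})

test_that("unimodality flattening leaves a single maximum", {
  x <- c(0.1, 0.5, 0.3, 0.8, 1.0, 0.7, 0.9, 0.2)
  f <- photostab:::flatten_unimodal(x)
  peak <- which.max(f)
  expect_true(all(diff(f[seq_len(peak)]) >= 0))
  expect_true(all(diff(f[peak:length(f)]) <= 0))
  # already unimodal input is untouched
  u <- c(0, 0.4, 1, 0.6, 0.2)
  expect_identical(photostab:::flatten_unimodal(u), u)
})

test_that("MCR results write a readable CSV/JSON bundle", {
  ser <- simulate_dhp_series(k1 = 1e-3, wavelengths = coarse_wl())
  m <- mcr_als(ser, 2)
  dir <- file.path(tempdir(), "mcr-out")
  write_mcr(m, dir)
  C <- utils::read.csv(file.path(dir, "C.csv"))
  expect_equal(nrow(C), length(ser$times))
  diag <- jsonlite::read_json(file.path(dir, "diagnostics.json"),
                              simplifyVector = TRUE)
  expect_equal(diag$lof_percent, m$lof_percent)
  unlink(dir, recursive = TRUE)
})
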