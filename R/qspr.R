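#' Remove zero-variance descriptor columns
#'
#' Descriptor matrices straight out of a calculator contain many columns
#' that are zero or constant across the compound set; they carry no
#' information and break autoscaling, so they are dropped before
#' modelling.
#'
#' @param x Numeric matrix (compound x descriptor).
#' @return List with `x` (surviving columns, order preserved) and
#'   `removed` (names, or indices when unnamed, of the dropped columns).
#' @export
drop_constant_columns <- function(x) {
  x <- as.matrix(x)
  if (length(x) == 0) stop("empty descriptor matrix")
  keep <- apply(x, 2, function(v) stats::var(v) > 0)
  if (!any(keep)) stop("all descriptor columns are constant")
  nm <- colnames(x)
  removed <- if (is.null(nm)) which(!keep) else nm[!keep]
  list(x = x[, keep, drop = FALSE], removed = removed)
}

#' Autoscale a descriptor matrix
#'
#' Centers each column to mean 0 and scales to unit standard deviation
#' (n - 1 denominator). Zero-variance columns are an error; remove them
#' first with [drop_constant_columns()].
#'
#' @param x Numeric matrix.
#' @return The scaled matrix with attributes `center` and `scale`
#'   (per-column means and SDs).
#' @export
autoscale <- function(x) {
  x <- as.matrix(x)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance column: call drop_constant_columns() first")
  out <- scale(x, center = TRUE, scale = sds)
  attr(out, "center") <- attr(out, "scaled:center")
  attr(out, "scale") <- attr(out, "scaled:scale")
  out
}

#' Fit a QSPR regression model
#'
#' Relates a photodegradation rate vector to molecular descriptors by
#' either ordinary least squares on the raw descriptors (`method =
#' "ols"`) or principal component regression (`method = "pcr"`): the
#' response is regressed on the first `n_components` scores of the
#' autoscaled descriptor matrix and the coefficients are back-transformed
#' to descriptor units. With all components retained, PCR reproduces the
#' OLS predictions. OLS uses the QR decomposition through [stats::lm()];
#' on rank-deficient problems a minimum-norm solution (SVD pseudoinverse)
#' is returned with a warning.
#'
#' @param x Compound x descriptor matrix (named columns recommended).
#' @param y Response vector (rates, conventionally in 1e-3 s^-1 units).
#' @param method `"ols"` or `"pcr"`.
#' @param n_components Number of principal components (PCR only).
#' @return Object of class `"qspr"`: `intercept`, `coefficients`
#'   (descriptor units), `bw` (standardized coefficients,
#'   `coefficient * column SD`), `scaling` (column means/SDs),
#'   `fitted.values`, `residuals`, `method`, `n_components`.
#' @export
qspr <- function(x, y, method = c("ols", "pcr"), n_components = NULL) {
  method <- match.arg(method)
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (nrow(x) != length(y)) stop("x and y differ in length")
  if (nrow(x) < 2) stop("at least two samples are required")
  if (anyNA(x) || anyNA(y)) stop("missing values are not allowed")
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  means <- colMeans(x)
  sds <- apply(x, 2, stats::sd)

  if (method == "ols") {
    Xd <- cbind(1, x)
    r <- qr(Xd)$rank
    if (r < ncol(Xd)) {
      warning("rank-deficient OLS problem (rank ", r, " < ", ncol(Xd),
              "); returning the minimum-norm solution")
      sv <- svd(Xd)
      pos <- sv$d > max(dim(Xd)) * .Machine$double.eps * sv$d[1]
      beta <- sv$v[, pos, drop = FALSE] %*%
        ((t(sv$u[, pos, drop = FALSE]) %*% y) / sv$d[pos])
      beta <- drop(beta)
    } else {
      fit <- stats::lm.fit(Xd, y)
      beta <- fit$coefficients
    }
    intercept <- beta[1]
    coefs <- beta[-1]
    names(coefs) <- colnames(x)
    n_components <- NULL
  } else {
    if (any(sds == 0))
      stop("zero-variance column: call drop_constant_columns() first")
    p <- ncol(x); n <- nrow(x)
    if (is.null(n_components)) n_components <- min(n - 1, p)
    if (n_components < 1 || n_components > min(n - 1, p))
      stop("n_components must be in 1..min(n_samples - 1, n_descriptors)")
    Xs <- autoscale(x)
    sv <- svd(Xs)
    a <- n_components
    scores <- sv$u[, seq_len(a), drop = FALSE] %*%
      diag(sv$d[seq_len(a)], a, a)
    g <- stats::lm.fit(cbind(1, scores), y)$coefficients
    b_scaled <- drop(sv$v[, seq_len(a), drop = FALSE] %*% g[-1])
    coefs <- b_scaled / sds
    names(coefs) <- colnames(x)
    intercept <- g[1] - sum(coefs * means)
  }
  fitted <- drop(intercept + x %*% coefs)
  structure(
    list(method = method, intercept = unname(intercept),
         coefficients = coefs, bw = coefs * sds,
         scaling = list(means = means, sds = sds),
         n_components = n_components,
         fitted.values = fitted, residuals = y - fitted,
         y = y, descriptors = colnames(x), call = match.call()),
    class = "qspr")
}

#' @export
print.qspr <- function(x, ...) {
  cat("QSPR model (", toupper(x$method),
      if (!is.null(x$n_components)) paste0(", ", x$n_components, " PC"),
      ") on ", length(x$descriptors), " descriptors\n", sep = "")
  cat(sprintf("  intercept %.6g; RMSEC %.6g\n", x$intercept,
              sqrt(mean(x$residuals^2))))
  invisible(x)
}

#' @export
summary.qspr <- function(object, ...) {
  print(object)
  df <- data.frame(descriptor = object$descriptors,
                   coefficient = unname(object$coefficients),
                   bw = unname(object$bw))
  print(df[order(-abs(df$bw)), ], row.names = FALSE)
  invisible(df)
}

#' @export
coef.qspr <- function(object, ...)
  c("(Intercept)" = object$intercept, object$coefficients)

#' @export
residuals.qspr <- function(object, ...) object$residuals

#' Predict photodegradation rates from a QSPR model
#'
#' Columns of `newdata` are aligned to the model's descriptors by name,
#' so column order is irrelevant; a missing descriptor is an error.
#'
#' @param object A `"qspr"` model.
#' @param newdata Matrix or data frame with the model's descriptor
#'   columns.
#' @param ... Unused.
#' @return Numeric vector of predicted rates.
#' @export
predict.qspr <- function(object, newdata, ...) {
  if (missing(newdata)) return(object$fitted.values)
  newdata <- as.matrix(newdata)
  if (is.null(colnames(newdata))) {
    if (ncol(newdata) != length(object$descriptors))
      stop("newdata has the wrong number of columns")
    colnames(newdata) <- object$descriptors
  }
  miss <- setdiff(object$descriptors, colnames(newdata))
  if (length(miss))
    stop("missing descriptor column(s): ", paste(miss, collapse = ", "))
  newdata <- newdata[, object$descriptors, drop = FALSE]
  drop(object$intercept + newdata %*% object$coefficients)
}

#' Leave-one-out cross-validation
#'
#' For each sample the model is refit on the remaining samples (any
#' scaling happens inside the fitter, so it is recomputed on every fold)
#' and the held-out sample is predicted. `RMSECV` is the root mean squared
#' LOO residual.
#'
#' @param x Descriptor matrix.
#' @param y Response vector (n >= 3).
#' @param fitter Function `(x, y) -> model` whose result supports
#'   `predict(model, newdata)`; defaults to OLS via [qspr()].
#' @return List with `rmsecv` and the per-sample LOO `predictions`.
#' @export
loo_cv <- function(x, y, fitter = function(x, y) qspr(x, y, method = "ols")) {
  x <- as.matrix(x); y <- as.numeric(y)
  n <- nrow(x)
  if (n < 3) stop("leave-one-out needs at least 3 samples")
  preds <- numeric(n)
  for (i in seq_len(n)) {
    m <- tryCatch(fitter(x[-i, , drop = FALSE], y[-i]),
                  error = function(e)
                    stop("fitter failed on fold ", i, ": ",
                         conditionMessage(e)))
    preds[i] <- predict(m, x[i, , drop = FALSE])
  }
  list(rmsecv = sqrt(mean((preds - y)^2)), predictions = preds)
}

#' Forward descriptor selection by cross-validated error
#'
#' Greedy selection: the first descriptor entering the model is the one
#' with the largest absolute Pearson correlation with the response; every
#' subsequent step adds the candidate whose inclusion gives the lowest
#' leave-one-out RMSECV of the refit model, stopping when no candidate
#' improves RMSECV by more than `min_improvement` or `max_vars` is
#' reached. Ties are broken by column order, so the trace is
#' deterministic.
#'
#' @inheritParams loo_cv
#' @param max_vars Cap on the number of selected descriptors.
#' @param min_improvement Minimum RMSECV drop (response units) required
#'   to accept a further descriptor.
#' @return Object of class `"qspr_selection"`: `selected` (names in entry
#'   order), `rmsecv_path`, and the final fitted `"qspr"` model.
#' @export
forward_select <- function(x, y,
                           fitter = function(x, y) qspr(x, y, method = "ols"),
                           max_vars = ncol(x), min_improvement = 1e-6) {
  x <- as.matrix(x); y <- as.numeric(y)
  if (ncol(x) < 1) stop("empty descriptor matrix")
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  max_vars <- min(max_vars, ncol(x))
  cors <- abs(suppressWarnings(stats::cor(x, y)))
  cors[!is.finite(cors)] <- -Inf
  sel <- which.max(cors)  # which.max takes the first maximum: tie by order
  path <- loo_cv(x[, sel, drop = FALSE], y, fitter)$rmsecv
  while (length(sel) < max_vars) {
    cand <- setdiff(seq_len(ncol(x)), sel)
    rms <- vapply(cand, function(j)
      loo_cv(x[, c(sel, j), drop = FALSE], y, fitter)$rmsecv, numeric(1))
    best <- which.min(rms)
    if (path[length(path)] - rms[best] <= min_improvement) break
    sel <- c(sel, cand[best])
    path <- c(path, rms[best])
  }
  structure(
    list(selected = colnames(x)[sel], indices = unname(sel),
         rmsecv_path = path,
         model = fitter(x[, sel, drop = FALSE], y)),
    class = "qspr_selection")
}

#' @export
print.qspr_selection <- function(x, ...) {
  cat("Forward selection:", length(x$selected), "descriptors\n")
  print(data.frame(step = seq_along(x$selected), descriptor = x$selected,
                   rmsecv = x$rmsecv_path), row.names = FALSE)
  invisible(x)
}

#' Validation report: experimental vs predicted rates
#'
#' Per-compound relative error `100 * (pred - exp) / exp`, plus the
#' aggregates RMSEP (root mean squared prediction error), mean absolute
#' error %, and the R-squared of predicted vs measured. `rmsec` /
#' `rmsecv` slots can be filled from the calibration fit and [loo_cv()].
#'
#' @param experimental Measured rates (> 0).
#' @param predicted Predicted rates, same length.
#' @param compound Optional compound labels.
#' @param rmsec,rmsecv Optional calibration / cross-validation errors to
#'   carry in the report.
#' @return Object of class `"qspr_validation"`: data frame `table` plus
#'   aggregate fields.
#' @export
validate <- function(experimental, predicted, compound = NULL,
                     rmsec = NA_real_, rmsecv = NA_real_) {
  experimental <- as.numeric(experimental)
  predicted <- as.numeric(predicted)
  if (length(experimental) != length(predicted)) stop("length mismatch")
  if (any(experimental <= 0)) stop("experimental rates must be > 0")
  if (is.null(compound)) compound <- paste0("sample", seq_along(experimental))
  err <- 100 * (predicted - experimental) / experimental
  structure(
    list(table = data.frame(compound = compound,
                            experimental = experimental,
                            predicted = predicted,
                            error_percent = err),
         rmsep = sqrt(mean((predicted - experimental)^2)),
         mean_abs_error_percent = mean(abs(err)),
         r2_pred_vs_exp = stats::cor(experimental, predicted)^2,
         rmsec = rmsec, rmsecv = rmsecv),
    class = "qspr_validation")
}

#' @export
print.qspr_validation <- function(x, ...) {
  print(x$table, row.names = FALSE)
  cat(sprintf("RMSEP %.5g | mean |error%%| %.4g | R2(pred,exp) %.4f\n",
              x$rmsep, x$mean_abs_error_percent, x$r2_pred_vs_exp))
  if (is.finite(x$rmsec) || is.finite(x$rmsecv))
    cat(sprintf("RMSEC %.5g | RMSECV %.5g\n", x$rmsec, x$rmsecv))
  invisible(x)
}
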