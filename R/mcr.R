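#' Estimate the chemical rank of a spectral series
#'
#' Counts the singular values of the data matrix that stand above both a
#' ratio cut relative to the leading singular value and an empirical noise
#' floor (three times the median of the trailing half of the singular
#' value spectrum). Species contributing to the measured spectra are
#' assumed to have singular values larger than noise-level contributions.
#'
#' @param series A [spectral_series()].
#' @param sv_ratio_threshold Keep singular values >= sigma1 / threshold.
#' @return Integer rank estimate (>= 1).
#' @export
estimate_rank <- function(series, sv_ratio_threshold = 25) {
  stopifnot(inherits(series, "spectral_series"))
  D <- series$absorbance
  if (all(D == 0)) stop("cannot estimate the rank of an all-zero matrix")
  d <- svd(D, nu = 0, nv = 0)$d
  floor_sv <- 3 * stats::median(d[seq(ceiling(length(d) / 2), length(d))])
  max(1L, sum(d >= d[1] / sv_ratio_threshold & d > floor_sv))
}

#' Purest-variable (SIMPLISMA-style) initial spectra
#'
#' Selects the `n_components` wavelengths of highest purity
#' `sd / (mean + offset)`, deflating each candidate by its projection onto
#' the already-selected columns so that successive picks are mutually
#' independent. The selected columns of `D` are the purest concentration
#' profiles; one least-squares step then yields the corresponding initial
#' spectra, clipped to non-negative and scaled to unit maximum.
#'
#' @param series A [spectral_series()].
#' @param n_components Number of components (<= min(dim)).
#' @param offset_frac Purity offset as a fraction of the largest column
#'   mean; damps wavelengths that are pure only because they are dark.
#' @return Wavelength x component matrix of initial spectra; the chosen
#'   wavelengths are attached as `attr(, "wavelengths")`.
#' @export
init_purest <- function(series, n_components, offset_frac = 0.05) {
  stopifnot(inherits(series, "spectral_series"))
  D <- series$absorbance
  if (n_components > min(dim(D)))
    stop("n_components exceeds the matrix dimensions")
  mu <- colMeans(D)
  sdv <- apply(D, 2, stats::sd)
  purity <- sdv / (mu + offset_frac * max(mu))
  norms <- sqrt(colSums(D^2))
  norms[norms == 0] <- 1
  Y <- sweep(D, 2, norms, "/")
  chosen <- integer(0)
  for (k in seq_len(n_components)) {
    w <- if (length(chosen)) {
      Q <- qr.Q(qr(Y[, chosen, drop = FALSE]))
      res <- Y - Q %*% (t(Q) %*% Y)
      sqrt(colSums(res^2))
    } else rep(1, ncol(D))
    score <- purity * w
    score[chosen] <- -Inf
    chosen <- c(chosen, which.max(score))
  }
  Cini <- D[, chosen, drop = FALSE]
  S <- t(solve(crossprod(Cini), t(Cini) %*% D))
  S[S < 0] <- 0
  mx <- apply(S, 2, max)
  if (any(mx == 0)) stop("degenerate initialization: a component is all zero")
  S <- sweep(S, 2, mx, "/")
  attr(S, "wavelengths") <- series$wavelengths[chosen]
  S
}

#' Lack of fit and explained variance of a bilinear decomposition
#'
#' `lof = 100 * sqrt(sum((D - C S^T)^2) / sum(D^2))` and
#' `r2 = 100 * (1 - sum((D - C S^T)^2) / sum(D^2))`, so the identity
#' `r2 = 100 - lof^2 / 100` holds by construction.
#'
#' @param D Data matrix (time x wavelength).
#' @param C Concentration profiles (time x component).
#' @param S Pure spectra (wavelength x component).
#' @return Named vector `c(lof_percent, r2_percent)`.
#' @export
fit_metrics <- function(D, C, S) {
  ssd <- sum(D^2)
  if (ssd == 0) stop("fit metrics are undefined for an all-zero data matrix")
  ssr <- sum((D - C %*% t(S))^2)
  c(lof_percent = 100 * sqrt(ssr / ssd),
    r2_percent = 100 * (1 - ssr / ssd))
}

# Flatten a profile to a single maximum: walking away from the peak, any
# value rising above the running extremum is replaced by it.
flatten_unimodal <- function(x) {
  m <- which.max(x)
  if (m > 1)
    for (i in (m - 1):1) if (x[i] > x[i + 1]) x[i] <- x[i + 1]
  if (m < length(x))
    for (i in (m + 1):length(x)) if (x[i] > x[i - 1]) x[i] <- x[i - 1]
  x
}

#' Multivariate curve resolution by constrained alternating least squares
#'
#' Decomposes the series' data matrix `D` (time x wavelength) into
#' `C S^T`: concentration profiles and pure component spectra. Each
#' iteration solves the two conditional least-squares problems and applies
#' the active constraints:
#' \itemize{
#'   \item non-negativity on `C` and/or `S` (negative entries clipped to 0);
#'   \item unimodality on the `C` columns (single maximum, enforced by
#'     monotone flattening away from the peak -- the parent's peak sits at
#'     t = 0, so its profile simply becomes a monotone decay);
#'   \item closure on `C`: every row is rescaled to the total concentration
#'     at t = 0 (mass balance of a unimolecular scheme).
#' }
#' Iteration stops when the relative change in lack of fit drops below
#' `tol` or `max_iter` is reached; the best iterate seen is returned.
#' Components are reported parent-first, ordered by the time at which
#' their concentration peaks. When closure is off, the scale ambiguity is
#' resolved by normalizing each spectrum to unit maximum; with closure on,
#' the row-sum constraint already fixes the scale and the spectra carry
#' the component amplitudes.
#'
#' @param series A [spectral_series()].
#' @param n_components Number of chemical components (see
#'   [estimate_rank()]).
#' @param constraints Named list of flags `nonneg_C`, `nonneg_S`,
#'   `unimodal_C`, `closure_C`; omitted entries default to `TRUE`.
#' @param init `"purest"` ([init_purest()]) or `"provided"` (pass
#'   `S_init`).
#' @param S_init Wavelength x component matrix of starting spectra when
#'   `init = "provided"`.
#' @param tol Relative lack-of-fit change declaring convergence.
#' @param max_iter Iteration cap.
#' @return An object of class `"mcr_als"` with elements `C`, `S`,
#'   `lof_percent`, `r2_percent`, `n_iter`, `converged`, plus the input
#'   series and call.
#' @export
mcr_als <- function(series, n_components,
                    constraints = list(), init = c("purest", "provided"),
                    S_init = NULL, tol = 1e-3, max_iter = 500) {
  stopifnot(inherits(series, "spectral_series"))
  init <- match.arg(init)
  if (tol <= 0) stop("tol must be > 0")
  if (max_iter < 1) stop("max_iter must be >= 1")
  if (n_components < 1 || n_components > min(dim(series$absorbance)))
    stop("n_components out of range")
  cn <- list(nonneg_C = TRUE, nonneg_S = TRUE, unimodal_C = TRUE,
             closure_C = TRUE)
  bad <- setdiff(names(constraints), names(cn))
  if (length(bad)) stop("unknown constraint flags: ", paste(bad, collapse = ", "))
  cn[names(constraints)] <- constraints

  D <- series$absorbance
  S <- if (init == "provided") {
    if (is.null(S_init)) stop("init = 'provided' needs S_init")
    as.matrix(S_init)
  } else init_purest(series, n_components)
  if (!identical(dim(S), c(ncol(D), as.integer(n_components))) &&
      !identical(dim(S), c(ncol(D), n_components)))
    stop("S_init must be length(wavelengths) x n_components")

  solve_ls <- function(A, B) {
    # rows of the solution X minimizing ||B - X A'||; guard collinearity
    out <- tryCatch(t(solve(crossprod(A), t(A) %*% t(B))),
                    error = function(e) NULL)
    if (is.null(out))
      stop("singular normal equations: the current spectra estimates are ",
           "collinear; lower n_components or provide a different S_init")
    out
  }

  best <- NULL
  lof_prev <- Inf
  converged <- FALSE
  n_iter <- 0L
  for (it in seq_len(max_iter)) {
    n_iter <- it
    C <- solve_ls(S, D)
    if (cn$nonneg_C) C[C < 0] <- 0
    if (cn$unimodal_C) C <- apply(C, 2, flatten_unimodal)
    if (cn$closure_C) {
      total <- sum(C[1, ])
      rs <- rowSums(C)
      ok <- rs > 0
      C[ok, ] <- C[ok, , drop = FALSE] * (total / rs[ok])
    }
    S <- solve_ls(C, t(D))
    if (cn$nonneg_S) S[S < 0] <- 0
    if (!cn$closure_C) {
      mx <- apply(S, 2, max)
      if (any(mx == 0))
        stop("a component spectrum collapsed to zero; lower n_components")
      S <- sweep(S, 2, mx, "/")
      C <- sweep(C, 2, mx, "*")
    }
    m <- fit_metrics(D, C, S)
    if (is.null(best) || m["lof_percent"] < best$lof) {
      best <- list(C = C, S = S, lof = unname(m["lof_percent"]),
                   r2 = unname(m["r2_percent"]))
    }
    # below ~1e-6 % the residual is at machine precision and the relative
    # change criterion only sees round-off jitter
    if (m["lof_percent"] < 1e-6 ||
        abs(lof_prev - m["lof_percent"]) / max(m["lof_percent"], 1e-300) < tol) {
      converged <- TRUE
      break
    }
    lof_prev <- m["lof_percent"]
  }
  if (!converged)
    warning("mcr_als did not converge in ", max_iter,
            " iterations; returning the best iterate")

  C <- best$C; S <- best$S
  ord <- order(series$times[apply(C, 2, which.max)])
  C <- C[, ord, drop = FALSE]
  S <- S[, ord, drop = FALSE]
  nm <- c("parent", paste0("PhP", seq_len(ncol(C) - 1)))[seq_len(ncol(C))]
  colnames(C) <- colnames(S) <- nm

  structure(
    list(C = C, S = S, lof_percent = best$lof, r2_percent = best$r2,
         n_iter = n_iter, converged = converged, constraints = cn,
         series = series, call = match.call()),
    class = "mcr_als")
}

#' @export
print.mcr_als <- function(x, ...) {
  cat("Constrained MCR-ALS decomposition of", x$series$compound_id, "\n")
  cat(sprintf("  %d components, %d iterations (%s)\n", ncol(x$C), x$n_iter,
              if (x$converged) "converged" else "not converged"))
  cat(sprintf("  lack of fit %.4g%%, explained variance %.6g%%\n",
              x$lof_percent, x$r2_percent))
  on <- names(Filter(isTRUE, x$constraints))
  cat("  constraints:", if (length(on)) paste(on, collapse = ", ") else "none",
      "\n")
  invisible(x)
}

#' @export
summary.mcr_als <- function(object, ...) {
  print(object)
  tmax <- object$series$times[apply(object$C, 2, which.max)]
  lmax <- object$series$wavelengths[apply(object$S, 2, which.max)]
  df <- data.frame(component = colnames(object$C),
                   conc_peak_time_s = tmax, spectrum_max_nm = lmax)
  cat("\n")
  print(df, row.names = FALSE)
  invisible(df)
}

#' @export
fitted.mcr_als <- function(object, ...) object$C %*% t(object$S)

#' @export
residuals.mcr_als <- function(object, ...)
  object$series$absorbance - fitted(object)

#' @export
coef.mcr_als <- function(object, ...) list(C = object$C, S = object$S)

#' @export
plot.mcr_als <- function(x, which = c("concentration", "spectra"), ...) {
  which <- match.arg(which)
  if (which == "concentration") {
    graphics::matplot(x$series$times / 60, x$C, type = "l", lty = 1,
                      xlab = "irradiation time (min)",
                      ylab = "concentration (a.u.)", ...)
  } else {
    graphics::matplot(x$series$wavelengths, x$S, type = "l", lty = 1,
                      xlab = "wavelength (nm)", ylab = "absorbance (AU)", ...)
  }
  graphics::legend("topright", colnames(x$C), lty = 1,
                   col = seq_len(ncol(x$C)), bty = "n")
  invisible(x)
}

#' Write an MCR result to disk
#'
#' Writes `C.csv` (time x component), `S.csv` (wavelength x component) and
#' `diagnostics.json` (lof, r2, iterations, convergence) into `dir`.
#'
#' @param x An `"mcr_als"` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_mcr <- function(x, dir) {
  stopifnot(inherits(x, "mcr_als"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(data.frame(time_s = x$series$times, x$C),
                   file.path(dir, "C.csv"), row.names = FALSE)
  utils::write.csv(data.frame(wavelength_nm = x$series$wavelengths, x$S),
                   file.path(dir, "S.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(lof_percent = x$lof_percent, r2_percent = x$r2_percent,
         n_iter = x$n_iter, converged = x$converged),
    file.path(dir, "diagnostics.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
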