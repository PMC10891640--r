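#' Spectral time series container
#'
#' Holds one photodegradation experiment: a matrix of absorbances recorded
#' over irradiation time on a fixed wavelength grid (the data matrix `D`
#' that curve resolution decomposes).
#'
#' @param wavelengths Strictly increasing wavelength grid (nm).
#' @param times Strictly increasing irradiation times (s), starting at 0.
#' @param absorbance Numeric matrix, `length(times)` rows by
#'   `length(wavelengths)` columns (AU). No missing values allowed.
#' @param compound_id Identifier carried through to results.
#' @param truth Optional list of ground-truth generating parameters
#'   (recorded by [simulate_series()] so recovery can be tested).
#'
#' @return An object of class `"spectral_series"`.
#' @seealso [simulate_series()], [mcr_als()]
#' @export
spectral_series <- function(wavelengths, times, absorbance,
                            compound_id = "unknown", truth = NULL) {
  wavelengths <- as.numeric(wavelengths)
  times <- as.numeric(times)
  absorbance <- as.matrix(absorbance)
  if (anyNA(wavelengths) || anyNA(times) || anyNA(absorbance))
    stop("spectral_series: missing values are not allowed")
  if (length(wavelengths) < 2 || any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly increasing")
  if (length(times) < 2 || any(diff(times) <= 0))
    stop("times must be strictly increasing")
  if (!identical(dim(absorbance), c(length(times), length(wavelengths))))
    stop("absorbance must be a length(times) x length(wavelengths) matrix")
  structure(
    list(wavelengths = wavelengths, times = times,
         absorbance = unname(absorbance), compound_id = compound_id,
         truth = truth),
    class = "spectral_series")
}

#' @export
print.spectral_series <- function(x, ...) {
  cat("Spectral time series:", x$compound_id, "\n")
  cat(sprintf("  %d spectra (%g-%g s) x %d wavelengths (%g-%g nm)\n",
              length(x$times), min(x$times), max(x$times),
              length(x$wavelengths), min(x$wavelengths), max(x$wavelengths)))
  if (!is.null(x$truth))
    cat("  synthetic; ground truth attached (k1 =", x$truth$k1, "s^-1 )\n")
  invisible(x)
}

#' Default analysis grids
#'
#' The default wavelength window is 215-450 nm in 1 nm steps (shorter
#' wavelengths carry mostly instrumental noise and are discarded before
#' resolution). The default time grid is the spectrum-acquisition schedule
#' of the irradiation experiments: t = 0 plus 1, 2, 3, 4, 5, 10, 15, 20,
#' 25, 30, 40, 50, 60, 80, 100, 120, 150, 180, 210, 240, 270 and 300 min,
#' stored in seconds.
#'
#' @return Numeric vector: wavelengths in nm, or times in seconds.
#' @export
default_wavelengths <- function() seq(215, 450, by = 1)

#' @rdname default_wavelengths
#' @param unit Return the grid in `"s"` (default) or `"min"`.
#' @export
default_times <- function(unit = c("s", "min")) {
  unit <- match.arg(unit)
  mins <- c(0, 1, 2, 3, 4, 5, 10, 15, 20, 25, 30, 40, 50, 60, 80,
            100, 120, 150, 180, 210, 240, 270, 300)
  if (unit == "s") mins * 60 else mins
}

#' Write / read a spectral series as CSV
#'
#' The on-disk layout is wavelength-major: first column `wavelength_nm`,
#' remaining columns named `t<seconds>`. For synthetic series the
#' generating parameters are written to a `.json` sidecar so that a
#' round-tripped file still supports recovery tests.
#'
#' @param series A [spectral_series()] object.
#' @param path CSV file path.
#' @return `read_spectral_series()` returns a `"spectral_series"`;
#'   `write_spectral_series()` returns `path` invisibly.
#' @export
write_spectral_series <- function(series, path) {
  stopifnot(inherits(series, "spectral_series"))
  df <- data.frame(wavelength_nm = series$wavelengths,
                   t(series$absorbance), check.names = FALSE)
  names(df)[-1] <- paste0("t", format(series$times, scientific = FALSE,
                                      trim = TRUE))
  utils::write.csv(df, path, row.names = FALSE)
  if (!is.null(series$truth)) {
    side <- series$truth
    side$C <- NULL; side$S <- NULL  # matrices stay in memory only
    jsonlite::write_json(c(list(compound_id = series$compound_id), side),
                         paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_spectral_series
#' @export
read_spectral_series <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1] != "wavelength_nm")
    stop("not a spectral series CSV: first column must be 'wavelength_nm'")
  times <- as.numeric(sub("^t", "", names(df)[-1]))
  if (anyNA(times)) stop("time columns must be named t<seconds>")
  keep <- df$wavelength_nm >= 215  # mirror the preprocessing window
  truth <- NULL
  side <- paste0(path, ".json")
  if (file.exists(side)) truth <- jsonlite::read_json(side, simplifyVector = TRUE)
  spectral_series(df$wavelength_nm[keep], times,
                  t(as.matrix(df[keep, -1, drop = FALSE])),
                  compound_id = if (!is.null(truth$compound_id))
                    truth$compound_id else basename(path),
                  truth = truth)
}
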