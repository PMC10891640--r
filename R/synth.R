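#' Gaussian band set for a pure component spectrum
#'
#' @param center Band centers (nm); must lie inside the wavelength grid
#'   the spectrum is later evaluated on.
#' @param width Band standard deviations (nm), > 0.
#' @param amplitude Peak absorbances (AU), > 0.
#' @return A data frame of bands, one row per Gaussian.
#' @export
spectral_bands <- function(center, width, amplitude) {
  df <- data.frame(center = as.numeric(center), width = as.numeric(width),
                   amplitude = as.numeric(amplitude))
  if (nrow(df) < 1) stop("at least one band is required")
  if (any(df$width <= 0)) stop("band widths must be > 0")
  if (any(df$amplitude <= 0)) stop("band amplitudes must be > 0")
  df
}

#' Evaluate a sum-of-Gaussians pure spectrum
#'
#' s(lambda) = sum_b amplitude_b * exp(-(lambda - center_b)^2 / (2 width_b^2)).
#'
#' @param bands A band set from [spectral_bands()] (or a data frame with
#'   columns `center`, `width`, `amplitude`).
#' @param wavelengths Strictly increasing evaluation grid (nm).
#' @return Non-negative numeric vector, one absorbance per wavelength.
#' @export
gaussian_spectrum <- function(bands, wavelengths) {
  if (is.null(dim(bands))) bands <- as.data.frame(as.list(bands))
  bands <- spectral_bands(bands$center, bands$width, bands$amplitude)
  wavelengths <- as.numeric(wavelengths)
  if (length(wavelengths) < 1 || any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly increasing")
  if (any(bands$center < min(wavelengths) | bands$center > max(wavelengths)))
    stop("band centers must lie within the wavelength grid")
  s <- numeric(length(wavelengths))
  for (b in seq_len(nrow(bands)))
    s <- s + bands$amplitude[b] *
      exp(-(wavelengths - bands$center[b])^2 / (2 * bands$width[b]^2))
  s
}

#' First-order photodegradation concentration profiles
#'
#' Closed-form solutions of the unimolecular schemes. `single` is
#' parent -> PhP1; `sequential` is parent -> PhP1 -> PhP2 with the
#' Bateman solution
#' `P1(t) = c0 k1/(k2 - k1) (exp(-k1 t) - exp(-k2 t))`.
#' Species always balance: every row sums to `c0` exactly.
#'
#' @param times Non-negative increasing times (s), first entry 0.
#' @param k1 Parent decay rate (s^-1), > 0.
#' @param k2 Secondary rate (s^-1) for the sequential scheme; must differ
#'   from `k1` (the analytic form is singular at `k2 == k1`).
#' @param c0 Initial parent concentration (arbitrary units).
#' @param scheme `"single"` (2 species) or `"sequential"` (3 species).
#' @return Matrix time x species with columns `parent`, `PhP1`
#'   (and `PhP2`).
#' @export
kinetic_profiles <- function(times, k1, k2 = NULL, c0 = 1,
                             scheme = c("single", "sequential")) {
  scheme <- match.arg(scheme)
  times <- as.numeric(times)
  if (length(times) < 1 || any(times < 0) || any(diff(times) <= 0) ||
      times[1] != 0)
    stop("times must be non-negative, increasing, and start at 0")
  if (!is.numeric(k1) || k1 <= 0) stop("k1 must be > 0")
  A <- c0 * exp(-k1 * times)
  if (scheme == "single") {
    out <- cbind(parent = A, PhP1 = c0 - A)
  } else {
    if (is.null(k2) || k2 <= 0) stop("sequential scheme needs k2 > 0")
    if (k2 == k1)
      stop("k2 must differ from k1: the sequential solution is singular at k2 == k1")
    P1 <- c0 * k1 / (k2 - k1) * (exp(-k1 * times) - exp(-k2 * times))
    out <- cbind(parent = A, PhP1 = P1, PhP2 = c0 - A - P1)
  }
  out
}

#' Simulate a bilinear spectral photodegradation series
#'
#' Builds `D = C S^T + E`: concentration profiles from
#' [kinetic_profiles()], pure spectra supplied as a matrix (wavelength x
#' species), and homoscedastic Gaussian noise whose SD is
#' `relative_sd * max|C S^T|`. The true `C`, `S` and rates are recorded in
#' the result's `truth` field for recovery tests.
#'
#' @param spectra Wavelength x species matrix of pure spectra (AU); column
#'   count must match the species count of the scheme.
#' @param wavelengths Wavelength grid (nm), default [default_wavelengths()].
#' @param times Time grid (s), default [default_times()].
#' @inheritParams kinetic_profiles
#' @param relative_sd Noise SD as a fraction of the global signal maximum
#'   (>= 0).
#' @param seed Integer seed; required whenever `relative_sd > 0` so every
#'   stochastic run is reproducible.
#' @param compound_id Label for the series.
#' @return A [spectral_series()] with `truth` attached.
#' @export
simulate_series <- function(spectra, k1, k2 = NULL, c0 = 1,
                            scheme = c("single", "sequential"),
                            wavelengths = default_wavelengths(),
                            times = default_times(),
                            relative_sd = 0, seed = NULL,
                            compound_id = "synthetic") {
  scheme <- match.arg(scheme)
  spectra <- as.matrix(spectra)
  n_species <- if (scheme == "single") 2L else 3L
  if (ncol(spectra) != n_species)
    stop(sprintf("spectra has %d columns but scheme '%s' has %d species",
                 ncol(spectra), scheme, n_species))
  if (nrow(spectra) != length(wavelengths))
    stop("spectra rows must match the wavelength grid")
  if (!is.numeric(relative_sd) || relative_sd < 0)
    stop("relative_sd must be >= 0")
  C <- kinetic_profiles(times, k1 = k1, k2 = k2, c0 = c0, scheme = scheme)
  D <- C %*% t(spectra)
  if (relative_sd > 0) {
    if (is.null(seed)) stop("a seed is required when relative_sd > 0")
    set.seed(seed)
    D <- D + matrix(stats::rnorm(length(D), sd = relative_sd * max(abs(D))),
                    nrow = nrow(D))
  }
  spectral_series(
    wavelengths, times, D, compound_id = compound_id,
    truth = list(C = C, S = spectra, k1 = k1, k2 = k2, c0 = c0,
                 scheme = scheme, relative_sd = relative_sd, seed = seed))
}

#' Simulate a dihydropyridine-like degradation series
#'
#' Convenience wrapper around [simulate_series()] with the spectral
#' signatures seen for this drug class: the parent absorbs near 360 nm
#' (the dihydropyridine band), the first photoproduct near 270 nm (the
#' aromatized pyridine), and an optional trace second photoproduct whose
#' amplitude defaults to 10% of the parent's.
#'
#' @inheritParams simulate_series
#' @param parent_center,product_center,product2_center Band centers (nm).
#' @param band_width Common Gaussian band SD (nm).
#' @param product_amplitude,product2_amplitude Peak absorbances relative
#'   to the parent's 1 AU.
#' @return A [spectral_series()] with ground truth attached.
#' @export
simulate_dhp_series <- function(k1, k2 = NULL,
                                scheme = if (is.null(k2)) "single" else "sequential",
                                relative_sd = 0, seed = NULL,
                                parent_center = 360, product_center = 270,
                                product2_center = 300, band_width = 20,
                                product_amplitude = 0.8,
                                product2_amplitude = 0.1,
                                wavelengths = default_wavelengths(),
                                times = default_times(),
                                compound_id = "synthetic-DHP") {
  S <- cbind(
    gaussian_spectrum(spectral_bands(parent_center, band_width, 1), wavelengths),
    gaussian_spectrum(spectral_bands(product_center, band_width,
                                     product_amplitude), wavelengths))
  if (scheme == "sequential")
    S <- cbind(S, gaussian_spectrum(
      spectral_bands(product2_center, band_width, product2_amplitude),
      wavelengths))
  simulate_series(S, k1 = k1, k2 = k2, scheme = scheme,
                  wavelengths = wavelengths, times = times,
                  relative_sd = relative_sd, seed = seed,
                  compound_id = compound_id)
}

#' Simulate a descriptor/response set with known sparse structure
#'
#' Draws a compound x descriptor matrix and a response
#' `y = intercept + sum(coef_j x_j) + N(0, noise_sd)` in which only the
#' listed columns carry signal, so selection and recovery can be tested
#' against a known generating model. Columns whose names match the packaged
#' descriptor table are drawn uniformly within that descriptor's observed
#' range; unnamed columns are standard normal.
#'
#' @param n_samples Number of compounds (>= 3, and at least two more than
#'   the number of informative columns).
#' @param n_descriptors Number of descriptor columns.
#' @param informative Numeric vector of true coefficients named by column
#'   index, e.g. `c("3" = 2, "10" = -1.5)`.
#' @param noise_sd Response noise SD (response units).
#' @param seed Integer seed (mandatory).
#' @param intercept True intercept.
#' @param descriptor_names Optional column names; names present in the
#'   packaged descriptor table trigger range-matched sampling.
#' @return List with `x` (matrix), `y` (vector) and `truth` (the
#'   generating model).
#' @export
simulate_qspr <- function(n_samples, n_descriptors, informative,
                          noise_sd = 0, seed, intercept = 0,
                          descriptor_names = NULL) {
  if (n_samples < 3) stop("n_samples must be >= 3")
  idx <- as.integer(names(informative))
  if (length(informative) && (anyNA(idx) || any(idx < 1) ||
                              any(idx > n_descriptors)))
    stop("informative indices must name columns 1..n_descriptors")
  if (n_samples < length(informative) + 2)
    stop("n_samples must exceed the informative count by at least 2")
  if (is.null(descriptor_names))
    descriptor_names <- paste0("V", seq_len(n_descriptors))
  set.seed(seed)
  ref <- load_fixture("table3")
  x <- matrix(NA_real_, n_samples, n_descriptors,
              dimnames = list(NULL, descriptor_names))
  for (j in seq_len(n_descriptors)) {
    nm <- descriptor_names[j]
    if (nm %in% names(ref)[-(1:2)]) {
      rng <- range(ref[[nm]])
      x[, j] <- stats::runif(n_samples, rng[1], rng[2])
    } else {
      x[, j] <- stats::rnorm(n_samples)
    }
  }
  beta <- numeric(n_descriptors)
  beta[idx] <- as.numeric(informative)
  y <- intercept + drop(x %*% beta) + stats::rnorm(n_samples, sd = noise_sd)
  list(x = x, y = y,
       truth = list(intercept = intercept, coefficients = beta,
                    informative = idx, noise_sd = noise_sd, seed = seed))
}
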