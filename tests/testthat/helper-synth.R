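# Shared helpers for the suite: a coarse wavelength grid keeps the ALS
# runs fast without changing any of the physics.

coarse_wl <- function() seq(215, 450, by = 5)

cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

# Independent fixed-step RK4 integrator for the sequential scheme
# A -> P1 -> P2; used as the oracle for the closed-form profiles.
rk4_sequential <- function(k1, k2, times, c0 = 1, dt = 1e-3) {
  deriv <- function(y) c(-k1 * y[1], k1 * y[1] - k2 * y[2], k2 * y[2])
  out <- matrix(NA_real_, length(times), 3)
  y <- c(c0, 0, 0)
  t_now <- 0
  for (i in seq_along(times)) {
    while (t_now < times[i] - 1e-12) {
      h <- min(dt, times[i] - t_now)
      K1 <- deriv(y); K2 <- deriv(y + h / 2 * K1)
      K3 <- deriv(y + h / 2 * K2); K4 <- deriv(y + h * K3)
      y <- y + h / 6 * (K1 + 2 * K2 + 2 * K3 + K4)
      t_now <- t_now + h
    }
    out[i, ] <- y
  }
  out
}

two_band_spectra <- function(wl = coarse_wl(), width = 20, amp2 = 0.8) {
  cbind(gaussian_spectrum(spectral_bands(360, width, 1), wl),
        gaussian_spectrum(spectral_bands(270, width, amp2), wl))
}
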