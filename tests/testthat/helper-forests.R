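# Shared synthetic study conditions used across test files.

# Strip the (informative) year axis so cross-dating has to recover offsets.
blind_axes <- function(series) {
  lapply(series, function(s) {
    s$first_year <- 1L
    s
  })
}

# Offset-recovery experiment: six trees with known start-year shifts, two
# radii each, moderate shared signal and red noise, plus shared marker years.
recovery_config <- function(seed) {
  forest_config(
    n_trees = 6L, years = 80L, radii_per_tree = 2L,
    offsets = c(0L, 5L, 10L, 15L, 20L, 25L),
    signal_gain = 0.5, noise_sd = 0.3, ar1_phi = 0.4,
    marker_years = data.frame(year = seq(12, 100, by = 17),
                              multiplier = rep(c(0.45, 1.6), length.out = 6)),
    seed = seed)
}

# Growth-response experiment: a skewed 30-yr oscillation (phase-aligned first
# harmonic) coupled into growth with sign `gain`. A symmetric sinusoid is
# sign-blind for the suppressed/enhanced statistic (exp(gC) and exp(-gC) are
# the same waveform half a period apart), so sign recovery requires waveform
# asymmetry -- sharp adverse years, the realistic case for stressed trees.
growth_config <- function(seed, gain) {
  forest_config(
    n_trees = 6L, years = 238L, radii_per_tree = 2L,
    climate_signal = list(list(period = 30, amplitude = 1.0, phase = 0),
                          list(period = 15, amplitude = 0.5, phase = 0)),
    climate_noise_sd = 0.3, ar1_phi = 0.3, noise_sd = 0.25,
    signal_gain = gain, seed = seed)
}

growth_suppressed_fraction <- function(seed, gain, band = c(20, 40)) {
  f <- simulate_forest(growth_config(seed, gain))
  ch <- build_chronology(f$series)
  dog <- cwt(ch$rwi, "dog", times = ch$years)
  dog <- rednoise_significance(dog, level = 0.05)
  gr <- growth_response(ch, dog, band = band)
  gr$suppressed_fraction
}

# Direct time-domain convolution oracle for the CWT (circular convolution on
# the padded grid with the periodized, time-sampled analytic wavelet).
cwt_direct <- function(x, family, dj = 1 / 16, s0 = 4, dt = 1, reps = 8) {
  n <- length(x)
  x0 <- (x - mean(x)) / sd(x)
  npad <- 2^ceiling(log2(n))
  xp <- c(x0, rep(0, npad - n))
  ff <- if (family == "morlet") 4 * pi / (6 + sqrt(38)) else 2 * pi / sqrt(2.5)
  J <- floor(log2(n * dt / (ff * s0)) / dj)
  scales <- s0 * 2^((0:J) * dj)
  psi0 <- function(eta) {
    if (family == "morlet")
      pi^(-1 / 4) * (exp(1i * 6 * eta) - exp(-18)) * exp(-eta^2 / 2)
    else (1 - eta^2) * exp(-eta^2 / 2) / sqrt(gamma(2.5))
  }
  offs <- 0:(npad - 1)
  W <- matrix(0 + 0i, length(scales), n)
  for (j in seq_along(scales)) {
    s <- scales[j]
    kern <- rep(0 + 0i, npad)
    for (r in -reps:reps) kern <- kern + psi0((offs + r * npad) * dt / s)
    for (t in 1:n)
      W[j, t] <- sqrt(dt / s) * sum(xp * Conj(kern[((offs - (t - 1)) %% npad) + 1]))
  }
  list(W = W, scales = scales, fourier_periods = ff * scales)
}

# Minimal hand-built DOG spectrum carrying an arbitrary significance mask,
# for tests that exercise the coincidence statistic in isolation.
fake_dog_spectrum <- function(years, periods, signif_mask) {
  structure(
    list(times = years, scales = periods / (2 * pi / sqrt(2.5)),
         fourier_periods = periods,
         coi = rep(max(periods) * 2, length(years)),
         signif_mask = signif_mask,
         wavelet = list(family = "dog", param = 2),
         n = length(years)),
    class = "wavelet_spectrum")
}
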