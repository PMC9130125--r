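## Wavelet descriptors ------------------------------------------------------

wavelet_desc <- function(family = c("morlet", "dog"), param = NULL) {
  family <- match.arg(family)
  if (is.null(param)) param <- if (family == "morlet") 6 else 2
  if (family == "morlet" && param != 6)
    stop("only the Morlet(6) wavelet is supported", call. = FALSE)
  if (family == "dog" && param != 2)
    stop("only the DOG(2) wavelet is supported", call. = FALSE)
  list(family = family, param = param)
}

## Ratio of Fourier period to scale.
fourier_factor <- function(wavelet) {
  if (wavelet$family == "morlet") {
    w0 <- wavelet$param
    4 * pi / (w0 + sqrt(2 + w0^2))
  } else {
    2 * pi / sqrt(wavelet$param + 0.5)
  }
}

## Frequency-domain mother wavelet at scale s (Torrence--Compo
## normalization excluded; multiply by sqrt(2*pi*s/dt) at use site).
psi_hat <- function(wavelet, s, omega) {
  if (wavelet$family == "morlet") {
    # exact admissible (zero-mean) Morlet spectrum, no positive-frequency
    # truncation: for w0 = 6 it differs from the truncated plane-wave form
    # by < 1.5e-8 but is the exact Fourier transform of the time-domain
    # wavelet, so frequency- and time-domain implementations agree
    w0 <- wavelet$param
    pi^(-1 / 4) * (exp(-(s * omega - w0)^2 / 2) -
                     exp(-w0^2 / 2) * exp(-(s * omega)^2 / 2))
  } else {
    m <- wavelet$param  # even m: -(i^m) = +1, real spectrum
    (s * omega)^m * exp(-(s * omega)^2 / 2) / sqrt(gamma(m + 0.5))
  }
}

## Degrees of freedom of single-cell wavelet power.
wavelet_dof <- function(wavelet) if (wavelet$family == "morlet") 2 else 1

## CWT -----------------------------------------------------------------------

#' Continuous wavelet transform with cone of influence
#'
#' FFT implementation of the continuous wavelet transform: the series is
#' mean-removed and variance-normalized (so power is in units of the series
#' variance), zero-padded to the next power of two, and convolved in the
#' frequency domain with the scaled wavelet,
#' `W(s, t) = ifft( fft(x) * Conj(sqrt(2 pi s / dt) * psi_hat(s w_k)) )`.
#' Scales form a dyadic grid `s_j = s0 * 2^(j * dj)` with `1/dj` voices per
#' octave, extended until the largest Fourier period reaches the series
#' length. The cone of influence is the e-folding period `sqrt(2) * s`
#' mapped to Fourier period, symmetric about the series midpoint; padded
#' regions only affect coefficients outside it.
#'
#' @param x Numeric series (finite, length >= 16), one value per year.
#' @param wavelet `"morlet"` (omega0 = 6; complex, best frequency
#'   resolution) or `"dog"` (2nd-derivative-of-Gaussian; real, time-aligned
#'   coefficients directly comparable to the input year by year).
#' @param dj Scale resolution in octaves (default 1/16: 16 voices per
#'   octave).
#' @param s0 Smallest scale, in sampling intervals (default `2 * dt`).
#' @param dt Sampling interval in years.
#' @param pad Zero-pad to the next power of two (recommended).
#' @param times Optional year axis (length of `x`).
#' @return Object of class `wavelet_spectrum`: `times`, `scales`,
#'   `fourier_periods`, `coef` (scale x time matrix, complex for Morlet,
#'   real for DOG), `power` (|W|^2 in variance units), `coi` (per-time
#'   e-folding period), `wavelet`, `dj`, `s0`, `dt`, `variance`,
#'   `x_norm` (the normalized input, kept for surrogate-based significance).
#' @export
cwt <- function(x, wavelet = c("morlet", "dog"), dj = 1 / 16, s0 = 2,
                dt = 1, pad = TRUE, times = NULL) {
  if (!is.numeric(x) || !all(is.finite(x)))
    stop("input series must be finite numeric", call. = FALSE)
  n <- length(x)
  if (n < 16L) stop("series too short for CWT (need >= 16)", call. = FALSE)
  wl <- if (is.list(wavelet)) wavelet else wavelet_desc(match.arg(wavelet))
  if (is.null(times)) times <- seq_len(n) * dt
  sigma2 <- var(x)
  # a constant series carries no oscillation: mean removal leaves zeros and
  # every coefficient is exactly 0 (variance normalization is skipped)
  x0 <- if (sigma2 == 0) x * 0 else (x - mean(x)) / sqrt(sigma2)

  npad <- if (pad) 2^ceiling(log2(n)) else n
  xhat <- fft(c(x0, rep(0, npad - n)))
  k <- 0:(npad - 1)
  k[k > npad / 2] <- k[k > npad / 2] - npad
  omega <- 2 * pi * k / (npad * dt)

  ff <- fourier_factor(wl)
  J <- floor(log2(n * dt / (ff * s0)) / dj)
  if (J < 1) stop("series too short for the requested s0/dj", call. = FALSE)
  scales <- s0 * 2^((0:J) * dj)

  W <- matrix(0 + 0i, nrow = length(scales), ncol = n)
  for (j in seq_along(scales)) {
    s <- scales[j]
    filt <- sqrt(2 * pi * s / dt) * psi_hat(wl, s, omega)
    w_full <- fft(xhat * Conj(filt), inverse = TRUE) / npad
    W[j, ] <- w_full[seq_len(n)]
  }
  if (wl$family == "dog") W <- matrix(complex(real = Re(W)), nrow = nrow(W))

  coi <- ff * sqrt(2) * dt * pmax(pmin(seq_len(n) - 1, n - seq_len(n)), 1e-5)
  structure(
    list(times = times, scales = scales, fourier_periods = ff * scales,
         coef = W, power = Mod(W)^2, coi = coi, wavelet = wl,
         dj = dj, s0 = s0, dt = dt, n = n, variance = sigma2, x_norm = x0),
    class = "wavelet_spectrum")
}

#' @export
print.wavelet_spectrum <- function(x, ...) {
  cat(sprintf("<wavelet_spectrum: %s, %d scales (periods %.1f..%.1f yr) x %d times, %d voices/octave>\n",
              x$wavelet$family, length(x$scales), min(x$fourier_periods),
              max(x$fourier_periods), x$n, round(1 / x$dj)))
  invisible(x)
}

#' In-cone-of-influence indicator matrix
#'
#' @param spec A `wavelet_spectrum` (or `coherence_spectrum`).
#' @return Logical scale x time matrix, `TRUE` where the Fourier period is
#'   shorter than the cone of influence (edge effects negligible).
#' @export
coi_mask <- function(spec) {
  outer(spec$fourier_periods, spec$coi, `<`)
}

## AR(1) ----------------------------------------------------------------------

#' Lag-1 autocorrelation (red-noise parameter) of a series
#'
#' @param x Numeric series, length >= 16, non-constant.
#' @return Lag-1 autocorrelation estimate, floored at 0 (red-noise nulls are
#'   defined for non-negative alpha).
#' @export
ar1_estimate <- function(x) {
  if (length(x) < 16L) stop("need >= 16 values", call. = FALSE)
  if (sd(x) == 0) stop("zero-variance series", call. = FALSE)
  n <- length(x)
  x <- x - mean(x)
  a <- sum(x[-1] * x[-n]) / sum(x^2)
  max(a, 0)
}

#' Simulate a unit-variance AR(1) (red-noise) series
#'
#' @param n Length.
#' @param alpha Lag-1 coefficient in `[0, 1)`.
#' @return Numeric vector with marginal variance 1.
#' @export
ar1_surrogate <- function(n, alpha) {
  ar1_noise(n, alpha, 1)
}

## Red-noise significance ------------------------------------------------------

#' Red-noise significance of wavelet power
#'
#' Tests each cell of the power matrix against the null hypothesis of an
#' AR(1) (red-noise) background. `method = "theoretical"` uses the discrete
#' red-noise spectrum at each scale's equivalent Fourier frequency,
#' `P(f) = (1 - a^2) / (1 + a^2 - 2 a cos(2 pi f dt))`, and flags power
#' exceeding `P * chisq_(1-level)(nu) / nu` with `nu = 2` for the complex
#' Morlet and `nu = 1` for the real DOG. `method = "montecarlo"` instead
#' flags power above the per-scale `(1 - level)` quantile over `n_sim` AR(1)
#' surrogates with matched alpha and unit variance.
#'
#' @param spec A [cwt()] result.
#' @param alpha AR(1) lag-1 coefficient of the null; default estimated from
#'   the (normalized) input series.
#' @param level Significance level in `(0, 1)`.
#' @param method `"theoretical"` or `"montecarlo"`.
#' @param n_sim Number of surrogates for the Monte-Carlo method; below 100 a
#'   warning is recorded in the output.
#' @param seed Seed for the Monte-Carlo surrogates.
#' @return The spectrum with fields added: `signif_mask` (logical matrix),
#'   `signif_level` (per-scale threshold in variance units), `ar1_alpha`,
#'   `level`, `signif_method`, and `warnings`.
#' @export
rednoise_significance <- function(spec, alpha = NULL, level = 0.05,
                                  method = c("theoretical", "montecarlo"),
                                  n_sim = 1000L, seed = 1L) {
  method <- match.arg(method)
  if (!(level > 0 && level < 1)) stop("level must be in (0, 1)", call. = FALSE)
  if (is.null(alpha)) alpha <- ar1_estimate(spec$x_norm)
  warnings <- character(0)

  if (method == "theoretical") {
    freq <- spec$dt / spec$fourier_periods  # cycles per sampling interval
    Pk <- (1 - alpha^2) / (1 + alpha^2 - 2 * alpha * cos(2 * pi * freq))
    dof <- wavelet_dof(spec$wavelet)
    thr <- Pk * qchisq(1 - level, dof) / dof
  } else {
    if (n_sim < 100) {
      warnings <- c(warnings, sprintf(
        "montecarlo significance with n_sim = %d (< 100) is unstable", n_sim))
    }
    old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
    })
    set.seed(as.integer(seed))
    inmask <- coi_mask(spec)
    # pool in-COI power per scale over all surrogates, take the quantile
    pooled <- matrix(NA_real_, nrow = length(spec$scales),
                     ncol = spec$n * n_sim)
    for (b in seq_len(n_sim)) {
      xs <- ar1_surrogate(spec$n, alpha)
      sp <- cwt(xs, spec$wavelet, dj = spec$dj, s0 = spec$s0, dt = spec$dt)
      pw <- sp$power
      pw[!inmask] <- NA
      pooled[, ((b - 1) * spec$n + 1):(b * spec$n)] <- pw
    }
    thr <- apply(pooled, 1, stats::quantile, probs = 1 - level, na.rm = TRUE)
  }
  spec$signif_mask <- spec$power > matrix(thr, nrow = length(spec$scales),
                                          ncol = spec$n)
  spec$signif_level <- thr
  spec$ar1_alpha <- alpha
  spec$level <- level
  spec$signif_method <- method
  spec$warnings <- warnings
  spec
}

## Cross-wavelet and coherence --------------------------------------------------

check_same_grid <- function(a, b) {
  if (!isTRUE(all.equal(a$scales, b$scales)) ||
      length(a$times) != length(b$times) ||
      !isTRUE(all.equal(a$times, b$times)) ||
      a$wavelet$family != b$wavelet$family)
    stop("spectra are not on matched time/scale grids", call. = FALSE)
}

#' Cross-wavelet transform
#'
#' `W_XY = W_X * Conj(W_Y)`: cross-power `|W_XY|` measures common power,
#' the phase `arg(W_XY)` the local phase relation (0 = in phase / positive
#' correlation, pi = antiphase / negative correlation; intermediate angles
#' indicate lead/lag).
#'
#' @param spec_x,spec_y [cwt()] results on identical grids.
#' @return List of class `cross_spectrum`: `times`, `scales`,
#'   `fourier_periods`, `wxy` (complex), `cross_power`, `phase`, `coi`
#'   (pointwise minimum of the two cones).
#' @export
xwt <- function(spec_x, spec_y) {
  check_same_grid(spec_x, spec_y)
  wxy <- spec_x$coef * Conj(spec_y$coef)
  structure(
    list(times = spec_x$times, scales = spec_x$scales,
         fourier_periods = spec_x$fourier_periods, wxy = wxy,
         cross_power = Mod(wxy), phase = Arg(wxy),
         coi = pmin(spec_x$coi, spec_y$coi)),
    class = "cross_spectrum")
}

## Gaussian time smoothing (std = s at each scale) with edge renormalization.
smooth_time <- function(M, scales, dt) {
  n <- ncol(M)
  out <- M
  for (j in seq_len(nrow(M))) {
    sj <- scales[j] / dt
    half <- max(1L, ceiling(4 * sj))
    k <- exp(-((-half:half)^2) / (2 * sj^2))
    row <- M[j, ]
    num <- conv_same(row, k)
    den <- conv_same(rep(1, n), k)
    out[j, ] <- num / den
  }
  out
}

## "Same"-mode linear convolution of x (possibly complex) with kernel k
## (odd length), via padded FFT.
conv_same <- function(x, k) {
  n <- length(x); m <- length(k); half <- (m - 1L) %/% 2L
  L <- 2^ceiling(log2(n + m))
  fx <- fft(c(x, rep(0, L - n)))
  fk <- fft(c(k, rep(0, L - m)))
  full <- fft(fx * fk, inverse = TRUE) / L
  res <- full[(half + 1L):(half + n)]
  if (is.complex(x)) res else Re(res)
}

## Boxcar scale smoothing over ~0.6 octave with edge renormalization.
smooth_scale <- function(M, dj, octaves = 0.6) {
  nv <- max(1L, round(octaves / dj))
  if (nv %% 2L == 0L) nv <- nv + 1L
  ns <- nrow(M)
  out <- M
  for (j in seq_len(ns)) {
    idx <- max(1L, j - (nv - 1L) %/% 2L):min(ns, j + (nv - 1L) %/% 2L)
    out[j, ] <- colMeans(M[idx, , drop = FALSE])
  }
  out
}

#' Wavelet coherence of two series
#'
#' Squared wavelet coherence
#' `R^2 = |S(W_XY / s)|^2 / ( S(|W_X|^2 / s) * S(|W_Y|^2 / s) )`
#' where `S` is Gaussian smoothing in time (standard deviation equal to the
#' scale) followed by boxcar smoothing over 0.6 octave in scale — a
#' localized, normalized correlation in time-scale space, in `[0, 1]`
#' regardless of power. Significance is assessed by Monte Carlo against
#' AR(1) surrogate pairs with the two series' estimated lag-1 coefficients:
#' a per-scale `(1 - level)` quantile of surrogate coherence inside the cone
#' of influence gives the cell mask, and the same construction on the
#' COI-interior time-average gives per-period significance of the mean
#' coherence.
#'
#' @param x,y Numeric series of equal length (Morlet spectra are computed
#'   internally; coherence smoothing is defined for the Morlet wavelet).
#' @param dj,s0,dt,pad Passed to [cwt()].
#' @param level Significance level.
#' @param n_sim Number of AR(1) surrogate pairs.
#' @param seed Seed for the surrogates.
#' @param smooth Must remain `TRUE`: unsmoothed coherence is identically 1.
#' @return Object of class `coherence_spectrum`: `times`, `scales`,
#'   `fourier_periods`, `coherence`, `phase`, `cross_power`, `signif_mask`,
#'   `coi`, `mean_coherence_by_period` (data.frame `period`,
#'   `mean_coherence`, `q_null`, `significant`), `level`, `n_sim`.
#' @export
wavelet_coherence <- function(x, y, dj = 1 / 16, s0 = 2, dt = 1, pad = TRUE,
                              level = 0.05, n_sim = 300L, seed = 1L,
                              smooth = TRUE) {
  if (!isTRUE(smooth))
    stop("unsmoothed coherence is identically 1; smoothing cannot be disabled",
         call. = FALSE)
  if (length(x) != length(y)) stop("series lengths differ", call. = FALSE)

  base <- function(xx, yy) {
    sx <- cwt(xx, "morlet", dj = dj, s0 = s0, dt = dt, pad = pad)
    sy <- cwt(yy, "morlet", dj = dj, s0 = s0, dt = dt, pad = pad)
    inv_s <- 1 / sx$scales
    wxy <- sweep(sx$coef * Conj(sy$coef), 1, inv_s, `*`)
    px <- sweep(Mod(sx$coef)^2, 1, inv_s, `*`)
    py <- sweep(Mod(sy$coef)^2, 1, inv_s, `*`)
    Sxy <- smooth_scale(smooth_time(wxy, sx$scales, dt), dj)
    Sx <- smooth_scale(smooth_time(px, sx$scales, dt), dj)
    Sy <- smooth_scale(smooth_time(py, sx$scales, dt), dj)
    r2 <- Mod(Sxy)^2 / (Sx * Sy)
    list(sx = sx, sy = sy, r2 = pmin(pmax(r2, 0), 1), sxy = Sxy)
  }

  obs <- base(x, y)
  spec <- obs$sx
  inmask <- coi_mask(spec)
  mean_coh <- rowSums(obs$r2 * inmask) / pmax(rowSums(inmask), 1)

  alpha_x <- ar1_estimate(x)
  alpha_y <- ar1_estimate(y)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(as.integer(seed))
  ns <- length(spec$scales)
  pooled <- matrix(NA_real_, nrow = ns, ncol = spec$n * n_sim)
  mean_q <- matrix(0, nrow = ns, ncol = n_sim)
  for (b in seq_len(n_sim)) {
    sim <- base(ar1_surrogate(spec$n, alpha_x), ar1_surrogate(spec$n, alpha_y))
    r2 <- sim$r2
    mean_q[, b] <- rowSums(r2 * inmask) / pmax(rowSums(inmask), 1)
    r2[!inmask] <- NA
    pooled[, ((b - 1) * spec$n + 1):(b * spec$n)] <- r2
  }
  thr_cell <- apply(pooled, 1, stats::quantile, probs = 1 - level, na.rm = TRUE)
  thr_mean <- apply(mean_q, 1, stats::quantile, probs = 1 - level)

  xw <- xwt(obs$sx, obs$sy)
  structure(
    list(times = spec$times, scales = spec$scales,
         fourier_periods = spec$fourier_periods,
         coherence = obs$r2, phase = Arg(obs$sxy),
         cross_power = xw$cross_power,
         signif_mask = obs$r2 > matrix(thr_cell, ns, spec$n),
         coi = xw$coi,
         mean_coherence_by_period = data.frame(
           period = spec$fourier_periods,
           mean_coherence = mean_coh,
           q_null = thr_mean,
           significant = mean_coh > thr_mean),
         ar1_alpha = c(x = alpha_x, y = alpha_y),
         level = level, n_sim = n_sim, n = spec$n),
    class = "coherence_spectrum")
}
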