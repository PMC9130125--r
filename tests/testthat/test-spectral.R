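test_that("a pure cosine puts the global power maximum at its period", {
  t <- 1:238
  sp <- cwt(cos(2 * pi * t / 30), "morlet")
  pk <- sp$fourier_periods[which.max(rowMeans(sp$power))]
  # the dyadic grid holds a period within half a voice of any target
  expect_lt(abs(log2(pk / 30)), 1 / 32 + 1e-9)
  expect_true(all(diff(sp$fourier_periods) > 0))
  expect_lte(max(sp$fourier_periods), 238)
})

test_that("a constant series has exactly zero power everywhere", {
  sp <- cwt(rep(2.5, 64), "morlet")
  expect_true(all(sp$power == 0))
})

test_that("power is invariant to offset and to input rescaling", {
  set.seed(2)
  x <- rnorm(128)
  p0 <- cwt(x, "morlet")$power
  expect_equal(cwt(x + 100, "morlet")$power, p0, tolerance = 1e-9)
  expect_equal(cwt(3 * x, "morlet")$power, p0, tolerance = 1e-9)
})

test_that("the cone of influence is symmetric and grows linearly from edges", {
  sp <- cwt(rnorm(100), "morlet")
  expect_equal(sp$coi, rev(sp$coi))
  ff <- 4 * pi / (6 + sqrt(38))
  expect_equal(sp$coi[11], ff * sqrt(2) * 10)
  expect_equal(sp$coi[50], ff * sqrt(2) * 49)
})

test_that("DOG(2) coefficients are real and flip sign with the input", {
  set.seed(3)
  x <- rnorm(64)
  a <- cwt(x, "dog"); b <- cwt(-x, "dog")
  expect_true(all(Im(a$coef) == 0))
  expect_equal(Re(b$coef), -Re(a$coef), tolerance = 1e-12)
})

test_that("rectified wavelet power satisfies a Parseval-style identity", {
  set.seed(5)
  # the identity is exact for the cyclic transform; zero padding deliberately
  # sheds edge power (quantified by the COI), so it is disabled here
  for (x in list(rnorm(238), cos(2 * pi * (1:238) / 30) + rnorm(238, sd = 0.5))) {
    sp <- cwt(x, "morlet", pad = FALSE)
    recon <- sum(sweep(sp$power, 1, sp$scales, "/")) * sp$dj * sp$dt /
      (0.776 * sp$n)
    expect_lt(abs(recon - 1), 0.1)  # power is in variance units
  }
})

test_that("invalid CWT input is rejected", {
  expect_error(cwt(c(rnorm(30), NA)), "finite")
  expect_error(cwt(rnorm(10)), "too short")
})

test_that("lag-1 autocorrelation estimation is calibrated", {
  set.seed(6)
  expect_lt(abs(ar1_estimate(rnorm(10000))), 0.05)
  expect_lt(abs(ar1_estimate(ar1_surrogate(10000, 0.7)) - 0.7), 0.05)
  expect_equal(ar1_estimate(ar1_surrogate(2000, 0)) >= 0, TRUE)  # floored
  expect_error(ar1_estimate(rep(1, 50)), "variance")
})

test_that("white-noise background reduces to the flat chi-square threshold", {
  sp <- cwt(rnorm(128), "morlet")
  sp <- rednoise_significance(sp, alpha = 0, level = 0.05)
  expect_equal(sp$signif_level,
               rep(qchisq(0.95, 2) / 2, length(sp$scales)), tolerance = 1e-12)
  spd <- rednoise_significance(cwt(rnorm(128), "dog"), alpha = 0)
  expect_equal(spd$signif_level,
               rep(qchisq(0.95, 1), length(spd$scales)), tolerance = 1e-12)
})

test_that("Monte-Carlo and theoretical masks agree on most in-COI cells", {
  set.seed(9)
  x <- ar1_surrogate(128, 0.4)
  th <- rednoise_significance(cwt(x, "morlet"), alpha = 0.4,
                              method = "theoretical")
  mc <- rednoise_significance(cwt(x, "morlet"), alpha = 0.4,
                              method = "montecarlo", n_sim = 500, seed = 30)
  m <- coi_mask(th)
  agree <- mean(th$signif_mask[m] == mc$signif_mask[m])
  expect_gt(agree, 0.9)
  expect_length(mc$warnings, 0)
  small <- rednoise_significance(cwt(x, "morlet"), alpha = 0.4,
                                 method = "montecarlo", n_sim = 50, seed = 1)
  expect_match(small$warnings, "unstable")
})

test_that("significance is never claimed where power is zero", {
  sp <- rednoise_significance(cwt(rep(1, 64)), alpha = 0)
  expect_false(any(sp$signif_mask))
})

test_that("cross-wavelet phase encodes sign and lag of the covariance", {
  t <- 1:128
  x <- cos(2 * pi * t / 16) + 0.1 * sin(2 * pi * t / 5)
  sx <- cwt(x, "morlet")
  sy <- cwt(x, "morlet")
  xw <- xwt(sx, sy)
  j <- which.min(abs(xw$fourier_periods - 16))
  expect_equal(max(abs(xw$phase[j, 30:100])), 0, tolerance = 1e-8)
  expect_equal(xw$cross_power, sx$power, tolerance = 1e-9)

  sneg <- cwt(-x, "morlet")
  xw2 <- xwt(sx, sneg)
  expect_equal(median(abs(xw2$phase[j, 30:100])), pi, tolerance = 1e-6)

  # quarter-period delay at the signal scale -> phase ~ +- pi/2
  y <- cos(2 * pi * (t - 4) / 16) + 0.1 * sin(2 * pi * (t - 4) / 5)
  xw3 <- xwt(sx, cwt(y, "morlet"))
  expect_equal(median(abs(xw3$phase[j, 30:100])), pi / 2, tolerance = 0.1)

  short <- cwt(rnorm(64), "morlet")
  expect_error(xwt(sx, short), "matched")
})

test_that("coherence of a series with itself is 1 and smoothing is mandatory", {
  set.seed(12)
  x <- rnorm(64)
  coh <- wavelet_coherence(x, x, n_sim = 20, seed = 2)
  expect_gt(min(coh$coherence), 0.999)
  expect_error(wavelet_coherence(x, x, smooth = FALSE), "identically 1")
  expect_error(wavelet_coherence(x, rnorm(32)), "lengths differ")
})

test_that("independent red-noise pairs show low, rarely significant coherence", {
  set.seed(13)
  x <- ar1_surrogate(128, 0.4); y <- ar1_surrogate(128, 0.4)
  coh <- wavelet_coherence(x, y, n_sim = 120, seed = 3)
  m <- coi_mask(coh)
  expect_lt(mean(coh$coherence[m]), 0.5)
  expect_lt(mean(coh$mean_coherence_by_period$significant), 0.25)
})

test_that("cross-wavelet power normalization matches the single spectra", {
  # |W_XY| of a series with itself equals its power (variance units)
  set.seed(14)
  x <- rnorm(80)
  sx <- cwt(x, "morlet")
  xw <- xwt(sx, sx)
  expect_equal(xw$cross_power, sx$power, tolerance = 1e-9)
})
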