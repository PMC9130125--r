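test_that("noise-free flat growth yields exactly unit widths", {
  cfg <- forest_config(n_trees = 2, years = 30,
                       age_trend = list(w0 = 1, decay = 0, floor = 0.5),
                       signal_gain = 0, noise_sd = 0, climate_noise_sd = 0)
  f <- simulate_forest(cfg)
  for (s in f$series) expect_equal(s$widths, rep(1, 30))
})

test_that("fixed seed reproduces the forest exactly; seeds differ", {
  f1 <- simulate_forest(forest_config(seed = 11))
  f2 <- simulate_forest(forest_config(seed = 11))
  f3 <- simulate_forest(forest_config(seed = 12))
  expect_identical(f1$series, f2$series)
  expect_identical(f1$true_climate, f2$true_climate)
  expect_false(identical(f1$series[[1]]$widths, f3$series[[1]]$widths))
})

test_that("with no radius noise and no offsets all radii are identical", {
  f <- simulate_forest(forest_config(n_trees = 3, radii_per_tree = 3,
                                     years = 40, noise_sd = 0, seed = 2))
  w1 <- f$series[[1]]$widths
  for (s in f$series) {
    expect_equal(s$widths, w1)
    expect_identical(s$first_year, 1L)
  }
})

test_that("offsets shift the year axis and are echoed as recoverable truth", {
  f <- simulate_forest(forest_config(n_trees = 3, years = 25,
                                     offsets = c(4L, 0L, 10L), seed = 5))
  expect_equal(unname(f$true_offsets), c(4, 0, 10))
  expect_equal(f$series[[1]]$first_year, 5L)  # normalized so min offset -> year 1
  expect_equal(f$true_span, 35L)
})

test_that("marker years multiply widths of all trees after noise", {
  mk <- data.frame(year = c(10, 20), multiplier = c(0.5, 2))
  base <- forest_config(n_trees = 2, years = 30, noise_sd = 0,
                        climate_noise_sd = 0, signal_gain = 0,
                        age_trend = list(w0 = 1, decay = 0, floor = 0.5))
  with_mk <- simulate_forest(do.call(forest_config, modifyList(
    unclass(base), list(marker_years = mk))))
  for (s in with_mk$series) {
    expect_equal(s$widths[10], 0.5)
    expect_equal(s$widths[20], 2)
    expect_equal(s$widths[15], 1)
  }
})

test_that("per-radius AR(1) noise has the configured lag-1 autocorrelation", {
  # 200 radii of 150 rings; with gain = 0 and a flat trend, log width is the
  # noise process itself
  phi <- 0.5
  f <- simulate_forest(forest_config(
    n_trees = 100, radii_per_tree = 2, years = 150,
    age_trend = list(w0 = 1, decay = 0, floor = 0.1),
    signal_gain = 0, noise_sd = 0.3, ar1_phi = phi, seed = 31))
  a1 <- vapply(f$series, function(s) ar1_estimate(log(s$widths)), numeric(1))
  expect_lt(abs(mean(a1) - phi), 0.05)
})

test_that("invalid forest configurations are rejected", {
  expect_error(forest_config(n_trees = 1), "n_trees")
  expect_error(forest_config(years = 19), "years")
  expect_error(forest_config(ar1_phi = 1), "ar1_phi")
  expect_error(forest_config(age_trend = list(w0 = -1, decay = 0, floor = 0.1)),
               "age_trend")
  expect_error(forest_config(marker_years = data.frame(year = 1, multiplier = 0)),
               "multiplier")
})

test_that("all simulated widths are strictly positive and finite", {
  for (seed in 1:5) {
    f <- simulate_forest(forest_config(seed = seed, noise_sd = 0.6,
                                       signal_gain = 1))
    w <- unlist(lapply(f$series, `[[`, "widths"))
    expect_true(all(is.finite(w) & w > 0))
  }
})

test_that("zero-gradient zero-noise paleosol is chemically uniform", {
  prof <- simulate_paleosol(n_horizons = 4, weathering_gradient = c(0, 0, 0),
                            noise_sd = 0, seed = 1)
  ox <- prof$horizons[, c("Al2O3", "CaO", "Na2O", "K2O", "MgO", "MnO")]
  for (j in seq_len(ncol(ox))) expect_equal(ox[[j]], rep(ox[[j]][1], 4))
  qc <- profile_qc(prof)
  expect_equal(qc$ciak_contrast_percent, 0)
  expect_false(qc$passes)
})

test_that("requested CIA-K increments are exact in the emitted chemistry", {
  prof <- simulate_paleosol(n_horizons = 3, weathering_gradient = c(6, 3),
                            noise_sd = 0, seed = 1)
  ciak <- vapply(seq_len(3), function(i)
    cia_k(to_molar(unlist(prof$horizons[i, c("Al2O3", "CaO", "Na2O",
                                             "K2O", "MgO", "MnO")]))),
    numeric(1))
  expect_equal(ciak[1] - ciak[3], 6, tolerance = 1e-10)
  expect_equal(ciak[2] - ciak[3], 3, tolerance = 1e-10)
  expect_true(profile_qc(prof)$passes)  # > 5% rule from a 4.5-point mean rise
})

test_that("impossible paleosol chemistry is rejected", {
  expect_error(simulate_paleosol(parent_chem = c(Al2O3 = -1, CaO = 3, Na2O = 2,
                                                 K2O = 2, MgO = 2, MnO = 0.1)),
               "finite and >= 0")
  expect_error(simulate_paleosol(n_horizons = 3,
                                 weathering_gradient = c(80, 10)),
               "outside")
  expect_error(simulate_paleosol(n_horizons = 1), "at least 2")
})

test_that("paleosol simulation is deterministic given the seed", {
  p1 <- simulate_paleosol(seed = 9)
  p2 <- simulate_paleosol(seed = 9)
  expect_identical(p1, p2)
})
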