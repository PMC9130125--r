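oxides <- c("Al2O3", "CaO", "Na2O", "K2O", "MgO", "MnO")

test_that("molar conversion divides by the oxide molar masses", {
  expect_equal(to_molar(c(Al2O3 = 101.96))[["Al2O3"]], 1)
  expect_equal(unname(to_molar(c(CaO = 0, MgO = 0))), c(0, 0))
  m <- to_molar(c(Al2O3 = 20, CaO = 5, Na2O = 3, K2O = 2))
  expect_equal(unname(m), c(20 / 101.96, 5 / 56.08, 3 / 61.98, 2 / 94.20),
               tolerance = 1e-12)
  expect_error(to_molar(c(SiO2 = 50)), "unknown oxide")
  expect_error(to_molar(c(CaO = -1)), ">= 0")
})

test_that("CIA and CIA-K match hand arithmetic and symmetry cases", {
  m <- to_molar(c(Al2O3 = 20, CaO = 5, Na2O = 3, K2O = 2))
  expect_equal(cia(m), 100 * 0.19616 / (0.19616 + 0.08916 + 0.04840 + 0.02123),
               tolerance = 1e-4)
  expect_equal(cia(m), 55.26, tolerance = 5e-4)
  expect_equal(cia_k(m), 58.78, tolerance = 5e-4)
  only_al <- c(Al2O3 = 0.2, CaO = 0, Na2O = 0, K2O = 0)
  expect_equal(cia(only_al), 100)
  eq <- c(Al2O3 = 0.1, CaO = 0.1, Na2O = 0.1, K2O = 0.1)
  expect_equal(cia(eq), 25)
  expect_error(cia(c(Al2O3 = 0, CaO = 1, Na2O = 1, K2O = 1)), "Al2O3")
})

test_that("weathering indices are invariant to uniform dilution", {
  wt <- c(Al2O3 = 14, CaO = 3.5, Na2O = 2, K2O = 2.8, MgO = 2.5, MnO = 0.12)
  for (f in c(0.2, 0.5, 2)) {
    expect_equal(cia(to_molar(wt * f)), cia(to_molar(wt)), tolerance = 1e-12)
    expect_equal(cia_k(to_molar(wt * f)), cia_k(to_molar(wt)),
                 tolerance = 1e-12)
  }
  expect_gt(cia_k(to_molar(wt)), cia(to_molar(wt)))  # K > 0
})

test_that("authigenic-K correction is a monotone, idempotent fixed point", {
  parent <- to_molar(c(Al2O3 = 14, CaO = 3.5, Na2O = 2, K2O = 2.8,
                       MgO = 2.5, MnO = 0.12))
  # fixed point: horizon at parent K proportion is unchanged
  k0 <- k_correction(parent, parent)
  expect_equal(k0$cia_corrected, cia(parent), tolerance = 1e-12)
  # K enrichment raises the corrected CIA above the plain CIA
  enr <- parent; enr[["K2O"]] <- enr[["K2O"]] * 1.8
  k1 <- k_correction(enr, parent)
  expect_gt(k1$cia_corrected, cia(enr))
  # idempotent
  again <- enr; again[["K2O"]] <- k1$k_corrected
  expect_equal(k_correction(again, parent)$cia_corrected, k1$cia_corrected,
               tolerance = 1e-12)
  # K-free parent zeroes the horizon K
  kfree <- parent; kfree[["K2O"]] <- 0
  expect_equal(k_correction(enr, kfree)$k_corrected, 0)
})

test_that("the precipitation transfer matches its calibration points", {
  expect_equal(map_from_ciak(0), 221.1)
  expect_equal(map_from_ciak(100), 221.1 * exp(1.97))
  expect_equal(map_from_ciak(100), 1585.4, tolerance = 5e-5)
  grid <- map_from_ciak(seq(0, 100, by = 5))
  expect_true(all(diff(grid) > 0))
  expect_error(map_from_ciak(120), "0, 100")
})

test_that("the temperature transfer is linear with the shipped defaults", {
  expect_equal(lst_from_cia(80), 19.1, tolerance = 1e-9)
  expect_equal(lst_from_cia(50, a = 0, b = 7), 7)
  expect_equal(lst_from_cia(60) - lst_from_cia(50), 5.6, tolerance = 1e-9)
  expect_error(lst_from_cia(80, strict = TRUE), "strict")
})

test_that("energy transfers behave as documented stand-ins", {
  tr <- default_energy_transfer()
  en0 <- eppt_et(1000, tr$t_ref)
  expect_equal(en0$eppt, 0)
  e1 <- eppt_et(500, 12); e2 <- eppt_et(1000, 12)
  expect_equal(e2$eppt, 2 * e1$eppt)
  expect_equal(e1$et, e2$et)
  # frozen golden values for the shipped defaults
  en <- eppt_et(1000, 10)
  expect_equal(en$eppt, 41.86, tolerance = 1e-9)
  expect_equal(en$et, 1443.785, tolerance = 1e-9)
  expect_error(eppt_et(0, 10), "MAP")
})

test_that("humidity provinces partition the plane with a wetter tie rule", {
  hp <- humidity_province(c(0.1, 1000), c(3000, 1000))
  expect_equal(hp$province, c("arid", "perhumid"))
  expect_equal(hp$floral_regime[2], "rainforest")
  # totality: every finite point gets exactly one label
  grid <- expand.grid(et = seq(1, 5000, length.out = 15),
                      eppt = seq(0, 400, length.out = 15))
  lab <- humidity_province(grid$eppt, grid$et)
  expect_false(any(is.na(lab$province)))
  # a point exactly on a boundary goes to the wetter side
  b <- default_humidity_boundaries()
  on_line <- humidity_province(2000 * 0.015, 2000)
  expect_equal(on_line$province, "subhumid")
  crossing <- list(lines = list(data.frame(et = c(0, 10), eppt = c(5, 0)),
                                data.frame(et = c(0, 10), eppt = c(0, 5))),
                   provinces = c("a", "b", "c"),
                   floral_regimes = c("x", "y", "z"))
  expect_error(humidity_province(1, 1, crossing), "cross")
})

test_that("profile QC applies the >5% CIA-K contrast rule", {
  mk_prof <- function(b_ciak_target) {
    # two-horizon profile built directly from chemistry with known CIA-K
    parent <- c(Al2O3 = 14, CaO = 3.5, Na2O = 2, K2O = 2.8, MgO = 2.5,
                MnO = 0.12)
    pm <- to_molar(parent)
    f <- pm[["Al2O3"]] * (100 - b_ciak_target) /
      (b_ciak_target * (pm[["CaO"]] + pm[["Na2O"]]))
    b <- parent; b["CaO"] <- b["CaO"] * f; b["Na2O"] <- b["Na2O"] * f
    paleosol_profile(data.frame(horizon = c("Bw1", "C"), depth_cm = c(20, 60),
                                rbind(b, parent)))
  }
  parent_ciak <- cia_k(to_molar(c(Al2O3 = 14, CaO = 3.5, Na2O = 2, K2O = 2.8,
                                  MgO = 2.5, MnO = 0.12)))
  pass <- profile_qc(mk_prof(parent_ciak * 1.10))
  expect_equal(pass$ciak_contrast_percent, 10, tolerance = 1e-6)
  expect_true(pass$passes)
  fail <- profile_qc(mk_prof(parent_ciak * 1.02))
  expect_false(fail$passes)
  expect_error(profile_qc(paleosol_profile(
    data.frame(horizon = c("A", "C"), depth_cm = c(10, 50),
               rbind(c(Al2O3 = 14, CaO = 3, Na2O = 2, K2O = 2, MgO = 2,
                       MnO = 0.1),
                     c(Al2O3 = 14, CaO = 3, Na2O = 2, K2O = 2, MgO = 2,
                       MnO = 0.1))))), "no B horizon")
})

test_that("the full proxy chain runs per horizon on a simulated profile", {
  prof <- simulate_paleosol(seed = 5)
  est <- paleosol_climate(prof)
  expect_equal(nrow(est), nrow(prof$horizons))
  expect_true(all(est$cia >= 0 & est$cia <= 100))
  expect_true(all(est$map_mm_yr > 0))
  expect_true(all(!is.na(est$humidity_province)))
  # weathered B horizons imply wetter estimates than the parent
  expect_gt(mean(est$map_mm_yr[-prof$parent_index]),
            est$map_mm_yr[prof$parent_index])
})
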