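test_that("Baillie-Pilcher transform matches hand arithmetic", {
  expect_equal(bp_transform(rw_series(rep(2, 9)))$values, rep(0, 5))
  tb <- bp_transform(rw_series(c(1, 1, 4, 1, 1)), window = 5)
  expect_equal(tb$values, log(4 / 1.6), tolerance = 1e-12)
  expect_equal(tb$years, 3L)
  expect_error(bp_transform(rw_series(1:4), window = 5), "at least as long")
})

test_that("Hollstein transform matches its closed form", {
  expect_equal(ho_transform(rw_series(rep(3, 6)))$values, rep(0, 5))
  expect_equal(ho_transform(rw_series(c(1, 10)))$values, 100)
  g <- 1.07
  geo <- rw_series(2 * g^(0:9))
  expect_equal(ho_transform(geo)$values, rep(100 * log10(g), 9),
               tolerance = 1e-9)
})

test_that("correlation t-statistic agrees with cor.test and flags degeneracy", {
  set.seed(4)
  x <- list(years = 1:27, values = rnorm(27))
  y <- list(years = 1:27, values = rnorm(27))
  st <- t_statistic(x, y)
  ct <- cor.test(x$values, y$values)
  expect_equal(st$t, unname(ct$statistic), tolerance = 1e-10)
  expect_equal(st$n, 27)
  # closed form at r = 0.6, n = 27: t = 0.6 * 5 / 0.8 = 3.75
  r <- 0.6; n <- 27
  expect_equal(r * sqrt(n - 2) / sqrt(1 - r^2), 3.75)

  ident <- t_statistic(x, x)
  expect_true(ident$degenerate)
  expect_identical(ident$t, Inf)
  flat <- list(years = 1:27, values = rep(1, 27))
  expect_true(t_statistic(x, flat)$degenerate)
})

test_that("Gleichlaeufigkeit scores sign agreement of first differences", {
  a <- rw_series(c(1, 2, 3, 2, 4))
  expect_equal(gleichlauf(a, a), 100)
  up <- rw_series(1:10); down <- rw_series(10:1)
  expect_equal(gleichlauf(up, down), 0)
  b <- rw_series(c(2, 3, 2, 3, 5))
  expect_equal(gleichlauf(a, b), 50)  # (+/+), (+/-), (-/+), (+/+)
  expect_error(gleichlauf(rw_series(1:3), rw_series(1:3, first_year = 10L)),
               "overlap")
})

test_that("a shifted noise-free copy is recovered at the exact lag with r = 1", {
  f <- simulate_forest(forest_config(n_trees = 2, years = 60, seed = 21))
  a <- f$series[[1]]
  b <- a; b$series_id <- "copy"; b$first_year <- 1L
  a$first_year <- 11L  # truth: b must shift +10 to align
  cm <- crossmatch(a, b)
  expect_equal(cm$lag[1], 10)
  expect_equal(cm$r[1], 1)
  expect_equal(cm$glk[1], 100)
  expect_identical(cm$t_bp[1], Inf)
  expect_true(cm$accepted[1])
})

test_that("cross-matching statistics are symmetric and scale invariant", {
  f <- simulate_forest(forest_config(n_trees = 2, years = 70, seed = 13))
  a <- f$series[[1]]; b <- f$series[[3]]
  ab <- crossmatch(a, b); ba <- crossmatch(b, a)
  for (k in seq_len(min(10, nrow(ab)))) {
    L <- ab$lag[k]
    row <- ba[ba$lag == -L, ]
    expect_equal(row$r, ab$r[k], tolerance = 1e-12)
    expect_equal(row$t_bp, ab$t_bp[k], tolerance = 1e-9)
    expect_equal(row$glk, ab$glk[k], tolerance = 1e-12)
    expect_equal(row$n_overlap, ab$n_overlap[k])
  }
  b10 <- b; b10$widths <- 10 * b$widths
  ab10 <- crossmatch(a, b10)
  expect_equal(ab10$r, ab$r, tolerance = 1e-12)
  expect_equal(ab10$t_bp, ab$t_bp, tolerance = 1e-9)
  expect_equal(ab10$glk, ab$glk, tolerance = 1e-12)
})

test_that("no candidate lag means an empty result, not an error", {
  a <- rw_series(runif(25) + 0.5)
  b <- rw_series(runif(25) + 0.5)
  cm <- crossmatch(a, b, min_overlap = 30)
  expect_s3_class(cm, "crossmatch_results")
  expect_equal(nrow(cm), 0)
})

test_that("false-positive acceptance on independent AR(1) pairs is rare", {
  set.seed(77)
  n_pairs <- 300
  fp <- 0
  for (i in seq_len(n_pairs)) {
    a <- rw_series(exp(ar1_noise(60, 0.4, 0.3)))
    b <- rw_series(exp(ar1_noise(60, 0.4, 0.3)))
    cm <- crossmatch(a, b)
    if (any(cm$accepted)) fp <- fp + 1
  }
  expect_lte(fp / n_pairs, 0.05)
})

test_that("build_master composes offsets, reports exclusions, detects conflicts", {
  s1 <- rw_series(runif(30) + 0.5, "A")
  s2 <- s1; s2$series_id <- "B"
  m <- crossmatch(s1, s2)[1, ]
  bm <- build_master(list(s1, s2), m)
  expect_equal(bm$chronology_length, 30)
  expect_equal(unname(bm$offsets), c(0, 0))
  expect_equal(bm$mean_overlap, 30)

  # disconnected third series is excluded
  s3 <- rw_series(runif(30) + 0.5, "C")
  bm2 <- build_master(list(s1, s2, s3), m)
  expect_equal(bm2$excluded, "C")

  # inconsistent cycle: A-B at 0, B-C at 5, A-C at 2 cannot all hold
  fake <- data.frame(series_a = c("A", "B", "A"), series_b = c("B", "C", "C"),
                     lag = c(0L, 5L, 2L), accepted = TRUE)
  expect_error(build_master(list(s1, s2, s3), fake), "alignment conflict")
})

test_that("intra-tree radii are averaged after matching; failures reported", {
  f <- simulate_forest(forest_config(n_trees = 2, years = 50,
                                     radii_per_tree = 2, noise_sd = 0,
                                     seed = 6))
  avg <- average_radii(f$series)
  expect_length(avg$trees, 2)
  expect_equal(avg$trees[[1]]$widths, f$series[[1]]$widths)  # identical radii
  expect_length(avg$dropped, 0)

  # an unrelated short series under the same tree id fails to match
  odd <- rw_series(runif(25) + 0.5, "T01R9", tree_id = "T01", radius_id = "r9")
  avg2 <- average_radii(c(f$series, list(odd)))
  expect_true("T01R9" %in% avg2$dropped)
})

test_that("known offsets are recovered exactly on a synthetic forest", {
  f <- simulate_forest(recovery_config(seed = 1))
  cd <- crossdate_set(blind_axes(f$series))
  expect_equal(unname(cd$master$offsets[names(f$true_offsets)]),
               unname(f$true_offsets))
  expect_equal(cd$master$chronology_length, f$true_span)
  expect_length(cd$master$excluded, 0)
})
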