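#' Simulate a paleosol weathering profile
#'
#' Generates a horizon-by-horizon major-element profile with the chemical
#' structure a pedogenically altered profile shows: Ca and Na depleted (and
#' consequently Al enriched, in index terms) upward from the parent material
#' by prescribed CIA-K increments, mild authigenic K and Mg enrichment in the
#' B horizons, and Mn depletion in the B horizons relative to the parent.
#'
#' For each non-parent horizon the Ca and Na weight percents are scaled by
#' the unique factor that moves the horizon's CIA-K to
#' `CIA-K(parent) + increment`, so the requested weathering gradient is exact
#' before measurement noise.
#'
#' @param n_horizons Total horizons including the parent (>= 2); horizons are
#'   ordered surface to parent, labelled `Bw1..Bw(n-1)` and `C`.
#' @param parent_chem Named oxide weight percents of the parent material
#'   (`Al2O3, CaO, Na2O, K2O, MgO, MnO`); must sum to <= 100.
#' @param weathering_gradient CIA-K increments over the parent for the
#'   `n_horizons - 1` non-parent horizons, surface first.
#' @param noise_sd Additive measurement noise per oxide, wt%.
#' @param seed Integer seed; output is deterministic given the seed.
#' @return A [paleosol_profile()].
#' @export
simulate_paleosol <- function(n_horizons = 6L,
                              parent_chem = c(Al2O3 = 14, CaO = 3.5,
                                              Na2O = 2.0, K2O = 2.8,
                                              MgO = 2.5, MnO = 0.12),
                              weathering_gradient = c(8, 7, 6, 4, 2),
                              noise_sd = 0.1,
                              seed = 1L) {
  n_horizons <- as.integer(n_horizons)
  if (n_horizons < 2L) stop("need at least 2 horizons (B + parent)", call. = FALSE)
  if (length(weathering_gradient) != n_horizons - 1L)
    stop("weathering_gradient must have n_horizons - 1 increments", call. = FALSE)
  if (any(!is.finite(unlist(parent_chem)) | unlist(parent_chem) < 0))
    stop("parent chemistry must be finite and >= 0", call. = FALSE)
  if (sum(unlist(parent_chem)) > 100)
    stop("parent chemistry sums to more than 100 wt%", call. = FALSE)

  parent_molar <- to_molar(parent_chem)
  ck0 <- cia_k(parent_molar)

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(as.integer(seed))

  rows <- vector("list", n_horizons)
  for (i in seq_len(n_horizons)) {
    wt <- unlist(parent_chem)
    if (i < n_horizons) {
      inc <- weathering_gradient[i]
      target <- ck0 + inc
      if (!is.finite(target) || target <= 0 || target >= 100)
        stop("requested CIA-K target ", round(target, 2),
             " is outside (0, 100)", call. = FALSE)
      m <- to_molar(wt)
      f <- m[["Al2O3"]] * (100 - target) /
        (target * (m[["CaO"]] + m[["Na2O"]]))
      if (!is.finite(f) || f < 0)
        stop("gradient produces negative oxide mass", call. = FALSE)
      wt["CaO"] <- wt["CaO"] * f
      wt["Na2O"] <- wt["Na2O"] * f
      # mild pedogenic overprint: authigenic K / Mg enrichment, Mn depletion
      wt["K2O"] <- wt["K2O"] * (1 + 0.015 * inc)
      wt["MgO"] <- wt["MgO"] * (1 + 0.010 * inc)
      wt["MnO"] <- wt["MnO"] * max(0.25, 1 - 0.12 * inc)
    }
    if (noise_sd > 0)
      wt <- pmax(wt + rnorm(length(wt), sd = noise_sd), 0.005)
    rows[[i]] <- c(list(horizon = if (i < n_horizons) paste0("Bw", i) else "C",
                        depth_cm = 15 + 20 * (i - 1)),
                   as.list(wt))
  }
  horizons <- do.call(rbind, lapply(rows, as.data.frame))
  paleosol_profile(horizons, parent_index = n_horizons)
}
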