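#' Configuration for a synthetic fossil forest
#'
#' Assembles and validates the parameters of [simulate_forest()]. Defaults
#' describe a small stand of the kind fossil-wood chronologies are built
#' from: a handful of trees, two measured radii per tree, strictly positive
#' lognormal ring widths with a negative-exponential age trend, a shared
#' oscillatory climate signal spanning interannual to multidecadal periods,
#' AR(1) tree-level noise, and occasional shared marker years (anomalously
#' narrow or wide rings).
#'
#' @param n_trees Number of trees (>= 2).
#' @param years Rings per tree (>= 20, the minimum ring count for replicable
#'   cross-dating). With `offsets` all zero this equals the chronology span;
#'   otherwise the span is `years + diff(range(offsets))`.
#' @param radii_per_tree Radial transects measured per tree (>= 2).
#' @param age_trend List `w0` (juvenile width, mm), `decay` (1/yr), `floor`
#'   (asymptotic width, mm). Expected width at ring age a is
#'   `max(floor, w0 * exp(-decay * a))`.
#' @param climate_signal List of components, each
#'   `list(period, amplitude, phase = 0, on_interval = NULL)`. The
#'   oscillatory part of the shared signal is
#'   `sum_i amplitude_i * cos(2*pi*t/period_i + phase_i)`, each component
#'   gated to zero outside its `on_interval = c(from, to)` (calendar years)
#'   when given — non-stationary oscillations.
#' @param climate_noise_sd Standard deviation of the shared *interannual*
#'   climate variability (white noise added to the oscillatory signal,
#'   identical for all trees). Year-to-year weather shared across a stand is
#'   what makes ring-width series cross-datable at all; a purely sinusoidal
#'   common signal realigns with itself at shifted lags and leaves the
#'   alignment ambiguous.
#' @param ar1_phi Lag-1 autocorrelation of the per-radius noise, in `[0, 1)`.
#' @param noise_sd Marginal standard deviation of the per-radius AR(1) noise
#'   on the log-width scale (dimensionless).
#' @param signal_gain Coupling of the climate signal into log width; negative
#'   values model climate oscillations adverse to growth.
#' @param marker_years Data frame or list with elements `year` and
#'   `multiplier`: shared anomalous years applied multiplicatively to every
#'   tree after noise. `NULL` for none.
#' @param offsets Integer start-year shift per tree (length `n_trees`,
#'   recycled from length 1). Tree k occupies relative years
#'   `offsets[k] + 1 .. offsets[k] + years`.
#' @param seed Integer seed; fixing it reproduces the forest exactly.
#'
#' @return A validated list of class `forest_config`.
#' @export
forest_config <- function(n_trees = 6L,
                          years = 120L,
                          radii_per_tree = 2L,
                          age_trend = list(w0 = 2.5, decay = 0.01, floor = 0.3),
                          climate_signal = list(
                            list(period = 30, amplitude = 1.0, phase = 0),
                            list(period = 11, amplitude = 0.5, phase = 1.1)),
                          climate_noise_sd = 0.8,
                          ar1_phi = 0.4,
                          noise_sd = 0.3,
                          signal_gain = 0.5,
                          marker_years = NULL,
                          offsets = 0L,
                          seed = 1L) {
  cfg <- list(n_trees = as.integer(n_trees), years = as.integer(years),
              radii_per_tree = as.integer(radii_per_tree),
              age_trend = age_trend, climate_signal = climate_signal,
              climate_noise_sd = climate_noise_sd,
              ar1_phi = ar1_phi, noise_sd = noise_sd,
              signal_gain = signal_gain, marker_years = marker_years,
              offsets = as.integer(rep_len(offsets, n_trees)),
              seed = as.integer(seed))
  validate_forest_config(cfg)
  class(cfg) <- "forest_config"
  cfg
}

validate_forest_config <- function(cfg) {
  with(cfg, {
    if (n_trees < 2L) stop("n_trees must be >= 2", call. = FALSE)
    if (years < 20L)
      stop("years must be >= 20 (minimum ring count for replicable cross-dating)",
           call. = FALSE)
    if (radii_per_tree < 1L) stop("radii_per_tree must be >= 1", call. = FALSE)
    if (!is.finite(ar1_phi) || ar1_phi < 0 || ar1_phi >= 1)
      stop("ar1_phi must lie in [0, 1)", call. = FALSE)
    if (!is.finite(noise_sd) || noise_sd < 0)
      stop("noise_sd must be finite and >= 0", call. = FALSE)
    if (!is.finite(climate_noise_sd) || climate_noise_sd < 0)
      stop("climate_noise_sd must be finite and >= 0", call. = FALSE)
    at <- age_trend
    if (!all(is.finite(c(at$w0, at$decay, at$floor))) ||
        at$w0 <= 0 || at$floor <= 0 || at$decay < 0)
      stop("age_trend parameters must be finite with w0 > 0, floor > 0, decay >= 0",
           call. = FALSE)
    for (comp in climate_signal) {
      if (!all(is.finite(c(comp$period, comp$amplitude))) || comp$period <= 0)
        stop("climate_signal components need finite amplitude and period > 0",
             call. = FALSE)
    }
    if (!is.null(marker_years)) {
      m <- as.data.frame(marker_years)
      if (!all(c("year", "multiplier") %in% names(m)))
        stop("marker_years needs columns year and multiplier", call. = FALSE)
      if (any(!is.finite(m$multiplier) | m$multiplier <= 0))
        stop("marker multipliers must be positive", call. = FALSE)
    }
  })
  invisible(cfg)
}

#' Shared climate signal of a forest configuration
#'
#' @param cfg A `forest_config`.
#' @param years Integer years at which to evaluate the signal.
#' @return Numeric vector `C(t)`, the summed (possibly interval-gated)
#'   sinusoids shared by all trees.
#' @export
climate_signal <- function(cfg, years) {
  C <- numeric(length(years))
  for (comp in cfg$climate_signal) {
    phase <- if (is.null(comp$phase)) 0 else comp$phase
    v <- comp$amplitude * cos(2 * pi * years / comp$period + phase)
    if (!is.null(comp$on_interval)) {
      gate <- years >= comp$on_interval[1] & years <= comp$on_interval[2]
      v <- v * gate
    }
    C <- C + v
  }
  C
}

## Sub-seeding rule: radius j of tree k (flat index i, 1-based) draws from its
## own stream seeded with (seed + 7919 * i) mod (2^31 - 1). Documented so
## per-series output is reproducible independently of evaluation order.
sub_seed <- function(seed, i) as.integer((as.numeric(seed) + 7919 * i) %% 2147483647)

ar1_noise <- function(n, phi, sd_marginal, burn = 50L) {
  if (sd_marginal == 0) return(numeric(n))
  innov_sd <- sd_marginal * sqrt(1 - phi^2)
  e <- rnorm(n + burn, sd = innov_sd)
  x <- numeric(n + burn)
  x[1] <- rnorm(1, sd = sd_marginal)  # start at the stationary distribution
  for (t in 2:(n + burn)) x[t] <- phi * x[t - 1] + e[t]
  x[(burn + 1):(burn + n)]
}

#' Simulate a fossil forest of ring-width series
#'
#' Generates `n_trees * radii_per_tree` ring-width series following the
#' multiplicative growth model
#' \deqn{w(t) = \max(floor, w_0 e^{-decay\,a}) \cdot
#'       e^{g\,C(t) + \epsilon(t)} \cdot m(t)}
#' where `a` is ring age, `C(t)` the shared climate signal, `g` the signal
#' gain, `eps` per-radius AR(1) noise on the log scale (so widths stay
#' positive and right-skewed), and `m(t)` the shared marker-year multiplier
#' applied after noise. Per-tree start-year offsets shift the relative year
#' axis; the true offsets and signal are returned for parameter-recovery
#' tests.
#'
#' @param cfg A [forest_config()].
#' @return An object of class `simulated_forest`: list with `series` (list of
#'   [rw_series()]), `true_climate` (data.frame `year`, `signal`),
#'   `true_offsets` (named integer vector per tree), `true_span` (years
#'   covered by the union of all trees) and `config`.
#' @export
simulate_forest <- function(cfg) {
  if (!inherits(cfg, "forest_config")) cfg <- do.call(forest_config, cfg)
  validate_forest_config(cfg)

  off <- cfg$offsets - min(cfg$offsets)   # normalize so the earliest tree starts at year 1
  all_years <- seq.int(1L, cfg$years + max(off))
  C <- climate_signal(cfg, all_years)

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })

  if (cfg$climate_noise_sd > 0) {
    set.seed(sub_seed(cfg$seed, 0L))  # shared interannual stream
    C <- C + rnorm(length(all_years), sd = cfg$climate_noise_sd)
  }

  markers <- rep(1, length(all_years))
  if (!is.null(cfg$marker_years)) {
    m <- as.data.frame(cfg$marker_years)
    idx <- match(m$year, all_years)
    markers[idx[!is.na(idx)]] <- m$multiplier[!is.na(idx)]
  }

  a <- seq_len(cfg$years)
  trend <- pmax(cfg$age_trend$floor,
                cfg$age_trend$w0 * exp(-cfg$age_trend$decay * a))

  series <- vector("list", cfg$n_trees * cfg$radii_per_tree)
  i <- 0L
  for (k in seq_len(cfg$n_trees)) {
    yrs <- off[k] + a
    ck <- C[yrs]
    mk <- markers[yrs]
    for (j in seq_len(cfg$radii_per_tree)) {
      i <- i + 1L
      set.seed(sub_seed(cfg$seed, i))
      eps <- ar1_noise(cfg$years, cfg$ar1_phi, cfg$noise_sd)
      w <- trend * exp(cfg$signal_gain * ck + eps) * mk
      series[[i]] <- rw_series(
        w,
        series_id = sprintf("T%02dR%d", k, j),
        tree_id = sprintf("T%02d", k),
        radius_id = sprintf("r%d", j),
        first_year = off[k] + 1L)
    }
  }

  structure(
    list(series = series,
         true_climate = data.frame(year = all_years, signal = C),
         true_offsets = stats::setNames(off, sprintf("T%02d", seq_len(cfg$n_trees))),
         true_span = length(all_years),
         config = cfg),
    class = "simulated_forest")
}

#' @export
print.simulated_forest <- function(x, ...) {
  cat(sprintf("<simulated_forest: %d trees x %d radii, %d rings/tree, span %d yr, seed %d>\n",
              x$config$n_trees, x$config$radii_per_tree, x$config$years,
              x$true_span, x$config$seed))
  invisible(x)
}
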