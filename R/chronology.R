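#' Smoothing-spline detrend of a ring-width series
#'
#' Fits a discrete penalized smoothing spline (second-difference penalty)
#' whose transfer function `1 / (1 + lambda * (2 - 2 cos w)^2)` equals `f`
#' (default 0.5) at the cutoff wavelength, the standard frequency-response
#' parameterization of dendro detrending splines. The default cutoff is 0.67
#' of the series length, the dominant convention for preserving multidecadal
#' climate signal while removing the age trend.
#'
#' @param series An [rw_series()] (length >= 10).
#' @param cutoff_frac Cutoff wavelength as a fraction of series length.
#' @param cutoff_years Absolute cutoff wavelength in years (overrides
#'   `cutoff_frac`).
#' @param f Frequency response at the cutoff wavelength.
#' @return List of class `detrend_fit`: `years`, `fitted` (> 0, floored),
#'   `cutoff_years`, `lambda`, `method`.
#' @export
spline_detrend <- function(series, cutoff_frac = 0.67, cutoff_years = NULL,
                           f = 0.5) {
  w <- series$widths
  n <- length(w)
  if (n < 10L) stop("series too short to detrend (need >= 10 rings)", call. = FALSE)
  p <- if (is.null(cutoff_years)) cutoff_frac * n else cutoff_years
  if (p <= 2) stop("cutoff wavelength must exceed 2 years", call. = FALSE)
  omega <- 2 * pi / p
  lambda <- (1 / f - 1) / (2 - 2 * cos(omega))^2
  fit <- whittaker_smooth(w, lambda)
  fit <- pmax(fit, 1e-6)
  structure(list(years = rw_years(series), fitted = fit,
                 cutoff_years = p, lambda = lambda,
                 method = "penalized smoothing spline (2nd difference)"),
            class = "detrend_fit")
}

## (I + lambda * D'D) fit = y with D the (n-2) x n second-difference matrix.
whittaker_smooth <- function(y, lambda) {
  n <- length(y)
  D <- diff(diag(n), differences = 2)
  A <- diag(n) + lambda * crossprod(D)
  as.numeric(solve(A, y))
}

#' Ring-width index
#'
#' `RWI[t] = width[t] / fitted[t]`: < 1 is less growth than expected, 1 is
#' expected growth, > 1 more growth than expected.
#'
#' @param series An [rw_series()].
#' @param fit The matching [spline_detrend()] result.
#' @return List with `years` and `values` (the per-year index).
#' @export
to_rwi <- function(series, fit) {
  if (!identical(fit$years, rw_years(series)))
    stop("detrend fit is not aligned to the series", call. = FALSE)
  list(years = fit$years, values = series$widths / fit$fitted)
}

## One-step Tukey biweight robust mean (c = 9, median/MAD start).
tukey_biweight <- function(x) {
  med <- median(x)
  s <- median(abs(x - med))
  if (s == 0) return(med)
  u <- (x - med) / (9 * s)
  w <- (1 - u^2)^2
  w[abs(u) >= 1] <- 0
  sum(w * x) / sum(w)
}

#' Average indexed series into a mean value chronology
#'
#' Per-year Tukey biweight robust mean of the ring-width indices (falling
#' back to the arithmetic mean where fewer than 4 series contribute), with
#' the per-year sample depth recorded.
#'
#' @param rwi_list List of indexed series (`years`, `values`).
#' @param method `"biweight"` (default) or `"mean"`.
#' @return List with `years`, `rwi`, `sample_depth`.
#' @export
average_chronology <- function(rwi_list, method = c("biweight", "mean")) {
  method <- match.arg(method)
  yrs <- sort(unique(unlist(lapply(rwi_list, `[[`, "years"))))
  if (length(yrs) == 0L) stop("no years to average", call. = FALSE)
  vals <- lapply(yrs, function(y) {
    unlist(lapply(rwi_list, function(s) {
      i <- match(y, s$years); if (is.na(i)) NULL else s$values[i]
    }))
  })
  depth <- lengths(vals)
  rwi <- vapply(seq_along(vals), function(i) {
    v <- vals[[i]]
    if (method == "mean" || depth[i] < 4L) mean(v) else tukey_biweight(v)
  }, numeric(1))
  list(years = yrs, rwi = rwi, sample_depth = as.integer(depth))
}

#' Subsample signal strength
#'
#' `SSS(n) = n (1 + (N - 1) rbar) / (N (1 + (n - 1) rbar))` (Wigley et al.
#' form): the fraction of the full-chronology common signal captured by a
#' subsample of `n` of `N` series with mean inter-series correlation `rbar`.
#' Equals `n/N` at `rbar = 0` and 1 at `n = N`; monotone non-decreasing
#' in `n`.
#'
#' @param rbar Mean inter-series correlation in `[0, 1]`.
#' @param n Subsample size(s), `1 <= n <= N` (vectorized).
#' @param N Total number of series.
#' @return SSS in `(0, 1]`.
#' @export
sss <- function(rbar, n, N) {
  if (!is.finite(rbar) || rbar < 0 || rbar > 1)
    stop("rbar must lie in [0, 1]", call. = FALSE)
  if (any(n > N)) stop("subsample size n cannot exceed N", call. = FALSE)
  if (any(n < 1) || N < 1) stop("n and N must be >= 1", call. = FALSE)
  n * (1 + (N - 1) * rbar) / (N * (1 + (n - 1) * rbar))
}

#' Mean inter-series correlation
#'
#' Mean of pairwise Pearson correlations of the ring-width indices over each
#' pair's common years, for pairs with at least `min_overlap` common years.
#'
#' @param rwi_list List of indexed series (`years`, `values`).
#' @param min_overlap Minimum common years for a pair to qualify.
#' @return Mean pairwise correlation.
#' @export
rbar <- function(rwi_list, min_overlap = 10L) {
  if (length(rwi_list) < 2L) stop("need at least 2 series", call. = FALSE)
  rs <- c()
  for (i in seq_along(rwi_list)) for (j in seq_along(rwi_list)) {
    if (i >= j) next
    a <- rwi_list[[i]]; b <- rwi_list[[j]]
    common <- intersect(a$years, b$years)
    if (length(common) < min_overlap) next
    va <- a$values[match(common, a$years)]
    vb <- b$values[match(common, b$years)]
    if (sd(va) == 0 || sd(vb) == 0) next
    rs <- c(rs, cor(va, vb))
  }
  if (length(rs) == 0L)
    stop("no series pair has sufficient overlap", call. = FALSE)
  mean(rs)
}

#' Build an RWI chronology from aligned series
#'
#' Detrends each series with [spline_detrend()], converts to RWI, averages
#' into a mean chronology, and attaches the chronology statistics: mean
#' inter-series correlation (`rbar`), per-year subsample signal strength
#' computed from the per-year sample depth, and the first year at which SSS
#' reaches the cutoff.
#'
#' @param series List of aligned [rw_series()] (e.g. `build_master()$aligned`).
#' @param cutoff_frac Spline cutoff as a fraction of each series' length.
#' @param method Averaging method, see [average_chronology()].
#' @param sss_cutoff SSS threshold marking the usable part of the chronology
#'   (0.5 by convention here; 0.85 is common elsewhere).
#' @param min_rbar_overlap Minimum pair overlap entering [rbar()].
#' @return Object of class `chronology`: `years`, `rwi`, `sample_depth`,
#'   `rbar`, `sss` (per year), `sss_year`, `sss_cutoff`, `n_total`.
#' @export
build_chronology <- function(series, cutoff_frac = 0.67,
                             method = "biweight", sss_cutoff = 0.5,
                             min_rbar_overlap = 10L) {
  rwi_list <- lapply(series, function(s) to_rwi(s, spline_detrend(s, cutoff_frac)))
  avg <- average_chronology(rwi_list, method)
  N <- length(series)
  rb <- if (N >= 2L) rbar(rwi_list, min_rbar_overlap) else NA_real_
  sss_vals <- if (is.na(rb)) rep(NA_real_, length(avg$years))
              else sss(max(0, min(1, rb)), avg$sample_depth, N)
  first_ok <- which(sss_vals >= sss_cutoff)
  structure(
    list(years = avg$years, rwi = avg$rwi, sample_depth = avg$sample_depth,
         rbar = rb, sss = sss_vals,
         sss_year = if (length(first_ok)) avg$years[first_ok[1]] else NA_integer_,
         sss_cutoff = sss_cutoff, n_total = N),
    class = "chronology")
}

#' @export
print.chronology <- function(x, ...) {
  cat(sprintf("<chronology: %d yr (%d..%d), N = %d, rbar = %.3f, SSS >= %.2f from year %s>\n",
              length(x$years), min(x$years), max(x$years), x$n_total,
              x$rbar, x$sss_cutoff, as.character(x$sss_year)))
  invisible(x)
}

#' @export
as.data.frame.chronology <- function(x, ...) {
  data.frame(year = x$years, rwi = x$rwi, sample_depth = x$sample_depth,
             sss = x$sss)
}

#' Normality diagnostic for a chronology
#'
#' Shapiro--Wilk test plus theoretical-vs-empirical quantile pairs for a
#' probability plot. Advisory: a non-Gaussian RWI distribution warns that
#' wavelet significance levels are approximate, but the transform itself is
#' still defined.
#'
#' @param x A `chronology` or numeric vector (>= 20 values).
#' @return List with `statistic`, `p_value`, `qq` (data.frame `theoretical`,
#'   `empirical`) and `degenerate`.
#' @export
normality_diagnostic <- function(x) {
  v <- if (inherits(x, "chronology")) x$rwi else as.numeric(x)
  if (length(v) < 20L) stop("need at least 20 values", call. = FALSE)
  qq <- data.frame(theoretical = qnorm(ppoints(length(v))),
                   empirical = sort(v))
  if (sd(v) == 0)
    return(list(statistic = NA_real_, p_value = NA_real_, qq = qq,
                degenerate = TRUE))
  sw <- shapiro.test(v)
  list(statistic = unname(sw$statistic), p_value = sw$p.value, qq = qq,
       degenerate = FALSE)
}
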