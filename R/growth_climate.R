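#' Growth response to significant climate oscillations
#'
#' The coincidence statistic linking wavelet-detected climate oscillations
#' to tree growth: a chronology year is *significant* when at least one
#' DOG(2) wavelet cell at a Fourier period inside `band` passes red-noise
#' significance at that year while lying inside the cone of influence.
#' Significant years are then classified by their ring-width index —
#' suppressed (`RWI < 1`), enhanced (`RWI > 1`) or neutral (`RWI = 1`
#' exactly) — and the fractions reported. Because DOG(2) coefficients are
#' real and time-aligned, this is a direct year-by-year comparison of the
#' oscillation to growth.
#'
#' @param chron A `chronology` (see [build_chronology()]).
#' @param spec A DOG(2) [cwt()] of the chronology's RWI with a significance
#'   mask (see [rednoise_significance()]).
#' @param band Fourier-period interval in years (default 20--40 yr,
#'   bracketing multidecadal oscillations around 30 yr).
#' @return Object of class `growth_response`: `band`, `significant_years`,
#'   `n_significant`, `suppressed_fraction` and `enhanced_fraction`
#'   (percent of significant years; `NA` when none), `counts`
#'   (suppressed/enhanced/neutral), `empty`.
#' @export
growth_response <- function(chron, spec, band = c(20, 40)) {
  if (spec$wavelet$family != "dog")
    stop("growth_response expects a DOG(2) spectrum", call. = FALSE)
  if (is.null(spec$signif_mask))
    stop("spectrum has no significance mask; run rednoise_significance()",
         call. = FALSE)
  if (length(spec$times) != length(chron$years) ||
      !isTRUE(all.equal(as.numeric(spec$times), as.numeric(chron$years))))
    stop("spectrum was not computed on this chronology's year axis",
         call. = FALSE)
  in_band <- spec$fourier_periods >= band[1] & spec$fourier_periods <= band[2]
  if (!any(in_band))
    stop("band [", band[1], ", ", band[2],
         "] yr is disjoint from the scale grid", call. = FALSE)

  sig <- spec$signif_mask & coi_mask(spec)
  year_sig <- colSums(sig[in_band, , drop = FALSE]) > 0
  sig_years <- chron$years[year_sig]
  rwi_sig <- chron$rwi[year_sig]
  n <- length(sig_years)
  counts <- c(suppressed = sum(rwi_sig < 1), enhanced = sum(rwi_sig > 1),
              neutral = sum(rwi_sig == 1))
  structure(
    list(band = band, significant_years = sig_years, n_significant = n,
         suppressed_fraction = if (n) 100 * counts[["suppressed"]] / n else NA_real_,
         enhanced_fraction = if (n) 100 * counts[["enhanced"]] / n else NA_real_,
         counts = counts, empty = n == 0L,
         rwi_significant = rwi_sig),
    class = "growth_response")
}

#' @export
print.growth_response <- function(x, ...) {
  if (x$empty) {
    cat("<growth_response: no significant years in band>\n")
  } else {
    cat(sprintf("<growth_response %g-%g yr: %d significant years, %.1f%% suppressed, %.1f%% enhanced>\n",
                x$band[1], x$band[2], x$n_significant,
                x$suppressed_fraction, x$enhanced_fraction))
  }
  invisible(x)
}

#' Contrast the suppressed-growth fractions of two epochs
#'
#' Difference in suppressed fraction (percentage points) between two
#' [growth_response()] results, with a bootstrap confidence interval
#' obtained by resampling each epoch's significant years with replacement.
#'
#' @param result_a,result_b Non-empty [growth_response()] results.
#' @param n_boot Bootstrap replicates.
#' @param conf Confidence level.
#' @param seed Seed for the resampling.
#' @return List with `delta_suppressed` (a minus b, percentage points),
#'   `ci` (length-2 vector), `conf`, and the two input fractions.
#' @export
contrast_epochs <- function(result_a, result_b, n_boot = 1000L, conf = 0.9,
                            seed = 1L) {
  if (result_a$empty || result_b$empty)
    stop("both growth_response results must be non-empty", call. = FALSE)
  delta <- result_a$suppressed_fraction - result_b$suppressed_fraction

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(as.integer(seed))
  frac <- function(rwi) 100 * mean(rwi < 1)
  boots <- vapply(seq_len(n_boot), function(i) {
    ra <- sample(result_a$rwi_significant, replace = TRUE)
    rb <- sample(result_b$rwi_significant, replace = TRUE)
    frac(ra) - frac(rb)
  }, numeric(1))
  qs <- quantile(boots, probs = c((1 - conf) / 2, 1 - (1 - conf) / 2))
  list(delta_suppressed = delta, ci = unname(qs), conf = conf,
       suppressed_a = result_a$suppressed_fraction,
       suppressed_b = result_b$suppressed_fraction)
}
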