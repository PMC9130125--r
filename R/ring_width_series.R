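#' Ring-width series
#'
#' One measured radial transect of annual ring widths on a relative
#' ("floating") year axis. Fossil chronologies cannot be anchored to calendar
#' years, so `first_year` is chronology-internal: only differences between
#' years are meaningful.
#'
#' @param widths Numeric vector of ring widths in mm; all finite and > 0,
#'   one value per consecutive year.
#' @param series_id Unique identifier of the transect.
#' @param tree_id Identifier of the tree the transect was measured on.
#' @param radius_id Identifier of the radius within the tree.
#' @param first_year Integer year (relative axis) of the first ring.
#' @param precision Measurement resolution in mm (e.g. 0.001 for
#'   high-precision caliper measurements).
#'
#' @return An object of class `rw_series`: a list with fields `series_id`,
#'   `tree_id`, `radius_id`, `first_year`, `widths`, `precision`.
#' @export
rw_series <- function(widths, series_id = "S1", tree_id = series_id,
                      radius_id = "r1", first_year = 1L,
                      precision = 0.001) {
  widths <- as.numeric(widths)
  if (length(widths) < 1L)
    stop("ring-width series must contain at least one ring", call. = FALSE)
  if (!all(is.finite(widths)))
    stop("ring widths must all be finite", call. = FALSE)
  if (any(widths <= 0))
    stop("ring widths must all be positive (series '", series_id, "')",
         call. = FALSE)
  if (!is.finite(first_year) || first_year != round(first_year))
    stop("first_year must be an integer year", call. = FALSE)
  structure(
    list(series_id = as.character(series_id),
         tree_id = as.character(tree_id),
         radius_id = as.character(radius_id),
         first_year = as.integer(first_year),
         widths = widths,
         precision = precision),
    class = "rw_series")
}

#' Year axis of a ring-width series
#'
#' @param x An `rw_series`.
#' @return Integer vector of relative years, one per ring.
#' @export
rw_years <- function(x) {
  stopifnot(inherits(x, "rw_series"))
  seq.int(x$first_year, length.out = length(x$widths))
}

#' @export
print.rw_series <- function(x, ...) {
  yrs <- rw_years(x)
  cat(sprintf("<rw_series '%s' (tree %s, radius %s): %d rings, years %d..%d, mean %.3f mm>\n",
              x$series_id, x$tree_id, x$radius_id, length(x$widths),
              min(yrs), max(yrs), mean(x$widths)))
  invisible(x)
}

#' @export
as.data.frame.rw_series <- function(x, ...) {
  data.frame(series_id = x$series_id, tree_id = x$tree_id,
             radius_id = x$radius_id, year = rw_years(x),
             width_mm = x$widths, stringsAsFactors = FALSE)
}

#' Overlapping segment of two ring-width series at a lag
#'
#' Internal helper: common relative years of `a` and `b` after shifting `b`
#' by `lag` years (positive lag moves `b` later).
#' @noRd
overlap_at_lag <- function(a, b, lag) {
  ya <- rw_years(a)
  yb <- rw_years(b) + lag
  common <- intersect(ya, yb)
  if (length(common) == 0L) return(NULL)
  list(years = common,
       wa = a$widths[match(common, ya)],
       wb = b$widths[match(common, yb)])
}
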