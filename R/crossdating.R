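#' Baillie--Pilcher transform
#'
#' Index each ring as the log of its width over the centered moving average
#' of the surrounding `window` years; years without a full window are
#' dropped. The transform removes growth-trend and scale so correlations
#' compare year-to-year variation only.
#'
#' @param series An [rw_series()].
#' @param window Moving-average window in years (odd; classic value 5).
#' @return List with `years` and `values` (length `n - window + 1`).
#' @export
bp_transform <- function(series, window = 5L) {
  w <- series$widths
  n <- length(w)
  if (window %% 2L != 1L) stop("window must be odd", call. = FALSE)
  if (n < window)
    stop("series must be at least as long as the moving-average window",
         call. = FALSE)
  ma <- as.numeric(stats::filter(w, rep(1 / window, window), sides = 2))
  keep <- !is.na(ma)
  list(years = rw_years(series)[keep], values = log(w[keep] / ma[keep]))
}

#' Hollstein transform
#'
#' Hollstein's "Wuchswerte": `100 * log10(w[t] / w[t-1])`, the percent
#' year-to-year growth change on a log scale; the value is indexed to the
#' later year, so the result has length `n - 1`.
#'
#' @param series An [rw_series()].
#' @return List with `years` and `values`.
#' @export
ho_transform <- function(series) {
  w <- series$widths
  if (length(w) < 2L) stop("series must have at least 2 rings", call. = FALSE)
  list(years = rw_years(series)[-1],
       values = 100 * log10(w[-1] / w[-length(w)]))
}

#' Correlation t-statistic of two aligned indexed series
#'
#' Pearson correlation over the common years and the associated Student t,
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)`. Zero variance in either series or
#' `|r| = 1` is flagged degenerate rather than failing (`t = Inf` sentinel
#' for a perfect match).
#'
#' @param x,y Lists with `years` and `values` (see [bp_transform()]).
#' @return List with `r`, `t`, `n`, `degenerate`.
#' @export
t_statistic <- function(x, y) {
  common <- intersect(x$years, y$years)
  n <- length(common)
  if (n < 3L) stop("aligned overlap must be at least 3", call. = FALSE)
  vx <- x$values[match(common, x$years)]
  vy <- y$values[match(common, y$years)]
  if (sd(vx) == 0 || sd(vy) == 0)
    return(list(r = NA_real_, t = NA_real_, n = n, degenerate = TRUE))
  r <- cor(vx, vy)
  if (abs(r) >= 1 - 1e-12)
    return(list(r = sign(r), t = sign(r) * Inf, n = n, degenerate = TRUE))
  list(r = r, t = r * sqrt(n - 2) / sqrt(1 - r^2), n = n, degenerate = FALSE)
}

glk_score <- function(dx, dy) {
  s <- ifelse(dx * dy > 0, 1,
              ifelse(dx == 0 & dy == 0, 1,
                     ifelse(dx == 0 | dy == 0, 0.5, 0)))
  100 * mean(s)
}

#' Percent parallel covariation (Gleichlaeufigkeit)
#'
#' Over the overlapping year-to-year differences of two raw series, score 1
#' when both change in the same (nonzero) direction or both are flat, 0.5
#' when exactly one is flat, 0 otherwise; GLK is 100 times the mean score.
#'
#' @param x,y [rw_series()] objects.
#' @param lag Shift of `y` relative to `x` in years.
#' @return GLK percentage in `[0, 100]`.
#' @export
gleichlauf <- function(x, y, lag = 0L) {
  ov <- overlap_at_lag(x, y, lag)
  if (is.null(ov) || length(ov$years) < 2L)
    stop("overlap must be at least 2 years", call. = FALSE)
  glk_score(diff(ov$wa), diff(ov$wb))
}

#' Exhaustive cross-match of two ring-width series
#'
#' Scans every lag with at least `min_overlap` overlapping years and scores
#' each candidate alignment with the Baillie--Pilcher t (`t_bp`), the
#' Hollstein t (`t_ho`), the Pearson correlation of the Baillie--Pilcher
#' transformed series (`r`) and the percent parallel covariation (`glk`). A
#' lag is accepted when all thresholds are met (both t-statistics must clear
#' `t_min`; requiring the two independent transforms jointly keeps the
#' false-positive rate of the exhaustive scan low). Results are sorted by
#' `t_bp` descending, ties broken by higher `glk`, then smaller `|lag|`.
#'
#' @param a,b [rw_series()] objects.
#' @param min_overlap Minimum overlapping rings for a candidate lag
#'   (default 20, the minimum ring count for replicable cross-dating).
#' @param thresholds List `t_min`, `glk_min`, `r_min` acceptance gates.
#' @param window Baillie--Pilcher moving-average window.
#' @return Data frame of class `crossmatch_results`: one row per lag with
#'   columns `series_a, series_b, lag, n_overlap, r, t_bp, t_ho, glk,
#'   accepted`; empty (zero rows) when no lag has sufficient overlap.
#' @export
crossmatch <- function(a, b, min_overlap = 20L,
                       thresholds = list(t_min = 3.5, glk_min = 65, r_min = 0.5),
                       window = 5L) {
  na <- length(a$widths); nb <- length(b$widths)
  a1 <- a$first_year; b1 <- b$first_year
  # overlap(L) = min(a2, b2 + L) - max(a1, b1 + L) + 1 >= min_overlap
  lags <- seq.int(a1 - b1 - nb + min_overlap, a1 - b1 + na - min_overlap)
  empty <- data.frame(series_a = character(0), series_b = character(0),
                      lag = integer(0), n_overlap = integer(0), r = numeric(0),
                      t_bp = numeric(0), t_ho = numeric(0), glk = numeric(0),
                      accepted = logical(0))
  class(empty) <- c("crossmatch_results", class(empty))
  if (length(lags) == 0L || min(na, nb) < min_overlap) return(empty)

  tb_a <- bp_transform(a, window); tb_b <- bp_transform(b, window)
  th_a <- ho_transform(a); th_b <- ho_transform(b)
  dwa <- diff(a$widths); dwb <- diff(b$widths)

  # contiguous-axis overlap: indices computed arithmetically per lag
  seg <- function(y1a, na, y1b, nb, L) {
    cs <- max(y1a, y1b + L); ce <- min(y1a + na - 1L, y1b + L + nb - 1L)
    if (ce < cs) return(NULL)
    list(ia = (cs - y1a + 1L):(ce - y1a + 1L),
         ib = (cs - y1b - L + 1L):(ce - y1b - L + 1L))
  }
  rt <- function(va, vb) {  # r and t with degeneracy handling
    if (sd(va) == 0 || sd(vb) == 0) return(c(NA_real_, NA_real_))
    r <- cor(va, vb)
    n <- length(va)
    if (abs(r) >= 1 - 1e-12) return(c(sign(r), sign(r) * Inf))
    c(r, r * sqrt(n - 2) / sqrt(1 - r^2))
  }

  ya1 <- a$first_year; yb1 <- b$first_year
  bp_a1 <- tb_a$years[1]; bp_b1 <- tb_b$years[1]
  ho_a1 <- th_a$years[1]; ho_b1 <- th_b$years[1]
  rows <- lapply(lags, function(L) {
    raw <- seg(ya1, na, yb1, nb, L)
    if (is.null(raw) || length(raw$ia) < min_overlap) return(NULL)
    bp <- seg(bp_a1, length(tb_a$values), bp_b1, length(tb_b$values), L)
    ho <- seg(ho_a1, length(th_a$values), ho_b1, length(th_b$values), L)
    if (is.null(bp) || length(bp$ia) < 3L || is.null(ho) || length(ho$ia) < 3L)
      return(NULL)
    st_bp <- rt(tb_a$values[bp$ia], tb_b$values[bp$ib])
    st_ho <- rt(th_a$values[ho$ia], th_b$values[ho$ib])
    glk <- glk_score(dwa[raw$ia[-length(raw$ia)]], dwb[raw$ib[-length(raw$ib)]])
    r <- st_bp[1]; t_bp <- st_bp[2]; t_ho <- st_ho[2]
    # acceptance requires BOTH t-statistics: a single t >= 3.5 is reachable
    # by chance over a many-lag scan at minimal overlap
    acc <- !is.na(t_bp) && !is.na(r) && !is.na(t_ho) &&
      t_bp >= thresholds$t_min && t_ho >= thresholds$t_min &&
      glk >= thresholds$glk_min && r >= thresholds$r_min
    list(lag = L, n_overlap = length(raw$ia), r = r, t_bp = t_bp,
         t_ho = st_ho[2], glk = glk, accepted = acc)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) return(empty)
  res <- data.frame(
    series_a = a$series_id, series_b = b$series_id,
    lag = vapply(rows, `[[`, numeric(1), "lag"),
    n_overlap = as.integer(vapply(rows, `[[`, numeric(1), "n_overlap")),
    r = vapply(rows, `[[`, numeric(1), "r"),
    t_bp = vapply(rows, `[[`, numeric(1), "t_bp"),
    t_ho = vapply(rows, `[[`, numeric(1), "t_ho"),
    glk = vapply(rows, `[[`, numeric(1), "glk"),
    accepted = vapply(rows, `[[`, logical(1), "accepted"))
  ord <- order(-res$t_bp, -res$glk, abs(res$lag))
  res <- res[ord, ]
  rownames(res) <- NULL
  class(res) <- c("crossmatch_results", class(res))
  res
}

#' Compose accepted cross-matches into a master alignment
#'
#' Offsets are composed along the graph of accepted matches (an edge
#' `a -- b` at lag `L` aligns `b`'s years shifted by `+L` with `a`'s).
#' Series not connected to the largest component are excluded; a cycle whose
#' lags do not sum to zero is an alignment conflict and raises an error
#' naming the offending edge.
#'
#' @param series List of [rw_series()].
#' @param matches A `crossmatch_results` data frame (typically best accepted
#'   lags, one row per pair).
#' @return List with `aligned` (series with shifted year axes, earliest year
#'   normalized to 1), `offsets` (named, min 0), `excluded` (series ids),
#'   `chronology_length` (span of the union of aligned years) and
#'   `mean_overlap` (mean pairwise overlap of retained aligned series).
#' @export
build_master <- function(series, matches) {
  ids <- vapply(series, `[[`, character(1), "series_id")
  names(series) <- ids
  m <- matches[matches$accepted, , drop = FALSE]
  offsets <- stats::setNames(rep(NA_real_, length(ids)), ids)

  if (length(ids)) {
    offsets[ids[1]] <- 0
    repeat {
      progressed <- FALSE
      for (i in seq_len(nrow(m))) {
        sa <- m$series_a[i]; sb <- m$series_b[i]; L <- m$lag[i]
        ka <- !is.na(offsets[sa]); kb <- !is.na(offsets[sb])
        if (ka && kb) {
          if (abs((offsets[sa] + L) - offsets[sb]) > 1e-9)
            stop("alignment conflict: cycle through ", sa, " -- ", sb,
                 " has inconsistent lag ", L, call. = FALSE)
        } else if (ka) {
          offsets[sb] <- offsets[sa] + L; progressed <- TRUE
        } else if (kb) {
          offsets[sa] <- offsets[sb] - L; progressed <- TRUE
        }
      }
      if (!progressed) break
    }
    # if the reference series is isolated, seed the next unvisited component:
    # retain only the component of the first series; others are excluded
  }
  excluded <- ids[is.na(offsets)]
  keep <- ids[!is.na(offsets)]
  if (length(keep) == 0L)
    stop("no series could be aligned", call. = FALSE)
  off <- offsets[keep]
  aligned <- lapply(keep, function(id) {
    s <- series[[id]]
    s$first_year <- as.integer(s$first_year + off[id])
    s
  })
  first <- min(vapply(aligned, function(s) min(rw_years(s)), numeric(1)))
  aligned <- lapply(aligned, function(s) {
    s$first_year <- as.integer(s$first_year - first + 1L); s
  })
  yrs <- sort(unique(unlist(lapply(aligned, rw_years))))
  overlaps <- c()
  if (length(aligned) > 1L) {
    for (i in seq_along(aligned)) for (j in seq_along(aligned)) {
      if (i < j) {
        ov <- length(intersect(rw_years(aligned[[i]]), rw_years(aligned[[j]])))
        if (ov > 0) overlaps <- c(overlaps, ov)
      }
    }
  }
  names(aligned) <- keep
  list(aligned = aligned,
       offsets = off - min(off),
       excluded = excluded,
       chronology_length = max(yrs) - min(yrs) + 1L,
       mean_overlap = if (length(overlaps)) mean(overlaps) else NA_real_)
}

#' Average replicate radii of each tree
#'
#' Replicate transects of a tree are cross-matched against the tree's first
#' radius and, where a successful match exists, aligned at the best accepted
#' lag and averaged (arithmetic mean per year). Radii that fail to match are
#' dropped and reported.
#'
#' @param series List of [rw_series()] (multiple radii per tree).
#' @inheritParams crossmatch
#' @return List with `trees` (one averaged [rw_series()] per tree, id =
#'   tree id) and `dropped` (series ids that failed intra-tree matching).
#' @export
average_radii <- function(series, min_overlap = 20L,
                          thresholds = list(t_min = 3.5, glk_min = 65, r_min = 0.5),
                          window = 5L) {
  tree_ids <- vapply(series, `[[`, character(1), "tree_id")
  dropped <- character(0)
  trees <- lapply(unique(tree_ids), function(tid) {
    radii <- series[tree_ids == tid]
    if (length(radii) == 1L) {
      s <- radii[[1]]; s$series_id <- tid
      return(s)
    }
    ref <- radii[[1]]
    kept <- list(ref)
    for (s in radii[-1]) {
      cm <- crossmatch(ref, s, min_overlap, thresholds, window)
      cm <- cm[cm$accepted, , drop = FALSE]
      if (nrow(cm) == 0L) {
        dropped <<- c(dropped, s$series_id)
        next
      }
      s$first_year <- as.integer(s$first_year + cm$lag[1])
      kept <- c(kept, list(s))
    }
    yrs <- sort(unique(unlist(lapply(kept, rw_years))))
    w <- vapply(yrs, function(y) {
      vals <- unlist(lapply(kept, function(s) {
        i <- match(y, rw_years(s)); if (is.na(i)) NULL else s$widths[i]
      }))
      mean(vals)
    }, numeric(1))
    rw_series(w, series_id = tid, tree_id = tid, radius_id = "mean",
              first_year = min(yrs), precision = radii[[1]]$precision)
  })
  list(trees = trees, dropped = dropped)
}

#' Cross-date a set of series end to end
#'
#' Averages replicate radii per tree, cross-matches every tree pair, keeps
#' the best accepted lag per pair, and composes the accepted matches into a
#' master alignment.
#'
#' @param series List of [rw_series()].
#' @inheritParams crossmatch
#' @return List with the [build_master()] result (`master`), the per-pair
#'   best-match table (`matches`) and intra-tree `dropped` ids.
#' @export
crossdate_set <- function(series, min_overlap = 20L,
                          thresholds = list(t_min = 3.5, glk_min = 65, r_min = 0.5),
                          window = 5L) {
  avg <- average_radii(series, min_overlap, thresholds, window)
  trees <- avg$trees
  best <- list()
  for (i in seq_along(trees)) for (j in seq_along(trees)) {
    if (i >= j) next
    cm <- crossmatch(trees[[i]], trees[[j]], min_overlap, thresholds, window)
    if (nrow(cm)) best[[length(best) + 1L]] <- cm[1, ]
  }
  matches <- do.call(rbind, best)
  master <- build_master(trees, matches)
  list(master = master, matches = matches, dropped = avg$dropped)
}
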