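#' Read a Tucson/decadal RWL ring-width file
#'
#' Parses the fixed-width Tucson interchange dialect: series id in columns
#' 1-8, decade start year in columns 9-12, then up to ten ring values per
#' row. Two unit dialects are auto-detected from the terminator value that
#' closes each series: `999` marks 0.01 mm units and `-9999` marks 0.001 mm
#' units; the detected measurement precision is recorded per series and the
#' terminator is never emitted as data.
#'
#' @param path Path to an RWL file.
#' @return List of [rw_series()] (tree/radius ids parsed from the series id
#'   when it matches the `<tree>R<radius>` pattern used by [write_rwl()]).
#' @export
read_rwl <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  ids <- trimws(substr(lines, 1L, 8L))
  out <- list()
  cur_id <- NULL; cur_vals <- numeric(0); cur_first <- NA_integer_
  cur_next <- NA_integer_

  finish <- function() {
    if (is.null(cur_id)) return()
    n <- length(cur_vals)
    if (n < 2L)
      stop("series '", cur_id, "': no terminator found", call. = FALSE)
    term <- cur_vals[n]
    prec <- if (term == -9999) 0.001 else if (term == 999) 0.01 else
      stop("series '", cur_id, "': last value ", term,
           " is not a recognized terminator (999 or -9999)", call. = FALSE)
    vals <- cur_vals[-n] * prec
    if (!is.null(out[[cur_id]]))
      stop("duplicate series id '", cur_id, "'", call. = FALSE)
    ids_split <- regmatches(cur_id, regexec("^(.*)R(\\d+)$", cur_id))[[1]]
    out[[cur_id]] <<- rw_series(
      vals, series_id = cur_id,
      tree_id = if (length(ids_split) == 3) ids_split[2] else cur_id,
      radius_id = if (length(ids_split) == 3) paste0("r", ids_split[3]) else "r1",
      first_year = cur_first, precision = prec)
  }

  for (i in seq_along(lines)) {
    year <- suppressWarnings(as.integer(substr(lines[i], 9L, 12L)))
    if (is.na(year))
      stop("malformed decade row at line ", i, ": cannot parse year in '",
           substr(lines[i], 1L, 12L), "'", call. = FALSE)
    tok <- strsplit(trimws(substr(lines[i], 13L, nchar(lines[i]))), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(tok))
    if (length(vals) == 0L || anyNA(vals))
      stop("malformed decade row at line ", i, ": non-numeric ring value",
           call. = FALSE)
    if (is.null(cur_id) || ids[i] != cur_id) {
      finish()
      cur_id <- ids[i]; cur_vals <- numeric(0)
      cur_first <- year; cur_next <- year
    } else if (year != cur_next) {
      stop("malformed decade row at line ", i, ": expected start year ",
           cur_next, ", found ", year, call. = FALSE)
    }
    cur_vals <- c(cur_vals, vals)
    cur_next <- year + length(vals)
  }
  finish()
  unname(out)
}

#' Write ring-width series to a Tucson/decadal RWL file
#'
#' The unit dialect follows each series' recorded `precision`: 0.001 mm
#' series are written as integer thousandths terminated by `-9999`, anything
#' coarser as integer hundredths terminated by `999`.
#'
#' @param series List of [rw_series()] (or a single one).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rwl <- function(series, path) {
  if (inherits(series, "rw_series")) series <- list(series)
  con <- file(path, "w")
  on.exit(close(con))
  for (s in series) {
    fine <- s$precision <= 0.001
    scale <- if (fine) 1000 else 100
    term <- if (fine) -9999L else 999L
    vals <- c(as.integer(round(s$widths * scale)), term)
    yrs <- c(rw_years(s), max(rw_years(s)) + 1L)
    row_start <- 1L
    while (row_start <= length(vals)) {
      y0 <- yrs[row_start]
      n_row <- min(10L - (y0 %% 10L), length(vals) - row_start + 1L)
      idx <- row_start:(row_start + n_row - 1L)
      writeLines(sprintf("%-8s%4d%s", s$series_id, y0,
                         paste0(sprintf("%6d", vals[idx]), collapse = "")), con)
      row_start <- row_start + n_row
    }
  }
  invisible(path)
}

#' Read / write ring-width series as long-form CSV
#'
#' Columns `series_id, tree_id, radius_id, year, width_mm`; one row per ring,
#' years contiguous within a series. The round trip is lossless.
#'
#' @param path File path.
#' @return `read_series_csv` returns a list of [rw_series()];
#'   `write_series_csv` returns `path` invisibly.
#' @export
read_series_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("series_id", "tree_id", "radius_id", "year", "width_mm")
  if (!all(req %in% names(d)))
    stop("CSV must have columns ", paste(req, collapse = ", "), call. = FALSE)
  bad <- which(!is.finite(d$width_mm) | d$width_mm <= 0)
  if (length(bad))
    stop("non-positive or missing width at row ", bad[1], call. = FALSE)
  lapply(split(d, factor(d$series_id, levels = unique(d$series_id))),
         function(g) {
           g <- g[order(g$year), ]
           if (any(diff(g$year) != 1L))
             stop("series '", g$series_id[1],
                  "': year axis not contiguous", call. = FALSE)
           rw_series(g$width_mm, series_id = g$series_id[1],
                     tree_id = g$tree_id[1], radius_id = g$radius_id[1],
                     first_year = g$year[1])
         }) |> unname()
}

#' @rdname read_series_csv
#' @param series List of [rw_series()] (or a single one).
#' @export
write_series_csv <- function(series, path) {
  if (inherits(series, "rw_series")) series <- list(series)
  d <- do.call(rbind, lapply(series, as.data.frame))
  write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
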