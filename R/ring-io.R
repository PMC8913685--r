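#' Dated ring-width series for a single tree
#'
#' A `ring_series` holds the dated ring widths of one tree together with the
#' stem diameter at breast height (DBH) measured when the tree was sampled.
#' The DBH anchors the outside-in reconstruction of stem radii used by
#' [rings_to_bai()]: the sampled radius may exceed the cumulative ring widths
#' (pith missed by the core) but never the reverse.
#'
#' @param tree_code Character tree identifier (unique within a site).
#' @param site_id Character site identifier.
#' @param first_year Calendar year of the innermost (oldest) measured ring.
#' @param widths Numeric vector of ring widths in mm, ordered oldest to
#'   youngest. All widths must be positive.
#' @param dbh_mm Diameter at breast height at sampling, mm.
#' @return An object of class `ring_series`.
#' @export
ring_series <- function(tree_code, site_id, first_year, widths, dbh_mm) {
  stopifnot(length(tree_code) == 1L, length(site_id) == 1L,
            length(first_year) == 1L, length(dbh_mm) == 1L)
  widths <- as.numeric(widths)
  if (length(widths) < 1L || any(!is.finite(widths)))
    stop("ring_series: widths must be a non-empty finite numeric vector")
  if (any(widths <= 0))
    stop(sprintf("ring_series: tree '%s' has non-positive ring widths; missing rings are not supported",
                 tree_code))
  if (dbh_mm < 2 * sum(widths) - 1e-9)
    stop(sprintf("ring_series: tree '%s' has dbh_mm (%.2f) < 2 * sum(widths) (%.2f)",
                 tree_code, dbh_mm, 2 * sum(widths)))
  structure(
    list(tree_code = as.character(tree_code), site_id = as.character(site_id),
         first_year = as.integer(first_year), widths = widths,
         dbh_mm = as.numeric(dbh_mm)),
    class = "ring_series")
}

#' @export
print.ring_series <- function(x, ...) {
  cat(sprintf("<ring_series> tree %s @ site %s: %d rings %d-%d, dbh %.1f mm\n",
              x$tree_code, x$site_id, length(x$widths),
              x$first_year, x$first_year + length(x$widths) - 1L, x$dbh_mm))
  invisible(x)
}

#' @export
format.ring_series <- function(x, ...) {
  sprintf("%s/%s [%d rings]", x$site_id, x$tree_code, length(x$widths))
}

# Tucson dialects: terminator 999 means values are hundredths of mm,
# terminator -9999 means thousandths of mm.
.rwl_dialects <- list(
  "0.01"  = list(scale = 100,  stop = 999L),
  "0.001" = list(scale = 1000, stop = -9999L)
)

#' Read a Tucson/rwl ring-width file
#'
#' Parses the fixed-width Tucson interchange format: each line carries a
#' series id (columns 1-8), the decade year (columns 9-12) and up to ten
#' integer ring widths. The measurement precision is inferred per series from
#' the stop marker: `999` codes widths in 0.01 mm, `-9999` in 0.001 mm.
#' Returned widths are always in mm.
#'
#' Because the rwl format carries no DBH, the returned series have `dbh_mm`
#' set from `metadata` when given (a data.frame with columns `tree_code`,
#' `site_id`, `dbh_mm`), else to twice the cumulative width (pith assumed
#' reached).
#'
#' @param path Path to an rwl file.
#' @param metadata Optional data.frame with `tree_code`, `site_id`, `dbh_mm`.
#' @return List of [ring_series()] objects.
#' @seealso [write_rwl()]
#' @export
read_rwl <- function(path, metadata = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  recs <- list()
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    id <- trimws(substr(ln, 1L, 8L))
    yr <- suppressWarnings(as.integer(trimws(substr(ln, 9L, 12L))))
    if (!nzchar(id) || is.na(yr))
      stop(sprintf("read_rwl: malformed decade line %d: '%s'", i, ln))
    vals <- suppressWarnings(as.integer(strsplit(trimws(substr(ln, 13L, nchar(ln))),
                                                 "\\s+")[[1]]))
    if (any(is.na(vals)))
      stop(sprintf("read_rwl: non-numeric value on line %d", i))
    recs[[length(recs) + 1L]] <- list(id = id, year = yr, vals = vals)
  }
  ids <- vapply(recs, `[[`, character(1), "id")
  series <- list()
  for (id in unique(ids)) {
    rs <- recs[ids == id]
    first_year <- rs[[1]]$year
    stream <- unlist(lapply(rs, `[[`, "vals"))
    stop_at <- which(stream == 999L | stream == -9999L)
    if (length(stop_at) == 0L)
      stop(sprintf("read_rwl: series '%s' has no recognised stop marker (999 or -9999)", id))
    stop_at <- stop_at[[length(stop_at)]]
    if (stop_at != length(stream))
      stop(sprintf("read_rwl: series '%s': values found after stop marker", id))
    dialect <- if (stream[stop_at] == 999L) .rwl_dialects[["0.01"]] else .rwl_dialects[["0.001"]]
    widths <- stream[-stop_at] / dialect$scale
    meta <- NULL
    if (!is.null(metadata)) {
      hit <- metadata$tree_code == id
      if (any(hit)) meta <- metadata[which(hit)[1], ]
    }
    series[[length(series) + 1L]] <- ring_series(
      tree_code = id,
      site_id = if (!is.null(meta)) meta$site_id else "unknown",
      first_year = first_year,
      widths = widths,
      dbh_mm = if (!is.null(meta)) meta$dbh_mm else 2 * sum(widths))
  }
  series
}

#' Write ring-width series to a Tucson/rwl file
#'
#' @param series List of [ring_series()] objects.
#' @param path Output path.
#' @param precision `"0.01"` (999 stop marker) or `"0.001"` (-9999 marker).
#' @return `path`, invisibly.
#' @export
write_rwl <- function(series, path, precision = c("0.01", "0.001")) {
  precision <- match.arg(precision)
  dialect <- .rwl_dialects[[precision]]
  con <- file(path, "w")
  on.exit(close(con))
  for (s in series) {
    vals <- as.integer(round(s$widths * dialect$scale))
    vals <- c(vals, dialect$stop)
    years <- seq(s$first_year, length.out = length(vals))
    decade <- years - (years %% 10L)
    for (d in unique(decade)) {
      sel <- decade == d
      writeLines(sprintf("%-8s%4d%s", substr(s$tree_code, 1, 8), years[sel][1],
                         paste0(sprintf("%6d", vals[sel]), collapse = "")), con)
    }
  }
  invisible(path)
}

#' Write / read the tree metadata table accompanying an rwl file
#'
#' @param series List of [ring_series()] objects.
#' @param path CSV path with columns `tree_code`, `site_id`, `dbh_mm`.
#' @return For the reader, a data.frame; for the writer, `path` invisibly.
#' @export
write_ring_metadata <- function(series, path) {
  df <- data.frame(
    tree_code = vapply(series, `[[`, character(1), "tree_code"),
    site_id = vapply(series, `[[`, character(1), "site_id"),
    dbh_mm = vapply(series, `[[`, numeric(1), "dbh_mm"))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ring_metadata
#' @export
read_ring_metadata <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("tree_code", "site_id", "dbh_mm")
  if (!all(need %in% names(df)))
    stop("read_ring_metadata: CSV must have columns tree_code, site_id, dbh_mm")
  df
}

#' Convert a ring-width series to annual basal area increments
#'
#' Reconstructs stem radii outside-in from the sampled DBH
#' (\eqn{R_n = dbh/2}, \eqn{R_{t-1} = R_t - w_t}) and returns the annual
#' basal area increment \eqn{BAI_t = \pi (R_t^2 - R_{t-1}^2)} in mm^2/yr,
#' together with the basal area at the start of each year
#' (\eqn{ba\_prev_t = \pi R_{t-1}^2}). Anchoring on the measured DBH rather
#' than on cumulative widths keeps period means comparable without classical
#' detrending.
#'
#' @param series A [ring_series()] or a list of them.
#' @return A `bai_table` data.frame with columns `site_id`, `tree_code`,
#'   `year`, `bai` (mm^2/yr) and `ba_prev` (mm^2).
#' @export
rings_to_bai <- function(series) {
  if (inherits(series, "ring_series")) series <- list(series)
  out <- lapply(series, function(s) {
    n <- length(s$widths)
    # radii outside-in: r[n+1] = dbh/2 down to r[1] (innermost)
    r <- numeric(n + 1L)
    r[n + 1L] <- s$dbh_mm / 2
    for (t in n:1) r[t] <- r[t + 1L] - s$widths[t]
    if (any(r < -1e-9))
      stop(sprintf("rings_to_bai: tree '%s': reconstructed radius negative (widths exceed sampled radius)",
                   s$tree_code))
    r[r < 0] <- 0
    data.frame(
      site_id = s$site_id, tree_code = s$tree_code,
      year = seq(s$first_year, length.out = n),
      bai = pi * (r[-1L]^2 - r[-(n + 1L)]^2),
      ba_prev = pi * r[-(n + 1L)]^2)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("bai_table", "data.frame")
  res
}

#' Fill or validate the lagged basal-area column of a BAI table
#'
#' Given per-tree annual BAI in consecutive years, (re)computes `ba_prev`
#' by telescoping: `ba_prev(t+1) = ba_prev(t) + bai(t)`, starting from the
#' first row's `ba_prev` if present (0 otherwise, i.e. pith reached). Errors
#' on gap years: series must be continuous.
#'
#' @param table A data.frame with `site_id`, `tree_code`, `year`, `bai` and
#'   optionally `ba_prev` (its first value per tree seeds the recursion).
#' @return The table with a consistent `ba_prev` column, ordered by tree and
#'   year.
#' @export
attach_previous_ba <- function(table) {
  stopifnot(all(c("site_id", "tree_code", "year", "bai") %in% names(table)))
  key <- interaction(table$site_id, table$tree_code, drop = TRUE)
  parts <- split(seq_len(nrow(table)), key)
  for (idx in parts) {
    idx <- idx[order(table$year[idx])]
    yrs <- table$year[idx]
    if (length(yrs) > 1L && any(diff(yrs) != 1L))
      stop(sprintf("attach_previous_ba: tree '%s' has gap years (%s); series must be continuous",
                   table$tree_code[idx[1]],
                   paste(yrs[c(FALSE, diff(yrs) != 1L)], collapse = ", ")))
    ba0 <- if ("ba_prev" %in% names(table) && is.finite(table$ba_prev[idx[1]]))
      table$ba_prev[idx[1]] else 0
    table$ba_prev[idx] <- ba0 + c(0, cumsum(table$bai[idx]))[seq_along(idx)]
  }
  table <- table[order(table$site_id, table$tree_code, table$year), ]
  rownames(table) <- NULL
  class(table) <- unique(c("bai_table", class(table)))
  table
}

#' Convert a BAI table between mm^2 and cm^2
#'
#' Internal computations use mm^2 throughout; growth is often reported in
#' cm^2/yr.
#'
#' @param table A `bai_table`.
#' @param to `"cm2"` or `"mm2"`.
#' @return The converted table (columns `bai`, `ba_prev` rescaled).
#' @export
convert_bai_units <- function(table, to = c("cm2", "mm2")) {
  to <- match.arg(to)
  f <- if (to == "cm2") 1 / 100 else 100
  table$bai <- table$bai * f
  table$ba_prev <- table$ba_prev * f
  table
}
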