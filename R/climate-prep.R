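#' Aggregate monthly climate to seasonal growth-model predictors
#'
#' Builds the six seasonal windows the growth model uses for each ring year
#' `t`: previous-year summer (`pSUM`) and autumn (`pAUT`), then current-year
#' winter (`WIN` = Dec of `t-1`, Jan, Feb), spring (`SPR` = MAM), summer
#' (`SUM` = JJA) and autumn (`AUT` = SON). Temperatures are averaged over the
#' three months of a season, precipitation is summed. Seasons with any month
#' missing are omitted.
#'
#' @param monthly Data.frame with columns `site_id`, `year`, `month`, `tmax`,
#'   `tmin`, `prcp` (degrees C and mm).
#' @return A `seasonal_climate` data.frame with columns `site_id`, `year`,
#'   `season` (one of `pSUM, pAUT, WIN, SPR, SUM, AUT`), `tmax_mean`,
#'   `tmin_mean`, `pp_sum`.
#' @export
aggregate_seasons <- function(monthly) {
  need <- c("site_id", "year", "month", "tmax", "tmin", "prcp")
  if (!all(need %in% names(monthly)))
    stop("aggregate_seasons: monthly table needs columns ",
         paste(need, collapse = ", "))
  if (any(monthly$prcp < 0, na.rm = TRUE))
    stop("aggregate_seasons: negative precipitation")
  m <- monthly
  # assign each month to a (base-season, season-year); Dec belongs to next
  # year's winter
  base <- character(nrow(m)); syear <- m$year
  mo <- m$month
  base[mo %in% 3:5] <- "SPR"
  base[mo %in% 6:8] <- "SUM"
  base[mo %in% 9:11] <- "AUT"
  base[mo %in% c(1L, 2L)] <- "WIN"
  base[mo == 12L] <- "WIN"
  syear[mo == 12L] <- m$year[mo == 12L] + 1L
  key <- paste(m$site_id, syear, base, sep = "\r")
  cnt <- tapply(rep(1L, nrow(m)), key, sum)
  complete <- names(cnt)[cnt == 3L]
  keep <- key %in% complete
  m <- m[keep, ]; key <- key[keep]
  agg <- data.frame(
    key = names(tapply(m$tmax, key, mean)),
    tmax_mean = as.numeric(tapply(m$tmax, key, mean)),
    tmin_mean = as.numeric(tapply(m$tmin, key, mean)),
    pp_sum = as.numeric(tapply(m$prcp, key, sum)))
  parts <- do.call(rbind, strsplit(agg$key, "\r", fixed = TRUE))
  cur <- data.frame(site_id = parts[, 1], year = as.integer(parts[, 2]),
                    season = parts[, 3],
                    tmax_mean = agg$tmax_mean, tmin_mean = agg$tmin_mean,
                    pp_sum = agg$pp_sum)
  # previous-year summer/autumn re-keyed to the ring year t
  prev <- cur[cur$season %in% c("SUM", "AUT"), ]
  prev$year <- prev$year + 1L
  prev$season <- paste0("p", prev$season)
  out <- rbind(cur, prev)
  out <- out[order(out$site_id, out$year, match(out$season, SEASONS)), ]
  rownames(out) <- NULL
  out$season <- factor(out$season, levels = SEASONS)
  class(out) <- c("seasonal_climate", "data.frame")
  out
}

#' De Martonne aridity index
#'
#' `AI = P / (10 + T)` with `P` the annual precipitation sum (mm) and `T` the
#' annual mean air temperature (degrees C). Higher values are wetter. Only
#' defined for `T > -10` (the pole of the index).
#'
#' @param p_annual Annual precipitation sum, mm (>= 0).
#' @param t_annual Annual mean temperature, degrees C (> -10).
#' @return Aridity index value(s).
#' @export
de_martonne <- function(p_annual, t_annual) {
  if (any(p_annual < 0)) stop("de_martonne: negative annual precipitation")
  if (any(t_annual <= -10))
    stop("de_martonne: t_annual <= -10 is outside the index domain")
  p_annual / (10 + t_annual)
}

.aridity_breaks <- c(0, 10, 20, 24, 28, 35, 55, Inf)
.aridity_labels <- c("arid", "semi-arid", "Mediterranean", "semi-humid",
                     "humid", "very humid", "extremely humid")

#' Classify a De Martonne aridity index value
#'
#' Classes partition `[0, Inf)` with lower-inclusive boundaries at
#' 10, 20, 24, 28, 35 and 55: arid `[0,10)`, semi-arid `[10,20)`,
#' Mediterranean `[20,24)`, semi-humid `[24,28)`, humid `[28,35)`,
#' very humid `[35,55)`, extremely humid `[55,Inf)`.
#'
#' @param ai Aridity index value(s), >= 0.
#' @return Factor with the seven class labels.
#' @export
classify_aridity <- function(ai) {
  if (any(ai < 0)) stop("classify_aridity: negative aridity index")
  cut(ai, breaks = .aridity_breaks, labels = .aridity_labels,
      right = FALSE, include.lowest = TRUE)
}

#' Annual precipitation sum and mean temperature per site-year
#'
#' Annual mean temperature is the mean of the twelve monthly midpoints
#' `(tmax + tmin)/2`; precipitation is the annual sum. Only complete years
#' (12 months) are returned.
#'
#' @param monthly Monthly climate data.frame (see [aggregate_seasons()]).
#' @return Data.frame with `site_id`, `year`, `p_annual`, `t_annual`.
#' @export
annual_climate_summary <- function(monthly) {
  key <- paste(monthly$site_id, monthly$year, sep = "\r")
  cnt <- tapply(rep(1L, nrow(monthly)), key, sum)
  keep <- key %in% names(cnt)[cnt == 12L]
  m <- monthly[keep, ]; key <- key[keep]
  tmid <- (m$tmax + m$tmin) / 2
  res <- data.frame(key = names(tapply(tmid, key, mean)),
                    t_annual = as.numeric(tapply(tmid, key, mean)),
                    p_annual = as.numeric(tapply(m$prcp, key, sum)))
  parts <- do.call(rbind, strsplit(res$key, "\r", fixed = TRUE))
  out <- data.frame(site_id = parts[, 1], year = as.integer(parts[, 2]),
                    p_annual = res$p_annual, t_annual = res$t_annual)
  out[order(out$site_id, out$year), ]
}

#' Long-term site aridity index
#'
#' Mean of the annual De Martonne index values over a reference window
#' (default 1950-2016). This is the mean of annual AI, not the AI of mean
#' climate; the two differ slightly because the index is nonlinear in T.
#'
#' @param monthly Monthly climate data.frame.
#' @param window Inclusive year interval `c(first, last)`.
#' @return Data.frame with `site_id`, `ai`.
#' @export
site_mean_ai <- function(monthly, window = c(1950L, 2016L)) {
  stopifnot(length(window) == 2L, window[1] <= window[2])
  ann <- annual_climate_summary(monthly)
  ann <- ann[ann$year >= window[1] & ann$year <= window[2], ]
  if (nrow(ann) == 0L)
    stop("site_mean_ai: no complete years inside the requested window")
  ann$ai_y <- de_martonne(ann$p_annual, ann$t_annual)
  out <- aggregate(ai_y ~ site_id, data = ann, FUN = mean)
  names(out) <- c("site_id", "ai")
  out
}

#' Ensemble-mean climate delta
#'
#' Averages per-model delta members into a single ensemble-mean
#' `scenario_delta`: arithmetic mean per (location, season), taken
#' separately over the temperature ensemble (`dtmax`, `dtmin`) and the
#' precipitation ensemble (`dpp`), whose member counts may differ.
#'
#' @param temp_members List of data.frames with `site_id`, `season`,
#'   `dtmax`, `dtmin`.
#' @param precip_members List of data.frames with `site_id`, `season`, `dpp`.
#' @param scenario,window Labels carried on the result.
#' @return A `scenario_delta` data.frame with `site_id`, `season`, `dtmax`,
#'   `dtmin`, `dpp` and attributes `scenario`, `window`.
#' @export
ensemble_mean_delta <- function(temp_members, precip_members,
                                scenario = NA_character_, window = NULL) {
  if (length(temp_members) < 1L || length(precip_members) < 1L)
    stop("ensemble_mean_delta: need at least one member per variable ensemble")
  keys <- function(df) paste(df$site_id, df$season, sep = "\r")
  ref <- temp_members[[1]][order(keys(temp_members[[1]])), ]
  kref <- keys(ref)
  align <- function(df, who) {
    df <- df[order(keys(df)), ]
    if (!identical(keys(df), kref))
      stop("ensemble_mean_delta: ", who,
           " member on a mismatched location/season set")
    df
  }
  tsum_max <- tsum_min <- numeric(nrow(ref))
  for (m in temp_members) {
    m <- align(m, "temperature")
    tsum_max <- tsum_max + m$dtmax
    tsum_min <- tsum_min + m$dtmin
  }
  psum <- numeric(nrow(ref))
  for (m in precip_members) {
    m <- align(m, "precipitation")
    psum <- psum + m$dpp
  }
  out <- data.frame(site_id = ref$site_id, season = ref$season,
                    dtmax = tsum_max / length(temp_members),
                    dtmin = tsum_min / length(temp_members),
                    dpp = psum / length(precip_members))
  attr(out, "scenario") <- scenario
  attr(out, "window") <- window
  class(out) <- c("scenario_delta", "data.frame")
  out
}

#' Shift a seasonal climatology by a scenario delta
#'
#' Adds the delta-change fields to the baseline seasonal climate:
#' `tmax + dtmax`, `tmin + dtmin`, `pp + dpp` with precipitation floored at
#' zero. Geographic variables and the long-term aridity index are not
#' touched by construction (they live in the site table, not here).
#'
#' @param baseline A `seasonal_climate` table.
#' @param delta A `scenario_delta` keyed by (`site_id`, `season`).
#' @return The shifted `seasonal_climate` table.
#' @export
apply_delta <- function(baseline, delta) {
  kb <- paste(baseline$site_id, baseline$season, sep = "\r")
  kd <- paste(delta$site_id, delta$season, sep = "\r")
  idx <- match(kb, kd)
  if (any(is.na(idx)))
    stop("apply_delta: baseline rows without a matching delta (site/season misalignment)")
  out <- baseline
  out$tmax_mean <- baseline$tmax_mean + delta$dtmax[idx]
  out$tmin_mean <- baseline$tmin_mean + delta$dtmin[idx]
  out$pp_sum <- pmax(0, baseline$pp_sum + delta$dpp[idx])
  out
}
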