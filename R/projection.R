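#' Predict annual BAI over a climate grid for a reference tree
#'
#' Applies a fitted growth model at population level (random effects zero)
#' to every pixel-year of a seasonal climate grid, holding basal area fixed
#' at a reference value — by default 86059.03 mm^2, the network-average
#' basal area of roughly an 80-year-old tree (DBH about 33 cm). Pixel-years
#' with incomplete seasonal climate are dropped with a message.
#'
#' @param model A `fitted_growth_model`.
#' @param grid_seasonal A `seasonal_climate` table over the grid pixels
#'   (pixel ids in `site_id`).
#' @param grid_meta Per-pixel table with `site_id`, `lat`, `alt`, `ai`.
#' @param ba_fixed Reference basal area, mm^2.
#' @return A `prediction_grid` data.frame: `site_id`, `year`, `bai`
#'   (mm^2/yr), with `ba_fixed` as an attribute.
#' @export
predict_grid <- function(model, grid_seasonal, grid_meta,
                         ba_fixed = 86059.03) {
  spec <- model$spec
  wide <- .seasonal_wide(grid_seasonal, spec$seasons, spec$climate_vars)
  clim_cols <- setdiff(names(wide), c("site_id", "year"))
  ok <- !Reduce(`|`, lapply(wide[clim_cols], is.na))
  if (any(!ok))
    message(sprintf("predict_grid: dropping %d pixel-year(s) with incomplete seasons",
                    sum(!ok)))
  wide <- wide[ok, , drop = FALSE]
  idx <- match(wide$site_id, grid_meta$site_id)
  if (anyNA(idx))
    stop("predict_grid: pixels missing from grid_meta: ",
         paste(unique(wide$site_id[is.na(idx)]), collapse = ", "))
  newdata <- cbind(
    data.frame(ai = grid_meta$ai[idx], lat = grid_meta$lat[idx],
               alt = grid_meta$alt[idx]),
    wide[clim_cols])
  bai <- predict_bai(model, newdata, ba_fixed = ba_fixed,
                     population_level = TRUE)
  out <- data.frame(site_id = wide$site_id, year = wide$year, bai = bai)
  attr(out, "ba_fixed") <- ba_fixed
  class(out) <- c("prediction_grid", "data.frame")
  out
}

#' Per-pixel mean predicted growth over an inclusive year window
#'
#' @param grid A [predict_grid()] result.
#' @param window Inclusive `c(first, last)` calendar years; every pixel must
#'   cover the full window.
#' @return Data.frame with `site_id`, `mean_bai`; the window length (e.g. 31
#'   years for 1955-1985) is attribute `n_years`.
#' @export
period_mean <- function(grid, window) {
  stopifnot(length(window) == 2L, window[1] <= window[2])
  years <- seq(window[1], window[2])
  g <- grid[grid$year %in% years, ]
  cnt <- tapply(g$year, g$site_id, function(y) length(unique(y)))
  bad <- names(cnt)[cnt < length(years)]
  if (length(bad) || length(cnt) == 0L) {
    miss <- if (length(cnt) == 0L) years else
      setdiff(years, unique(g$year[g$site_id == bad[1]]))
    stop("period_mean: window ", window[1], "-", window[2],
         " not fully covered (missing years e.g. ",
         paste(head(miss, 5), collapse = ", "), ")")
  }
  m <- tapply(g$bai, g$site_id, mean)
  out <- data.frame(site_id = names(m), mean_bai = as.numeric(m))
  attr(out, "n_years") <- length(years)
  out
}

#' Percent growth change between two period means
#'
#' `100 * (mean_b - mean_a) / mean_a`.
#'
#' @param mean_a Reference period mean(s), must be > 0.
#' @param mean_b Comparison period mean(s).
#' @return Percent change.
#' @export
percent_change <- function(mean_a, mean_b) {
  if (any(mean_a <= 0)) stop("percent_change: reference mean must be > 0")
  100 * (mean_b - mean_a) / mean_a
}

#' Applicability-domain mask for gridded prediction
#'
#' For every seasonal climate variable, the training range (min/max pooled
#' over the whole training domain) is computed; a future pixel lies outside
#' the applicability domain if any of its values falls outside the trained
#' range, in which case predictions there are extrapolations.
#'
#' @param training_seasonal `seasonal_climate` of the training domain
#'   (canonically 1901-2016).
#' @param future_seasonal `seasonal_climate` to screen.
#' @return List of class `ad_mask`: `pixels` (data.frame `site_id`,
#'   `inside`), `violations` (data.frame `site_id`, `variable`, `season`,
#'   `direction`) and `ranges` (the training min/max per variable-season).
#' @export
applicability_domain <- function(training_seasonal, future_seasonal) {
  if (nrow(training_seasonal) == 0L)
    stop("applicability_domain: empty training set")
  vars <- c("tmax_mean", "tmin_mean", "pp_sum")
  key_t <- paste(training_seasonal$season)
  ranges <- do.call(rbind, lapply(vars, function(v) {
    lo <- tapply(training_seasonal[[v]], key_t, min)
    hi <- tapply(training_seasonal[[v]], key_t, max)
    data.frame(variable = v, season = names(lo), lo = as.numeric(lo),
               hi = as.numeric(hi))
  }))
  viol <- list()
  for (v in vars) {
    i <- match(paste(future_seasonal$season),
               ranges$season[ranges$variable == v])
    r <- ranges[ranges$variable == v, ][i, ]
    x <- future_seasonal[[v]]
    above <- x > r$hi; below <- x < r$lo
    if (any(above))
      viol[[length(viol) + 1L]] <- data.frame(
        site_id = future_seasonal$site_id[above],
        variable = v, season = as.character(future_seasonal$season[above]),
        direction = "above")
    if (any(below))
      viol[[length(viol) + 1L]] <- data.frame(
        site_id = future_seasonal$site_id[below],
        variable = v, season = as.character(future_seasonal$season[below]),
        direction = "below")
  }
  violations <- if (length(viol)) unique(do.call(rbind, viol)) else
    data.frame(site_id = character(0), variable = character(0),
               season = character(0), direction = character(0))
  pixels <- data.frame(site_id = unique(future_seasonal$site_id))
  pixels$inside <- !(pixels$site_id %in% violations$site_id)
  structure(list(pixels = pixels, violations = violations, ranges = ranges),
            class = "ad_mask")
}

#' @export
print.ad_mask <- function(x, ...) {
  cat(sprintf("<ad_mask> %d/%d pixels inside the applicability domain (%d violations)\n",
              sum(x$pixels$inside), nrow(x$pixels), nrow(x$violations)))
  invisible(x)
}

#' Project growth change under delta-shifted climate scenarios
#'
#' For each scenario x future-window combination: averages the per-model
#' delta members into an ensemble mean, shifts the baseline seasonal grid
#' by it (preserving the baseline's interannual variability), predicts
#' annual BAI for the reference tree, takes the period mean over the
#' baseline years, and expresses the result as percent change relative to
#' the unshifted baseline period mean. An applicability-domain mask against
#' the training climate is attached to every combination.
#'
#' @param model A `fitted_growth_model`.
#' @param baseline_seasonal `seasonal_climate` of the baseline period
#'   (canonically 1986-2016) over the grid.
#' @param grid_meta Per-pixel `site_id`, `lat`, `alt`, `ai`.
#' @param ensembles Nested list from [generate_scenario_ensemble()] (or the
#'   same shape built from real model output).
#' @param training_seasonal `seasonal_climate` spanning the training domain
#'   for the AD mask.
#' @param baseline_window Inclusive years of the baseline period mean.
#' @param ba_fixed Reference basal area, mm^2.
#' @param scenarios,windows The expected combinations; an error is raised if
#'   any is missing from `ensembles`.
#' @return List of class `scenario_projection`: one element per combination
#'   with `scenario`, `window`, `change` (per-pixel `mean_a`, `mean_b`,
#'   `pct_change`) and `ad` (an `ad_mask`).
#' @export
run_scenarios <- function(model, baseline_seasonal, grid_meta, ensembles,
                          training_seasonal,
                          baseline_window = c(1986L, 2016L),
                          ba_fixed = 86059.03,
                          scenarios = c("SSP1-2.6", "SSP5-8.5"),
                          windows = c("2020-2050", "2040-2070", "2060-2090")) {
  for (sc in scenarios) for (w in windows)
    if (is.null(ensembles[[sc]][[w]]))
      stop("run_scenarios: missing delta set for ", sc, " ", w)
  base_grid <- predict_grid(model, baseline_seasonal, grid_meta,
                            ba_fixed = ba_fixed)
  base_mean <- period_mean(base_grid, baseline_window)
  out <- list()
  for (sc in scenarios) for (w in windows) {
    memb <- ensembles[[sc]][[w]]
    delta <- ensemble_mean_delta(memb$temp_members, memb$precip_members,
                                 scenario = sc, window = w)
    shifted <- apply_delta(baseline_seasonal, delta)
    fut_grid <- predict_grid(model, shifted, grid_meta, ba_fixed = ba_fixed)
    fut_mean <- period_mean(fut_grid, baseline_window)
    i <- match(base_mean$site_id, fut_mean$site_id)
    change <- data.frame(site_id = base_mean$site_id,
                         mean_a = base_mean$mean_bai,
                         mean_b = fut_mean$mean_bai[i])
    change$pct_change <- percent_change(change$mean_a, change$mean_b)
    ad <- applicability_domain(training_seasonal, shifted)
    out[[paste(sc, w)]] <- list(scenario = sc, window = w,
                                change = change, ad = ad)
  }
  class(out) <- "scenario_projection"
  out
}

#' @export
print.scenario_projection <- function(x, ...) {
  cat(sprintf("<scenario_projection> %d scenario x window combinations\n", length(x)))
  for (el in x)
    cat(sprintf("  %s %s: median change %+.1f%%, %d/%d pixels in AD\n",
                el$scenario, el$window, stats::median(el$change$pct_change),
                sum(el$ad$pixels$inside), nrow(el$ad$pixels)))
  invisible(x)
}
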