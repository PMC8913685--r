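#' Generate a synthetic European site network
#'
#' Sites are placed uniformly in the bounding box of the continental
#' beech tree-ring network (longitude 5.8-28.4 degrees E, latitude
#' 38.8-58.5 degrees N) with altitudes between 1 and 1900 m a.s.l.
#'
#' @param n_sites Number of sites (>= 1).
#' @param seed Integer RNG seed; identical seeds give identical networks.
#' @return Data.frame with `site_id`, `lat`, `lon`, `alt` (and `ai` = NA,
#'   filled once climate exists).
#' @export
generate_sites <- function(n_sites, seed = 1L) {
  if (!is.numeric(n_sites) || n_sites < 1)
    stop("generate_sites: n_sites must be >= 1")
  n_sites <- as.integer(n_sites)
  set.seed(seed)
  data.frame(
    site_id = sprintf("S%03d", seq_len(n_sites)),
    lat = runif(n_sites, 38.8, 58.5),
    lon = runif(n_sites, 5.8, 28.4),
    alt = runif(n_sites, 1, 1900),
    ai = NA_real_)
}

#' Generate monthly site climate with seasonal cycle, gradients and trend
#'
#' Produces monthly maximum/minimum temperature and precipitation per site
#' and year from: a site climatology driven by latitude and altitude lapse
#' gradients (calibrated so long-term site means fall inside the observed
#' network envelope of 3.8-13.5 degrees C and 500-2000 mm), a sinusoidal
#' seasonal cycle peaking in July, AR(1) interannual anomalies, independent
#' monthly noise, and a linear warming trend centred on the middle of the
#' series.
#'
#' @param sites Site table from [generate_sites()].
#' @param year_range Inclusive `c(first, last)` calendar years.
#' @param trend Warming trend, degrees C per decade.
#' @param seed Integer RNG seed.
#' @param ar1 AR(1) coefficient of the interannual temperature anomaly.
#' @param noise_sd SD of the annual temperature anomaly innovations,
#'   degrees C. Zero (with `prcp_sd = prcp_month_sd = 0` and `trend = 0`)
#'   makes every year identical.
#' @param prcp_sd SD of the multiplicative annual precipitation anomaly
#'   (fraction of the site normal).
#' @param prcp_month_sd SD of the multiplicative log-scale monthly
#'   precipitation noise.
#' @param t_month_sd SD of independent monthly temperature noise, degrees C
#'   (applied separately to `tmax` and `tmin` anomalies so the two carry
#'   independent information, as in observed records).
#' @param site_t_sd,site_p_sd SD of site-level climatology offsets (degrees
#'   C and mm) independent of the latitude/altitude gradients; they keep
#'   long-term aridity from being a deterministic function of geography.
#'   Clamped so site normals stay inside the network envelope.
#' @param seasonal_amp Amplitude of the seasonal temperature cycle, degrees C.
#'   A small second harmonic skews the cycle so spring and autumn differ.
#' @param dtr Mean diurnal temperature range (`tmax - tmin`), degrees C; the
#'   realised range varies seasonally and randomly but never drops below
#'   0.5 degrees C, so `tmin <= tmax` always.
#' @return Data.frame with `site_id`, `year`, `month`, `tmax`, `tmin`,
#'   `prcp`.
#' @export
generate_monthly_climate <- function(sites, year_range = c(1949L, 2016L),
                                     trend = 0.1, seed = 1L,
                                     ar1 = 0.3, noise_sd = 0.25,
                                     prcp_sd = 0.08, prcp_month_sd = 0.3,
                                     t_month_sd = 0.8,
                                     site_t_sd = 0.25, site_p_sd = 45,
                                     seasonal_amp = 8, dtr = 8) {
  stopifnot(length(year_range) == 2L, year_range[1] <= year_range[2])
  set.seed(seed + 1L)
  years <- seq(year_range[1], year_range[2])
  ny <- length(years)
  mid <- mean(years)
  lat_n <- (sites$lat - 38.8) / (58.5 - 38.8)
  alt_n <- sites$alt / 1900
  # site climatology: latitude/altitude lapse gradients plus local offsets
  # (exposure, continentality, soils) independent of geography, so moisture
  # carries information beyond latitude and altitude
  t_site <- 12.6 - 3.4 * lat_n - 3.9 * alt_n + rnorm(nrow(sites), 0, site_t_sd)
  p_site <- 650 + 600 * alt_n + 450 * lat_n + rnorm(nrow(sites), 0, site_p_sd)
  t_site <- pmin(pmax(t_site, 4.0), 13.3)
  p_site <- pmin(pmax(p_site, 540), 1920)
  months <- 1:12
  # skewed annual cycle shape: July peak plus a second harmonic so that
  # spring and autumn are not mirror images
  cyc_shape <- cos(2 * pi * (months - 7) / 12) +
    0.15 * sin(4 * pi * (months - 7) / 12)
  # continentality: seasonal amplitude grows eastward, with local spread;
  # annual means are unaffected (the cycle integrates to ~zero)
  lon_n <- if (!is.null(sites$lon)) (sites$lon - 5.8) / (28.4 - 5.8) else 0.5
  amp_site <- seasonal_amp * (0.75 + 0.5 * lon_n + rnorm(nrow(sites), 0, 0.05))
  # precipitation regime: winter-wet (Mediterranean) in the south grading to
  # summer-wet in the north, with local spread; shares always positive and
  # summing to one, so the annual total is regime-independent
  regime <- tanh(2 * (lat_n - 0.35) + rnorm(nrow(sites), 0, 0.6))
  dtr_m <- pmax(0.5, dtr + 2 * cos(2 * pi * (months - 7) / 12))
  out <- vector("list", nrow(sites))
  for (i in seq_len(nrow(sites))) {
    # AR(1) annual temperature anomaly
    innov <- rnorm(ny, 0, noise_sd)
    anomT <- numeric(ny)
    if (ny > 0) anomT[1] <- innov[1] / sqrt(max(1 - ar1^2, 1e-12))
    for (y in seq_len(ny)[-1]) anomT[y] <- ar1 * anomT[y - 1] + innov[y]
    p_year <- p_site[i] * pmax(0.2, 1 + rnorm(ny, 0, prcp_sd))
    tm <- t_site[i] + trend * (years - mid) / 10 + anomT
    cyc <- amp_site[i] * cyc_shape
    pshare <- 1 + 0.3 * regime[i] * cos(2 * pi * (months - 7) / 12)
    pshare <- pshare / sum(pshare)
    tmon <- outer(tm, cyc, `+`)                      # ny x 12
    noise_hi <- matrix(rnorm(ny * 12, 0, t_month_sd), ny, 12)
    noise_lo <- matrix(rnorm(ny * 12, 0, t_month_sd), ny, 12)
    dtr_real <- pmax(0.5, matrix(dtr_m, ny, 12, byrow = TRUE) +
                       (noise_hi - noise_lo))
    tmid <- tmon + (noise_hi + noise_lo) / 2
    praw <- matrix(pshare, ny, 12, byrow = TRUE) *
      exp(matrix(rnorm(ny * 12, 0, prcp_month_sd), ny, 12))
    praw <- praw / rowSums(praw) * p_year
    out[[i]] <- data.frame(
      site_id = sites$site_id[i],
      year = rep(years, each = 12L),
      month = rep(months, ny),
      tmax = as.vector(t(tmid + dtr_real / 2)),
      tmin = as.vector(t(tmid - dtr_real / 2)),
      prcp = as.vector(t(praw)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate tree growth forward from ground-truth parameters
#'
#' For each tree, draws a correlated random intercept and random slope from
#' the truth's bivariate normal, then iterates over years: forms the linear
#' predictor from the standardized design (same construction as
#' [build_design()], with previous-year basal area standardized by the
#' truth's fixed reference scale), draws annual BAI from a gamma
#' distribution with mean `exp(eta)` and the truth's shape, updates basal
#' area, and emits the ring width as the radius increment rounded to
#' 0.01 mm (floored at 0.01 mm so every ring is measurable). The recorded
#' DBH is twice the final emitted radius, so reconstruction by
#' [rings_to_bai()] retraces the emitted radius path exactly.
#'
#' Rings are simulated for every climate year whose previous-year seasons
#' exist, i.e. a span of `y` climate years yields `y - 1` rings per tree.
#'
#' @param climate Monthly climate data.frame covering the simulation years.
#' @param sites Site table (`site_id`, `lat`, `alt`; `ai` computed from the
#'   climate if absent).
#' @param truth A [true_params()] object.
#' @param trees_per_site Trees per site (>= 1).
#' @param initial_radius Starting stem radius, mm.
#' @param seed Integer RNG seed.
#' @return List of class `simulated_growth`: `rings` (list of
#'   [ring_series()]), `bai` (truth BAI table with `eta`), `sites` (with
#'   `ai` filled), `scaler` (the standardization the truth was simulated
#'   under, reusable via `build_design(..., scaler = )`), `truth`.
#' @export
simulate_growth <- function(climate, sites, truth = default_true_params(),
                            trees_per_site = 5L, initial_radius = 5,
                            seed = 1L) {
  stopifnot(inherits(truth, "true_params"))
  if (trees_per_site < 1) stop("simulate_growth: trees_per_site must be >= 1")
  spec <- truth$spec
  set.seed(seed + 2L)
  if (is.null(sites$ai) || anyNA(sites$ai)) {
    yr <- range(climate$year)
    ai <- site_mean_ai(climate, window = yr)
    sites$ai <- ai$ai[match(sites$site_id, ai$site_id)]
  }
  seasonal <- aggregate_seasons(climate)
  wide <- .seasonal_wide(seasonal, spec$seasons, spec$climate_vars)
  clim_cols <- setdiff(names(wide), c("site_id", "year"))
  ok <- !Reduce(`|`, lapply(wide[clim_cols], is.na))
  wide <- wide[ok, ]
  # keep years with complete seasons at every site
  cnt <- table(wide$year)
  years <- sort(as.integer(names(cnt)[cnt == nrow(sites)]))
  years <- years[years >= min(climate$year) & years <= max(climate$year)]
  if (length(years) < 1L)
    stop("simulate_growth: no year has complete seasonal climate at every site")
  wide <- wide[wide$year %in% years, ]
  sidx <- match(wide$site_id, sites$site_id)
  base <- cbind(
    data.frame(ai = sites$ai[sidx], lat = sites$lat[sidx],
               alt = sites$alt[sidx],
               ba_prev = rep(truth$ba_ref[["mean"]], nrow(wide))),
    wide[clim_cols])
  dm <- .design_matrix(base, spec, ba_ref = truth$ba_ref)
  beta <- truth_beta(truth)
  stopifnot(identical(colnames(dm$X), names(beta)))
  contrib <- truth$intercept + drop(dm$X %*% beta)   # ba column is 0 here
  beta_ba <- if ("ba_prev" %in% names(beta)) beta[["ba_prev"]] else 0
  Sigma <- matrix(c(truth$re_sd_intercept^2,
                    rep(truth$re_corr * truth$re_sd_intercept * truth$re_sd_slope, 2),
                    truth$re_sd_slope^2), 2, 2)
  ref_m <- truth$ba_ref[["mean"]]; ref_s <- truth$ba_ref[["sd"]]
  rings <- list(); bai_rows <- list()
  for (i in seq_len(nrow(sites))) {
    sid <- sites$site_id[i]
    rows <- which(wide$site_id == sid)
    c_iy <- setNames(contrib[rows], wide$year[rows])
    b <- MASS::mvrnorm(trees_per_site, c(0, 0), Sigma)
    if (trees_per_site == 1L) b <- matrix(b, 1L)
    for (k in seq_len(trees_per_site)) {
      code <- sprintf("%sT%02d", sid, k)
      ba <- pi * initial_radius^2
      r_emit <- initial_radius
      r_true <- initial_radius
      widths <- numeric(length(years))
      bai_t <- ba_prev_t <- eta_t <- numeric(length(years))
      for (y in seq_along(years)) {
        z_ba <- (ba - ref_m) / ref_s
        eta <- c_iy[[as.character(years[y])]] +
          (beta_ba + b[k, 2]) * z_ba + b[k, 1]
        if (!is.finite(eta))
          stop(sprintf("simulate_growth: non-finite linear predictor at site %s year %d",
                       sid, years[y]))
        bai <- rgamma(1L, shape = truth$gamma_shape,
                      rate = truth$gamma_shape / exp(eta))
        ba_prev_t[y] <- ba; eta_t[y] <- eta; bai_t[y] <- bai
        ba <- ba + bai
        r_true <- sqrt(ba / pi)
        w <- max(0.01, round(r_true - r_emit, 2))
        widths[y] <- w
        r_emit <- r_emit + w
      }
      rings[[length(rings) + 1L]] <- ring_series(
        tree_code = code, site_id = sid, first_year = years[1],
        widths = widths, dbh_mm = 2 * r_emit)
      bai_rows[[length(bai_rows) + 1L]] <- data.frame(
        site_id = sid, tree_code = code, year = years,
        bai = bai_t, ba_prev = ba_prev_t, eta = eta_t)
    }
  }
  structure(
    list(rings = rings,
         bai = do.call(rbind, bai_rows),
         sites = sites,
         scaler = dm$scaler,
         truth = truth,
         years = years,
         seed = seed),
    class = "simulated_growth")
}

#' @export
print.simulated_growth <- function(x, ...) {
  cat(sprintf("<simulated_growth> %d trees at %d sites, years %d-%d\n",
              length(x$rings), nrow(x$sites), min(x$years), max(x$years)))
  invisible(x)
}

#' Generate a per-model scenario delta ensemble
#'
#' Emulates a CMIP6-style delta-change ensemble: for each scenario and
#' future window, per-model seasonal climate offsets relative to a historic
#' analogue window (default 1985-2014). Temperature deltas grow with the
#' scenario severity and the future window; precipitation deltas follow a
#' north-south gradient (drying in the south, wetting in the north).
#' Member-to-member spread enters as model offsets plus per-pixel noise.
#' Defaults produce 21 temperature-delta and 26 precipitation-delta members
#' per scenario and window.
#'
#' @param sites Site/pixel table with `site_id`, `lat`.
#' @param scenarios Character vector of scenario labels.
#' @param future_windows List of inclusive `c(first, last)` future windows.
#' @param historic_window Historic analogue window `c(first, last)`; must
#'   not overlap any future window.
#' @param n_temp_models,n_precip_models Ensemble sizes.
#' @param magnitude Overall scaling of every delta (0 gives all-zero
#'   deltas).
#' @param seed Integer RNG seed.
#' @return Nested list: `[[scenario]][[window label]]` with `temp_members`,
#'   `precip_members` (lists of data.frames) plus `scenario`, `window`.
#' @export
generate_scenario_ensemble <- function(sites,
                                       scenarios = c("SSP1-2.6", "SSP5-8.5"),
                                       future_windows = list(c(2020L, 2050L),
                                                             c(2040L, 2070L),
                                                             c(2060L, 2090L)),
                                       historic_window = c(1985L, 2014L),
                                       n_temp_models = 21L,
                                       n_precip_models = 26L,
                                       magnitude = 1,
                                       seed = 1L) {
  if (n_temp_models < 1 || n_precip_models < 1)
    stop("generate_scenario_ensemble: ensemble sizes must be >= 1")
  for (w in future_windows)
    if (w[1] <= historic_window[2] && historic_window[1] <= w[2])
      stop("generate_scenario_ensemble: historic and future windows overlap")
  set.seed(seed + 3L)
  lat_n <- (sites$lat - 38.8) / (58.5 - 38.8)
  seas_t <- c(pSUM = 1.2, pAUT = 1.0, WIN = 0.8, SPR = 1.0, SUM = 1.2, AUT = 1.0)
  warm_base <- list("SSP1-2.6" = c(1.0, 1.3, 1.5),
                    "SSP5-8.5" = c(1.5, 2.5, 3.8))
  pp_base <- list("SSP1-2.6" = c(10, 12, 15),
                  "SSP5-8.5" = c(20, 35, 50))
  grid <- expand.grid(site_id = sites$site_id, season = SEASONS,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g_lat <- lat_n[match(grid$site_id, sites$site_id)]
  g_seas <- seas_t[grid$season]
  out <- list()
  for (sc in scenarios) {
    wb <- warm_base[[sc]] %||% rep(2, length(future_windows))
    pb <- pp_base[[sc]] %||% rep(20, length(future_windows))
    out[[sc]] <- list()
    for (wi in seq_along(future_windows)) {
      win <- future_windows[[wi]]
      label <- paste(win[1], win[2], sep = "-")
      dT_mean <- wb[min(wi, length(wb))] * g_seas
      dP_mean <- pb[min(wi, length(pb))] * (g_lat - 0.5) * 2
      temp_members <- lapply(seq_len(n_temp_models), function(m) {
        off <- rnorm(1, 0, 0.2)
        data.frame(site_id = grid$site_id, season = grid$season,
                   dtmax = magnitude * (dT_mean + off + rnorm(nrow(grid), 0, 0.1)),
                   dtmin = magnitude * (0.9 * dT_mean + off + rnorm(nrow(grid), 0, 0.1)))
      })
      precip_members <- lapply(seq_len(n_precip_models), function(m) {
        off <- rnorm(1, 0, 3)
        data.frame(site_id = grid$site_id, season = grid$season,
                   dpp = magnitude * (dP_mean + off + rnorm(nrow(grid), 0, 2)))
      })
      out[[sc]][[label]] <- list(scenario = sc, window = win,
                                 temp_members = temp_members,
                                 precip_members = precip_members)
    }
  }
  out
}

#' Generate a complete synthetic growth network
#'
#' Convenience wrapper chaining [generate_sites()],
#' [generate_monthly_climate()] and [simulate_growth()]. Per-stage seeds are
#' derived from the master seed.
#'
#' @param n_sites,trees_per_site Network size.
#' @param year_range Climate years (rings cover all but the first year).
#' @param truth A [true_params()] object.
#' @param seed Master integer seed.
#' @param ... Passed to [generate_monthly_climate()].
#' @return List of class `synthetic_network` with `sites`, `climate`,
#'   `rings`, `bai`, `scaler`, `truth`, `seed`.
#' @export
synthetic_network <- function(n_sites = 324L, trees_per_site = 18L,
                              year_range = c(1949L, 2016L),
                              truth = default_true_params(), seed = 1L, ...) {
  sites <- generate_sites(n_sites, seed = seed)
  climate <- generate_monthly_climate(sites, year_range = year_range,
                                      seed = seed, ...)
  sim <- simulate_growth(climate, sites, truth = truth,
                         trees_per_site = trees_per_site, seed = seed)
  structure(
    list(sites = sim$sites, climate = climate, rings = sim$rings,
         bai = sim$bai, scaler = sim$scaler, truth = truth, seed = seed,
         years = sim$years),
    class = "synthetic_network")
}

#' @export
print.synthetic_network <- function(x, ...) {
  cat(sprintf("<synthetic_network> %d sites, %d trees, climate %d-%d (seed %d)\n",
              nrow(x$sites), length(x$rings), min(x$climate$year),
              max(x$climate$year), x$seed))
  invisible(x)
}

#' Write a synthetic network to plain-text files
#'
#' Writes the ring series as a Tucson rwl file plus a tree metadata CSV, the
#' sites as CSV, the monthly climate as CSV, and the ground-truth parameters
#' as YAML (for recovery tests).
#'
#' @param network A [synthetic_network()] object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_network <- function(network, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_rwl(network$rings, file.path(dir, "rings.rwl"))
  write_ring_metadata(network$rings, file.path(dir, "trees.csv"))
  write.csv(network$sites, file.path(dir, "sites.csv"), row.names = FALSE)
  write.csv(network$climate, file.path(dir, "climate_monthly.csv"),
            row.names = FALSE)
  tr <- network$truth
  yaml::write_yaml(list(
    intercept = tr$intercept,
    coef_main = tr$coef_main,
    coef_interaction = tr$coef_interaction,
    re_sd_intercept = tr$re_sd_intercept,
    re_sd_slope = tr$re_sd_slope,
    re_corr = tr$re_corr,
    gamma_shape = tr$gamma_shape,
    ba_ref = as.list(tr$ba_ref)),
    file.path(dir, "truth.yaml"))
  invisible(dir)
}
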