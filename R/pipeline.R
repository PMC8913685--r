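#' Configuration of the end-to-end growth-analysis pipeline
#'
#' Bundles every setting of a pipeline run: synthetic network size, model
#' structure, analysis windows, scenario labels, the reference basal area
#' and the master seed. Windows follow the analysis conventions: model
#' period 1950-2016, historical comparison periods 1955-1985 and 1986-2016,
#' aridity-index window 1950-2016, applicability-domain training window
#' 1901-2016, future windows 2020-2050 / 2040-2070 / 2060-2090.
#'
#' @param n_sites,trees_per_site Synthetic network size.
#' @param climate_years Inclusive years of generated monthly climate.
#' @param smooth_df,interactions Passed to [model_spec()].
#' @param period_a,period_b Historical comparison windows.
#' @param future_windows List of future windows.
#' @param training_window Applicability-domain training window.
#' @param ai_window Aridity-index averaging window.
#' @param scenarios Scenario labels.
#' @param scenario_magnitude Overall scaling of generated scenario deltas
#'   (0 = zero-delta run).
#' @param ba_fixed Reference basal area, mm^2.
#' @param ladder Fit the full eight-model comparison ladder (else only the
#'   full and null models).
#' @param seed Master integer seed; stage seeds are derived from it by
#'   fixed offsets.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(n_sites = 20L, trees_per_site = 3L,
                            climate_years = c(1949L, 2016L),
                            smooth_df = 2L, interactions = character(0),
                            period_a = c(1955L, 1985L),
                            period_b = c(1986L, 2016L),
                            future_windows = list(c(2020L, 2050L),
                                                  c(2040L, 2070L),
                                                  c(2060L, 2090L)),
                            training_window = c(1901L, 2016L),
                            ai_window = c(1950L, 2016L),
                            scenarios = c("SSP1-2.6", "SSP5-8.5"),
                            scenario_magnitude = 1,
                            ba_fixed = 86059.03,
                            ladder = TRUE,
                            seed = 1L) {
  cfg <- list(n_sites = as.integer(n_sites),
              trees_per_site = as.integer(trees_per_site),
              climate_years = as.integer(climate_years),
              smooth_df = as.integer(smooth_df),
              interactions = as.character(unlist(interactions)),
              period_a = as.integer(period_a), period_b = as.integer(period_b),
              future_windows = lapply(future_windows, as.integer),
              training_window = as.integer(training_window),
              ai_window = as.integer(ai_window),
              scenarios = scenarios,
              scenario_magnitude = scenario_magnitude,
              ba_fixed = ba_fixed, ladder = isTRUE(ladder),
              seed = as.integer(seed))
  for (w in c(list(cfg$climate_years, cfg$period_a, cfg$period_b,
                   cfg$training_window, cfg$ai_window), cfg$future_windows))
    if (length(w) != 2L || anyNA(w) || w[1] > w[2])
      stop("pipeline_config: malformed window (need start <= end): ",
           paste(w, collapse = "-"))
  if (is.na(cfg$seed)) stop("pipeline_config: seed must be an integer")
  class(cfg) <- "pipeline_config"
  cfg
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat(sprintf("<pipeline_config> %d sites x %d trees, climate %d-%d, seed %d\n",
              x$n_sites, x$trees_per_site, x$climate_years[1],
              x$climate_years[2], x$seed))
  invisible(x)
}

#' Read / write a pipeline configuration as YAML
#' @param path YAML file path.
#' @return For the reader, a [pipeline_config()]; for the writer, `path`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' @rdname read_pipeline_config
#' @param config A [pipeline_config()].
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full synthetic growth-analysis pipeline
#'
#' Executes simulate -> BAI conversion -> seasonal climate + aridity ->
#' design + GLMM fit -> model ladder -> historical change map -> six
#' scenario projections with applicability-domain masks, and writes all
#' artifacts (CSV/rwl/YAML/JSON) plus a run manifest to `outdir`. Identical
#' config and seed reproduce identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory.
#' @return Invisibly, a list with the fitted model, comparison table,
#'   historical change table and scenario projections.
#' @export
run_pipeline <- function(config, outdir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  spec <- model_spec(smooth_df = config$smooth_df,
                     interactions = config$interactions)
  truth <- default_true_params(spec)
  message("[simulate] generating synthetic network")
  network <- synthetic_network(
    n_sites = config$n_sites, trees_per_site = config$trees_per_site,
    year_range = config$climate_years, truth = truth, seed = config$seed)
  write_network(network, file.path(outdir, "network"))
  message("[bai] converting ring widths to basal area increments")
  bai <- rings_to_bai(network$rings)
  write.csv(bai, file.path(outdir, "bai.csv"), row.names = FALSE)
  message("[climate] seasonal aggregation and aridity index")
  seasonal <- aggregate_seasons(network$climate)
  aiw <- c(max(config$ai_window[1], min(network$climate$year)),
           min(config$ai_window[2], max(network$climate$year)))
  ai <- site_mean_ai(network$climate, window = aiw)
  sites <- network$sites
  sites$ai <- ai$ai[match(sites$site_id, ai$site_id)]
  message("[fit] gamma log-link GLMM")
  design <- build_design(bai, seasonal, sites, spec)
  comparison <- if (config$ladder) {
    compare_models(design)
  } else {
    compare_models(design, ladder = list(
      "Null model" = character(0), "Full model" = c("ai", "cli", "geo")))
  }
  fits <- attr(comparison, "fits")
  model <- fits[[which(comparison$model == "Full model")]]
  write.csv(as.data.frame(comparison),
            file.path(outdir, "model_comparison.csv"), row.names = FALSE)
  yaml::write_yaml(list(
    beta = as.list(model$beta), se = as.list(setNames(model$se, names(model$beta))),
    re_cov = as.list(as.data.frame(model$re_cov)),
    gamma_shape = model$gamma_shape, loglik = model$loglik,
    aic = model$aic, n_params = model$n_params,
    scaler = list(var = model$scaler$var, col = model$scaler$col)),
    file.path(outdir, "model.yaml"))
  message("[project] historical period means")
  grid <- predict_grid(model, seasonal, sites, ba_fixed = config$ba_fixed)
  mean_a <- period_mean(grid, config$period_a)
  mean_b <- period_mean(grid, config$period_b)
  i <- match(mean_a$site_id, mean_b$site_id)
  hist_change <- data.frame(site_id = mean_a$site_id,
                            mean_a = mean_a$mean_bai,
                            mean_b = mean_b$mean_bai[i])
  hist_change$pct_change <- percent_change(hist_change$mean_a, hist_change$mean_b)
  write.csv(hist_change, file.path(outdir, "historical_change.csv"),
            row.names = FALSE)
  message("[project] scenario ensembles")
  ens <- generate_scenario_ensemble(
    sites, scenarios = config$scenarios,
    future_windows = config$future_windows,
    magnitude = config$scenario_magnitude, seed = config$seed)
  baseline_seasonal <- seasonal[seasonal$year >= config$period_b[1] &
                                  seasonal$year <= config$period_b[2], ]
  training_seasonal <- seasonal[seasonal$year >= config$training_window[1] &
                                  seasonal$year <= config$training_window[2], ]
  wlabels <- vapply(config$future_windows,
                    function(w) paste(w[1], w[2], sep = "-"), character(1))
  proj <- run_scenarios(model, baseline_seasonal, sites, ens,
                        training_seasonal,
                        baseline_window = config$period_b,
                        ba_fixed = config$ba_fixed,
                        scenarios = config$scenarios, windows = wlabels)
  for (el in proj) {
    tag <- gsub("[^A-Za-z0-9.-]", "_", paste(el$scenario, el$window, sep = "_"))
    write.csv(el$change, file.path(outdir, paste0("change_", tag, ".csv")),
              row.names = FALSE)
    write.csv(merge(el$ad$pixels, el$ad$violations, by = "site_id", all.x = TRUE),
              file.path(outdir, paste0("ad_", tag, ".csv")), row.names = FALSE)
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("baigrowth")),
    config = unclass(config),
    artifacts = sort(list.files(outdir, recursive = TRUE)),
    n_scenario_outputs = length(proj))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(model = model, comparison = comparison,
                 historical_change = hist_change, projections = proj,
                 sites = sites, outdir = outdir))
}

#' Summarise a completed pipeline run by latitude band
#'
#' Reads the artifacts of [run_pipeline()] and reports, per latitude band,
#' mean historical and scenario percent growth changes and the fraction of
#' pixels inside the applicability domain.
#'
#' @param outdir The artifact directory of a completed run.
#' @param breaks Latitude band boundaries, degrees N.
#' @return Data.frame with `band`, `scenario`, `window`, `mean_pct_change`,
#'   `ad_fraction`; also written to `report.csv` in `outdir`.
#' @export
pipeline_report <- function(outdir, breaks = c(38.8, 45, 50, 55, 58.5)) {
  manifest_path <- file.path(outdir, "manifest.json")
  if (!file.exists(manifest_path))
    stop("pipeline_report: no manifest.json in ", outdir, "; incomplete run?")
  sites <- read.csv(file.path(outdir, "network", "sites.csv"))
  sites$band <- cut(sites$lat, breaks = breaks, include.lowest = TRUE)
  rows <- list()
  band_of <- function(ids) sites$band[match(ids, sites$site_id)]
  hist_path <- file.path(outdir, "historical_change.csv")
  if (file.exists(hist_path)) {
    h <- read.csv(hist_path)
    agg <- tapply(h$pct_change, band_of(h$site_id), mean)
    rows[[length(rows) + 1L]] <- data.frame(
      band = names(agg), scenario = "historical",
      window = "1986-2016 vs 1955-1985",
      mean_pct_change = as.numeric(agg), ad_fraction = NA_real_)
  }
  for (f in list.files(outdir, pattern = "^change_.*\\.csv$")) {
    ch <- read.csv(file.path(outdir, f))
    tag <- sub("^change_", "", sub("\\.csv$", "", f))
    adf <- file.path(outdir, paste0("ad_", tag, ".csv"))
    ad <- if (file.exists(adf)) read.csv(adf) else NULL
    agg <- tapply(ch$pct_change, band_of(ch$site_id), mean)
    frac <- if (!is.null(ad)) {
      u <- unique(ad[c("site_id", "inside")])
      as.numeric(tapply(u$inside, band_of(u$site_id), mean))
    } else NA_real_
    parts <- strsplit(tag, "_")[[1]]
    rows[[length(rows) + 1L]] <- data.frame(
      band = names(agg), scenario = parts[1],
      window = parts[length(parts)],
      mean_pct_change = as.numeric(agg), ad_fraction = frac)
  }
  if (length(rows) == 0L) stop("pipeline_report: no change maps found in ", outdir)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  write.csv(out, file.path(outdir, "report.csv"), row.names = FALSE)
  out
}
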