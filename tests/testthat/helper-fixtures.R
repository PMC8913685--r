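# shared small fixtures, built once per test file

# a compact model structure used for fast fitting tests: two seasons,
# linear smooths, no interactions
small_spec <- function() {
  model_spec(seasons = c("WIN", "SUM"), smooth_df = 1L,
             interactions = character(0))
}

small_truth <- function(spec = small_spec(), climate_zero = FALSE) {
  cm <- list(ai = 0.15, lat = 0.1, alt = -0.1, ba_prev = -0.08)
  if (!climate_zero)
    cm <- c(cm, list(tmax_SUM = -0.12, pp_SUM = 0.1, tmin_WIN = 0.06))
  true_params(spec, coef_main = cm,
              re_sd_intercept = 0.2, re_sd_slope = 0.06, re_corr = 0.2,
              gamma_shape = 8)
}

# small simulated network + derived tables, cached per session
small_network <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sites <- generate_sites(8, seed = 42)
      climate <- generate_monthly_climate(sites, c(1990, 2016), seed = 42)
      truth <- small_truth()
      sim <- simulate_growth(climate, sites, truth, trees_per_site = 3,
                             seed = 42)
      cache <<- list(sites = sim$sites, climate = climate, sim = sim,
                     truth = truth,
                     bai = rings_to_bai(sim$rings),
                     seasonal = aggregate_seasons(climate))
    }
    cache
  }
})

small_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      nw <- small_network()
      design <- build_design(nw$bai, nw$seasonal, nw$sites, nw$truth$spec,
                             scaler = nw$sim$scaler)
      cache <<- list(design = design,
                     fit = suppressWarnings(fit_glmm(design)))
    }
    cache
  }
})
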