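# baigrowth

Continental-scale tree-growth analysis from ring-width networks: basal area
increment (BAI) conversion, a gamma log-link mixed growth model driven by
seasonal climate, aridity and geography, nested AIC/likelihood-ratio model
validation, and delta-change climate-scenario projection with
applicability-domain masking. A synthetic-data generator with known ground
truth makes the whole chain testable end to end.

**Who it is for:** dendroecologists and quantitative ecologists who want to
(i) turn dated ring widths plus sampled diameters into comparable annual
growth rates, (ii) model those rates across a species range as a function
of seasonal climate, moisture regime and geography, and (iii) ask where —
and under which CMIP6-style scenario — growth is projected to decline.

## The model

Annual BAI of tree *j* at site *i* in year *t* is gamma-distributed with a
log link:

```
log BAI_ijt = β0 + log AI_i + f(LAT_i) + f(ALT_i)
            + Σ_k [ f(Tmax_itk) + f(Tmin_itk) + log PP_itk ]
            + interaction blocks (AI×Geo, Geo×Geo, AI×Cli, LAT×Cli, ALT×Cli)
            + b0_j + b1_j · BA_ijt
```

where *k* runs over six seasons (previous-year summer and autumn; current
winter, spring, summer, autumn) — 18 seasonal variables + aridity index +
latitude + altitude = **21 main variables** — and `(b0_j, b1_j)` is a
correlated per-tree random intercept and random slope on previous-year
basal area `BA` that absorbs size/age trends so period means compare
without detrending. `AI = P / (10 + T)` is the De Martonne aridity index.
All design columns are standardized; smooths are quadratic by default.
Estimation is maximum likelihood (Laplace) via `glmmTMB`.

## Worked example

Simulate a small 12-site network from the default ground truth, refit the
model, and project the six scenario × window combinations:

```r
library(baigrowth)

truth   <- default_true_params()
sites   <- generate_sites(12, seed = 1)
climate <- generate_monthly_climate(sites, c(1949, 2016), seed = 1)
sim     <- simulate_growth(climate, sites, truth, trees_per_site = 3, seed = 1)

bai      <- rings_to_bai(sim$rings)          # widths + DBH -> BAI (mm^2/yr)
seasonal <- aggregate_seasons(climate)       # six seasonal predictors
design   <- build_design(bai, seasonal, sim$sites, truth$spec)
fit      <- fit_glmm(design)
fit
#> <fitted_growth_model> gamma(log) GLMM: 2412 obs, 36 trees
#>   36 fixed effects | shape 7.82 | logLik -16923.0 | AIC 33928.0 (41 params)
#>   re sd (int, slope) = (0.207, 0.0964), corr 0.35

ens  <- generate_scenario_ensemble(sim$sites, seed = 1)
proj <- run_scenarios(fit, seasonal[seasonal$year >= 1986, ], sim$sites,
                      ens, seasonal, ba_fixed = 86059.03)
proj
#> <scenario_projection> 6 scenario x window combinations
#>   SSP1-2.6 2020-2050: median change -8.9%, 8/12 pixels in AD
#>   SSP1-2.6 2040-2070: median change -12.1%, 8/12 pixels in AD
#>   SSP1-2.6 2060-2090: median change -14.4%, 8/12 pixels in AD
#>   SSP5-8.5 2020-2050: median change -15.5%, 8/12 pixels in AD
#>   SSP5-8.5 2040-2070: median change -29.5%, 3/12 pixels in AD
#>   SSP5-8.5 2060-2090: median change -49.3%, 0/12 pixels in AD
```

Reading the output: the fitted model recovers the generating gamma shape
(8) and random-effect SDs (0.25, 0.08); growth of a reference tree with a
fixed basal area of 86059.03 mm² (~80-year-old beech) declines by a median
~9% under the optimistic near-term scenario, deepening to ~−50% under the
pessimistic late-century scenario — whose pixels, however, fall almost
entirely outside the model's applicability domain (the future climate
leaves the trained 1901–2016 range), so those estimates are flagged as
extrapolation rather than silently trusted.

An end-to-end run with artifacts on disk (rwl + CSV + YAML + manifest) is
one call: `run_pipeline(pipeline_config(seed = 1), "out/")`, summarised by
latitude band via `pipeline_report("out/")`.

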