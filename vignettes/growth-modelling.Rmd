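---
title: "Modelling continental tree growth from ring widths and seasonal climate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling continental tree growth from ring widths and seasonal climate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(baigrowth)
```

## The problem

Tree-ring networks record annual radial growth of individual trees across a
species' whole geographic and climatic range. Used carefully, they support
two questions that single-site dendroecology cannot answer: *where* has
growth changed over recent decades, and *what will happen* to growth under
projected climate change. `baigrowth` implements a complete analysis chain
for those questions, built around European beech-style networks (hundreds
of sites spanning roughly 5.8–28.4°E, 38.8–58.5°N, 1–1900 m elevation,
annual climates of 500–2000 mm and ~4–13.5 °C), and a synthetic-data
generator with known ground truth so that every stage of the chain is
testable end to end without any external data.

## From ring widths to basal area increment

Raw ring widths carry a strong geometric/ontogenetic trend. Rather than
detrending (which destroys comparability of absolute growth levels between
periods), widths are converted to **basal area increment** (BAI, mm²/yr):

$$\mathrm{BAI}_t = \pi\,(R_t^2 - R_{t-1}^2),$$

with radii reconstructed *outside-in* from the diameter at breast height
measured at sampling: $R_n = \mathrm{DBH}/2$, $R_{t-1} = R_t - w_t$.
Anchoring on the sampled DBH (rather than summing widths from the pith)
propagates no cumulative error to recent rings and tolerates cores that
miss the pith; the innermost reconstructed radius is then positive.
`rings_to_bai()` enforces non-negativity of all reconstructed radii and the
resulting table satisfies exact disc conservation,
$\sum_t \mathrm{BAI}_t = \pi (\mathrm{DBH}/2)^2 - \pi R_0^2$.

Working units are mm² throughout (conversion helpers to cm² exist); mixing
the two silently is the classic failure mode of BAI code. Missing rings
(zero widths) are rejected rather than imputed.

## Seasonal climate predictors and the aridity index

Monthly maximum/minimum temperature and precipitation are aggregated to six
meteorological seasons relative to the ring year *t*: previous-year summer
(`pSUM`) and autumn (`pAUT`), then winter (December of *t−1* + January +
February), spring, summer and autumn of *t*. Temperatures are averaged,
precipitation is summed, and a season missing any month is omitted rather
than approximated. December belongs to the following winter — the standard
dendroclimatic convention.

Long-term site moisture is summarised by the De Martonne aridity index

$$AI = \frac{P}{10 + T},$$

with $P$ the annual precipitation sum (mm) and $T$ the annual mean
temperature (°C), averaged over 1950–2016 by default. We average the
*annual* index values rather than evaluating the index at the mean climate;
the index is nonlinear in $T$, so the two differ slightly, and the
mean-of-annual-values reading is implemented and tested. Class boundaries
(10, 20, 24, 28, 35, 55; arid → extremely humid) are lower-inclusive — the
source intervals touch without stating inclusivity, so we fixed one
convention and test it exhaustively.

## The growth model

Annual BAI of tree *j* at site *i* in year *t* is modelled as gamma with a
log link:

$$\log \mathrm{BAI}_{ijt} = \beta_0 + \log AI_i + f(\mathrm{LAT}_i) +
f(\mathrm{ALT}_i) + \sum_k \big[ f(T^{max}_{itk}) + f(T^{min}_{itk}) +
\log PP_{itk} \big] + \text{interactions} + b_{0j} + b_{1j}\,\mathrm{BA}_{ijt},$$

where $k$ runs over the six seasons — 18 seasonal variables plus aridity,
latitude and altitude give exactly **21 main variables** — and
$(b_{0j}, b_{1j})$ is a correlated per-tree random intercept and random
slope on previous-year basal area. The random BA slope absorbs
individual size/age trajectories so that period means are comparable
without detrending; its deterministic companion (a fixed BA effect) is kept
in every model, including the null, because predictions "for a reference
tree of fixed basal area" are only meaningful with a population-level BA
term.

Design construction order is: log transform (aridity, precipitation with a
+1 mm offset guarding zeros) → per-variable z-standardization → polynomial
basis expansion → interaction products → a final z-standardization of every
design column. The smooths $f(\cdot)$ are orthogonal-in-effect quadratic
polynomials (df = 2) by default: the source analysis never specifies its
smoothers, and a quadratic keeps the bookkeeping transparent (21 mains →
35 main columns; all five interaction blocks → 194 fixed columns) while
allowing the unimodal climate responses that matter here. The complete
standardization state (the *scaler*) is stored on the design and reused at
prediction time; it can also be frozen externally, which is how simulation
studies compare estimates and generating truth on an identical scale.

Fitting maximizes the Laplace-approximated marginal likelihood (ML, not
REML) via `glmmTMB`. With a two-dimensional random effect, adaptive
Gauss–Hermite quadrature is impractical; Laplace is its one-point case, and
the package's tests verify on a tiny instance that the Laplace
log-likelihood agrees with a dense 50-point-per-dimension Gauss–Hermite
integration to ~10⁻³. Fits are warm-started from a fixed-effects-only gamma
GLM. When a random-effect variance collapses to the boundary the observed
Hessian is not positive definite and `glmmTMB` withholds its `logLik`; the
optimizer objective is still the maximized likelihood and is used, with a
warning, so likelihood-ratio ladders remain well defined.

### Model validation ladder

`compare_models()` fits the eight inclusion patterns of the three fixed
effect groups — moisture (AI), seasonal climate (Cli), geography (Geo) —
with random effects always present, and reports AIC, ΔAIC and a chi-square
likelihood-ratio test of each model against the null (random effects
only). A genuinely open design point: the source table's per-row
chi-square comparator is not fully recoverable from the published text, so
the null-reference convention was chosen and documented.

## Projection and applicability domain

`predict_grid()` applies a fitted model at population level over a seasonal
climate grid, holding basal area fixed at a reference value — default
86059.03 mm² (≈ 860.6 cm², DBH ≈ 33 cm, roughly an 80-year-old beech; the
printed unit annotation "(1/10,000 mm²)" in the source is treated as a
typo for mm², since 8.6 mm² would be a seedling). Period means use
inclusive endpoints — 1955–1985 and 1986–2016 each aggregate exactly 31
years — and change is reported as $100\,(\bar g_b - \bar g_a)/\bar g_a$.

Scenario projection follows the **delta-change method**: per climate model,
the difference between future-window and historic (1985–2014) seasonal
climatologies is computed; deltas are averaged over the temperature
ensemble (21 members) and the precipitation ensemble (26 members)
separately, then *added* to the observed baseline seasonality (additive for
temperature and precipitation, precipitation floored at zero; geographic
variables and the long-term aridity index stay fixed). Applying deltas to
the 31 individual baseline years — rather than to a flat climatology —
preserves interannual variability in the future period mean; this is an
interpretation choice, flagged as such. Two scenarios × three future
windows give exactly six growth-change maps.

Extrapolation is flagged by an **applicability domain**: for every seasonal
variable the training min/max over the whole 1901–2016 training domain is
recorded, and a future pixel with any value outside a trained range is
marked outside, with the violating (variable, season, side) enumerated.
Ranges are pooled over the domain rather than per pixel (the per-pixel
variant is a config choice away); outside pixels are reported, never
silently dropped.

## The synthetic-data generator

`generate_sites()`, `generate_monthly_climate()`, `simulate_growth()` and
`generate_scenario_ensemble()` emulate the study conditions: 324 sites
uniform in the network bounding box by default, site climatologies inside
the observed envelope (3.8–13.5 °C, 500–2000 mm), a July-peaked seasonal
cycle with a second harmonic (spring ≠ autumn), AR(1) interannual anomalies
(coefficient 0.3), a centred linear warming trend (0.1 °C/decade default),
and independent monthly noise in maximum and minimum temperature.

Two generator features deserve emphasis because they are *required* for the
model's variable groups to be distinguishable, not cosmetic realism:
site-level climatology offsets independent of latitude/altitude (local
exposure/continentality/soil effects), and a precipitation-regime gradient
from winter-wet (Mediterranean) in the south to summer-wet in the north
plus an eastward continentality gradient in seasonal temperature
amplitude. Without them, long-term aridity is a deterministic function of
geography and season means, and the moisture group would be exactly
redundant — a degenerate design no real network exhibits.

Growth is simulated forward from `true_params()`: per tree a correlated
(intercept, BA-slope) pair is drawn, then years iterate — linear predictor
on the standardized design, gamma draw with mean $e^\eta$, basal-area
update, ring width emitted as the radius increment rounded to 0.01 mm
(floored at 0.01 mm, mirroring measurement precision) and DBH recorded as
twice the final emitted radius, so BAI reconstruction retraces the emitted
path exactly and the simulate → widths → BAI round trip is bounded by the
rounding, about $2\pi R \times 0.01$ mm² per ring. Trees start from a 5 mm
radius; bark is ignored (the source is silent on it). Rings exist for every
climate year whose previous-year seasons exist, so *y* climate years yield
*y − 1* rings per tree.

The default truth sets growth near 800 mm²/yr, aridity/geography/climate
effects all active (wetter and warmer-winter sites grow more, hot summers
hurt, summer/spring rain helps), a *negative* lagged-BA coefficient
(−0.08): mature-tree growth decelerates with size, and — equally important
— any positive total size slope would compound super-exponentially over a
60-year forward simulation. Between-tree SDs are 0.25 (intercept) and 0.08
(BA slope), correlation 0.2, gamma shape 8 (CV ≈ 35%), all in the range of
single-species network analyses.

What the generator does **not** emulate: masting, competition, disturbance,
soil nutrition, spatial autocorrelation between sites, crossdating error,
or the grid structure of real climate products. Passing tests therefore
demonstrate the correctness and calibration of the *pipeline* under its own
assumptions, not the field realism of any particular coefficient.

## Study designs used by the package's own checks

Problem sizes were chosen as the smallest designs at which the respective
question is statistically answerable:

* **Parameter recovery** — 20 replicate networks of 50 sites × 5 trees ×
  60 climate years (~14,750 observations), canonical 21-variable
  main-effects design, scaler frozen to the generating scale; at least 90%
  of true fixed effects must fall within ±3 estimated SE pooled over
  replicates.
* **Model-selection ladder** — 60 sites × 3 trees × 30 years with a
  three-season spec including the aridity×geography and aridity×climate
  interaction blocks and active interaction truth; the full model must
  attain minimum AIC, every reduced model must beat the null. The
  interaction blocks are what give the moisture group observation-level
  signal (see above) — exactly the role they play in the source analysis.
* **Null calibration** — 200 replicate small networks (8 sites × 2 trees ×
  26 years, two-season linear spec) with climate truth zero; the
  climate-block likelihood-ratio test must reject at the nominal 5% level
  within a 99.8% binomial band.
* **Applicability domain** — brute-force range-check equivalence on 1000
  random pixels.

## Numerical choices and degenerate inputs

* Convergence: `nlminb` with raised iteration caps (1000/1200);
  non-convergence is an error by default, downgradeable to a warning for
  replicate studies.
* Constant design columns (zero variance) are an error naming the column;
  zero or negative seasonal precipitation under a zero offset is an error
  directing to `pp_offset`.
* Gap years within a tree are an error — series must be continuous.
* The gamma parameterisation is (shape, rate = shape/mean) so the mean is
  exactly $e^\eta$ and the shape is the reciprocal squared coefficient of
  variation; `glmmTMB`'s dispersion maps to shape as $1/\sigma^2$.
* Aridity classes and season/window endpoints are inclusive on the left;
  year windows are inclusive on both ends (31 years for 1955–1985).
* Ties in the model ladder are broken by AIC as computed; no significance
  pruning of interactions is performed by default (the source's count of
  "66 significant interactions" depends on an unstated selection rule, so
  no attempt is made to reproduce it).

## Known limitations

* The fixed-effect structure treats sites as exchangeable given the
  predictors; no spatial random effects or autocorrelation.
* Temporal structure within a tree beyond the lagged-BA slope (e.g. AR
  noise in growth) is not modelled.
* The applicability domain is a marginal (per-variable) box; joint
  (multivariate) extrapolation can evade it.
* Real-data ingestion is limited to Tucson/rwl plus CSV metadata; gridded
  NetCDF climate must be flattened to the tabular monthly format first.
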