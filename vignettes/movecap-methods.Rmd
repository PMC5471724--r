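---
title: "Cross-scale movement capacity from GPS telemetry: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-scale movement capacity from GPS telemetry: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`movecap` quantifies how far and how much animals move per nocturnal day,
per month, and over a whole monitoring period, and how individual,
meteorological, temporal, geographic and landscape covariates shape those
responses at each temporal scale. It was built for multi-study GPS telemetry
compilations — collections of collar datasets with wildly different fix
schedules (15 minutes to twice a day), monitoring spans, and study areas —
where the analysis must be robust to heterogeneous effort. This vignette
documents the models, the defaults and why they were chosen, the synthetic
data generator used for validation, and the package's known limitations.

## Screening and the biological day

Many of the species this workflow targets (wild pigs prominently among
them) are mostly nocturnal, so the analysis "day" is the window from 18:00
to 08:00 the following morning: fixes at or after 18:00 carry that calendar
date, fixes before 08:00 carry the previous date, and fixes between 08:00
and 18:00 are excluded entirely. Timestamps are treated as local study
clock time with no daylight-saving arithmetic — the nocturnal window is
applied to clock time, the simplest defensible reading when collars are
programmed locally. Screening applies, in order:

1. drop fixes with dilution of precision (DOP) above 10 — DOP exactly 10 is
   kept, reading "greater than 10" strictly;
2. drop diurnal fixes;
3. drop biological days with fewer than 2 fixes;
4. drop animals with fewer than 20 retained biological days — counted as
   retained days, not calendar span, for consistency with the monthly rule
   (span counting is available via `count_span`);
5. flag animal-months with fewer than 15 retained days as ineligible for
   monthly aggregation.

The 2-fix rule runs after the DOP and nocturnal filters because the
analyses only ever see surviving nocturnal fixes. `screen_fixes()` returns
an audit of the count removed at each step; screening is idempotent and
insensitive to input row order.

## Movement responses

Two responses are computed per animal-day. **MxD** (maximum daily distance)
is the largest great-circle distance between any two of the day's fixes.
**MHD** (mean hourly distance) is the plain average of distances between
fix pairs approximately one hour apart: for each fix, the subsequent fix
whose separation falls in [50, 70] minutes and is closest to 60 minutes is
its partner (ties to the earlier fix); a fix may be the target of one pair
and the origin of another. With fixes every half hour from 8:00 to 10:30
this yields exactly four distances. The 50–70 minute window is a package
choice — "approximately one hour" needs a tolerance, and the window is a
configurable parameter. MHD is deliberately not normalized by the exact
time separation; it is a mean of distances, matching the plain-averaging
definition of the response. Days with no qualifying pair contribute to MxD
but not MHD.

Distances use the haversine formula on a sphere of radius 6371.0088 km;
at study scales (tens of km) the difference from ellipsoidal geodesics is
far below GPS noise. Daily values are averaged per animal-month (eligible
months only) and per animal overall — the overall mean is taken over all
daily values combined, not over monthly means. Record weights are the mean
number of fixes per day at each scale, mirroring how precision varies with
fix rate.

## Home ranges

**MCP.** The percent minimum convex polygon retains the `ceiling(p/100 * n)`
fixes nearest the arithmetic centroid (ties keep the earlier fix), projects
them to a local azimuthal equal-area plane centred on the centroid, and
takes the convex-hull area (monotone chain, shoelace formula) in km².
Trimming conventions differ between software packages; this one mirrors the
common nearest-to-centroid rule and is documented precisely so results are
reproducible. Daily-scale home ranges are not estimated — a night of
fixes does not support a range estimate.

**Variograms and the OU fit.** The empirical semivariogram uses the
two-dimensional convention γ(l) = E‖Δr‖²/4 (km²), pooled across animals
within a study (pairs never span animals). An Ornstein–Uhlenbeck model
γ(l) = σ²(1 − e^(−l/τ)) is fitted by weighted least squares (weights =
pair counts) with a multistart τ grid to avoid local minima. A fitted τ
below a tenth of the smallest informative lag is flagged as independence.

**sAKDE.** The simplified autocorrelation-aware kernel density estimator
keeps the key mechanism of autocorrelated KDE — positional autocorrelation
shrinks the effective sample size N_eff = max(2, duration/τ), which
inflates the Gaussian-reference bandwidth H = Σ̂ · N_eff^(−1/3) (the d = 2
plug-in exponent) — and computes the area of the smallest highest-density
region containing 95% of mass by grid summation (128×128 default; halving
the cell size changes areas by under 1%). It is explicitly **not** a full
continuous-time movement-model AKDE: there is no OUF model selection, no
maximum-likelihood autocorrelation fit, and no bias-corrected bandwidth.
Estimates are tagged `sAKDE` so they are never mistaken for the full
method, and a fitted τ at or beyond the monitoring duration raises an
`unreliable` flag — the non-stationarity signature that makes
autocorrelated estimators balloon relative to MCP.

## Covariates

Five categories attach to each record at its fix centroid and time window:

- **individual** — the sex-age class (six levels from
  {juvenile, subadult, adult} × {M, F}, collapsing to `unknown` when either
  component is missing) and a management indicator;
- **meteorological** — max/min/mean temperature, relative humidity,
  saturation vapor-pressure deficit, precipitation total, surface pressure,
  wind speed and growing degree days, aggregated over the same 18:00–08:00
  window as the responses. Windows missing more than 20% of hours yield NA
  rather than imputed values. Saturation vapor pressure uses Tetens,
  610.78·exp(17.27 T/(T + 237.3)) Pa, converted to mm Hg; GDD uses
  max(0, (tmax + tmin)/2 − 10);
- **temporal** — month (entering models cyclically) and year, plus, at the
  monthly scale, lags 1–12 of monthly mean temperature and total
  precipitation (the weather generator provides a year of burn-in so all
  lags are defined);
- **geographic** — the level-III ecoregion containing the centroid
  (ray-casting point-in-polygon; boundary points go to the first polygon in
  file order);
- **landscape** — distances (km) from the centroid to the nearest water
  body, stream, agricultural field, forest patch, and major/medium/minor
  road, computed in the local equal-area plane (distance 0 inside a
  polygon).

Weather is attached from the study's series (nearest-series attachment,
which keeps the synthetic path exact); monthly meteorology is the mean of
the record's contributing daily values, with precipitation and GDD
totalled.

## Predictor screening

Meteorological (and monthly-lag) covariates are strongly collinear, so
those categories pass through a two-step screen before modeling. First a
random-forest regression ranks predictors by out-of-bag permutation
importance (permutation rather than impurity importance — robust to scale
and cardinality; deterministic under a seed). Then a greedy scan in
importance order keeps each predictor only if its absolute Pearson
correlation with every already-kept predictor is below 0.5 (categorical
predictors are exempt). Optionally, predictors are then added in importance
order until out-of-bag R² stops improving by at least ε = 0.01 — the
explicit form of "stops improving predictive accuracy", and the fallback
used when a model will not converge.

Two subtleties are worth knowing. The greedy filter is *not* monotone in
its threshold: a stricter threshold can drop a high-ranked blocker and
thereby admit a predictor the looser threshold would have excluded, so only
the within-set guarantee (all pairwise |r| below the threshold) holds.
And among near-duplicate predictors (e.g. GDD is mean temperature shifted
by 10 °C wherever temperatures exceed the base), which family member the
filter keeps is importance-ranking noise; `swap_representative()` lets an
analysis substitute the interpretable raw variable for a near-duplicate
blocker, and the package's own validation analyses use the raw temperature
as the family representative whenever the filter kept a derived transform.

## The additive mixed models

One model is fitted per response × scale × category. Smooth terms use
penalized cubic regression splines with equally spaced knots (k = 10 per
smooth, k = 8 for the spatial smooths) plus a null-space shrinkage penalty,
so uninfluential terms shrink toward zero rather than staying linear;
month uses a cyclic basis. Landscape distances and the management
indicator enter linearly; sex-age and ecoregion as factors. Every model
includes separate univariate smooths of latitude and longitude (a literal
two-smooth reading, not a bivariate surface) to absorb broad spatial
trends, and random intercepts for animal and study (study only at the
overall scale, where each animal contributes one record). Weights are the
fix counts described above; fits are invariant to the overall weight
scale. The response is modeled in km on the identity scale by default,
with a log-transform flag (`log_link`) used when variance components are
to be interpreted on the generative log scale. Smoothing parameters are
chosen by REML. Term significance uses the approximate Wald tests of the
backend at α = 0.05 with no multiplicity correction — the convention is
reported, not endorsed.

At the daily scale residuals are serially correlated, so daily models add
an AR(1) residual term estimated by a Cochrane–Orcutt-style iteration: fit,
estimate ρ as the pooled lag-1 autocorrelation of within-animal residuals
over unbroken day runs (gaps break a run; single-day runs contribute
nothing), refit with the AR(1) prewhitening at that ρ, and repeat until
|Δρ| < 10⁻³ (at most 20 iterations; ρ is clipped to (−0.99, 0.99) and
flagged if it escapes). Residual-AR was chosen over a lagged-response term
as the cleaner reading of "a linear autoregressive term"; the response-lag
variant can be emulated by adding the lag as a covariate.

**Reaction norms.** `reaction_norm()` evaluates a covariate's centred
partial effect on a grid with a ±2 SE band and reports the argmax and a
concavity indicator computed from second differences over the central 50%
of the grid: the curve is concave (convex) when the net slope change is
negative (positive), its window-scaled magnitude exceeds 0.2 relative to
the curve amplitude (a pure quadratic spanning the grid scores about 2, a
line about 0), and at least 70% of second differences agree in sign.

## The synthetic generator

Because the descriptive statistics of any real compilation derive from
restricted raw data, validation rests on a generator whose truth is known.
Animals follow a discrete-time Ornstein–Uhlenbeck attraction to a home
centre (Euler step at the fix interval, with internal substepping whenever
the interval exceeds τ/4, where the plain Euler step is unstable; the
exact OU transition is available by flag). The per-step displacement scale
s (km per √hour) is log-linear in covariates:

log s = α(ecoregion) + a·T² + b·T + c + β_P·(P − 101325) + δ(sex-age) +
u(animal) + v(study),

with defaults a = −0.002, b = 0.08, c = −0.8 (a concave reaction norm
peaking at 20 °C), β_P = 10⁻⁴ per Pa, adult males +0.25 log units over
females, animal-level intercept sd 0.3 and study-level sd 0.2 — chosen so
simulated MxD (~0.5–4 km), MHD (~0.4 km) and home ranges (a few km²) sit
in the range reported for wild pig compilations. T is the day's mean
temperature (seasonal sinusoid plus daily AR(1) anomalies): movement
responds to the night's thermal regime, which also makes the daily-mean
temperature the exactly-identified covariate in recovery runs. Fixes are
emitted around the clock (the nocturnal filter is downstream's job, as
with real collars), thinned by a fix-failure probability, and given
lognormal DOP draws calibrated so about 5% exceed 10, exercising the
precision filter.

The default (`preset = "paper"`) configuration emulates a multi-study
compilation: 13 studies across 6 states, monitoring windows between 2004
and 2016, 226 animals, fix intervals from 15 minutes to 12 hours, nine
level-III ecoregions, and a large fraction of animals with unknown age.
The `"recovery"` preset is the designed validation scenario: 100 animals,
60 days from mid-March, hourly fixes, 6 studies over 3 ecoregions with two
studies per ecoregion, widely spaced ecoregion intercepts (−1.35, −1.05,
−0.75) and a small study-level sd (0.1) so ecoregion contrasts are
identifiable, and no within-day temperature cycle so the temperature trio
collapses cleanly under the collinearity filter. These sizes keep the full
validation suite within minutes on a single core while leaving parameter
recovery comfortably inside its tolerances.

What the generator does *not* emulate — habitat selection, behavioral
states, irregular fix schedules within a study, dispersal other than a
constant-velocity centre drift, DOP-dependent position error — bounds what
passing tests show: they demonstrate that the estimators recover the
structure the generator encodes, not that real pig movement follows an OU
process. The generator is an idealization chosen for testability.

## Numerical choices and degenerate inputs

- OU variogram fitting: multistart over τ ∈ {0.5, …, 128} h; flat
  variograms fall back to independence (τ at its lower bound, flagged), in
  which case sAKDE uses N_eff = n.
- KDE: data whitened by the Cholesky factor of H so the kernel is
  standard normal and the density evaluation is a separable matrix
  product; grids cover the data ±3 bandwidths.
- MCP with all points identical returns area 0 with a `degenerate` flag;
  fewer than 5 points is an error.
- Smooths of covariates with fewer distinct values than basis functions
  get reduced bases (warning); 2 distinct values demote the term to
  linear; constants are dropped. Single-level factors are dropped.
  Single-study data drop the study random intercept.
- Grid cells whose model cannot be fitted are retried with the predictor
  set halved (importance order) and otherwise marked failed without
  aborting the rest of the grid.

## Interfaces

All stages are plain R functions returning data frames;
`run_pipeline(run_config(...))` orchestrates the full grid (simulate or
ingest → screen → metrics → home ranges → covariates → screening → models)
and `summarize_run()` tabulates term significance across the grid — the
tabular equivalent of a significant-variables summary. Data interchange is
deliberately plain text: the telemetry/weather/landscape schemas are CSV
(geometries as WKT strings), and the generator's truth is JSON, so every
artifact diffs and version-controls cleanly.

## Limitations

Reproducing any specific published compilation's numbers requires that
compilation's raw telemetry; the package ships the machinery and its
validation, not the data. sAKDE is a mechanism-preserving stand-in, not a
substitute for a full CTMM-based AKDE when publication-grade
autocorrelated home ranges are needed. Covariate × sex interactions,
step-selection analyses, and utilization-distribution overlap are out of
scope.
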