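# movecap

Cross-scale analysis of animal movement capacity from GPS telemetry.

Multi-study collar compilations — many studies, many fix schedules, many
landscapes — raise one recurring question: how far and how much do animals
move per day, per month, and overall, and which conditions shape that
capacity at each temporal scale? `movecap` implements the full workflow for
answering it:

- **screening**: DOP ≤ 10, the nocturnal "biological day" (18:00–08:00),
  ≥ 2 fixes/day, ≥ 20 monitored days per animal, ≥ 15 days for monthly
  eligibility, with a per-rule removal audit;
- **responses**: per-day maximum distance (MxD, the largest pairwise
  great-circle distance among a night's fixes) and mean hourly distance
  (MHD, the average of distances between fix pairs ~1 h apart), averaged to
  monthly and overall scales with fix-count weights;
- **home ranges**: percent-trimmed minimum convex polygons, pooled
  empirical semivariograms with an Ornstein–Uhlenbeck fit
  γ(l) = σ²(1 − e^(−l/τ)), and a clearly-labelled simplified
  autocorrelation-aware KDE (`sAKDE`) whose bandwidth inflates as the
  effective sample size N_eff = duration/τ shrinks;
- **covariates**: individual (sex-age, management), meteorological
  (temperature, humidity, Tetens vapor-pressure deficit, precipitation,
  pressure, wind, growing degree days over a 10 °C base), temporal (cyclic
  month, year, monthly lags 1–12), geographic (level-III ecoregion) and
  landscape (distances to water, streams, agriculture, forest, three road
  classes);
- **predictor screening**: random-forest permutation importance, the greedy
  pairwise |r| < 0.5 filter, and an out-of-bag R² stopping rule;
- **models**: one generalized additive mixed model per response × scale ×
  category — penalized cubic regression splines with shrinkage, factor and
  linear terms, latitude/longitude smooths, animal/study random intercepts,
  fix-count weights, and AR(1) residuals (Cochrane–Orcutt-style iteration)
  at the daily scale — with reaction-norm extraction (argmax, amplitude,
  concavity);
- **synthetic data**: a multi-study telemetry generator
  (Ornstein–Uhlenbeck movement, log-linear covariate-driven step scale
  log s = α_eco + aT² + bT + c + β_P(P − 101325) + δ_sexage + u_animal +
  v_study, DOP noise, fix failures) so every stage is testable against
  known truth.

## Worked example

Simulate a small two-study dataset with a concave temperature effect
peaking at 20 °C, screen it, compute responses and home ranges, and fit
the daily meteorological model:

```r
library(movecap)

cfg <- sim_config(preset = "recovery", seed = 42)
cfg$studies <- cfg$studies[1:2, ]
cfg$studies$n_animals <- c(6, 6)
ds  <- simulate_dataset(cfg)

scr <- screen_fixes(ds$telemetry)
str(scr$audit)
#> $ n_input             : int 16479
#> $ removed_dop         : int 843       # DOP > 10
#> $ removed_diurnal     : int 6509      # outside 18:00-08:00
#> $ removed_sparse_day  : int 0
#> $ removed_short_animal: int 0
#> $ n_retained          : int 9127
#> $ n_animals           : int 12

daily <- daily_metrics(scr$fixes)
summary(daily$mxd_km)
#>   Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#> 0.3135  1.2342  1.5444  1.7009  1.9977  4.3614

home_ranges(scr$fixes, "overall")[1:4, ]
#>   animal_id method area_km2 n_fixes    tau_h     neff flag
#> 1  R01_A001    MCP 4.809893     765       NA 727.0000
#> 2  R01_A001  sAKDE 6.389712     765 5.766327 249.5523
#> 3  R01_A002    MCP 6.076677     759       NA 722.0000
#> 4  R01_A002  sAKDE 7.832389     759 5.766327 249.3789

cov <- attach_covariates(daily, "daily", scr$fixes, ds$weather, ds$landscape)
fit <- fit_gamm(gamm_spec("mxd", "daily", "meteorological",
                          smooth_vars = c("tmean_c", "pressure_pa"),
                          weights_col = "n_fixes"), cov)
fit
#> Additive mixed model: mxd_km ~ meteorological covariates (daily scale)
#>   n = 720, adj R^2 = 0.587, AR(1) rho = 0.030
#>   smooth terms:
#>                     edf Ref.df        F p-value
#> s(tmean_c)       2.4711      9   1.3961  0.0014
#> s(pressure_pa)   0.9434      9   1.8574  0.0000
#> ...

rn <- reaction_norm(fit, "tmean_c")
c(peak = rn$argmax, shape = rn$concavity)
#> peak: 21.6 C; shape: concave
```

The fitted τ ≈ 5.8 h sits next to the generator's 6 h truth, the sAKDE/MCP
ratios are within a factor of ~1.3 on these stationary ranges, and the
temperature smooth recovers the concave reaction norm near its generative
20 °C peak. `run_pipeline(run_config(...))` orchestrates the full
response × scale × category grid end to end and `summarize_run()` tabulates
which terms are significant in which model.

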