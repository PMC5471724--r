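small_cfg <- function(..., n_animals = 2, days = 20, interval = 60, seed = 5) {
  cfg <- sim_config(preset = "recovery", seed = seed, ...)
  cfg$studies <- cfg$studies[1, , drop = FALSE]
  cfg$studies$n_animals <- n_animals
  cfg$studies$fix_interval_min <- interval
  cfg$studies$end <- cfg$studies$start + days - 1
  cfg
}

test_that("weather generator is deterministic and honours the noise-free case", {
  cfg <- small_cfg()
  w1 <- simulate_weather(cfg)
  w2 <- simulate_weather(cfg)
  expect_identical(w1, w2)
  # zero-amplitude anomalies: temperature equals the deterministic seasonal curve
  cfg0 <- small_cfg(weather = list(temp_anom_sd = 0))
  w0 <- simulate_weather(cfg0)
  expect_equal(w0$temp_c, weather_baseline_temp(w0$timestamp, cfg0$weather),
               tolerance = 1e-12)
  # pressure fluctuates around the standard atmosphere
  expect_lt(abs(mean(w1$pressure_pa) - 101325), 500)
  expect_error(simulate_weather({
    c2 <- small_cfg(); c2$studies$end <- c2$studies$start; c2$studies$end <- c2$studies$start - 1; c2
  }), "span")
})

test_that("AR(1) anomalies have the requested lag-1 autocorrelation", {
  set.seed(99)
  x <- ar1_noise(10000, phi = 0.7, sd = 2)
  expect_equal(stats::acf(x, plot = FALSE)$acf[2], 0.7, tolerance = 0.05)
  expect_equal(sd(x), 2, tolerance = 0.1)
})

test_that("OU tracks reach the closed-form stationary spread", {
  # constant covariates: set all effects to zero except a known intercept
  cfg <- small_cfg(n_animals = 30, days = 40, interval = 60, exact_ou = TRUE,
                   fix_fail_prob = 0, weather = list(temp_anom_sd = 0,
                                                     pressure_sd = 0))
  eff <- cfg$effects
  eff$temp_a <- 0; eff$temp_b <- 0; eff$pressure_slope <- 0
  eff$animal_sd <- 0; eff$study_sd <- 0
  eff$ecoregion_intercept[] <- log(0.4); eff$temp_c <- 0
  eff$sexage_offset[] <- 0
  cfg$effects <- eff
  ds <- simulate_dataset(cfg)
  s <- 0.4
  sd_theory <- s * sqrt(cfg$tau_pos_h / 2)
  deg_per_km <- 1 / (6371.0088 * pi / 180)
  # pooled per-axis positional sd across animals (lat axis avoids the
  # cos(lat) longitude scaling)
  by_animal <- split(ds$telemetry$lat, ds$telemetry$animal_id)
  sds <- vapply(by_animal, function(v) sd(v) / deg_per_km, numeric(1))
  expect_equal(mean(sds), sd_theory, tolerance = 0.10)
})

test_that("a sex-age offset of log(2) doubles mean step length", {
  cfg <- small_cfg(n_animals = 50, days = 15, interval = 60,
                   fix_fail_prob = 0,
                   weather = list(temp_anom_sd = 0, pressure_sd = 0))
  eff <- cfg$effects
  eff$temp_a <- 0; eff$temp_b <- 0; eff$temp_c <- 0; eff$pressure_slope <- 0
  eff$animal_sd <- 0; eff$study_sd <- 0
  eff$ecoregion_intercept[] <- log(0.3)
  eff$sexage_offset[] <- 0
  eff$sexage_offset["adult-M"] <- log(2)
  cfg$effects <- eff
  cfg$sexage_probs <- c("adult-M" = 0.5, "adult-F" = 0.5)
  ds <- simulate_dataset(cfg)
  step_mean <- function(sub) {
    mean(unlist(lapply(split(sub, sub$animal_id), function(tr) {
      n <- nrow(tr)
      geo_distance(tr$lon[-n], tr$lat[-n], tr$lon[-1], tr$lat[-1])
    })))
  }
  m <- step_mean(ds$telemetry[ds$telemetry$sex == "M", ])
  f <- step_mean(ds$telemetry[ds$telemetry$sex == "F", ])
  expect_equal(m / f, 2, tolerance = 0.15)
})

test_that("fix failure of 1 empties the track and DOP noise exercises the filter", {
  cfg <- small_cfg(fix_fail_prob = 1)
  ds <- simulate_dataset(cfg)
  expect_equal(nrow(ds$telemetry), 0)
  cfg <- small_cfg(n_animals = 5, days = 30, fix_fail_prob = 0)
  ds <- simulate_dataset(cfg)
  frac_high_dop <- mean(ds$telemetry$dop > 10)
  expect_gt(frac_high_dop, 0.01)
  expect_lt(frac_high_dop, 0.12)
})

test_that("a stronger pressure slope increases the pressure / step-length covariance", {
  base <- small_cfg(n_animals = 5, days = 40, fix_fail_prob = 0, seed = 21)
  eff0 <- base$effects
  eff0$temp_a <- 0; eff0$temp_b <- 0; eff0$animal_sd <- 0; eff0$study_sd <- 0
  covar_for <- function(slope) {
    cfg <- base
    eff <- eff0; eff$pressure_slope <- slope
    cfg$effects <- eff
    ds <- simulate_dataset(cfg)
    wx <- ds$weather
    per_animal <- lapply(split(ds$telemetry, ds$telemetry$animal_id), function(tr) {
      n <- nrow(tr)
      step <- geo_distance(tr$lon[-n], tr$lat[-n], tr$lon[-1], tr$lat[-1])
      idx <- findInterval(as.numeric(tr$timestamp[-n]), as.numeric(wx$timestamp))
      cbind(wx$pressure_pa[idx], log(pmax(step, 1e-9)))
    })
    m <- do.call(rbind, per_animal)
    stats::cov(m[, 1], m[, 2])
  }
  expect_gt(covar_for(3e-4), covar_for(0))
})

test_that("landscape features cover every study and respect density 0", {
  cfg <- sim_config(seed = 2)
  ls <- simulate_landscape(cfg)
  for (st in cfg$studies$study_id) {
    sub <- ls[ls$study_id == st, ]
    expect_setequal(unique(sub$feature_class),
                    c("water", "stream", "road", "agriculture", "forest",
                      "ecoregion"))
    expect_setequal(sub$class_detail[sub$feature_class == "road"],
                    c("major", "medium", "minor"))
  }
  expect_identical(simulate_landscape(cfg), simulate_landscape(cfg))
  ls0 <- simulate_landscape(cfg, density = 0)
  expect_setequal(unique(ls0$feature_class), "ecoregion")
  # downstream: distance to a suppressed class is flagged missing
  expect_warning(d <- distance_to_feature(-82, 29.5, ls0, "road"), "no features")
  expect_true(is.na(d))
})

test_that("export round-trips through the reader without loss", {
  cfg <- small_cfg(n_animals = 3, days = 25, seed = 9)
  ds <- simulate_dataset(cfg)
  dir <- withr::local_tempdir()
  export_dataset(ds, dir)
  dir2 <- withr::local_tempdir()
  export_dataset(ds, dir2)
  expect_identical(readLines(file.path(dir, "telemetry.csv")),
                   readLines(file.path(dir2, "telemetry.csv")))
  back <- read_fixes(file.path(dir, "telemetry.csv"))
  expect_equal(nrow(back), nrow(ds$telemetry))
  expect_equal(attr(back, "parse_report")$n_duplicates, 0)
  truth <- jsonlite::fromJSON(file.path(dir, "truth.json"))
  expect_equal(truth$effects$temp_a, cfg$effects$temp_a)
  expect_equal(unlist(truth$effects$ecoregion_intercept),
               cfg$effects$ecoregion_intercept)
})

test_that("scheduled fix counts match direct enumeration", {
  cfg <- small_cfg(n_animals = 10, days = 90, interval = 60, fix_fail_prob = 0)
  ds <- simulate_dataset(cfg)
  # hourly schedule: 24 fixes per animal-day
  expect_equal(nrow(ds$telemetry), 10 * 90 * 24)
  # nocturnal window holds 14 of the 24 hourly fixes per day
  hod <- as.numeric(format(ds$telemetry$timestamp, "%H"))
  expect_equal(sum(hod >= 18 | hod < 8), 10 * 90 * 14)
})
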