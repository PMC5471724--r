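# Multi-study synthetic GPS telemetry with known covariate-driven movement
# structure. Animals follow a discrete-time Ornstein-Uhlenbeck attraction to a
# home-range centre; the per-step displacement scale s is log-linear in
# covariates, so the generative reaction norms (quadratic temperature effect,
# linear pressure effect, sex-age offsets, ecoregion intercepts, animal- and
# study-level random intercepts) are known exactly and downstream estimators
# can be checked for parameter recovery.

# deterministic per-stage seed fan-out: one user seed reproduces every stage
# independently of execution order
seed_for <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483587L)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Stationary AR(1) noise series
#'
#' Gaussian AR(1) anomalies used for the weather generator's daily departures
#' from the seasonal cycle. Initialized from the stationary distribution.
#'
#' @param n Series length.
#' @param phi Lag-1 autoregressive coefficient, |phi| < 1.
#' @param sd Stationary (marginal) standard deviation.
#' @return Numeric vector of length \code{n}.
#' @export
ar1_noise <- function(n, phi, sd) {
  stopifnot(abs(phi) < 1, sd >= 0, n >= 1)
  if (sd == 0) return(numeric(n))
  innov_sd <- sd * sqrt(1 - phi^2)
  e <- stats::rnorm(n, 0, innov_sd)
  e[1] <- stats::rnorm(1, 0, sd)
  as.numeric(stats::filter(e, phi, method = "recursive"))
}

#' Known generative effects of the simulator
#'
#' The coefficient set that drives the per-step displacement scale
#' \eqn{\log s = \alpha_{eco} + aT^2 + bT + c + \beta_P (P - 101325) +
#' \delta_{sexage} + u_{animal} + v_{study}} (log km per root-hour). Defaults
#' give a concave temperature reaction norm peaking at 20 degrees C, a
#' positive pressure slope, and adult males moving more than females.
#'
#' @param temp_a,temp_b,temp_c Quadratic temperature coefficients on the log
#'   step scale. Defaults peak at \code{-temp_b/(2*temp_a)} = 20 degrees C.
#' @param pressure_slope Log-scale slope per Pa of surface pressure (pressure
#'   is centred at the standard atmosphere, 101325 Pa).
#' @param ecoregion_intercept Named log-km baseline per level-III ecoregion.
#' @param sexage_offset Named log-scale offsets per sex-age class.
#' @param animal_sd,study_sd Standard deviations of the animal- and
#'   study-level Gaussian random intercepts (log scale).
#' @return A list of class \code{true_effects}.
#' @export
true_effects <- function(temp_a = -0.002, temp_b = 0.08, temp_c = -0.8,
                         pressure_slope = 1e-4,
                         ecoregion_intercept = NULL,
                         sexage_offset = NULL,
                         animal_sd = 0.3, study_sd = 0.2) {
  if (is.null(ecoregion_intercept)) {
    ecoregion_intercept <- stats::setNames(
      -1.05 + seq(-0.3, 0.3, length.out = length(ECOREGIONS)), ECOREGIONS)
  }
  if (is.null(sexage_offset)) {
    sexage_offset <- c("adult-M" = 0.25, "adult-F" = 0,
                       "subadult-M" = 0.10, "subadult-F" = 0,
                       "juvenile-M" = -0.2, "juvenile-F" = -0.2,
                       "unknown" = 0)
  }
  stopifnot(animal_sd >= 0, study_sd >= 0)
  structure(list(temp_a = temp_a, temp_b = temp_b, temp_c = temp_c,
                 pressure_slope = pressure_slope,
                 ecoregion_intercept = ecoregion_intercept,
                 sexage_offset = sexage_offset,
                 animal_sd = animal_sd, study_sd = study_sd),
            class = "true_effects")
}

# the nine level-III ecoregions of the southeastern study area
ECOREGIONS <- c("Southern Coastal Plain", "Southeastern Plains",
                "Mississippi Alluvial Plain", "Western Gulf Coastal Plain",
                "South Central Plains", "Ozark Highlands",
                "Central Irregular Plains", "East Central Texas Plains",
                "Southern Texas Plains")

default_studies <- function() {
  centers <- list(FL = c(-82.0, 29.5), GA = c(-83.5, 32.5), LA = c(-92.0, 31.0),
                  MO = c(-92.5, 37.0), SC = c(-81.0, 33.5), TX = c(-98.0, 28.5))
  st <- c("FL", "FL", "GA", "GA", "LA", "LA", "MO", "MO", "SC", "TX", "TX", "TX", "TX")
  eco <- ECOREGIONS[c(1, 2, 2, 1, 3, 5, 6, 7, 1, 4, 8, 9, 9)]
  interval <- c(15, 60, 30, 120, 60, 240, 60, 480, 120, 720, 60, 30, 240)
  n_animals <- c(10, 15, 20, 25, 12, 18, 22, 30, 14, 16, 11, 13, 20) # sums to 226
  start_year <- c(2004, 2006, 2007, 2008, 2009, 2010, 2011, 2012, 2013, 2014, 2015, 2016, 2005)
  start <- as.Date(sprintf("%d-03-01", start_year)) + (seq_along(st) * 11) %% 90
  span <- c(90, 60, 120, 75, 90, 100, 60, 110, 80, 70, 90, 60, 100)
  jitter_lon <- seq(-0.5, 0.5, length.out = length(st))
  data.frame(
    study_id = sprintf("S%02d", seq_along(st)),
    state = st,
    ecoregion = eco,
    center_lon = vapply(st, function(s) centers[[s]][1], 0) + jitter_lon,
    center_lat = vapply(st, function(s) centers[[s]][2], 0) + rev(jitter_lon) / 2,
    fix_interval_min = interval,
    n_animals = n_animals,
    start = start,
    end = start + span,
    stringsAsFactors = FALSE
  )
}

# 100 animals, 60 days, hourly fixes, 6 studies over 3 ecoregions (2 studies
# per ecoregion, widely spaced intercepts, small study-level noise): the
# designed parameter-recovery scenario. The within-day temperature cycle is
# switched off so the daily-mean temperature is exactly the covariate that
# carries the generative reaction norm.
recovery_studies <- function() {
  eco <- ECOREGIONS[c(3, 3, 2, 2, 6, 6)]
  start <- as.Date("2011-03-15")
  data.frame(
    study_id = sprintf("R%02d", 1:6),
    state = c("LA", "LA", "GA", "GA", "MO", "MO"),
    ecoregion = eco,
    center_lon = c(-91.8, -92.2, -83.2, -83.8, -92.3, -92.7),
    center_lat = c(30.8, 31.2, 32.3, 32.7, 36.8, 37.2),
    fix_interval_min = 60,
    n_animals = c(17, 17, 17, 17, 17, 15), # 100 total
    start = start,
    end = start + 59,
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration
#'
#' Bundles the study design, observation model and generative effects. The
#' default preset emulates the conditions of a multi-study southeastern-US
#' wild pig telemetry compilation: 13 studies across 6 states spanning
#' 2004-2016, 226 animals, fix intervals from 15 min to 12 h, nine level-III
#' ecoregions, lognormal DOP noise with about 5 percent of draws above 10,
#' and occasional fix failures. The \code{"recovery"} preset is the designed
#' parameter-recovery scenario: 100 animals monitored for 60 days at hourly
#' fixes across 6 studies in 3 ecoregions.
#'
#' @param preset \code{"paper"} (default multi-study conditions) or
#'   \code{"recovery"}.
#' @param studies Optional data frame overriding the study table (columns
#'   study_id, state, ecoregion, center_lon, center_lat, fix_interval_min,
#'   n_animals, start, end).
#' @param seed Integer RNG seed; identical seeds give byte-identical exports.
#' @param effects A \code{\link{true_effects}} object.
#' @param tau_pos_h Ornstein-Uhlenbeck position autocorrelation timescale
#'   (hours).
#' @param exact_ou Use the exact OU transition instead of the Euler step.
#' @param drift_km_day Home-centre drift speed (km/day); 0 gives stationary
#'   range residency, positive values generate the non-stationary scenario
#'   used to probe home-range estimator bias.
#' @param fix_fail_prob Probability a scheduled fix is not recorded.
#' @param dop_meanlog,dop_sdlog Lognormal DOP parameters (defaults put about
#'   5 percent of mass above 10 so the precision filter is exercised).
#' @param sexage_probs Named sampling probabilities for sex-age classes.
#' @param managed_prob Probability a study is under active management.
#' @param study_halfwidth_deg Half-width of each study's bounding box (deg).
#' @param home_scatter_deg SD of animal home-centre scatter around the study
#'   centre (deg).
#' @param weather List of weather-generator parameters: \code{temp_mean},
#'   \code{temp_amp}, \code{temp_peak_doy}, \code{diurnal_amp},
#'   \code{temp_anom_sd}, \code{temp_anom_phi}, \code{pressure_sd},
#'   \code{pressure_phi}, \code{wind_mean}, \code{wind_sd}, \code{rh_mean},
#'   \code{rh_sd}, \code{precip_wet_prob}, \code{precip_mean_mm}.
#' @param burn_in_days Weather history simulated before each study start so
#'   that 12 monthly lags are always available.
#' @return A list of class \code{sim_config}.
#' @export
sim_config <- function(preset = c("paper", "recovery"),
                       studies = NULL, seed = 1L,
                       effects = NULL,
                       tau_pos_h = 6, exact_ou = FALSE, drift_km_day = 0,
                       fix_fail_prob = 0.05,
                       dop_meanlog = log(10) - 1.645 * 0.8, dop_sdlog = 0.8,
                       sexage_probs = NULL, managed_prob = 0.4,
                       study_halfwidth_deg = 0.15, home_scatter_deg = 0.05,
                       weather = list(), burn_in_days = 370) {
  preset <- match.arg(preset)
  if (is.null(studies)) {
    studies <- if (preset == "recovery") recovery_studies() else default_studies()
  }
  stopifnot(all(studies$fix_interval_min > 0),
            fix_fail_prob >= 0, fix_fail_prob <= 1,
            tau_pos_h > 0)
  if (is.null(effects)) {
    effects <- if (preset == "recovery") {
      eff <- true_effects(study_sd = 0.1)
      eff$ecoregion_intercept[] <- -1.05
      eff$ecoregion_intercept[unique(recovery_studies()$ecoregion)] <-
        c(-1.35, -1.05, -0.75)
      eff
    } else true_effects()
  }
  if (is.null(sexage_probs)) {
    sexage_probs <- if (preset == "recovery") {
      c("adult-M" = 0.3, "adult-F" = 0.3, "subadult-M" = 0.2, "subadult-F" = 0.2)
    } else {
      c("adult-M" = 0.15, "adult-F" = 0.15, "subadult-M" = 0.10,
        "subadult-F" = 0.10, "juvenile-F" = 0.01, "unknown" = 0.49)
    }
  }
  wdef <- list(temp_mean = 19, temp_amp = 9, temp_peak_doy = 200,
               diurnal_amp = if (preset == "recovery") 0 else 3,
               temp_anom_sd = 3.5, temp_anom_phi = 0.8,
               pressure_sd = 600, pressure_phi = 0.8,
               wind_mean = 3, wind_sd = 1, rh_mean = 70, rh_sd = 10,
               precip_wet_prob = 0.05, precip_mean_mm = 1.5)
  wdef[names(weather)] <- weather
  structure(list(preset = preset, studies = studies, seed = as.integer(seed),
                 effects = effects, tau_pos_h = tau_pos_h, exact_ou = exact_ou,
                 drift_km_day = drift_km_day, fix_fail_prob = fix_fail_prob,
                 dop_meanlog = dop_meanlog, dop_sdlog = dop_sdlog,
                 sexage_probs = sexage_probs / sum(sexage_probs),
                 managed_prob = managed_prob,
                 study_halfwidth_deg = study_halfwidth_deg,
                 home_scatter_deg = home_scatter_deg,
                 weather = wdef, burn_in_days = burn_in_days),
            class = "sim_config")
}

#' Deterministic baseline temperature of the weather generator
#'
#' Seasonal sinusoid plus (optional) within-day cycle; the noise-free
#' expectation of the simulated hourly temperature.
#'
#' @param time POSIXct times.
#' @param w Weather parameter list from a \code{\link{sim_config}}.
#' @return Temperature in degrees C.
#' @export
weather_baseline_temp <- function(time, w) {
  doy <- as.numeric(difftime(time, as.POSIXct(format(time, "%Y-01-01"),
                                              tz = "UTC"), units = "days"))
  hod <- as.numeric(format(time, "%H")) + as.numeric(format(time, "%M")) / 60
  w$temp_mean + w$temp_amp * cos(2 * pi * (doy - w$temp_peak_doy) / 365.25) +
    w$diurnal_amp * cos(2 * pi * (hod - 15) / 24)
}

#' Simulate hourly weather series for every study
#'
#' Hourly temperature (degrees C), surface pressure (Pa), precipitation (mm),
#' wind speed (m/s) and relative humidity (percent) per study, covering the
#' monitoring span plus a burn-in year so monthly lags of up to 12 months are
#' always defined. Temperature is a seasonal sinusoid plus stationary AR(1)
#' daily anomalies; pressure fluctuates around the standard atmosphere
#' (101325 Pa) with AR(1) daily anomalies.
#'
#' @param config A \code{\link{sim_config}}.
#' @return Data frame with columns study_id, timestamp, temp_c, pressure_pa,
#'   precip_mm, wind_ms, rh_pct, plus the daily-mean temperature anomaly
#'   driver in \code{temp_day_c} (seasonal + daily anomaly, no diurnal term).
#' @export
simulate_weather <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  spans <- as.numeric(config$studies$end - config$studies$start)
  if (any(spans < 1)) stop("invalid config: monitoring span shorter than 1 day")
  w <- config$weather
  out <- lapply(seq_len(nrow(config$studies)), function(i) {
    st <- config$studies[i, ]
    with_seed(seed_for(config$seed, paste0("weather/", st$study_id)), {
      t0 <- as.POSIXct(paste(st$start - config$burn_in_days, "00:00:00"), tz = "UTC")
      t1 <- as.POSIXct(paste(st$end, "23:00:00"), tz = "UTC")
      ts <- seq(t0, t1, by = 3600)
      nh <- length(ts)
      nd <- ceiling(nh / 24)
      day_idx <- rep(seq_len(nd), each = 24L)[seq_len(nh)]
      t_anom <- ar1_noise(nd, w$temp_anom_phi, w$temp_anom_sd)
      p_anom <- ar1_noise(nd, w$pressure_phi, w$pressure_sd)
      wind_d <- pmax(0, w$wind_mean + ar1_noise(nd, 0.6, w$wind_sd))
      rh_d <- pmin(100, pmax(20, w$rh_mean + ar1_noise(nd, 0.6, w$rh_sd)))
      base <- weather_baseline_temp(ts, w)
      seasonal_day <- w$temp_mean +
        w$temp_amp * cos(2 * pi * (as.numeric(format(ts, "%j")) - 1 +
                                     0.5 - w$temp_peak_doy) / 365.25)
      wet <- stats::runif(nh) < w$precip_wet_prob
      precip <- ifelse(wet, stats::rexp(nh, 1 / w$precip_mean_mm), 0)
      data.frame(
        study_id = st$study_id,
        timestamp = ts,
        temp_c = base + t_anom[day_idx],
        pressure_pa = 101325 + p_anom[day_idx],
        precip_mm = round(precip, 3),
        wind_ms = round(wind_d[day_idx], 3),
        rh_pct = round(rh_d[day_idx], 2),
        temp_day_c = seasonal_day + t_anom[day_idx],
        stringsAsFactors = FALSE
      )
    })
  })
  do.call(rbind, out)
}

# animal roster for a config: ids, classes, random effects, home centres
simulate_animals <- function(config) {
  eff <- config$effects
  out <- lapply(seq_len(nrow(config$studies)), function(i) {
    st <- config$studies[i, ]
    with_seed(seed_for(config$seed, paste0("animals/", st$study_id)), {
      n <- st$n_animals
      cls <- sample(names(config$sexage_probs), n, replace = TRUE,
                    prob = config$sexage_probs)
      sex <- ifelse(grepl("-M$", cls), "M", ifelse(grepl("-F$", cls), "F", "unknown"))
      age <- ifelse(cls == "unknown", "unknown", sub("-[MF]$", "", cls))
      managed <- stats::runif(1) < config$managed_prob
      data.frame(
        animal_id = sprintf("%s_A%03d", st$study_id, seq_len(n)),
        study_id = st$study_id,
        sex = sex, age_class = age, sexage = cls,
        managed = managed,
        ecoregion = st$ecoregion,
        home_lon = st$center_lon + stats::rnorm(n, 0, config$home_scatter_deg),
        home_lat = st$center_lat + stats::rnorm(n, 0, config$home_scatter_deg),
        animal_effect = stats::rnorm(n, 0, eff$animal_sd),
        stringsAsFactors = FALSE
      )
    })
  })
  animals <- do.call(rbind, out)
  with_seed(seed_for(config$seed, "study_effects"), {
    se <- stats::rnorm(nrow(config$studies), 0, eff$study_sd)
  })
  animals$study_effect <- se[match(animals$study_id, config$studies$study_id)]
  animals
}

#' Simulate one animal's GPS track
#'
#' Discrete-time Ornstein-Uhlenbeck attraction to the animal's home centre,
#' stepped at the study fix interval (Euler with internal substepping for
#' stability when the interval exceeds tau/4, or the exact OU transition when
#' \code{config$exact_ou}). The per-step displacement scale follows the
#' log-linear covariate link of \code{\link{true_effects}} using the day's
#' mean temperature and the hour's surface pressure. Scheduled fixes are
#' thinned by the fix-failure probability and each retained fix receives a
#' lognormal DOP draw.
#'
#' @param animal One row of the roster built by the simulator (list or
#'   single-row data frame with study/class/home-centre/random-effect fields).
#' @param weather Weather series for the animal's study (from
#'   \code{\link{simulate_weather}}).
#' @param effects A \code{\link{true_effects}}.
#' @param config The \code{\link{sim_config}}.
#' @return Data frame of fixes: study_id, animal_id, sex, age_class, managed,
#'   timestamp, lon, lat, dop.
#' @export
simulate_track <- function(animal, weather, effects, config) {
  animal <- as.list(animal)
  st <- config$studies[config$studies$study_id == animal$study_id, ]
  wx <- weather[weather$study_id == animal$study_id, ]
  if (nrow(wx) == 0) stop("weather does not cover study ", animal$study_id)
  t0 <- as.POSIXct(paste(st$start, "00:00:00"), tz = "UTC")
  t1 <- as.POSIXct(paste(st$end, "23:59:59"), tz = "UTC")
  if (min(wx$timestamp) > t0 || max(wx$timestamp) < t1 - 3600) {
    stop("weather does not cover the monitoring span for study ", animal$study_id)
  }
  sched <- seq(t0, t1, by = st$fix_interval_min * 60)
  dt_h <- st$fix_interval_min / 60
  # covariates at each scheduled step
  hr_idx <- findInterval(as.numeric(sched), as.numeric(wx$timestamp))
  hr_idx[hr_idx < 1] <- 1
  tday <- wx$temp_day_c[hr_idx]
  pres <- wx$pressure_pa[hr_idx]
  log_s <- effects$ecoregion_intercept[[animal$ecoregion]] +
    effects$temp_a * tday^2 + effects$temp_b * tday + effects$temp_c +
    effects$pressure_slope * (pres - 101325) +
    effects$sexage_offset[[animal$sexage]] +
    animal$animal_effect + animal$study_effect
  s <- exp(log_s)                       # km per sqrt(hour)
  tau <- config$tau_pos_h
  n <- length(sched)
  if (config$exact_ou) {
    alpha <- exp(-dt_h / tau)
    step_sd <- s * sqrt(tau / 2 * (1 - alpha^2))
  } else {
    nsub <- max(1L, ceiling(dt_h / (tau / 4)))
    h <- dt_h / nsub
    a <- 1 - h / tau
    alpha <- a^nsub
    # variance of the aggregated Euler substeps: s^2 h (1 + a^2 + ... + a^(2(nsub-1)))
    step_sd <- s * sqrt(h * sum(a^(2 * (seq_len(nsub) - 1))))
  }
  drift_t <- config$drift_km_day * as.numeric(difftime(sched, t0, units = "days"))
  with_seed(seed_for(config$seed, paste0("track/", animal$animal_id)), {
    simulate_axis <- function(center_path) {
      innov <- stats::rnorm(n, 0, 1) * step_sd + (1 - alpha) * center_path
      x0 <- stats::rnorm(1, center_path[1], s[1] * sqrt(tau / 2))
      as.numeric(stats::filter(innov, alpha, method = "recursive", init = x0))
    }
    x <- simulate_axis(drift_t)          # drift (if any) moves the centre east
    y <- simulate_axis(numeric(n))
    keep <- stats::runif(n) >= config$fix_fail_prob
    dop <- stats::rlnorm(n, config$dop_meanlog, config$dop_sdlog)
  })
  deg_per_km_lat <- 1 / (EARTH_RADIUS_KM * pi / 180)
  deg_per_km_lon <- deg_per_km_lat / cos(animal$home_lat * pi / 180)
  nk <- sum(keep)
  data.frame(
    study_id = rep(animal$study_id, nk),
    animal_id = rep(animal$animal_id, nk),
    sex = rep(animal$sex, nk), age_class = rep(animal$age_class, nk),
    managed = rep(as.integer(animal$managed), nk),
    timestamp = sched[keep],
    lon = animal$home_lon + x[keep] * deg_per_km_lon,
    lat = animal$home_lat + y[keep] * deg_per_km_lat,
    dop = round(dop[keep], 2),
    stringsAsFactors = FALSE
  )
}

#' Simulate labelled landscape features per study
#'
#' Places water points, stream and road polylines (three road classes),
#' agriculture and forest polygons inside each study's bounding box, plus one
#' ecoregion polygon per study so the ecoregion polygons partition the study
#' areas. Every study area intersects at least one feature of each class.
#'
#' @param config A \code{\link{sim_config}}.
#' @param density Multiplier on per-study feature counts (0 suppresses all
#'   but the guaranteed ecoregion polygons; see Details).
#' @details With \code{density = 0} no water/stream/road/agriculture/forest
#'   features are emitted at all, so downstream distances to those classes are
#'   flagged missing rather than fabricated.
#' @return Data frame: study_id, feature_class, class_detail, wkt, label.
#' @export
simulate_landscape <- function(config, density = 1) {
  hw <- config$study_halfwidth_deg
  out <- lapply(seq_len(nrow(config$studies)), function(i) {
    st <- config$studies[i, ]
    with_seed(seed_for(config$seed, paste0("landscape/", st$study_id)), {
      cx <- st$center_lon; cy <- st$center_lat
      runif_box <- function(n) cbind(lon = stats::runif(n, cx - hw, cx + hw),
                                     lat = stats::runif(n, cy - hw, cy + hw))
      rows <- list()
      add <- function(class, detail, type, coords, label) {
        rows[[length(rows) + 1L]] <<- data.frame(
          study_id = st$study_id, feature_class = class,
          class_detail = detail, wkt = to_wkt(type, coords), label = label,
          stringsAsFactors = FALSE)
      }
      n_of <- function(base) if (density <= 0) 0L else max(1L, round(base * density))
      for (k in seq_len(n_of(5))) {
        add("water", NA_character_, "point", runif_box(1), sprintf("water_%d", k))
      }
      polyline <- function() {
        nseg <- 5L
        x <- seq(cx - hw, cx + hw, length.out = nseg)
        y <- stats::runif(nseg, cy - hw, cy + hw)
        cbind(lon = x, lat = y)
      }
      for (k in seq_len(n_of(2))) {
        add("stream", NA_character_, "linestring", polyline(), sprintf("stream_%d", k))
      }
      for (cls in c("major", "medium", "minor")) {
        for (k in seq_len(n_of(1))) {
          add("road", cls, "linestring", polyline(), sprintf("road_%s_%d", cls, k))
        }
      }
      rect <- function() {
        w <- stats::runif(1, hw / 8, hw / 3); h <- stats::runif(1, hw / 8, hw / 3)
        p <- runif_box(1)
        cbind(lon = p[1] + c(-w, w, w, -w), lat = p[2] + c(-h, -h, h, h))
      }
      for (k in seq_len(n_of(2))) {
        add("agriculture", NA_character_, "polygon", rect(), sprintf("ag_%d", k))
      }
      for (k in seq_len(n_of(2))) {
        add("forest", NA_character_, "polygon", rect(), sprintf("forest_%d", k))
      }
      add("ecoregion", NA_character_, "polygon",
          cbind(lon = cx + hw * 1.5 * c(-1, 1, 1, -1),
                lat = cy + hw * 1.5 * c(-1, -1, 1, 1)),
          st$ecoregion)
      do.call(rbind, rows)
    })
  })
  do.call(rbind, out)
}

#' Simulate a complete multi-study dataset
#'
#' Runs the weather, roster, track and landscape generators and bundles the
#' result with the generative truth for parameter-recovery testing.
#'
#' @param config A \code{\link{sim_config}}.
#' @return List with elements \code{telemetry}, \code{weather},
#'   \code{landscape}, \code{animals}, \code{truth} (effects + config).
#' @export
simulate_dataset <- function(config = sim_config()) {
  weather <- simulate_weather(config)
  animals <- simulate_animals(config)
  tracks <- lapply(seq_len(nrow(animals)), function(i) {
    simulate_track(animals[i, ], weather, config$effects, config)
  })
  telemetry <- do.call(rbind, tracks)
  landscape <- simulate_landscape(config)
  effects_json <- unclass(config$effects)
  effects_json$ecoregion_intercept <- as.list(effects_json$ecoregion_intercept)
  effects_json$sexage_offset <- as.list(effects_json$sexage_offset)
  list(telemetry = telemetry, weather = weather, landscape = landscape,
       animals = animals,
       truth = list(effects = effects_json,
                    seed = config$seed, preset = config$preset,
                    tau_pos_h = config$tau_pos_h,
                    drift_km_day = config$drift_km_day))
}

#' Export a simulated dataset to plain-text files
#'
#' Writes telemetry.csv, weather.csv, landscape.csv (WKT-in-CSV) and
#' truth.json into \code{dir}. Deterministic: identical seeds give
#' byte-identical files.
#'
#' @param dataset From \code{\link{simulate_dataset}}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of file paths written.
#' @export
export_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (file.access(dir, 2) != 0) stop("directory not writable: ", dir)
  fmt_time <- function(t) format(t, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  tel <- dataset$telemetry
  tel$timestamp <- fmt_time(tel$timestamp)
  wx <- dataset$weather
  wx$temp_c <- round(wx$temp_c, 4)
  wx$pressure_pa <- round(wx$pressure_pa, 2)
  wx$temp_day_c <- round(wx$temp_day_c, 4)
  wx$timestamp <- fmt_time(wx$timestamp)
  tel$lon <- round(tel$lon, 7); tel$lat <- round(tel$lat, 7)
  paths <- file.path(dir, c("telemetry.csv", "weather.csv", "landscape.csv",
                            "truth.json"))
  utils::write.csv(tel, paths[1], row.names = FALSE)
  utils::write.csv(wx, paths[2], row.names = FALSE)
  utils::write.csv(dataset$landscape, paths[3], row.names = FALSE)
  writeLines(jsonlite::toJSON(dataset$truth, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE), paths[4])
  invisible(paths)
}
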