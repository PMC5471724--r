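# Independent oracles and shared fixtures. Oracles here are deliberately
# written without reusing package internals so the tests are dual-route.

# scalar spherical law-of-cosines distance (km) -- independent of the
# package's haversine implementation
oracle_distance_km <- function(lon1, lat1, lon2, lat2) {
  r <- pi / 180
  ca <- sin(lat1 * r) * sin(lat2 * r) +
    cos(lat1 * r) * cos(lat2 * r) * cos((lon2 - lon1) * r)
  6371.0088 * acos(pmin(1, pmax(-1, ca)))
}

# O(n^2) double-loop maximum pairwise distance
oracle_max_pairwise <- function(lon, lat) {
  n <- length(lon)
  best <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      best <- max(best, oracle_distance_km(lon[i], lat[i], lon[j], lat[j]))
    }
  }
  best
}

# Jarvis-march (gift wrapping) convex hull area via the surveyor formula,
# on planar points
oracle_hull_area <- function(xy) {
  n <- nrow(xy)
  start <- which.min(xy[, 1] + 1e-9 * xy[, 2])
  hull <- start
  repeat {
    p <- hull[length(hull)]
    cand <- if (p == 1) 2 else 1
    for (q in seq_len(n)) {
      if (q == p) next
      cr <- (xy[cand, 1] - xy[p, 1]) * (xy[q, 2] - xy[p, 2]) -
        (xy[cand, 2] - xy[p, 2]) * (xy[q, 1] - xy[p, 1])
      d_cand <- sum((xy[cand, ] - xy[p, ])^2)
      d_q <- sum((xy[q, ] - xy[p, ])^2)
      if (cr < 0 || (cr == 0 && d_q > d_cand)) cand <- q
    }
    if (cand == start) break
    hull <- c(hull, cand)
    if (length(hull) > n) stop("gift wrapping failed")
  }
  v <- xy[hull, , drop = FALSE]
  m <- nrow(v)
  if (m < 3) return(0)
  j <- c(m, seq_len(m - 1))
  abs(sum(v[j, 1] * v[, 2] - v[, 1] * v[j, 2]) / 2)
}

# winding-number point-in-polygon oracle
oracle_point_in_polygon <- function(p, verts) {
  n <- nrow(verts)
  wn <- 0
  for (i in seq_len(n)) {
    a <- verts[i, ]; b <- verts[if (i == n) 1 else i + 1, ]
    if (a[2] <= p[2]) {
      if (b[2] > p[2] &&
          (b[1] - a[1]) * (p[2] - a[2]) - (p[1] - a[1]) * (b[2] - a[2]) > 0) {
        wn <- wn + 1
      }
    } else if (b[2] <= p[2] &&
               (b[1] - a[1]) * (p[2] - a[2]) - (p[1] - a[1]) * (b[2] - a[2]) < 0) {
      wn <- wn - 1
    }
  }
  wn != 0
}

# build a fix table by hand
make_fixes <- function(times, lon, lat, dop = 1, animal_id = "a1",
                       study_id = "s1", sex = "F", age_class = "adult",
                       managed = 0L) {
  data.frame(study_id = study_id, animal_id = animal_id, sex = sex,
             age_class = age_class, managed = managed,
             timestamp = as.POSIXct(times, tz = "UTC"),
             lon = lon, lat = lat, dop = dop, stringsAsFactors = FALSE)
}

# random nocturnal fix days for oracle comparisons
random_day_fixes <- function(n, seed) {
  set.seed(seed)
  times <- as.POSIXct("2010-06-01 18:00:00", tz = "UTC") +
    sort(sample(0:(14 * 3600), n))
  make_fixes(times, lon = -82 + rnorm(n, sd = 0.01),
             lat = 29 + rnorm(n, sd = 0.01))
}

# shared recovery-scenario computation, built once per test run (used by the
# parameter-recovery, scale-attenuation and variance-component checks)
.recovery_cache <- new.env(parent = emptyenv())
recovery_fit_bundle <- function() {
  if (!is.null(.recovery_cache$bundle)) return(.recovery_cache$bundle)
  cfg <- sim_config(preset = "recovery", seed = 101)
  ds <- simulate_dataset(cfg)
  scr <- screen_fixes(ds$telemetry)
  daily <- daily_metrics(scr$fixes)
  monthly <- aggregate_metrics(daily, "monthly", scr$month_eligibility)
  cov_d <- attach_covariates(daily, "daily", scr$fixes, ds$weather, ds$landscape)
  cov_m <- attach_covariates(monthly, "monthly", scr$fixes, ds$weather,
                             ds$landscape)
  met_cols <- attr(cov_d, "categories")$meteorological
  ok <- stats::complete.cases(cov_d[c("mxd_km", met_cols)])
  sc <- screen_predictors(cov_d$mxd_km[ok], cov_d[ok, met_cols],
                          weights = cov_d$n_fixes[ok],
                          seed = 7, n_trees = 300)
  # the temperature family is collinear by design; when the filter kept a
  # derived transform (gdd, svpd) instead of a raw temperature, substitute
  # the raw variable as the family representative for interpretation
  kept <- swap_representative(sc, c("tmean_c", "tmax_c", "tmin_c"))
  raw_temp <- c("tmean_c", "tmax_c", "tmin_c")
  if (!any(raw_temp %in% kept)) {
    derived <- intersect(kept, c("gdd", "svpd_mmhg"))
    if (length(derived)) kept[kept == derived[1]] <- "tmean_c"
  }
  kept_temp <- intersect(kept, raw_temp)
  spec_met <- movecap:::category_spec(cov_d, "mxd", "daily", "meteorological",
                                      kept = kept, weights_col = "n_fixes")
  fit_met_d <- fit_gamm(spec_met, cov_d)
  spec_met_m <- movecap:::category_spec(cov_m, "mxd", "monthly",
                                        "meteorological",
                                        kept = intersect(kept, names(cov_m)))
  fit_met_m <- fit_gamm(spec_met_m, cov_m)
  spec_ind <- movecap:::category_spec(cov_d, "mxd", "daily", "individual",
                                      weights_col = "n_fixes", log_link = TRUE)
  fit_ind_log <- fit_gamm(spec_ind, cov_d)
  spec_geo <- movecap:::category_spec(cov_d, "mxd", "daily", "geographic",
                                      weights_col = "n_fixes")
  fit_geo <- fit_gamm(spec_geo, cov_d)
  .recovery_cache$bundle <- list(
    cfg = cfg, ds = ds, scr = scr, daily = daily, cov_d = cov_d, cov_m = cov_m,
    screening = sc, kept_temp = kept_temp,
    fit_met_d = fit_met_d, fit_met_m = fit_met_m,
    fit_ind_log = fit_ind_log, fit_geo = fit_geo)
  .recovery_cache$bundle
}
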