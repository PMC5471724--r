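test_that("saturation deficit follows Tetens and its limiting cases", {
  # saturated air: zero deficit
  expect_equal(svp_tetens(20) * (1 - 100 / 100), 0)
  # SVP(25 C) ~ 23.76 mm Hg; at RH 50 percent the deficit is half of it
  svp25_mmhg <- svp_tetens(25) / 133.322
  expect_equal(svp25_mmhg, 23.76, tolerance = 0.01)
  expect_equal(svp25_mmhg * 0.5, 11.88, tolerance = 0.005)
  # deficit increases with temperature at fixed RH
  expect_true(all(diff(svp_tetens(seq(0, 40, 5)) * 0.5) > 0))
})

test_that("growing degree days use the floored midpoint convention", {
  expect_equal(gdd(25, 15), 10)
  expect_equal(gdd(12, 4), 0)
  expect_equal(sum(gdd(rep(25, 30), rep(15, 30))), 300)
  expect_error(gdd(4, 12), "tmax < tmin")
})

hourly_weather <- function(days, temp = 20, rh = 100, precip = 0,
                           pressure = 101325, wind = 2, study = "s1") {
  ts <- seq(as.POSIXct(paste(days[1], "00:00:00"), tz = "UTC"),
            as.POSIXct(paste(days[length(days)], "23:00:00"), tz = "UTC"),
            by = 3600)
  data.frame(study_id = study, timestamp = ts,
             temp_c = rep_len(temp, length(ts)),
             pressure_pa = pressure, precip_mm = rep_len(precip, length(ts)),
             wind_ms = wind, rh_pct = rep_len(rh, length(ts)),
             stringsAsFactors = FALSE)
}

test_that("biological-day weather aggregation matches direct arithmetic", {
  w <- hourly_weather(as.character(as.Date("2010-03-01") + 0:4),
                      temp = 20, rh = 100, precip = 0.5)
  d <- daily_weather_aggregate(w)
  # constant 20 C at 100 percent RH: zero deficit, equal max/min/mean
  full <- d[d$day == as.Date("2010-03-02"), ]
  expect_equal(full$tmax_c, 20)
  expect_equal(full$tmin_c, 20)
  expect_equal(full$svpd_mmhg, 0)
  # 0.5 mm per hour over the 14-hour window: 7 mm total
  expect_equal(full$precip_mm, 7)
  expect_equal(full$gdd, 10)
  # truncated trailing window (last evening only) is reported missing
  last <- d[d$day == as.Date("2010-03-05"), ]
  expect_true(is.na(last$tmean_c))
})

test_that("monthly lags equal a brute-force shift", {
  days <- as.character(seq(as.Date("2009-01-01"), as.Date("2010-12-31"), by = "day"))
  set.seed(4)
  w <- hourly_weather(days)
  w$temp_c <- rnorm(nrow(w), 15, 8)
  w$precip_mm <- rexp(nrow(w), 2)
  dw <- daily_weather_aggregate(w)
  mw <- monthly_weather(dw, max_lag = 12)
  mw <- mw[order(mw$month), ]
  for (k in c(1, 5, 12)) {
    expect_equal(mw[[sprintf("tmean_lag%d", k)]][-seq_len(k)],
                 mw$tmean_c[seq_len(nrow(mw) - k)], tolerance = 1e-12)
    expect_true(all(is.na(mw[[sprintf("tmean_lag%d", k)]][seq_len(k)])))
  }
  # lag columns commute with series shifts: lag-2 of lag-3 source = lag-5
  expect_equal(mw$tmean_lag5[-(1:5)], mw$tmean_lag2[3:(nrow(mw) - 3)],
               tolerance = 1e-12)
})

test_that("feature distances match closed-form planar geometry", {
  mk_ls <- function(type, coords, class = "water", detail = NA) {
    data.frame(study_id = "s1", feature_class = class, class_detail = detail,
               wkt = to_wkt(type, coords), label = "f", stringsAsFactors = FALSE)
  }
  deg <- 1 / (6371.0088 * pi / 180)
  # single water point 1 km north of the centroid
  ls <- mk_ls("point", cbind(0, 1 * deg))
  expect_equal(distance_to_feature(0, 0, ls, "water"), 1, tolerance = 1e-4)
  # point (0,1) km against segment (-1,0)-(1,0) km
  ls_stream <- mk_ls("linestring", cbind(c(-1, 1) * deg, c(0, 0)), class = "stream")
  expect_equal(distance_to_feature(0, 1 * deg, ls_stream, "stream"), 1,
               tolerance = 1e-4)
  # centroid beyond an endpoint: distance to the endpoint
  expect_equal(distance_to_feature(4 * deg, 4 * deg, ls_stream, "stream"),
               sqrt(3^2 + 4^2), tolerance = 1e-3)
  # inside a polygon: zero
  ls <- mk_ls("polygon", cbind(c(-1, 1, 1, -1) * deg, c(-1, -1, 1, 1) * deg),
              class = "forest")
  expect_equal(distance_to_feature(0, 0, ls, "forest"), 0)
  # translation consistency
  ls2 <- mk_ls("linestring", cbind(c(-1, 1) * deg + 0.02, c(0, 0) + 0.02),
               class = "stream")
  expect_equal(distance_to_feature(0.02, 1 * deg + 0.02, ls2, "stream"),
               distance_to_feature(0, 1 * deg, ls_stream, "stream"),
               tolerance = 1e-6)
})

test_that("ecoregion lookup agrees with the winding-number oracle", {
  poly_a <- cbind(lon = c(0, 1, 1, 0), lat = c(0, 0, 1, 1))
  poly_b <- cbind(lon = c(1, 2, 2, 1), lat = c(0, 0, 1, 1))
  ls <- data.frame(study_id = "s1", feature_class = "ecoregion",
                   class_detail = NA,
                   wkt = c(to_wkt("polygon", poly_a), to_wkt("polygon", poly_b)),
                   label = c("A", "B"), stringsAsFactors = FALSE)
  expect_equal(ecoregion_lookup(0.5, 0.5, ls), "A")
  expect_equal(ecoregion_lookup(1.5, 0.5, ls), "B")
  # boundary points go to the first polygon in file order
  expect_equal(ecoregion_lookup(1, 0.5, ls), "A")
  expect_warning(out <- ecoregion_lookup(5, 5, ls), "outside")
  expect_true(is.na(out))

  set.seed(9)
  pts <- cbind(runif(1000, -0.5, 2.5), runif(1000, -0.5, 1.5))
  for (i in sample(1000, 200)) {
    mine <- suppressWarnings(ecoregion_lookup(pts[i, 1], pts[i, 2], ls))
    in_a <- oracle_point_in_polygon(pts[i, ], poly_a)
    in_b <- oracle_point_in_polygon(pts[i, ], poly_b)
    orac <- if (in_a) "A" else if (in_b) "B" else NA_character_
    # ray casting counts boundary points as inside; the winding oracle is
    # open on edges, so only compare strictly interior/exterior points
    on_edge <- min(abs(pts[i, 1] - c(0, 1, 2))) < 1e-9 ||
      min(abs(pts[i, 2] - c(0, 1))) < 1e-9
    if (!on_edge) expect_identical(mine, orac)
  }
})

test_that("covariate attachment joins weather, classes and landscape", {
  days <- as.character(as.Date("2010-03-01") + 0:24)
  deg <- 1 / (6371.0088 * pi / 180)
  f <- do.call(rbind, lapply(days, function(d) {
    make_fixes(as.POSIXct(paste(d, c("19:00:00", "21:00:00", "23:00:00")),
                          tz = "UTC"),
               lon = c(0, 0.4, 0.8) * deg, lat = c(0, 0.3, 0.6) * deg,
               sex = "M", age_class = "adult")
  }))
  scr <- screen_fixes(f)
  d <- daily_metrics(scr$fixes)
  w <- hourly_weather(as.character(as.Date("2010-02-25") + 0:30),
                      temp = 18, rh = 60)
  ls <- data.frame(study_id = "s1", feature_class = "ecoregion",
                   class_detail = NA,
                   wkt = to_wkt("polygon", cbind(c(-1, 1, 1, -1), c(-1, -1, 1, 1))),
                   label = "Southeastern Plains", stringsAsFactors = FALSE)
  cov <- attach_covariates(d, "daily", scr$fixes, w, ls)
  # constant weather: all records share identical meteorology
  expect_equal(unique(cov$tmean_c), 18)
  expect_equal(unique(cov$rh_pct), 60)
  # sex-age concatenation
  expect_equal(unique(cov$sexage), "adult-M")
  expect_equal(unique(cov$ecoregion), "Southeastern Plains")
  # unknown age collapses the class
  f2 <- f; f2$age_class <- "unknown"
  scr2 <- screen_fixes(f2)
  cov2 <- attach_covariates(daily_metrics(scr2$fixes), "daily", scr2$fixes, w, ls)
  expect_equal(unique(cov2$sexage), "unknown")
  # category manifest covers the five groups
  cats <- attr(cov, "categories")
  expect_setequal(names(cats),
                  c("individual", "meteorological", "temporal", "geographic",
                    "landscape"))
  expect_true(all(unlist(cats) %in% names(cov)))
})

test_that("monthly covariates average the contributing days", {
  days <- as.character(as.Date("2010-03-01") + 0:19)
  f <- do.call(rbind, lapply(days, function(d) {
    make_fixes(as.POSIXct(paste(d, c("19:00:00", "21:00:00")), tz = "UTC"),
               lon = c(0, 0.001), lat = c(0, 0.001))
  }))
  scr <- screen_fixes(f)
  w <- hourly_weather(as.character(as.Date("2009-02-01") + 0:450))
  set.seed(2); w$temp_c <- rnorm(nrow(w), 15, 6)
  m <- aggregate_metrics(daily_metrics(scr$fixes), "monthly",
                         scr$month_eligibility)
  cov <- attach_covariates(m, "monthly", scr$fixes, w, landscape = NULL)
  dw <- daily_weather_aggregate(w)
  expected <- mean(dw$tmean_c[dw$day %in% unique(scr$fixes$day)])
  expect_equal(cov$tmean_c, expected, tolerance = 1e-12)
  # 12 monthly lags present at the monthly scale only
  expect_true(all(sprintf("tmean_lag%d", 1:12) %in% names(cov)))
  expect_false(any(is.na(cov$tmean_lag12)))
})
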