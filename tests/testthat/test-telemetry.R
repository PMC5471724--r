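write_telemetry <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

test_that("read_fixes parses, reports bad rows and drops exact duplicates", {
  f <- make_fixes(c("2010-03-05 19:30:00", "2010-03-05 20:30:00",
                    "2010-03-05 21:30:00"), lon = c(-82, -82.01, -82.02),
                  lat = c(29, 29.01, 29.02))
  p <- withr::local_tempfile(fileext = ".csv")
  f$timestamp <- format(f$timestamp, "%Y-%m-%dT%H:%M:%S")
  write_telemetry(f, p)
  fx <- read_fixes(p)
  expect_equal(nrow(fx), 3)
  expect_s3_class(fx$timestamp, "POSIXct")

  # invalid latitude is rejected and reported, not silently dropped
  f2 <- f; f2$lat[2] <- 95
  write_telemetry(f2, p)
  fx <- read_fixes(p)
  expect_equal(nrow(fx), 2)
  expect_equal(attr(fx, "parse_report")$n_bad_coord, 1)

  # duplicated row counted once
  f3 <- rbind(f, f[1, ])
  write_telemetry(f3, p)
  fx <- read_fixes(p)
  expect_equal(nrow(fx), 3)
  expect_equal(attr(fx, "parse_report")$n_duplicates, 1)

  # missing column named in the error
  f4 <- f; f4$dop <- NULL
  write_telemetry(f4, p)
  expect_error(read_fixes(p), "dop")
})

test_that("biological day follows the 18:00-08:00 nocturnal rule", {
  ts <- as.POSIXct(c("2010-03-05 19:30:00", "2010-03-06 07:59:00",
                     "2010-03-06 12:00:00", "2010-03-06 18:00:00",
                     "2010-03-06 08:00:00"), tz = "UTC")
  d <- assign_biological_day(ts)
  expect_equal(d[1], as.Date("2010-03-05"))
  expect_equal(d[2], as.Date("2010-03-05")) # before 08:00 -> previous date
  expect_true(is.na(d[3]))                  # diurnal, excluded
  expect_equal(d[4], as.Date("2010-03-06")) # 18:00 sharp starts the night
  expect_true(is.na(d[5]))                  # 08:00 sharp is already diurnal
})

nightly_times <- function(day, hours) {
  # hours >= 18 on `day`, hours < 8 on `day + 1`
  as.POSIXct(paste(ifelse(hours >= 18, day, as.character(as.Date(day) + 1)),
                   sprintf("%02d:00:00", hours)), tz = "UTC")
}

test_that("screening applies the precision and effort rules in order", {
  days <- as.character(as.Date("2010-03-01") + 0:24)
  f <- do.call(rbind, lapply(days, function(d) {
    make_fixes(nightly_times(d, c(19, 22, 2)), lon = runif(3, -82.01, -82),
               lat = runif(3, 29, 29.01))
  }))
  # DOP boundary: exactly 10 is kept, 10.01 is removed
  f$dop <- 1
  f$dop[1] <- 10
  f$dop[2] <- 10.01
  scr <- screen_fixes(f)
  expect_equal(scr$audit$removed_dop, 1)
  expect_true(any(scr$fixes$dop == 10))

  # a day with a single fix is dropped at the sparse-day step
  f1 <- rbind(f, make_fixes(nightly_times("2010-04-10", 20), -82, 29))
  scr <- screen_fixes(f1)
  expect_equal(scr$audit$removed_sparse_day, 1)

  # an animal with 19 retained days is removed by the 20-day rule
  f19 <- do.call(rbind, lapply(days[1:19], function(d) {
    make_fixes(nightly_times(d, c(20, 23)), lon = -81, lat = 30,
               animal_id = "short")
  }))
  scr <- screen_fixes(rbind(f, f19))
  expect_equal(scr$audit$removed_short_animal, 38)
  expect_false("short" %in% scr$fixes$animal_id)

  # months with < 15 retained days flagged ineligible
  expect_equal(nrow(scr$month_eligibility), 1)
  expect_true(all(scr$month_eligibility$eligible)) # 25 days in March
  scr2 <- screen_fixes(f[1:42, ]) # 14 days only -> animal dropped entirely
  expect_equal(nrow(scr2$fixes), 0)
})

test_that("diurnal fixes are excluded before the per-day count", {
  d <- "2010-05-01"
  f <- rbind(
    make_fixes(nightly_times(d, c(19, 23)), lon = c(-82, -82), lat = c(29, 29)),
    make_fixes(as.POSIXct(paste(d, "12:00:00"), tz = "UTC"), -82, 29)
  )
  scr <- screen_fixes(f, min_days = 1)
  expect_equal(scr$audit$removed_diurnal, 1)
  expect_equal(nrow(scr$fixes), 2)
})

test_that("screening audit matches a brute-force recount on random input", {
  set.seed(33)
  n <- 600
  f <- make_fixes(
    as.POSIXct("2010-03-01", tz = "UTC") + runif(n, 0, 40 * 86400),
    lon = runif(n, -82.1, -82), lat = runif(n, 29, 29.1),
    dop = rlnorm(n, 1, 0.9),
    animal_id = sample(paste0("a", 1:4), n, replace = TRUE))
  scr <- screen_fixes(f, min_days = 5)

  # independent recount
  ok_dop <- f$dop <= 10
  hod <- as.numeric(format(f$timestamp, "%H")) +
    as.numeric(format(f$timestamp, "%M")) / 60 +
    as.numeric(format(f$timestamp, "%S")) / 3600
  nocturnal <- hod >= 18 | hod < 8
  day <- as.Date(format(f$timestamp, "%Y-%m-%d"))
  day[hod < 8] <- day[hod < 8] - 1
  g <- f[ok_dop & nocturnal, ]
  gday <- day[ok_dop & nocturnal]
  key <- paste(g$animal_id, gday)
  g2 <- g[table(key)[key] >= 2, ]
  g2day <- gday[table(key)[key] >= 2]
  ndays <- tapply(g2day, g2$animal_id, function(d) length(unique(d)))
  g3 <- g2[g2$animal_id %in% names(ndays)[ndays >= 5], ]

  expect_equal(scr$audit$removed_dop, sum(!ok_dop))
  expect_equal(scr$audit$removed_diurnal, sum(!nocturnal & ok_dop))
  expect_equal(scr$audit$n_retained, nrow(g3))
  expect_equal(nrow(scr$fixes), nrow(g3))
})

test_that("screening is idempotent, order-insensitive and threshold-monotone", {
  set.seed(55)
  n <- 800
  f <- make_fixes(
    as.POSIXct("2011-01-01", tz = "UTC") + sort(runif(n, 0, 60 * 86400)),
    lon = runif(n, -90, -89.9), lat = runif(n, 33, 33.1),
    dop = rlnorm(n, 1, 0.9),
    animal_id = sample(paste0("b", 1:3), n, replace = TRUE))
  s1 <- screen_fixes(f, min_days = 3)
  s2 <- screen_fixes(s1$fixes[names(f)], min_days = 3)
  expect_equal(s2$fixes[names(f)], s1$fixes[names(f)])
  expect_equal(s2$audit$removed_dop + s2$audit$removed_diurnal +
                 s2$audit$removed_sparse_day + s2$audit$removed_short_animal, 0)

  shuf <- f[sample(nrow(f)), ]
  s3 <- screen_fixes(shuf, min_days = 3)
  expect_equal(s3$fixes, s1$fixes)

  # tightening any threshold never increases the retained count
  for (args in list(list(max_dop = 8, min_days = 3),
                    list(min_fixes_per_day = 3, min_days = 3),
                    list(min_days = 10))) {
    s_t <- do.call(screen_fixes, c(list(fixes = f), args))
    expect_lte(nrow(s_t$fixes), nrow(s1$fixes))
  }
})
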