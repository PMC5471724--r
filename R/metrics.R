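# Daily movement metrics and their monthly / overall aggregation.
#
# MxD: maximum great-circle distance between any two fixes within one
# biological day (the farthest an animal ranged that night).
# MHD: the mean of distances between fix pairs approximately one hour apart
# within the day (short-term movement intensity). With fixes every half hour
# from 8:00 to 10:30 the pairing rule yields exactly four distances (origins
# 8:00, 8:30, 9:00 and 9:30), the canonical worked example.

#' Maximum daily distance (MxD)
#'
#' Maximum pairwise great-circle distance among a day's fixes, with the time
#' separation of the maximizing pair (used to diagnose whether daily maxima
#' rest on fixes more than 3 h apart).
#'
#' @param lon,lat Coordinates of the day's fixes (>= 2).
#' @param timestamp POSIXct times of the fixes.
#' @return List with \code{mxd} (km), \code{pair_dt_h} (hours between the
#'   argmax pair).
#' @export
daily_mxd <- function(lon, lat, timestamp) {
  n <- length(lon)
  if (n < 2) stop("MxD undefined: fewer than 2 fixes in the day")
  i <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  j <- sequence((n - 1L):1L) + i
  d <- geo_distance(lon[i], lat[i], lon[j], lat[j])
  best <- which.max(d)
  list(mxd = d[best],
       pair_dt_h = abs(as.numeric(difftime(timestamp[j[best]],
                                           timestamp[i[best]], units = "hours"))))
}

#' Approximately-hourly fix pairs
#'
#' For each fix (origin), among subsequent fixes whose time separation falls
#' in \code{window}, selects the one with separation closest to
#' \code{target}; ties go to the earlier fix. A fix may serve as the origin
#' of one pair and the target of another, so overlapping pairs are allowed.
#'
#' @param timestamp POSIXct times, sorted ascending.
#' @param target Target separation in minutes (default 60).
#' @param window Length-2 acceptance window in minutes (default c(50, 70)).
#' @return Two-column integer matrix of (origin, target) fix indices; zero
#'   rows when no pair qualifies.
#' @export
hour_pairs <- function(timestamp, target = 60, window = c(50, 70)) {
  n <- length(timestamp)
  out <- matrix(integer(0), ncol = 2,
                dimnames = list(NULL, c("from", "to")))
  if (n < 2) return(out)
  if (is.unsorted(timestamp)) stop("timestamps must be sorted")
  tmin <- as.numeric(timestamp) / 60
  for (i in seq_len(n - 1L)) {
    dt <- tmin[(i + 1L):n] - tmin[i]
    ok <- which(dt >= window[1] & dt <= window[2])
    if (length(ok) > 0) {
      pick <- ok[which.min(abs(dt[ok] - target))]
      out <- rbind(out, c(i, i + pick))
    }
  }
  out
}

#' Mean hourly distance (MHD)
#'
#' Arithmetic mean of the great-circle distances of the day's
#' approximately-hourly fix pairs (no time normalization). Undefined (NA)
#' when the day has no qualifying pair; such days still contribute to MxD.
#'
#' @inheritParams daily_mxd
#' @param target,window Passed to \code{\link{hour_pairs}}.
#' @return List with \code{mhd} (km or NA) and \code{n_pairs}.
#' @export
daily_mhd <- function(lon, lat, timestamp, target = 60, window = c(50, 70)) {
  pr <- hour_pairs(timestamp, target, window)
  if (nrow(pr) == 0) return(list(mhd = NA_real_, n_pairs = 0L))
  d <- geo_distance(lon[pr[, 1]], lat[pr[, 1]], lon[pr[, 2]], lat[pr[, 2]])
  list(mhd = mean(d), n_pairs = nrow(pr))
}

#' Per-day movement records
#'
#' Computes MxD, MHD, fix counts (the daily weights) and fix centroids for
#' every animal-day of a screened fix table.
#'
#' @param fixes Screened fixes with a \code{day} column (from
#'   \code{\link{screen_fixes}}).
#' @param target,window MHD pairing parameters, see \code{\link{hour_pairs}}.
#' @return Data frame: animal_id, study_id, day, month, mxd_km, mxd_pair_dt_h,
#'   mhd_km, n_hour_pairs, n_fixes, centroid_lon, centroid_lat.
#' @export
daily_metrics <- function(fixes, target = 60, window = c(50, 70)) {
  if (nrow(fixes) == 0) {
    return(data.frame(animal_id = character(), study_id = character(),
                      day = as.Date(character()), month = character(),
                      mxd_km = numeric(), mxd_pair_dt_h = numeric(),
                      mhd_km = numeric(), n_hour_pairs = integer(),
                      n_fixes = integer(), centroid_lon = numeric(),
                      centroid_lat = numeric()))
  }
  fixes <- fixes[order(fixes$animal_id, fixes$timestamp), , drop = FALSE]
  key <- paste(fixes$animal_id, fixes$day)
  groups <- split(seq_len(nrow(fixes)), key)
  rows <- lapply(groups, function(idx) {
    g <- fixes[idx, ]
    mx <- daily_mxd(g$lon, g$lat, g$timestamp)
    mh <- daily_mhd(g$lon, g$lat, g$timestamp, target, window)
    data.frame(animal_id = g$animal_id[1], study_id = g$study_id[1],
               day = g$day[1], month = format(g$day[1], "%Y-%m"),
               mxd_km = mx$mxd, mxd_pair_dt_h = mx$pair_dt_h,
               mhd_km = mh$mhd, n_hour_pairs = mh$n_pairs,
               n_fixes = nrow(g),
               centroid_lon = mean(g$lon), centroid_lat = mean(g$lat),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$animal_id, out$day), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Aggregate daily records to the monthly or overall scale
#'
#' Unweighted mean of daily values per animal(-month); the record weight is
#' the mean number of fixes per day, and the centroid is the mean of the
#' daily centroids weighted by daily fix counts (i.e. the mean over
#' contributing fixes). MHD aggregates only over MHD-defined days. At the
#' monthly scale only months flagged eligible (>= 15 retained days) appear;
#' the overall mean is taken over all daily values combined, not over
#' monthly means.
#'
#' @param daily From \code{\link{daily_metrics}}.
#' @param scale \code{"monthly"} or \code{"overall"}.
#' @param month_eligibility From \code{\link{screen_fixes}}; required for the
#'   monthly scale.
#' @return Data frame with animal_id (and month), mxd_km, mhd_km, weight,
#'   n_days, centroid_lon, centroid_lat.
#' @export
aggregate_metrics <- function(daily, scale = c("monthly", "overall"),
                              month_eligibility = NULL) {
  scale <- match.arg(scale)
  if (scale == "monthly") {
    if (is.null(month_eligibility)) stop("month_eligibility required at the monthly scale")
    elig <- month_eligibility[month_eligibility$eligible, , drop = FALSE]
    key <- paste(daily$animal_id, daily$month)
    daily <- daily[key %in% paste(elig$animal_id, elig$month), , drop = FALSE]
    keys <- c("animal_id", "month")
  } else {
    keys <- "animal_id"
  }
  if (nrow(daily) == 0) {
    out <- data.frame(animal_id = character(), mxd_km = numeric(),
                      mhd_km = numeric(), weight = numeric(),
                      n_days = integer(), centroid_lon = numeric(),
                      centroid_lat = numeric())
    if (scale == "monthly") out$month <- character()
    return(out)
  }
  groups <- split(seq_len(nrow(daily)), daily[keys], drop = TRUE)
  rows <- lapply(groups, function(idx) {
    g <- daily[idx, ]
    data.frame(animal_id = g$animal_id[1],
               month = if (scale == "monthly") g$month[1] else NA_character_,
               mxd_km = mean(g$mxd_km),
               mhd_km = if (any(!is.na(g$mhd_km))) mean(g$mhd_km, na.rm = TRUE) else NA_real_,
               weight = mean(g$n_fixes),
               n_days = nrow(g),
               centroid_lon = sum(g$centroid_lon * g$n_fixes) / sum(g$n_fixes),
               centroid_lat = sum(g$centroid_lat * g$n_fixes) / sum(g$n_fixes),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (scale == "overall") out$month <- NULL
  out <- out[order(out$animal_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
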