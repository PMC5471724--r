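# Telemetry ingest and screening. The analysis "day" is the nocturnal window
# from 18:00 to 08:00 the following morning: fixes at or after 18:00 belong
# to that calendar date, fixes before 08:00 belong to the previous date, and
# fixes in [08:00, 18:00) are diurnal and excluded from all analyses.
# Timestamps are treated as local study clock time with no DST arithmetic.

TELEMETRY_COLUMNS <- c("study_id", "animal_id", "sex", "age_class", "managed",
                       "timestamp", "lon", "lat", "dop")

#' Read a telemetry CSV
#'
#' Parses the standard telemetry schema (study_id, animal_id, sex, age_class,
#' managed, timestamp ISO-8601, lon, lat, dop). Rows with unparseable
#' coordinates or timestamps, or coordinates outside valid ranges, are
#' counted and reported in the attached parse report rather than silently
#' dropped; exact duplicate rows are removed (and counted).
#'
#' @param path Path to the CSV file.
#' @return A data frame of fixes sorted by animal and timestamp, with
#'   attribute \code{"parse_report"}: a list with \code{n_raw},
#'   \code{n_duplicates}, \code{n_bad_coord}, \code{n_bad_time},
#'   \code{n_fixes}.
#' @export
read_fixes <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  missing_cols <- setdiff(TELEMETRY_COLUMNS, names(raw))
  if (length(missing_cols) > 0) {
    stop("telemetry file is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  n_raw <- nrow(raw)
  dup <- duplicated(raw)
  n_dup <- sum(dup)
  raw <- raw[!dup, , drop = FALSE]
  suppressWarnings({
    lon <- as.numeric(raw$lon)
    lat <- as.numeric(raw$lat)
    dop <- as.numeric(raw$dop)
    ts <- as.POSIXct(raw$timestamp, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
    ts2 <- as.POSIXct(raw$timestamp, format = "%Y-%m-%d %H:%M:%S", tz = "UTC")
  })
  ts[is.na(ts)] <- ts2[is.na(ts)]
  bad_coord <- is.na(lon) | is.na(lat) | lat < -90 | lat > 90 |
    lon < -180 | lon > 180 | is.na(dop) | dop < 0
  bad_time <- is.na(ts)
  keep <- !bad_coord & !bad_time
  fixes <- data.frame(
    study_id = raw$study_id[keep],
    animal_id = raw$animal_id[keep],
    sex = raw$sex[keep],
    age_class = raw$age_class[keep],
    managed = as.integer(raw$managed[keep]),
    timestamp = ts[keep],
    lon = lon[keep], lat = lat[keep], dop = dop[keep],
    stringsAsFactors = FALSE
  )
  fixes <- fixes[order(fixes$animal_id, fixes$timestamp), , drop = FALSE]
  rownames(fixes) <- NULL
  attr(fixes, "parse_report") <- list(
    n_raw = n_raw, n_duplicates = n_dup,
    n_bad_coord = sum(bad_coord & !bad_time), n_bad_time = sum(bad_time),
    n_fixes = nrow(fixes))
  fixes
}

#' Assign the biological (nocturnal) day
#'
#' Fixes at local clock time >= 18:00 get that calendar date; fixes before
#' 08:00 get the previous calendar date; fixes in [08:00, 18:00) are labelled
#' diurnal (NA day) and are excluded from all analyses downstream.
#'
#' @param timestamp POSIXct vector (local study time).
#' @return A Date vector; NA marks diurnal fixes.
#' @examples
#' assign_biological_day(as.POSIXct("2010-03-05 19:30:00", tz = "UTC"))
#' @export
assign_biological_day <- function(timestamp) {
  hod <- as.numeric(format(timestamp, "%H")) +
    as.numeric(format(timestamp, "%M")) / 60 +
    as.numeric(format(timestamp, "%S")) / 3600
  date <- as.Date(format(timestamp, "%Y-%m-%d"))
  day <- rep(as.Date(NA), length(timestamp))
  day[hod >= 18] <- date[hod >= 18]
  day[hod < 8] <- date[hod < 8] - 1L
  day
}

#' Screen telemetry with the standard effort and precision rules
#'
#' Applies, in order: (1) drop fixes with DOP > 10 (DOP exactly 10 is kept);
#' (2) drop diurnal fixes (outside the 18:00-08:00 nocturnal window);
#' (3) drop biological days with fewer than \code{min_fixes_per_day} fixes;
#' (4) drop animals with fewer than \code{min_days} retained biological days;
#' (5) flag animal-months with fewer than \code{min_days_month} retained days
#' as ineligible for monthly aggregation. An audit report records the count
#' removed at each step.
#'
#' @param fixes Data frame from \code{\link{read_fixes}} (or the simulator).
#' @param max_dop DOP threshold; fixes strictly above it are dropped.
#' @param min_fixes_per_day Minimum fixes per biological day.
#' @param min_days Minimum retained biological days per animal.
#' @param min_days_month Minimum retained days for a month to be eligible.
#' @param count_span Count the 20-day rule on the calendar span (first to
#'   last retained day) instead of the number of retained days.
#' @return List with \code{fixes} (screened, with \code{day} and \code{month}
#'   columns), \code{month_eligibility} (animal_id, month, n_days, eligible)
#'   and \code{audit} (removal counts per rule).
#' @export
screen_fixes <- function(fixes, max_dop = 10, min_fixes_per_day = 2,
                         min_days = 20, min_days_month = 15,
                         count_span = FALSE) {
  audit <- list(n_input = nrow(fixes), removed_dop = 0L, removed_diurnal = 0L,
                removed_sparse_day = 0L, removed_short_animal = 0L,
                n_retained = 0L, n_animals = 0L, months_ineligible = 0L)
  empty <- function() {
    list(fixes = fixes[0, , drop = FALSE],
         month_eligibility = data.frame(animal_id = character(),
                                        month = character(),
                                        n_days = integer(),
                                        eligible = logical()),
         audit = audit)
  }
  if (nrow(fixes) == 0) return(empty())
  fixes <- fixes[order(fixes$animal_id, fixes$timestamp), , drop = FALSE]

  keep <- fixes$dop <= max_dop
  audit$removed_dop <- sum(!keep)
  fixes <- fixes[keep, , drop = FALSE]

  day <- assign_biological_day(fixes$timestamp)
  audit$removed_diurnal <- sum(is.na(day))
  fixes <- fixes[!is.na(day), , drop = FALSE]
  fixes$day <- day[!is.na(day)]
  if (nrow(fixes) == 0) return(empty())

  ad <- paste(fixes$animal_id, fixes$day)
  nfix <- table(ad)
  keep <- nfix[ad] >= min_fixes_per_day
  audit$removed_sparse_day <- sum(!keep)
  fixes <- fixes[keep, , drop = FALSE]
  if (nrow(fixes) == 0) return(empty())

  days_by_animal <- tapply(fixes$day, fixes$animal_id, function(d) {
    if (count_span) as.integer(max(d) - min(d)) + 1L else length(unique(d))
  })
  ok_animals <- names(days_by_animal)[days_by_animal >= min_days]
  keep <- fixes$animal_id %in% ok_animals
  audit$removed_short_animal <- sum(!keep)
  fixes <- fixes[keep, , drop = FALSE]

  fixes$month <- format(fixes$day, "%Y-%m")
  if (nrow(fixes) > 0) {
    am <- unique(fixes[, c("animal_id", "month", "day")])
    tab <- stats::aggregate(day ~ animal_id + month, data = am, FUN = length)
    names(tab)[3] <- "n_days"
    tab$eligible <- tab$n_days >= min_days_month
    tab <- tab[order(tab$animal_id, tab$month), , drop = FALSE]
    rownames(tab) <- NULL
  } else {
    tab <- data.frame(animal_id = character(), month = character(),
                      n_days = integer(), eligible = logical())
  }
  audit$n_retained <- nrow(fixes)
  audit$n_animals <- length(unique(fixes$animal_id))
  audit$months_ineligible <- sum(!tab$eligible)
  rownames(fixes) <- NULL
  list(fixes = fixes, month_eligibility = tab, audit = audit)
}
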