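# Covariate construction: the five predictor categories (individual,
# meteorological, temporal, geographic, landscape) attached to each modeling
# record at its home-range centroid and time window. Meteorology is
# aggregated over the same 18:00-08:00 nocturnal window as the responses.

MMHG_PER_PA <- 1 / 133.322

#' Saturation vapor pressure (Tetens)
#'
#' @param temp_c Air temperature in degrees C.
#' @return Saturation vapor pressure in Pa:
#'   610.78 * exp(17.27 * T / (T + 237.3)).
#' @export
svp_tetens <- function(temp_c) 610.78 * exp(17.27 * temp_c / (temp_c + 237.3))

#' Growing degree days
#'
#' Daily degree-days over a base temperature: max(0, (tmax + tmin)/2 - base).
#'
#' @param tmax,tmin Daily maximum and minimum temperature (degrees C).
#' @param base Base temperature (default 10 degrees C).
#' @return Degree-days (>= 0).
#' @export
gdd <- function(tmax, tmin, base = 10) {
  if (any(tmax < tmin, na.rm = TRUE)) stop("tmax < tmin")
  pmax(0, (tmax + tmin) / 2 - base)
}

#' Aggregate hourly weather to biological days
#'
#' For every study and biological day (the 18:00-08:00 nocturnal window,
#' matching the response window) computes max/min/mean temperature, mean RH,
#' mean saturation vapor pressure deficit (mm Hg, Tetens), total
#' precipitation, mean surface pressure, mean wind speed and growing degree
#' days. Windows missing more than 20 percent of their hours yield NA rather
#' than imputed values.
#'
#' @param weather Hourly weather data frame (study_id, timestamp, temp_c,
#'   pressure_pa, precip_mm, wind_ms, rh_pct).
#' @param max_gap_frac Maximum tolerated fraction of missing window hours.
#' @return Data frame keyed by study_id + day with columns tmax_c, tmin_c,
#'   tmean_c, rh_pct, svpd_mmhg, precip_mm, pressure_pa, wind_ms, gdd.
#' @export
daily_weather_aggregate <- function(weather, max_gap_frac = 0.2) {
  day <- assign_biological_day(weather$timestamp)
  keep <- !is.na(day)
  w <- weather[keep, , drop = FALSE]
  day <- day[keep]
  svpd <- svp_tetens(w$temp_c) * (1 - w$rh_pct / 100) * MMHG_PER_PA
  key <- paste(w$study_id, day)
  groups <- split(seq_len(nrow(w)), key)
  full_window_h <- 14 # 18:00 through 07:00 next morning
  rows <- lapply(groups, function(idx) {
    g <- w[idx, ]
    n <- nrow(g)
    if (n < (1 - max_gap_frac) * full_window_h) {
      vals <- rep(NA_real_, 9)
    } else {
      tmax <- max(g$temp_c); tmin <- min(g$temp_c)
      vals <- c(tmax, tmin, mean(g$temp_c), mean(g$rh_pct), mean(svpd[idx]),
                sum(g$precip_mm), mean(g$pressure_pa), mean(g$wind_ms),
                gdd(tmax, tmin))
    }
    data.frame(study_id = g$study_id[1], day = day[idx[1]],
               tmax_c = vals[1], tmin_c = vals[2], tmean_c = vals[3],
               rh_pct = vals[4], svpd_mmhg = vals[5], precip_mm = vals[6],
               pressure_pa = vals[7], wind_ms = vals[8], gdd = vals[9],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$study_id, out$day), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Monthly weather series with lags
#'
#' Collapses biological-day weather to calendar months per study (means;
#' precipitation and GDD totals) and appends lag-k columns of monthly mean
#' temperature and total precipitation for k = 1..max_lag. Lag-k of a month
#' is the value k months earlier; months without enough history get NA.
#'
#' @param daily_wx From \code{\link{daily_weather_aggregate}}.
#' @param max_lag Maximum monthly lag (default 12).
#' @return Data frame keyed by study_id + month (\"YYYY-MM\") with monthly
#'   aggregates and \code{tmean_lag1..}, \code{precip_lag1..} columns.
#' @export
monthly_weather <- function(daily_wx, max_lag = 12) {
  m <- format(daily_wx$day, "%Y-%m")
  groups <- split(seq_len(nrow(daily_wx)), paste(daily_wx$study_id, m))
  rows <- lapply(groups, function(idx) {
    g <- daily_wx[idx, ]
    data.frame(study_id = g$study_id[1], month = format(g$day[1], "%Y-%m"),
               tmax_c = mean(g$tmax_c), tmin_c = mean(g$tmin_c),
               tmean_c = mean(g$tmean_c), rh_pct = mean(g$rh_pct),
               svpd_mmhg = mean(g$svpd_mmhg), precip_mm = sum(g$precip_mm),
               pressure_pa = mean(g$pressure_pa), wind_ms = mean(g$wind_ms),
               gdd = sum(g$gdd), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$study_id, out$month), , drop = FALSE]
  rownames(out) <- NULL
  month_index <- function(mm) {
    y <- as.integer(substr(mm, 1, 4)); mo <- as.integer(substr(mm, 6, 7))
    y * 12L + mo
  }
  for (st in unique(out$study_id)) {
    sel <- which(out$study_id == st)
    idx <- month_index(out$month[sel])
    for (k in seq_len(max_lag)) {
      pos <- match(idx - k, idx)
      out[sel, sprintf("tmean_lag%d", k)] <- out$tmean_c[sel][pos]
      out[sel, sprintf("precip_lag%d", k)] <- out$precip_mm[sel][pos]
    }
  }
  rownames(out) <- NULL
  out
}

#' Distance from a centroid to the nearest feature of a class
#'
#' Minimum distance (km) from the point to any feature of the class in the
#' local azimuthal equal-area plane centred on the point; 0 inside a
#' polygon. An empty feature class yields NA with a warning.
#'
#' @param lon,lat Centroid coordinates (degrees).
#' @param landscape Landscape data frame (feature_class, class_detail, wkt).
#' @param feature_class Class name (e.g. \"water\", \"road\").
#' @param class_detail Optional detail filter (e.g. road class \"major\").
#' @return Distance in km, or NA.
#' @export
distance_to_feature <- function(lon, lat, landscape, feature_class,
                                class_detail = NULL) {
  sel <- landscape$feature_class == feature_class
  if (!is.null(class_detail)) sel <- sel & landscape$class_detail %in% class_detail
  feats <- landscape[sel, , drop = FALSE]
  if (nrow(feats) == 0) {
    warning("no features of class '", feature_class,
            if (!is.null(class_detail)) paste0("/", class_detail) else "",
            "': distance undefined")
    return(NA_real_)
  }
  p <- c(0, 0)
  dmin <- Inf
  for (i in seq_len(nrow(feats))) {
    geom <- parse_wkt(feats$wkt[i])
    verts <- project_laea(geom$coords[, 1], geom$coords[, 2], lon, lat)
    dmin <- min(dmin, point_feature_distance(p, verts, geom$type))
  }
  dmin
}

#' Ecoregion label at a centroid
#'
#' Ray-casting point-in-polygon lookup over the landscape's ecoregion
#' polygons; boundary points go to the first polygon in file order. Returns
#' NA with a warning when the point is outside all polygons.
#'
#' @param lon,lat Centroid coordinates.
#' @param landscape Landscape data frame with feature_class \"ecoregion\".
#' @return The containing polygon's label, or NA.
#' @export
ecoregion_lookup <- function(lon, lat, landscape) {
  polys <- landscape[landscape$feature_class == "ecoregion", , drop = FALSE]
  for (i in seq_len(nrow(polys))) {
    geom <- parse_wkt(polys$wkt[i])
    if (point_in_polygon(c(lon, lat), geom$coords)) return(polys$label[i])
  }
  warning("centroid (", lon, ", ", lat, ") outside all ecoregion polygons")
  NA_character_
}

# per-animal attribute table from screened fixes; sex-age concatenation
# collapses to "unknown" when either component is unknown (six known levels
# plus "unknown")
animal_attributes <- function(fixes) {
  a <- unique(fixes[, c("animal_id", "study_id", "sex", "age_class", "managed")])
  a$sexage <- ifelse(a$sex %in% c("M", "F") &
                       a$age_class %in% c("juvenile", "subadult", "adult"),
                     paste0(a$age_class, "-", a$sex), "unknown")
  rownames(a) <- NULL
  a
}

LANDSCAPE_DISTANCE_COLS <- c(dist_water_km = "water", dist_stream_km = "stream",
                             dist_agriculture_km = "agriculture",
                             dist_forest_km = "forest")
ROAD_CLASSES <- c(dist_road_major_km = "major", dist_road_medium_km = "medium",
                  dist_road_minor_km = "minor")

#' Attach the five covariate categories to modeling records
#'
#' Joins per-record predictors at the record's centroid and time window:
#' individual attributes (sex-age class, management flag), meteorology
#' aggregated over the record's biological days, temporal terms (month,
#' year, and at the monthly scale lagged monthly temperature/precipitation),
#' the ecoregion label, and distances to landscape features. The returned
#' table carries a \code{"categories"} attribute mapping predictor columns to
#' their category.
#'
#' @param records Daily records (\code{\link{daily_metrics}}) or aggregated
#'   records (\code{\link{aggregate_metrics}}).
#' @param scale \code{"daily"}, \code{"monthly"} or \code{"overall"}.
#' @param fixes Screened fixes (for animal attributes).
#' @param weather Hourly weather data frame.
#' @param landscape Landscape data frame; NULL skips geographic/landscape
#'   columns.
#' @param max_lag Monthly lag depth.
#' @return The records data frame extended with covariate columns.
#' @export
attach_covariates <- function(records, scale = c("daily", "monthly", "overall"),
                              fixes, weather, landscape = NULL, max_lag = 12) {
  scale <- match.arg(scale)
  out <- records
  attrs <- animal_attributes(fixes)
  ai <- match(out$animal_id, attrs$animal_id)
  out$study_id <- attrs$study_id[ai]
  out$sexage <- attrs$sexage[ai]
  out$managed <- attrs$managed[ai]

  dwx <- daily_weather_aggregate(weather)
  met_cols <- c("tmax_c", "tmin_c", "tmean_c", "rh_pct", "svpd_mmhg",
                "precip_mm", "pressure_pa", "wind_ms", "gdd")
  if (scale == "daily") {
    wi <- match(paste(out$study_id, out$day), paste(dwx$study_id, dwx$day))
    out[met_cols] <- dwx[wi, met_cols]
    out$month_num <- as.integer(format(out$day, "%m"))
    out$year <- as.integer(format(out$day, "%Y"))
  } else {
    # meteorology averaged over the record's monitored biological days
    day_tab <- daily_metrics_days(fixes)
    per_rec <- function(r) {
      days <- day_tab$day[day_tab$animal_id == out$animal_id[r] &
                            (scale == "overall" |
                               format(day_tab$day, "%Y-%m") == out$month[r])]
      wi <- match(paste(out$study_id[r], days), paste(dwx$study_id, dwx$day))
      wsub <- dwx[wi[!is.na(wi)], , drop = FALSE]
      if (nrow(wsub) == 0) return(rep(NA_real_, length(met_cols)))
      v <- colMeans(wsub[met_cols], na.rm = TRUE)
      v["precip_mm"] <- sum(wsub$precip_mm, na.rm = TRUE)
      v["gdd"] <- sum(wsub$gdd, na.rm = TRUE)
      v
    }
    met <- t(vapply(seq_len(nrow(out)), per_rec, numeric(length(met_cols))))
    colnames(met) <- met_cols
    out[met_cols] <- as.data.frame(met)
    if (scale == "monthly") {
      out$month_num <- as.integer(substr(out$month, 6, 7))
      out$year <- as.integer(substr(out$month, 1, 4))
      mwx <- monthly_weather(dwx, max_lag)
      mi <- match(paste(out$study_id, out$month), paste(mwx$study_id, mwx$month))
      lag_cols <- c(sprintf("tmean_lag%d", seq_len(max_lag)),
                    sprintf("precip_lag%d", seq_len(max_lag)))
      out[lag_cols] <- mwx[mi, lag_cols]
    } else {
      # overall records span months; use the midpoint year for the temporal term
      yr <- vapply(seq_len(nrow(out)), function(r) {
        days <- day_tab$day[day_tab$animal_id == out$animal_id[r]]
        as.integer(format(stats::median(days), "%Y"))
      }, integer(1))
      out$year <- yr
    }
  }

  if (!is.null(landscape)) {
    dist_cols <- c(names(LANDSCAPE_DISTANCE_COLS), names(ROAD_CLASSES))
    # parse each study's geometries once; distances themselves stay
    # per-record in the projection centred on that record's centroid
    geoms_by_study <- lapply(split(landscape, landscape$study_id), function(ls) {
      lapply(seq_len(nrow(ls)), function(i) {
        g <- parse_wkt(ls$wkt[i])
        g$col <- if (ls$feature_class[i] == "road") {
          names(ROAD_CLASSES)[match(ls$class_detail[i], ROAD_CLASSES)]
        } else {
          names(LANDSCAPE_DISTANCE_COLS)[match(ls$feature_class[i],
                                               LANDSCAPE_DISTANCE_COLS)]
        }
        g$eco_label <- if (ls$feature_class[i] == "ecoregion") ls$label[i] else NA
        g
      })
    })
    eco <- character(nrow(out))
    dist_mat <- matrix(NA_real_, nrow(out), length(dist_cols),
                       dimnames = list(NULL, dist_cols))
    for (r in seq_len(nrow(out))) {
      geoms <- geoms_by_study[[out$study_id[r]]]
      p_lon <- out$centroid_lon[r]; p_lat <- out$centroid_lat[r]
      eco[r] <- NA_character_
      for (g in geoms) {
        if (!is.na(g$eco_label)) {
          if (is.na(eco[r]) && point_in_polygon(c(p_lon, p_lat), g$coords)) {
            eco[r] <- g$eco_label
          }
          next
        }
        if (is.na(g$col)) next
        verts <- project_laea(g$coords[, 1], g$coords[, 2], p_lon, p_lat)
        d <- point_feature_distance(c(0, 0), verts, g$type)
        if (is.na(dist_mat[r, g$col]) || d < dist_mat[r, g$col]) {
          dist_mat[r, g$col] <- d
        }
      }
    }
    out[dist_cols] <- as.data.frame(dist_mat)
    out$ecoregion <- eco
  }

  categories <- list(
    individual = c("sexage", "managed"),
    meteorological = met_cols,
    temporal = c("month_num", "year",
                 if (scale == "monthly") c(sprintf("tmean_lag%d", seq_len(max_lag)),
                                           sprintf("precip_lag%d", seq_len(max_lag)))),
    geographic = if (!is.null(landscape)) "ecoregion" else character(0),
    landscape = if (!is.null(landscape)) c(names(LANDSCAPE_DISTANCE_COLS),
                                           names(ROAD_CLASSES)) else character(0))
  if (scale == "overall") {
    categories$temporal <- "year"
    out$month_num <- NULL
  }
  attr(out, "categories") <- categories
  out
}

# distinct animal-days present in the screened fixes
daily_metrics_days <- function(fixes) {
  unique(fixes[, c("animal_id", "day")])
}
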