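# Planar and spherical geometry primitives shared by the metrics, home-range
# and covariate stages. All great-circle work uses a sphere of radius
# 6371.0088 km (IUGG mean radius); planar work happens in a local azimuthal
# equal-area projection so that hull areas and feature distances come out in
# km / km^2 with negligible distortion at study scale (tens of km).

EARTH_RADIUS_KM <- 6371.0088

#' Great-circle distance between coordinate pairs
#'
#' Haversine distance on a sphere of radius 6371.0088 km. Inputs are recycled
#' and may be vectors, so all pairwise day-level distances can be computed in
#' one call.
#'
#' @param lon1,lat1,lon2,lat2 Coordinates in decimal degrees (WGS84).
#' @return Distance(s) in km.
#' @examples
#' geo_distance(0, 0, 1, 0) # one degree of longitude on the equator
#' @export
geo_distance <- function(lon1, lat1, lon2, lat2) {
  rad <- pi / 180
  dlat <- (lat2 - lat1) * rad
  dlon <- (lon2 - lon1) * rad
  a <- sin(dlat / 2)^2 + cos(lat1 * rad) * cos(lat2 * rad) * sin(dlon / 2)^2
  a <- pmin(1, pmax(0, a))
  2 * EARTH_RADIUS_KM * asin(sqrt(a))
}

# Lambert azimuthal equal-area projection centered at (lon0, lat0).
# Returns a matrix with columns x, y in km. Equal-area so shoelace areas of
# projected polygons are true areas.
project_laea <- function(lon, lat, lon0, lat0) {
  rad <- pi / 180
  lam <- lon * rad; phi <- lat * rad
  lam0 <- lon0 * rad; phi0 <- lat0 * rad
  denom <- 1 + sin(phi0) * sin(phi) + cos(phi0) * cos(phi) * cos(lam - lam0)
  # antipodal points (denom ~ 0) never occur at study scale; guard anyway
  denom[denom < 1e-12] <- 1e-12
  k <- sqrt(2 / denom)
  x <- EARTH_RADIUS_KM * k * cos(phi) * sin(lam - lam0)
  y <- EARTH_RADIUS_KM * k * (cos(phi0) * sin(phi) - sin(phi0) * cos(phi) * cos(lam - lam0))
  cbind(x = x, y = y)
}

# Convex hull of a 2-column point matrix by Andrew's monotone chain.
# Returns indices of hull vertices in counter-clockwise order (no repeat of
# the first vertex). Collinear points on the hull boundary are dropped.
convex_hull_indices <- function(xy) {
  n <- nrow(xy)
  if (n == 1L) return(1L)
  ord <- order(xy[, 1], xy[, 2])
  cross <- function(o, a, b) {
    (xy[a, 1] - xy[o, 1]) * (xy[b, 2] - xy[o, 2]) -
      (xy[a, 2] - xy[o, 2]) * (xy[b, 1] - xy[o, 1])
  }
  build <- function(idx) {
    h <- integer(0)
    for (i in idx) {
      while (length(h) >= 2 &&
             cross(h[length(h) - 1], h[length(h)], i) <= 0) {
        h <- h[-length(h)]
      }
      h <- c(h, i)
    }
    h
  }
  lower <- build(ord)
  upper <- build(rev(ord))
  hull <- c(lower[-length(lower)], upper[-length(upper)])
  if (length(hull) == 0L) hull <- ord[1L]  # all points identical/collinear
  unique(hull)
}

# Signed shoelace area of a polygon given as a 2-column vertex matrix
# (not closed). Positive for counter-clockwise orientation.
shoelace_area <- function(xy) {
  n <- nrow(xy)
  if (is.null(n) || n < 3L) return(0)
  x <- xy[, 1]; y <- xy[, 2]
  j <- c(n, seq_len(n - 1L))
  sum(x[j] * y - x * y[j]) / 2
}

# Minimum distance from point p (length-2) to segment a--b in the plane.
point_segment_distance <- function(p, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 == 0) return(sqrt(sum((p - a)^2)))
  t <- sum((p - a) * ab) / len2
  t <- min(1, max(0, t))
  proj <- a + t * ab
  sqrt(sum((p - proj)^2))
}

# Minimum distance from point p to a polyline given as an n x 2 matrix.
point_polyline_distance <- function(p, verts) {
  n <- nrow(verts)
  if (n == 1L) return(sqrt(sum((p - verts[1, ])^2)))
  d <- Inf
  for (i in seq_len(n - 1L)) {
    d <- min(d, point_segment_distance(p, verts[i, ], verts[i + 1L, ]))
  }
  d
}

# Even-odd ray-casting point-in-polygon test. `verts` is an n x 2 matrix of
# polygon vertices (closed or unclosed both accepted). Points exactly on an
# edge count as inside.
point_in_polygon <- function(p, verts) {
  n <- nrow(verts)
  if (all(verts[1, ] == verts[n, ])) { verts <- verts[-n, , drop = FALSE]; n <- n - 1L }
  if (n < 3L) return(FALSE)
  x <- p[1]; y <- p[2]
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- verts[i, 1]; yi <- verts[i, 2]
    xj <- verts[j, 1]; yj <- verts[j, 2]
    # boundary check
    if (point_segment_distance(p, c(xi, yi), c(xj, yj)) < 1e-12) return(TRUE)
    if ((yi > y) != (yj > y)) {
      xcross <- xi + (y - yi) / (yj - yi) * (xj - xi)
      if (x < xcross) inside <- !inside
    }
    j <- i
  }
  inside
}

# Minimum distance (km, in the local plane) from a projected point to a
# projected feature geometry; 0 if inside a polygon.
point_feature_distance <- function(p, verts, type) {
  type <- tolower(type)
  if (type == "point") {
    min(sqrt((verts[, 1] - p[1])^2 + (verts[, 2] - p[2])^2))
  } else if (type == "linestring") {
    point_polyline_distance(p, verts)
  } else if (type == "polygon") {
    if (point_in_polygon(p, verts)) 0 else {
      ring <- rbind(verts, verts[1, ])
      point_polyline_distance(p, ring)
    }
  } else {
    stop("unknown geometry type: ", type)
  }
}

## ---- minimal WKT support (POINT / LINESTRING / POLYGON, single ring) ----

#' Parse a WKT geometry string
#'
#' Supports the three geometry types used by the landscape interchange format:
#' \code{POINT}, \code{LINESTRING} and single-ring \code{POLYGON}.
#'
#' @param wkt A WKT string.
#' @return A list with elements \code{type} (lower-case) and \code{coords}
#'   (matrix with columns lon, lat).
#' @export
parse_wkt <- function(wkt) {
  wkt <- trimws(wkt)
  m <- regexec("^([A-Za-z]+)\\s*\\((.*)\\)$", wkt)
  parts <- regmatches(wkt, m)[[1]]
  if (length(parts) != 3L) stop("malformed WKT: ", wkt)
  type <- tolower(parts[2])
  body <- parts[3]
  if (type == "polygon") {
    body <- sub("^\\s*\\(", "", body)
    body <- sub("\\)\\s*$", "", body)
    if (grepl("\\)\\s*,\\s*\\(", body)) stop("multi-ring polygons not supported")
  }
  pairs <- strsplit(body, ",")[[1]]
  coords <- t(vapply(pairs, function(p) {
    nums <- as.numeric(strsplit(trimws(p), "\\s+")[[1]])
    if (length(nums) != 2L || anyNA(nums)) stop("malformed WKT coordinate: ", p)
    nums
  }, numeric(2)))
  dimnames(coords) <- list(NULL, c("lon", "lat"))
  if (type == "polygon" && nrow(coords) > 1L &&
      all(coords[1, ] == coords[nrow(coords), ])) {
    coords <- coords[-nrow(coords), , drop = FALSE]
  }
  if (!type %in% c("point", "linestring", "polygon")) {
    stop("unsupported WKT type: ", type)
  }
  list(type = type, coords = coords)
}

#' Serialize coordinates to WKT
#'
#' @param type One of \code{"point"}, \code{"linestring"}, \code{"polygon"}.
#' @param coords Matrix with columns lon, lat.
#' @return A WKT string (polygon rings are closed on output).
#' @export
to_wkt <- function(type, coords) {
  type <- tolower(type)
  coords <- rbind(coords)
  fmt <- function(m) paste(sprintf("%.8f %.8f", m[, 1], m[, 2]), collapse = ", ")
  switch(type,
    point = sprintf("POINT (%s)", fmt(coords[1, , drop = FALSE])),
    linestring = sprintf("LINESTRING (%s)", fmt(coords)),
    polygon = {
      if (!all(coords[1, ] == coords[nrow(coords), ])) coords <- rbind(coords, coords[1, ])
      sprintf("POLYGON ((%s))", fmt(coords))
    },
    stop("unsupported WKT type: ", type)
  )
}
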