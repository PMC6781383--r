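# Geometry on lon/lat polylines.  All distances are haversine metres on
# consecutive vertices; polylines are matrices with columns lon, lat and
# optionally t (timestamp, s).

EARTH_R <- 6378137

hav_m <- function(lon1, lat1, lon2, lat2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2), r = EARTH_R)
}

# scalar haversine without the geosphere call overhead, for tight loops
hav1 <- function(lon1, lat1, lon2, lat2) {
  p <- pi / 180
  dlat <- (lat2 - lat1) * p / 2
  dlon <- (lon2 - lon1) * p / 2
  a <- sin(dlat)^2 + cos(lat1 * p) * cos(lat2 * p) * sin(dlon)^2
  2 * EARTH_R * asin(min(1, sqrt(a)))
}

#' Length of a lon/lat polyline in metres
#'
#' Sum of haversine distances over consecutive vertices. A polyline with
#' fewer than two vertices has length 0.
#'
#' @param coords matrix with columns `lon`, `lat` (extra columns ignored).
#' @return length in metres.
#' @export
polyline_length <- function(coords) {
  if (is.null(coords) || nrow(coords) < 2) return(0)
  sum(hav_m(coords[-nrow(coords), 1], coords[-nrow(coords), 2],
            coords[-1, 1], coords[-1, 2]))
}

# cumulative chain distance at each vertex
chain_dist <- function(coords) {
  n <- nrow(coords)
  if (n < 2) return(0)
  c(0, cumsum(hav_m(coords[-n, 1], coords[-n, 2],
                    coords[-1, 1], coords[-1, 2])))
}

# Positions along a polyline at chain distances d (clamped to [0, total]).
# Linear interpolation in lon/lat is adequate at urban scales.
interpolate_along <- function(coords, d) {
  if (nrow(coords) == 1) {
    return(cbind(lon = rep(coords[1, 1], length(d)),
                 lat = rep(coords[1, 2], length(d))))
  }
  cd <- chain_dist(coords)
  total <- cd[length(cd)]
  d <- pmin(pmax(d, 0), total)
  if (total == 0) {
    return(cbind(lon = rep(coords[1, 1], length(d)),
                 lat = rep(coords[1, 2], length(d))))
  }
  seg <- findInterval(d, cd, rightmost.closed = TRUE)
  seg[seg >= nrow(coords)] <- nrow(coords) - 1
  w <- (d - cd[seg]) / pmax(cd[seg + 1] - cd[seg], 1e-12)
  cbind(lon = coords[seg, 1] + w * (coords[seg + 1, 1] - coords[seg, 1]),
        lat = coords[seg, 2] + w * (coords[seg + 1, 2] - coords[seg, 2]))
}

# local equirectangular projection (metres) around a reference latitude
local_xy <- function(lon, lat, lon0, lat0) {
  p <- pi / 180
  cbind(x = (lon - lon0) * p * EARTH_R * cos(lat0 * p),
        y = (lat - lat0) * p * EARTH_R)
}

# metre offsets -> lon/lat displacement around a reference point
offset_lonlat <- function(lon0, lat0, dx_m, dy_m) {
  p <- pi / 180
  cbind(lon = lon0 + dx_m / (EARTH_R * cos(lat0 * p) * p),
        lat = lat0 + dy_m / (EARTH_R * p))
}

# minimum distance (m) from each point to a polyline, via local projection
dist_to_polyline <- function(pts_lonlat, line) {
  lat0 <- mean(line[, 2])
  lon0 <- mean(line[, 1])
  P <- local_xy(pts_lonlat[, 1], pts_lonlat[, 2], lon0, lat0)
  L <- local_xy(line[, 1], line[, 2], lon0, lat0)
  if (nrow(L) == 1) {
    return(sqrt((P[, 1] - L[1, 1])^2 + (P[, 2] - L[1, 2])^2))
  }
  ax <- L[-nrow(L), 1]; ay <- L[-nrow(L), 2]
  bx <- L[-1, 1];       by <- L[-1, 2]
  vx <- bx - ax; vy <- by - ay
  vv <- vx^2 + vy^2
  out <- numeric(nrow(P))
  for (i in seq_len(nrow(P))) {
    wx <- P[i, 1] - ax; wy <- P[i, 2] - ay
    tt <- pmin(pmax(ifelse(vv > 0, (wx * vx + wy * vy) / vv, 0), 0), 1)
    dx <- wx - tt * vx; dy <- wy - tt * vy
    out[i] <- sqrt(min(dx^2 + dy^2))
  }
  out
}
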