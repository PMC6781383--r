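# Rectangular street grid: nodes indexed (i, j), spacing in metres, centred
# on the region reference point.  Stands in for the street network when
# recreating itineraries.

#' Build the street grid for a region
#'
#' @param cfg a [tw_config()] object (uses `half_extent_m`,
#'   `grid_spacing_m`, `centre_lon`, `centre_lat`).
#' @return A list of class `street_grid` with fields `nx`, `ny`,
#'   `spacing_m`, node coordinate vectors `lon` (length nx) and `lat`
#'   (length ny), and the region bounding box.
#' @export
street_grid <- function(cfg = tw_config()) {
  n_half <- floor(cfg$half_extent_m / cfg$grid_spacing_m)
  xs <- seq(-n_half, n_half) * cfg$grid_spacing_m
  ll <- offset_lonlat(cfg$centre_lon, cfg$centre_lat, xs, 0)
  lon <- ll[, "lon"]
  ll <- offset_lonlat(cfg$centre_lon, cfg$centre_lat, 0, xs)
  lat <- ll[, "lat"]
  structure(list(
    nx = length(xs), ny = length(xs), spacing_m = cfg$grid_spacing_m,
    x_m = xs, lon = lon, lat = lat,
    bbox = c(lon_min = min(lon), lon_max = max(lon),
             lat_min = min(lat), lat_max = max(lat))
  ), class = "street_grid")
}

grid_node_lonlat <- function(grid, i, j) {
  cbind(lon = grid$lon[i], lat = grid$lat[j])
}

# snap a lon/lat to the nearest grid node -> c(i, j)
grid_snap <- function(grid, lon, lat) {
  i <- which.min(abs(grid$lon - lon))
  j <- which.min(abs(grid$lat - lat))
  c(i = i, j = j)
}

in_bbox <- function(grid, lon, lat) {
  lon >= grid$bbox["lon_min"] & lon <= grid$bbox["lon_max"] &
    lat >= grid$bbox["lat_min"] & lat <= grid$bbox["lat_max"]
}

#' Shortest street-network itinerary between two locations
#'
#' Both endpoints are snapped to the street grid; the returned polyline is a
#' minimal-length grid path. Among the many tied shortest grid paths the
#' lexicographic one is returned (all east-west movement first, then
#' north-south), making the routing deterministic.
#'
#' @param origin,destination length-2 numeric `c(lon, lat)`.
#' @param grid a [street_grid()].
#' @return polyline matrix (columns `lon`, `lat`) through consecutive grid
#'   nodes; a single row when origin and destination snap to the same node.
#' @export
shortest_path_itinerary <- function(origin, destination, grid) {
  if (!in_bbox(grid, origin[1], origin[2]) ||
      !in_bbox(grid, destination[1], destination[2])) {
    stop("routing error: endpoint outside the street grid")
  }
  a <- grid_snap(grid, origin[1], origin[2])
  b <- grid_snap(grid, destination[1], destination[2])
  is <- if (a[1] <= b[1]) seq(a[1], b[1]) else seq(a[1], b[1], by = -1)
  js <- if (a[2] <= b[2]) seq(a[2], b[2]) else seq(a[2], b[2], by = -1)
  # east-west leg at the origin row, then north-south at the target column
  ii <- c(is, rep(b[1], length(js) - 1))
  jj <- c(rep(a[2], length(is)), js[-1])
  cbind(lon = grid$lon[ii], lat = grid$lat[jj])
}
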