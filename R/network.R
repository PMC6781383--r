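# Transit network: straight lines with equally spaced stations.  Each
# station belongs to exactly one line; transfer hubs are modelled as
# co-located distinct stations.

make_line <- function(cfg, line_id, mode, from_xy, to_xy, spacing_m) {
  len <- sqrt(sum((to_xy - from_xy)^2))
  n_st <- max(2, floor(len / spacing_m) + 1)
  f <- seq(0, 1, length.out = n_st)
  xs <- from_xy[1] + f * (to_xy[1] - from_xy[1])
  ys <- from_xy[2] + f * (to_xy[2] - from_xy[2])
  ll <- offset_lonlat(cfg$centre_lon, cfg$centre_lat, xs, ys)
  data.frame(line_id = line_id, mode = mode, station_idx = seq_len(n_st),
             lon = ll[, "lon"], lat = ll[, "lat"],
             pos_m = f * len, stringsAsFactors = FALSE)
}

#' Build the synthetic transit network
#'
#' Deterministic layout: a grid of bus lines across the whole region, a
#' denser grid of metro lines restricted to the core city, two tangential
#' tramway lines in the close suburb, and four radial suburban-train lines
#' crossing the full region. Station spacing per mode comes from
#' `cfg$station_spacing_m`.
#'
#' @param cfg a [tw_config()].
#' @return A data frame of class `transit_network` with one row per station:
#'   `line_id`, `mode`, `station_idx`, `lon`, `lat`, `pos_m` (chainage along
#'   the line).
#' @export
transit_network <- function(cfg = tw_config()) {
  H <- cfg$half_extent_m
  sp <- cfg$station_spacing_m
  lines <- list()
  add <- function(id, mode, from, to, spacing) {
    lines[[length(lines) + 1]] <<- make_line(cfg, id, mode, from, to, spacing)
  }
  # bus: full-region grid of lines
  offs <- seq(-H + cfg$bus_line_spacing_m, H - cfg$bus_line_spacing_m,
              by = cfg$bus_line_spacing_m)
  for (k in seq_along(offs)) {
    add(sprintf("bus_v%02d", k), "bus", c(offs[k], -H), c(offs[k], H),
        sp[["bus"]])
    add(sprintf("bus_h%02d", k), "bus", c(-H, offs[k]), c(H, offs[k]),
        sp[["bus"]])
  }
  # metro: grid confined to the core city box
  R <- cfg$core_radius_m
  offs <- seq(-R + cfg$metro_line_spacing_m, R - cfg$metro_line_spacing_m,
              by = cfg$metro_line_spacing_m)
  for (k in seq_along(offs)) {
    add(sprintf("metro_v%02d", k), "metro", c(offs[k], -R), c(offs[k], R),
        sp[["metro"]])
    add(sprintf("metro_h%02d", k), "metro", c(-R, offs[k]), c(R, offs[k]),
        sp[["metro"]])
  }
  # tramway: two tangential lines in the close suburb
  Rt <- (cfg$core_radius_m + cfg$close_radius_m) / 2
  add("tram_n", "tramway", c(-Rt, Rt), c(Rt, Rt), sp[["tramway"]])
  add("tram_s", "tramway", c(-Rt, -Rt), c(Rt, -Rt), sp[["tramway"]])
  # suburban train: four radial lines through the centre
  add("sub_ew", "suburban_train", c(-H, 0), c(H, 0), sp[["suburban_train"]])
  add("sub_ns", "suburban_train", c(0, -H), c(0, H), sp[["suburban_train"]])
  d <- H / sqrt(2)
  add("sub_d1", "suburban_train", c(-d, -d), c(d, d), sp[["suburban_train"]])
  add("sub_d2", "suburban_train", c(-d, d), c(d, -d), sp[["suburban_train"]])
  net <- do.call(rbind, lines)
  class(net) <- c("transit_network", class(net))
  net
}

# nearest station of a given mode (optionally restricted to one line);
# returns list(row, dist_m) or NULL if the mode has no stations
nearest_station <- function(net, lon, lat, mode, line_id = NULL) {
  sel <- net$mode == mode
  if (!is.null(line_id)) sel <- sel & net$line_id == line_id
  if (!any(sel)) return(NULL)
  sub <- net[sel, , drop = FALSE]
  d <- hav_m(lon, lat, sub$lon, sub$lat)
  k <- which.min(d)
  list(row = sub[k, , drop = FALSE], dist_m = d[k])
}

# stations of any transit mode within radius of a point
stations_within <- function(net, lon, lat, radius_m) {
  d <- hav_m(lon, lat, net$lon, net$lat)
  net[d <= radius_m, , drop = FALSE]
}

# best line of one mode for an origin/destination pair: minimises total
# access+egress walk; returns NULL or list(line_id, board, alight, walk_m)
best_line <- function(net, mode, o_lon, o_lat, d_lon, d_lat) {
  sub <- net[net$mode == mode, , drop = FALSE]
  if (nrow(sub) == 0) return(NULL)
  best <- NULL
  for (lid in unique(sub$line_id)) {
    st <- sub[sub$line_id == lid, , drop = FALSE]
    do <- hav_m(o_lon, o_lat, st$lon, st$lat)
    dd <- hav_m(d_lon, d_lat, st$lon, st$lat)
    a <- which.min(do); b <- which.min(dd)
    if (a == b) next  # boarding = alighting: no ride on this line
    cost <- do[a] + dd[b]
    if (is.null(best) || cost < best$walk_m) {
      best <- list(line_id = lid, board = st[a, , drop = FALSE],
                   alight = st[b, , drop = FALSE], walk_m = cost,
                   max_end_walk_m = max(do[a], dd[b]))
    }
  }
  best
}
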