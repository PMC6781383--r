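# Synthetic world: region, participants, and ground-truth activity-travel
# diaries.  Every diary day is a gapless alternation of visits and trips
# tiling [0, 86400) in seconds from the study origin (midnight of day 1);
# within a trip, consecutive stages are separated by a punctual transfer
# episode sharing their endpoints.

ZONES <- c("core_city", "close_suburb", "far_suburb")
PT_MODES <- c("bus", "metro", "suburban_train", "tramway")

# zone-specific trip-mode mixture: PT and walking supply decline with
# distance from the core, the freed probability mass going to the car
zone_mode_mix <- function(cfg, zone) {
  m <- cfg$mode_mix / sum(cfg$mode_mix)
  ptf <- cfg$zone_pt_factor[[zone]]
  wf <- cfg$zone_walk_factor[[zone]]
  avail <- vapply(cfg$pt_availability, `[[`, numeric(1), zone)
  m[PT_MODES] <- m[PT_MODES] * ptf * avail[PT_MODES]
  m[c("walk", "bike_roller_skateboard")] <-
    m[c("walk", "bike_roller_skateboard")] * wf
  deficit <- 1 - sum(m)
  carw <- m[c("car_driver", "car_passenger")]
  m[c("car_driver", "car_passenger")] <-
    pmax(carw + deficit * carw / sum(carw), 0)
  m / sum(m)
}

# expected overall mode shares implied by the configuration (zone mixture
# marginalised out); used as the exact-counting reference for the generator
expected_mode_shares <- function(cfg) {
  mix <- vapply(ZONES, function(z) zone_mode_mix(cfg, z),
                numeric(length(cfg$mode_mix)))
  as.numeric(mix %*% cfg$zone_probs[ZONES]) |>
    setNames(names(cfg$mode_mix))
}

sample_home <- function(cfg, grid, net, zone) {
  rng <- switch(zone,
    core_city = c(500, cfg$core_radius_m),
    close_suburb = c(cfg$core_radius_m, cfg$close_radius_m),
    far_suburb = c(cfg$close_radius_m, cfg$half_extent_m * 0.95))
  for (try in 1:20) {
    r <- sqrt(runif(1, rng[1]^2, rng[2]^2))  # uniform over the annulus
    th <- runif(1, 0, 2 * pi)
    ll <- offset_lonlat(cfg$centre_lon, cfg$centre_lat,
                        r * cos(th), r * sin(th))
    ij <- grid_snap(grid, ll[1, "lon"], ll[1, "lat"])
    node <- grid_node_lonlat(grid, ij[1], ij[2])
    ns <- nearest_station(net, node[1, "lon"], node[1, "lat"], "bus")
    if (!is.null(ns) && ns$dist_m <= 1000) break
  }
  node
}

# destination at a mode-typical crow-fly distance from the origin, biased
# towards the region centre for public transport, snapped to the grid
sample_destination <- function(cfg, grid, origin, mode) {
  key <- if (mode %in% PT_MODES) "pt"
         else if (mode %in% c("car_driver", "car_passenger")) "car"
         else if (mode %in% names(cfg$trip_crow_lnorm)) mode else "walk"
  par <- cfg$trip_crow_lnorm[[key]]
  d <- rlnorm(1, par[["meanlog"]], par[["sdlog"]])
  if (mode %in% PT_MODES) {
    xy0 <- local_xy(origin[1], origin[2], cfg$centre_lon, cfg$centre_lat)
    th0 <- atan2(-xy0[1, 2], -xy0[1, 1])  # bearing towards the centre
    th <- th0 + rnorm(1, 0, pi / 6)
  } else {
    th <- runif(1, 0, 2 * pi)
  }
  ll <- offset_lonlat(origin[1], origin[2], d * cos(th), d * sin(th))
  lim <- 0.95 * cfg$half_extent_m
  xy <- local_xy(ll[1, "lon"], ll[1, "lat"], cfg$centre_lon, cfg$centre_lat)
  xy <- pmin(pmax(xy, -lim), lim)
  ll <- offset_lonlat(cfg$centre_lon, cfg$centre_lat, xy[1], xy[2])
  ij <- grid_snap(grid, ll[1, "lon"], ll[1, "lat"])
  oij <- grid_snap(grid, origin[1], origin[2])
  if (all(ij == oij)) {  # degenerate draw: move one block over
    ij[1] <- if (ij[1] < grid$nx) ij[1] + 1L else ij[1] - 1L
  }
  grid_node_lonlat(grid, ij[1], ij[2])
}

seg_row <- function(pid, day, kind, trip_id, mode, start, end, geom) {
  data.frame(participant_id = pid, day = day, kind = kind,
             trip_id = if (is.null(trip_id)) NA_character_ else trip_id,
             mode = if (is.null(mode)) NA_character_ else mode,
             start = start, end = end,
             geometry = I(list(geom)), stringsAsFactors = FALSE)
}

# walk leg on the street grid, terminating exactly at `to` (e.g. a station)
walk_leg_path <- function(grid, from, to) {
  p <- shortest_path_itinerary(c(from[1], from[2]), c(to[1], to[2]), grid)
  if (hav1(p[nrow(p), 1], p[nrow(p), 2], to[1], to[2]) > 1) {
    p <- rbind(p, c(to[1], to[2]))
  }
  if (hav1(p[1, 1], p[1, 2], from[1], from[2]) > 1) {
    p <- rbind(c(from[1], from[2]), p)
  }
  p
}

# Outbound public-transport leg: board at the nearest station of the
# drawn mode, ride to the station closest to a mode-typical trip length,
# and alight to a destination drawn in the station's walkshed.  NULL when
# no line of the mode is within walking reach (the traveller drives).
pt_outbound <- function(cfg, grid, net, mode, origin) {
  sub <- net[net$mode == mode, , drop = FALSE]
  if (nrow(sub) == 0) return(NULL)
  d <- hav_m(origin[1], origin[2], sub$lon, sub$lat)
  k <- which.min(d)
  if (d[k] > cfg$max_pt_access_walk_m) return(NULL)
  board <- sub[k, , drop = FALSE]
  line <- sub[sub$line_id == board$line_id, , drop = FALSE]
  par <- cfg$trip_crow_lnorm[["pt"]]
  D <- rlnorm(1, par[["meanlog"]], par[["sdlog"]])
  cand <- line[line$station_idx != board$station_idx, , drop = FALSE]
  if (nrow(cand) == 0) return(NULL)
  j <- which.min(abs(abs(cand$pos_m - board$pos_m) - D))
  alight <- cand[j, , drop = FALSE]
  th <- runif(1, 0, 2 * pi)
  rr <- runif(1, 100, 600)
  ll <- offset_lonlat(alight$lon, alight$lat, rr * cos(th), rr * sin(th))
  ij <- grid_snap(grid, ll[1, "lon"], ll[1, "lat"])
  list(board = board, alight = alight,
       dest = grid_node_lonlat(grid, ij[1], ij[2]))
}

# Build the stage/transfer rows of one trip starting at time t0; `dest`
# may be NULL for public-transport legs (chosen along a reachable line)
# and is then reported back.  Falls back to driving when no line of the
# drawn mode is workable.
make_trip <- function(cfg, grid, net, pid, day, trip_id, origin, dest,
                      mode, t0) {
  sp_mps <- cfg$speeds_kmh / 3.6
  stages <- list()   # list of list(mode, poly)
  if (mode %in% PT_MODES) {
    if (is.null(dest)) {
      leg <- pt_outbound(cfg, grid, net, mode, origin)
      if (!is.null(leg)) dest <- c(leg$dest[1, 1], leg$dest[1, 2])
    } else {
      bl <- best_line(net, mode, origin[1], origin[2], dest[1], dest[2])
      leg <- if (!is.null(bl) &&
                   bl$max_end_walk_m <= cfg$max_pt_access_walk_m) {
        list(board = bl$board, alight = bl$alight)
      } else NULL
    }
    if (is.null(leg)) {
      mode <- "car_driver"   # no workable line: falls back to driving
    } else {
      board <- c(leg$board$lon, leg$board$lat)
      alight <- c(leg$alight$lon, leg$alight$lat)
      wa <- walk_leg_path(grid, origin, board)
      if (polyline_length(wa) > 1) {
        stages[[length(stages) + 1]] <- list(mode = "walk", poly = wa)
      }
      stages[[length(stages) + 1]] <-
        list(mode = mode, poly = rbind(board, alight))
      wb <- walk_leg_path(grid, alight, dest)
      if (polyline_length(wb) > 1) {
        stages[[length(stages) + 1]] <- list(mode = "walk", poly = wb)
      }
    }
  }
  if (length(stages) == 0) {  # unimodal leg on the street grid
    if (is.null(dest)) {
      dest_ll <- sample_destination(cfg, grid, origin, mode)
      dest <- c(dest_ll[1, 1], dest_ll[1, 2])
    }
    p <- shortest_path_itinerary(origin, dest, grid)
    if (nrow(p) < 2) p <- rbind(p, p)  # degenerate same-node trip
    stages[[1]] <- list(mode = mode, poly = p)
  }
  rows <- list()
  t <- t0
  for (k in seq_along(stages)) {
    st <- stages[[k]]
    if (k > 1) {  # transfer at the shared endpoint
      tdur <- runif(1, cfg$transfer_dur_range_s[1], cfg$transfer_dur_range_s[2])
      pt <- st$poly[1, , drop = FALSE]
      rows[[length(rows) + 1]] <-
        seg_row(pid, day, "transfer", trip_id, NA, t, t + tdur, pt)
      t <- t + tdur
    }
    dur <- max(polyline_length(st$poly) / sp_mps[[st$mode]], 1)
    rows[[length(rows) + 1]] <-
      seg_row(pid, day, "stage", trip_id, st$mode, t, t + dur, st$poly)
    t <- t + dur
  }
  nw <- setdiff(vapply(stages, `[[`, "", "mode"), "walk")
  list(rows = do.call(rbind, rows), end = t,
       main_mode = if (length(nw) > 0) nw[1] else "walk",
       dest = stages[[length(stages)]]$poly[
         nrow(stages[[length(stages)]]$poly), , drop = FALSE])
}

gen_day <- function(cfg, grid, net, pid, day, home, mix) {
  day0 <- (day - 1) * 86400
  k <- sample(seq_along(cfg$n_dest_probs), 1, prob = cfg$n_dest_probs)
  n_legs <- k + 1
  modes <- sample(names(mix), n_legs, replace = TRUE, prob = mix)
  dep1 <- runif(1, cfg$first_departure_range_h[1],
                cfg$first_departure_range_h[2]) * 3600
  visit_durs <- runif(k, cfg$visit_dur_range_h[1],
                      cfg$visit_dur_range_h[2]) * 3600
  rows <- list()
  t <- dep1
  origin <- home
  for (leg in seq_len(n_legs)) {
    dest <- if (leg == n_legs) c(home[1], home[2]) else NULL
    trip_id <- sprintf("%s_d%02d_t%02d", pid, day, leg)
    tr <- make_trip(cfg, grid, net, pid, day, trip_id,
                    c(origin[1], origin[2]), dest, modes[leg], t)
    rows[[length(rows) + 1]] <- tr$rows
    t <- tr$end
    origin <- tr$dest
    if (leg < n_legs) {
      # shrink remaining visits if the day is running long
      budget <- cfg$latest_return_h * 3600 - t - 600 * (n_legs - leg)
      rem <- sum(visit_durs[leg:k])
      if (rem > budget && rem > 0) {
        visit_durs[leg:k] <- visit_durs[leg:k] * max(budget, 600) / rem
      }
      rows[[length(rows) + 1]] <-
        seg_row(pid, day, "visit", NULL, NULL, t, t + visit_durs[leg], origin)
      t <- t + visit_durs[leg]
    }
  }
  trips <- do.call(rbind, rows)
  if (max(trips$end) >= 86400) {  # safety: compress an over-long day
    sc <- (86400 - 60 - dep1) / (max(trips$end) - dep1)
    trips$start <- dep1 + (trips$start - dep1) * sc
    trips$end <- dep1 + (trips$end - dep1) * sc
  }
  out <- rbind(
    seg_row(pid, day, "visit", NULL, NULL, 0, trips$start[1], home),
    trips,
    seg_row(pid, day, "visit", NULL, NULL, max(trips$end), 86400,
            trips$geometry[[nrow(trips)]][
              nrow(trips$geometry[[nrow(trips)]]), , drop = FALSE])
  )
  out$start <- out$start + day0
  out$end <- out$end + day0
  out
}

#' Generate a synthetic region, cohort and ground-truth diaries
#'
#' Builds the street grid and transit network deterministically from the
#' configuration, then draws, for each participant, an urbanicity zone, a
#' residence near the transit network, habitual-mode priors, and `n_days`
#' activity-travel diary days. Each diary day begins and ends at the
#' residence and tiles `[0, 86400)` with alternating visits and trips; trip
#' stages and transfer episodes use half-open, contiguous intervals.
#'
#' All randomness is drawn from one stream per participant derived from
#' `(cfg$seed, participant)`, so worlds are byte-identical across runs and
#' invariant to participant insertion order.
#'
#' @param cfg a [tw_config()].
#' @param n_participants,n_days positive counts.
#' @return A list of class `synthetic_world`: `config`, `grid`, `network`,
#'   `participants` (data frame with `participant_id`, `zone`, `home_lon`,
#'   `home_lat` and a `prior` list-column on the imputation mode alphabet),
#'   and `diaries` (named list of per-participant diary data frames with
#'   columns `participant_id`, `day`, `kind` in visit/stage/transfer,
#'   `trip_id`, `mode`, `start`, `end`, `geometry`).
#' @examples
#' w <- generate_world(tw_config(seed = 3), n_participants = 1, n_days = 2)
#' table(w$diaries[[1]]$kind)
#' @export
generate_world <- function(cfg = tw_config(), n_participants = 1, n_days = 7) {
  stopifnot(n_participants >= 1, n_days >= 1)
  validate_config(cfg)
  grid <- street_grid(cfg)
  net <- transit_network(cfg)
  participants <- list()
  diaries <- list()
  for (p in seq_len(n_participants)) {
    pid <- sprintf("p%03d", p)
    set.seed(stream_seed(cfg$seed, p, "world"))
    zone <- sample(ZONES, 1, prob = cfg$zone_probs[ZONES])
    home <- sample_home(cfg, grid, net, zone)
    mix <- zone_mode_mix(cfg, zone)
    prior <- prior_from_mix(mix)
    days <- lapply(seq_len(n_days), function(d)
      gen_day(cfg, grid, net, pid, d, home, mix))
    diaries[[pid]] <- do.call(rbind, days)
    participants[[p]] <- data.frame(
      participant_id = pid, zone = zone,
      home_lon = home[1, "lon"], home_lat = home[1, "lat"],
      prior = I(list(prior)), stringsAsFactors = FALSE)
  }
  structure(list(config = cfg, grid = grid, network = net,
                 participants = do.call(rbind, participants),
                 diaries = diaries),
            class = "synthetic_world")
}

# collapse a diary-mode mixture onto the imputation alphabet -> ModePrior
prior_from_mix <- function(mix) {
  g <- mode_to_imputation(names(mix))
  pr <- tapply(mix, g, sum)
  out <- setNames(numeric(length(imputation_modes())), imputation_modes())
  out[names(pr)] <- pr
  out / sum(out)
}

#' Ground-truth trip distances of a diary
#'
#' Per-trip distance is the sum of the trip's stage polyline lengths;
#' transfer episodes are punctual and contribute nothing.
#'
#' @param diary a diary data frame from [generate_world()].
#' @return data frame `trip_id`, `day`, `length_m`.
#' @export
diary_trip_distances <- function(diary) {
  st <- diary[diary$kind == "stage", , drop = FALSE]
  len <- vapply(st$geometry, polyline_length, numeric(1))
  stats::aggregate(data.frame(length_m = len),
                   by = list(trip_id = st$trip_id, day = st$day), FUN = sum)
}
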