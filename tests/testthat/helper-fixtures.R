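# Shared fixtures, built in code and cached across test files.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# small clean world used by several recovery tests
clean_world_small <- function() {
  fixture("clean_world_small", {
    generate_world(tw_config_clean(tw_config(seed = 11)),
                   n_participants = 3, n_days = 2)
  })
}

noisy_world_small <- function() {
  fixture("noisy_world_small", {
    generate_world(tw_config(seed = 12, dropout_prob = 0),
                   n_participants = 3, n_days = 2)
  })
}

# clean world with public-transport-heavy behaviour (core residents), so
# multimodal walk-ride-walk trips are guaranteed to occur
pt_world_small <- function() {
  fixture("pt_world_small", {
    cfg <- tw_config_clean(tw_config(
      seed = 15,
      zone_probs = c(core_city = 1, close_suburb = 0, far_suburb = 0),
      mode_mix = c(walk = 0.25, bike_roller_skateboard = 0.02,
                   bus = 0.2, metro = 0.35, suburban_train = 0.03,
                   tramway = 0.0, car_driver = 0.1,
                   car_passenger = 0.05)))
    generate_world(cfg, n_participants = 2, n_days = 2)
  })
}

# diary with one straight northbound trip between two visits, built by hand
straight_trip_diary <- function(pid = "p001", len_m = 1000,
                                speed_kmh = 4.8, dep_s = 36000,
                                mode = "walk", lon0 = 2.35, lat0 = 48.85) {
  p2 <- tripwalk:::offset_lonlat(lon0, lat0, 0, len_m)
  poly <- rbind(c(lon0, lat0), c(p2[1, "lon"], p2[1, "lat"]))
  dur <- len_m / (speed_kmh / 3.6)
  rbind(
    seg_df(pid, "visit", NA, NA, 0, dep_s, matrix(c(lon0, lat0), 1)),
    seg_df(pid, "stage", sprintf("%s_d01_t01", pid), mode, dep_s,
           dep_s + dur, poly),
    seg_df(pid, "visit", NA, NA, dep_s + dur, 86400,
           matrix(c(p2[1, "lon"], p2[1, "lat"]), 1)))
}

# one diary segment row with the package's schema
seg_df <- function(pid, kind, trip_id, mode, start, end, geom, day = 1) {
  d <- data.frame(participant_id = pid, day = day, kind = kind,
                  trip_id = if (is.na(trip_id)) NA_character_ else trip_id,
                  mode = if (is.na(mode)) NA_character_ else mode,
                  start = start, end = end, stringsAsFactors = FALSE)
  colnames(geom) <- c("lon", "lat")[seq_len(min(2, ncol(geom)))]
  d$geometry <- list(geom)
  d
}

# merge ground-truth visit rows that continue across midnight into episodes
truth_visit_episodes <- function(diary) {
  v <- diary[diary$kind == "visit", , drop = FALSE]
  v <- v[order(v$start), , drop = FALSE]
  if (nrow(v) < 2) return(nrow(v))
  same_loc <- vapply(2:nrow(v), function(i) {
    abs(v$start[i] - v$end[i - 1]) < 1e-6 &&
      tripwalk:::hav1(v$geometry[[i]][1, 1], v$geometry[[i]][1, 2],
                      v$geometry[[i - 1]][1, 1],
                      v$geometry[[i - 1]][1, 2]) < 1
  }, logical(1))
  1 + sum(!same_loc)
}

# timetable-style segment rows for classification tests (no geometry)
trip_segments <- function(trip_id, modes, pid = "p001", day = 1,
                          t0 = 3600, stage_s = 600, transfer_s = 60,
                          length_m = 500) {
  rows <- list()
  t <- t0
  for (i in seq_along(modes)) {
    if (i > 1) {
      rows[[length(rows) + 1]] <- data.frame(
        participant_id = pid, day = day, kind = "transfer",
        trip_id = trip_id, mode = NA_character_, start = t,
        end = t + transfer_s, length_m = 0, stringsAsFactors = FALSE)
      t <- t + transfer_s
    }
    rows[[length(rows) + 1]] <- data.frame(
      participant_id = pid, day = day, kind = "trip_stage",
      trip_id = trip_id, mode = modes[i], start = t, end = t + stage_s,
      length_m = length_m, stringsAsFactors = FALSE)
    t <- t + stage_s
  }
  do.call(rbind, rows)
}
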