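# Study configuration: one list drives the synthetic world, the two sensor
# renderers and the processing defaults.

#' Synthetic-study configuration
#'
#' Returns the full configuration for the synthetic world and sensor
#' emulation, with defaults chosen to emulate a week-long multi-sensor
#' mobility study in a large European metropolitan region: a 40 x 40 km
#' region split into a core city, a close suburb ring and a far suburb ring;
#' a grid street network; bus/metro/tramway/suburban-train lines; and a
#' trip-mode mixture matching typical observed shares (42% entirely walked,
#' 41% private motorized, 11% public transport, 5% other active).
#'
#' GPS artefacts are controlled by `jitter_sd_m` (autocorrelated position
#' jitter while at fixed places), `track_noise_m` (autocorrelated noise on
#' trip tracks), `pseudo_ambulation_rate` (expected spurious indoor
#' random-walk bursts per visit-hour) and `dropout_prob` (probability that a
#' whole trip leaves no GPS trace, as when the receiver is left at home).
#' The accelerometer draws per-epoch steps from a mode-specific cadence
#' model truncated at zero and zeroes everything outside the wear schedule.
#'
#' @param ... named overrides of any default field (nested lists are
#'   replaced wholesale).
#' @return A list of class `tw_config`.
#' @examples
#' cfg <- tw_config(seed = 7, dropout_prob = 0)
#' cfg$gps_period_s
#' @export
tw_config <- function(...) {
  cfg <- list(
    seed = 1,
    # region geometry (centred on an arbitrary reference point)
    centre_lon = 2.35, centre_lat = 48.85,
    half_extent_m = 20000,
    grid_spacing_m = 500,
    core_radius_m = 5000,
    close_radius_m = 12000,
    # transit network: station spacing per mode (m) and line layout spacing
    station_spacing_m = c(bus = 450, metro = 600, tramway = 500,
                          suburban_train = 2500),
    bus_line_spacing_m = 3000,
    metro_line_spacing_m = 1500,
    # behaviour
    zone_probs = c(core_city = 0.35, close_suburb = 0.45, far_suburb = 0.20),
    mode_mix = c(walk = 0.423, bike_roller_skateboard = 0.048,
                 bus = 0.030, metro = 0.062, suburban_train = 0.018,
                 tramway = 0.008, car_driver = 0.360, car_passenger = 0.051),
    # multiplicative accessibility gradients across zones (PT and walking
    # supply decline away from the core; freed mass moves to car)
    zone_pt_factor = c(core_city = 1, close_suburb = 0.7, far_suburb = 0.4),
    # supply structure: metro serves the core only, tramways mostly the
    # close suburb, suburban trains gain weight outwards
    pt_availability = list(
      bus = c(core_city = 1, close_suburb = 1, far_suburb = 1),
      metro = c(core_city = 1, close_suburb = 0.15, far_suburb = 0),
      suburban_train = c(core_city = 0.6, close_suburb = 1,
                         far_suburb = 1.3),
      tramway = c(core_city = 0.4, close_suburb = 1.6,
                  far_suburb = 0.2)),
    zone_walk_factor = c(core_city = 1, close_suburb = 0.85, far_suburb = 0.6),
    n_dest_probs = c(0.2, 0.35, 0.3, 0.15),   # 1..4 out-of-home anchors/day
    trip_crow_lnorm = list(                   # crow-fly distance draws (m)
      walk = c(meanlog = log(600), sdlog = 0.5),
      bike_roller_skateboard = c(meanlog = log(2000), sdlog = 0.5),
      pt = c(meanlog = log(6000), sdlog = 0.4),
      car = c(meanlog = log(7000), sdlog = 0.6)
    ),
    max_pt_access_walk_m = 1500,  # beyond this the traveller takes the car
    speeds_kmh = c(walk = 4.8, bike_roller_skateboard = 15, bus = 19,
                   coach = 60, metro = 28, suburban_train = 45, tramway = 18,
                   car_driver = 29, car_passenger = 29,
                   long_distance_train = 180, plane = 700, jogging = 9,
                   dog_walking = 4, ski_chairlift = 15),
    transfer_dur_range_s = c(0, 180),
    first_departure_range_h = c(7.5, 9.5),
    visit_dur_range_h = c(1, 5),
    latest_return_h = 23,
    # GPS sensor
    gps_period_s = 5,
    jitter_sd_m = 3, jitter_ar = 0.95,
    track_noise_m = 2, track_noise_ar = 0.9,
    pseudo_ambulation_rate = 0.12,   # bursts per visit-hour
    pa_burst_points = 90, pa_step_sd_m = 30,
    dropout_prob = 0.05,
    # reception loss during rides (underground running) and stop-and-go
    # along-track progress noise of vehicle stages
    signal_loss = c(metro = 0.7, suburban_train = 0.25, tramway = 0.05,
                    bus = 0.05, plane = 1),
    ride_progress_noise_m = 40, ride_progress_ar = 0.9,
    # accelerometer
    accel_epoch_s = 60,
    cadence_spm = list(               # steps/min: mean, sd by context
      walk = c(100, 8), jogging = c(160, 15), dog_walking = c(90, 10),
      bike_roller_skateboard = c(15, 8), bus = c(0, 2), coach = c(0, 2),
      metro = c(0, 2), suburban_train = c(0, 2), tramway = c(0, 2),
      car_driver = c(0, 2), car_passenger = c(0, 2),
      long_distance_train = c(0, 2), plane = c(0, 2),
      ski_chairlift = c(5, 5),
      visit = c(5, 4), transfer = c(30, 15)
    ),
    vm_lambda = c(walk = 2500, jogging = 6000, dog_walking = 2200,
                  bike_roller_skateboard = 1500, bus = 600, coach = 600,
                  metro = 600, suburban_train = 600, tramway = 600,
                  car_driver = 500, car_passenger = 500,
                  long_distance_train = 500, plane = 500,
                  ski_chairlift = 800, visit = 150, transfer = 1200),
    wear_schedule = list(c(7 * 3600, 21.5 * 3600)),
    # survey emulation
    recall_prob = 1.0,
    recall_noise_sd_s = 0,
    corridor_m = 60,
    # processing defaults
    speed_threshold_kmh = 1.0,
    dwell_min_s = 300, visit_radius_m = 50,
    stage_split_kmh = 7, station_snap_m = 75, smooth_k = 5
  )
  dots <- list(...)
  if (length(dots) > 0) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad) > 0 || is.null(names(dots)) || any(names(dots) == "")) {
      stop("unknown configuration field(s): ", paste(bad, collapse = ", "))
    }
    cfg[names(dots)] <- dots
  }
  validate_config(cfg)
  structure(cfg, class = "tw_config")
}

validate_config <- function(cfg) {
  chk <- function(ok, field, msg) {
    if (!ok) stop("invalid configuration: field '", field, "' ", msg,
                  call. = FALSE)
  }
  chk(is.numeric(cfg$gps_period_s) && cfg$gps_period_s > 0,
      "gps_period_s", "must be > 0")
  chk(cfg$accel_epoch_s > 0 && 86400 %% cfg$accel_epoch_s == 0,
      "accel_epoch_s", "must be > 0 and divide the day")
  for (f in c("dropout_prob", "recall_prob")) {
    chk(cfg[[f]] >= 0 && cfg[[f]] <= 1, f, "must be a probability in [0,1]")
  }
  chk(cfg$pseudo_ambulation_rate >= 0, "pseudo_ambulation_rate",
      "must be >= 0")
  chk(all(vapply(cfg$cadence_spm, function(x) x[1] >= 0, logical(1))),
      "cadence_spm", "cadence means must be >= 0")
  chk(all(cfg$zone_probs >= 0) && abs(sum(cfg$zone_probs) - 1) < 1e-6,
      "zone_probs", "must be nonnegative and sum to 1")
  chk(all(cfg$mode_mix >= 0) && sum(cfg$mode_mix) > 0,
      "mode_mix", "must be nonnegative with positive mass")
  chk(cfg$jitter_sd_m >= 0, "jitter_sd_m", "must be >= 0")
  chk(cfg$recall_noise_sd_s >= 0, "recall_noise_sd_s", "must be >= 0")
  chk(cfg$seed == as.integer(cfg$seed), "seed", "must be an integer")
  invisible(cfg)
}

#' Turn off all sensor artefacts and survey noise
#'
#' Convenience used for parameter-recovery runs: zero jitter, track noise,
#' pseudo-ambulation, dropout and recall timestamp noise, with perfect
#' recall.
#'
#' @param cfg a [tw_config()] object.
#' @return the modified configuration.
#' @export
tw_config_clean <- function(cfg = tw_config()) {
  cfg$jitter_sd_m <- 0
  cfg$track_noise_m <- 0
  cfg$pseudo_ambulation_rate <- 0
  cfg$dropout_prob <- 0
  cfg$signal_loss[] <- 0
  cfg$ride_progress_noise_m <- 0
  cfg$recall_prob <- 1
  cfg$recall_noise_sd_s <- 0
  cfg
}

#' Read a configuration from a YAML file
#'
#' Every top-level key in the file overrides the corresponding
#' [tw_config()] default; unknown keys are an error.
#'
#' @param path path to a YAML file.
#' @return A `tw_config` object.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  for (nm in intersect(names(vals),
                       c("zone_probs", "mode_mix", "zone_pt_factor",
                         "zone_walk_factor", "speeds_kmh", "vm_lambda",
                         "station_spacing_m"))) {
    vals[[nm]] <- unlist(vals[[nm]])
  }
  do.call(tw_config, vals)
}

# participant-scoped RNG stream: reproducible and insertion-order invariant
stream_seed <- function(seed, pid, what = "world") {
  h <- sum(utf8ToInt(what)) * 131
  as.integer((abs(seed) * 48271 + pid * 69621 + h) %% 2147483562) + 1L
}
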