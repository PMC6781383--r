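# End-to-end orchestration: synthetic world -> sensors -> algorithm ->
# survey -> timetable -> metrics.

as_algo_segments <- function(visits, stages_imputed) {
  if (nrow(visits) > 0) {
    visits$mode <- NA_character_
    visits$median_kmh <- NA_real_
  }
  out <- rbind(visits, stages_imputed)
  out[order(out$start), , drop = FALSE]
}

# algorithm-only processing of one participant's raw points
process_participant <- function(points, network, cfg, prior) {
  filt <- filter_low_speed(points, cfg$speed_threshold_kmh)
  segs <- detect_visits(filt, cfg$dwell_min_s, cfg$visit_radius_m)
  moves <- which(segs$kind == "move")
  stage_list <- lapply(moves, function(i)
    split_stages(segs[i, ], network, cfg$stage_split_kmh,
                 cfg$station_snap_m, cfg$smooth_k))
  move_id <- rep(seq_along(moves), vapply(stage_list, nrow, integer(1)))
  stages <- do.call(rbind, stage_list)
  imp <- if (!is.null(stages) && nrow(stages) > 0) {
    impute_modes(stages, prior, network, move_id = move_id)
  } else stages
  list(filtered = filt,
       segments = as_algo_segments(segs[segs$kind == "visit", , drop = FALSE],
                                   imp))
}

#' Run the full measurement chain on a synthetic world
#'
#' Renders the GPS and accelerometer streams for every participant,
#' applies the algorithm-only GPS processing (speed filter, visit
#' detection, stage splitting, mode imputation), reconciles the result
#' against recall into a validated timetable, links accelerometer steps,
#' applies the exclusion rules, and computes the headline reports.
#'
#' @param world a [generate_world()] object.
#' @param recall a [recall_model()]; defaults to the world configuration's
#'   recall parameters.
#' @return list: `filtered` (retained GPS points), `algo_segments`,
#'   `timetable` (with steps), `epochs`, `wear`, `exclusions` (ledger +
#'   flagged segments), `trips` (with `accel_excluded`), `metrics`
#'   (per-trip table), `three_way` (distance report), `accuracy` (pooled
#'   time-weighted mode agreement).
#' @export
run_pipeline <- function(world, recall = NULL) {
  cfg <- world$config
  if (is.null(recall)) {
    recall <- recall_model(cfg$recall_prob, cfg$recall_noise_sd_s)
  }
  filtered <- list()
  algo <- list()
  tt <- list()
  eps <- list()
  acc <- list()
  for (p in seq_len(nrow(world$participants))) {
    pid <- world$participants$participant_id[p]
    diary <- world$diaries[[pid]]
    gps <- render_gps(diary, cfg)
    pr <- process_participant(gps, world$network, cfg,
                              world$participants$prior[[p]])
    filtered[[pid]] <- pr$filtered
    algo[[pid]] <- pr$segments
    acc[[pid]] <- mode_accuracy_report(pr$segments, diary)
    tt[[pid]] <- reconcile(pr$segments, diary, recall, world$grid,
                           cfg$corridor_m,
                           seed = stream_seed(cfg$seed, p, "survey"))
    eps[[pid]] <- render_accel(diary, cfg)
  }
  filtered <- do.call(rbind, filtered)
  algo_segments <- do.call(rbind, algo)
  timetable <- do.call(rbind, tt)
  rownames(timetable) <- NULL
  epochs <- do.call(rbind, eps)
  wear <- detect_nonwear(epochs)
  timetable <- steps_per_segment(epochs, timetable)
  excl <- apply_exclusions(timetable)
  trips <- flag_nonwear_trips(excl$trips, wear)
  metrics <- build_metrics_table(excl$retained_segments, trips,
                                 world$participants)
  metrics$accel_excluded <- trips$accel_excluded[
    match(metrics$trip_id, trips$trip_id)]
  list(filtered = filtered, algo_segments = algo_segments,
       timetable = timetable, epochs = epochs, wear = wear,
       exclusions = excl, trips = trips, metrics = metrics,
       three_way = three_way_distance_report(filtered, algo_segments,
                                             timetable),
       accuracy = pool_mode_accuracy(acc))
}
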