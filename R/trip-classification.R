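# Trip assembly, crude/detailed classification with the multi-mode rule,
# and the analytical-sample exclusion rules.

#' Classify a trip by its stage modes
#'
#' A trip whose stages are all walking is `entirely_walked`; a trip with
#' exactly one distinct non-walking mode group (at the granularity of the
#' scheme) takes that group's class; a trip with two or more distinct
#' non-walking groups is `multi_mode`. Walking stages never create
#' multi-modality.
#'
#' @param trip either a character vector of stage modes or a data frame of
#'   timetable segments (rows with `kind` in `stage`/`trip_stage` are
#'   used).
#' @param scheme `"crude"` or `"detailed"`.
#' @return a single class label.
#' @examples
#' classify_trip(c("walk", "metro", "walk"), "crude")     # public_transport
#' classify_trip(c("walk", "metro", "walk", "bus"), "detailed") # multi_mode
#' @export
classify_trip <- function(trip, scheme = c("crude", "detailed")) {
  scheme <- match.arg(scheme)
  modes <- if (is.data.frame(trip)) {
    trip$mode[trip$kind %in% c("stage", "trip_stage")]
  } else trip
  if (length(modes) == 0) stop("trip has no stages")
  nw <- modes[modes != "walk"]
  if (length(nw) == 0) return("entirely_walked")
  groups <- unique(if (scheme == "crude") crude_group(nw)
                   else detailed_group(nw))
  if (length(groups) == 1) groups else "multi_mode"
}

#' Assemble trips from a timetable
#'
#' Groups trip-stage and transfer rows by `trip_id` and classifies each
#' trip under both schemes.
#'
#' @param timetable a [reconcile()] timetable (or any segment table with
#'   `trip_id`, `kind`, `mode`, `start`, `end`, `length_m`).
#' @return data frame: one row per trip with `trip_id`, `participant_id`,
#'   `day`, `start`, `end`, `n_segments`, `n_stages`, `crude_class`,
#'   `detailed_class`, `distance_m`.
#' @export
assemble_trips <- function(timetable) {
  tr <- timetable[!is.na(timetable$trip_id), , drop = FALSE]
  if (nrow(tr) == 0) {
    return(data.frame(trip_id = character(0)))
  }
  by_trip <- split(seq_len(nrow(tr)), tr$trip_id)
  is_stage <- tr$kind %in% c("stage", "trip_stage")
  out <- lapply(names(by_trip), function(tid) {
    idx <- by_trip[[tid]]
    st <- idx[is_stage[idx]]
    data.frame(trip_id = tid, participant_id = tr$participant_id[idx[1]],
               day = tr$day[idx[1]], start = min(tr$start[idx]),
               end = max(tr$end[idx]),
               n_segments = length(idx), n_stages = length(st),
               crude_class = classify_trip(tr$mode[st], "crude"),
               detailed_class = classify_trip(tr$mode[st], "detailed"),
               distance_m = sum(tr$length_m[st]), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Apply the analytical-sample exclusion rules to trip segments
#'
#' Operates on the trip-related segments of a timetable (stages and
#' transfers): a trip containing a ski/chairlift stage is deleted whole
#' (every segment flagged, reason `ski_chairlift`); jogging and dog-walking
#' stages are flagged individually together with their immediately
#' preceding and following transfer episodes (reason `jogging_dog`), the
#' rest of the trip being retained; long-distance train and plane stages
#' are retained, as they pertain to transport. Trips whose stages are all
#' excluded are dropped entirely; retained modified trips are reclassified.
#'
#' @param timetable segment table with `trip_id`, `kind`, `mode`.
#' @return list: `segments` (input plus `excluded` flag and `reason`),
#'   `trips` (the [assemble_trips()] table of retained segments),
#'   `ledger` (counts: segments in, excluded by reason, retained).
#' @export
apply_exclusions <- function(timetable) {
  seg <- timetable[!is.na(timetable$trip_id), , drop = FALSE]
  seg$excluded <- FALSE
  seg$reason <- NA_character_
  by_trip <- split(seq_len(nrow(seg)), seg$trip_id)
  is_stage <- seg$kind %in% c("stage", "trip_stage")
  for (idx in by_trip) {
    idx <- idx[order(seg$start[idx])]
    if (any(is_stage[idx] & !is.na(seg$mode[idx]) &
              seg$mode[idx] == "ski_chairlift")) {
      seg$excluded[idx] <- TRUE
      seg$reason[idx] <- "ski_chairlift"
      next
    }
    jd <- which(!is.na(seg$mode[idx]) &
                  seg$mode[idx] %in% c("jogging", "dog_walking"))
    for (i in jd) {
      hit <- i
      if (i > 1 && seg$kind[idx[i - 1]] == "transfer") hit <- c(hit, i - 1)
      if (i < length(idx) && seg$kind[idx[i + 1]] == "transfer") {
        hit <- c(hit, i + 1)
      }
      seg$excluded[idx[hit]] <- TRUE
      seg$reason[idx[hit]] <- "jogging_dog"
    }
  }
  retained <- seg[!seg$excluded, , drop = FALSE]
  # trips left with no stage at all are dropped wholesale
  has_stage <- tapply(retained$kind %in% c("stage", "trip_stage"),
                      retained$trip_id, any)
  keep_ids <- names(has_stage)[has_stage]
  retained <- retained[retained$trip_id %in% keep_ids, , drop = FALSE]
  ledger <- c(
    segments_in = nrow(seg),
    excluded_ski = sum(seg$reason == "ski_chairlift", na.rm = TRUE),
    excluded_jogging_dog = sum(seg$reason == "jogging_dog", na.rm = TRUE),
    segments_retained = nrow(retained))
  list(segments = seg, trips = assemble_trips(retained),
       retained_segments = retained, ledger = ledger)
}

#' Flag trips overlapping accelerometer nonwear
#'
#' Exclusion is at the trip level: a trip is flagged if *any* part of it
#' (including transfers) overlaps a nonwear interval of the wear mask.
#'
#' @param trips an [assemble_trips()] table.
#' @param wear a [detect_nonwear()] wear mask covering the trips'
#'   participant-days.
#' @return `trips` with a logical `accel_excluded` column.
#' @export
flag_nonwear_trips <- function(trips, wear) {
  nw <- wear$nonwear
  covered <- unique(wear$epochs_cover[c("participant_id", "day")])
  miss <- !paste(trips$participant_id, trips$day) %in%
    paste(covered$participant_id, covered$day)
  if (any(miss)) {
    stop("coverage error: no accelerometer epochs for ",
         sum(miss), " trip participant-day(s)")
  }
  trips$accel_excluded <- vapply(seq_len(nrow(trips)), function(i) {
    sel <- nw$participant_id == trips$participant_id[i]
    any(sel & nw$start < trips$end[i] & nw$end > trips$start[i])
  }, logical(1))
  trips
}

#' Surveyed-day accounting
#'
#' The mobility survey is only run on days meeting the study's inclusion
#' rule; this summarises the scheduled-vs-surveyed ledger.
#'
#' @param scheduled_days days scheduled per participant (scalar or vector).
#' @param surveyed_days number of surveyed days per participant (vector),
#'   or a single total.
#' @param n_participants participant count (defaults to
#'   `length(surveyed_days)`).
#' @return named vector: `scheduled`, `surveyed`, `excluded`.
#' @export
surveyed_day_ledger <- function(scheduled_days, surveyed_days,
                                n_participants = length(surveyed_days)) {
  sched <- if (length(scheduled_days) == 1) {
    scheduled_days * n_participants
  } else sum(scheduled_days)
  surv <- sum(surveyed_days)
  if (surv > sched) stop("more surveyed than scheduled days")
  c(scheduled = sched, surveyed = surv, excluded = sched - surv)
}
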