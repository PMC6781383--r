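# Emulation of the phone-administered GPS-based mobility survey: confirm,
# correct, recreate and clean the algorithm output against recall (the
# ground-truth diary stands in for the participant on the phone), and emit
# the validated timetable.

#' Recall model for the emulated mobility survey
#'
#' @param prob probability that a trip the GPS missed entirely is recalled
#'   and recreated during the survey.
#' @param noise_sd_s sd (s) of Gaussian noise on recalled boundary
#'   timestamps.
#' @return list of class `recall_model`.
#' @export
recall_model <- function(prob = 1.0, noise_sd_s = 0) {
  stopifnot(prob >= 0, prob <= 1, noise_sd_s >= 0)
  structure(list(prob = prob, noise_sd_s = noise_sd_s),
            class = "recall_model")
}

# group transport rows (stages/transfers) into moves by time contiguity
derive_moves <- function(segments) {
  tr <- segments[segments$kind %in% c("stage", "trip_stage", "transfer"), ,
                 drop = FALSE]
  tr <- tr[order(tr$start), , drop = FALSE]
  if (nrow(tr) == 0) {
    return(list(iv = data.frame(start = numeric(0), end = numeric(0)),
                geom = list(), stages = tr))
  }
  brk <- c(FALSE, tr$start[-1] - tr$end[-nrow(tr)] > 1e-6)
  gid <- cumsum(brk) + 1
  iv <- data.frame(
    start = tapply(tr$start, gid, min),
    end = tapply(tr$end, gid, max))
  geom <- lapply(split(seq_len(nrow(tr)), gid), function(idx) {
    g <- do.call(rbind, tr$geometry[idx])
    if (ncol(g) < 3) g <- cbind(g, t = NA_real_)
    if (nrow(g) > 1) {  # drop repeated boundary vertices (same timestamp)
      dup <- c(FALSE, !is.na(diff(g[, 3])) & diff(g[, 3]) == 0)
      g <- g[!dup, , drop = FALSE]
    }
    colnames(g) <- c("lon", "lat", "t")
    g
  })
  list(iv = iv, geom = unname(geom), stages = tr, gid = gid)
}

# the full retained fix sequence across all segments, ordered by time
full_track <- function(segments) {
  gs <- segments$geometry[vapply(segments$geometry, function(g)
    !is.null(g) && ncol(g) >= 3 && !all(is.na(g[, 3])), logical(1))]
  if (length(gs) == 0) return(NULL)
  g <- do.call(rbind, gs)
  g <- g[order(g[, 3]), , drop = FALSE]
  g <- g[!duplicated(g[, 3]), , drop = FALSE]
  colnames(g) <- c("lon", "lat", "t")
  g
}

# clip a timestamped polyline to [s, e], interpolating the boundary points
clip_geometry <- function(g, s, e) {
  if (is.null(g) || ncol(g) < 3 || all(is.na(g[, 3]))) return(NULL)
  t <- g[, 3]
  inside <- which(t >= s & t <= e)
  if (length(inside) == 0) return(NULL)
  rows <- g[inside, , drop = FALSE]
  a <- inside[1]
  if (a > 1 && t[a] > s) {
    w <- (s - t[a - 1]) / (t[a] - t[a - 1])
    rows <- rbind(c(g[a - 1, 1] + w * (g[a, 1] - g[a - 1, 1]),
                    g[a - 1, 2] + w * (g[a, 2] - g[a - 1, 2]), s), rows)
  }
  b <- inside[length(inside)]
  if (b < nrow(g) && t[b] < e) {
    w <- (e - t[b]) / (t[b + 1] - t[b])
    rows <- rbind(rows, c(g[b, 1] + w * (g[b + 1, 1] - g[b, 1]),
                          g[b, 2] + w * (g[b + 1, 2] - g[b, 2]), e))
  }
  colnames(rows) <- c("lon", "lat", "t")
  rows
}

add_time_col <- function(g, s, e) {
  if (ncol(g) >= 3) return(g)
  d <- chain_dist(g)
  tot <- d[length(d)]
  tt <- if (tot > 0) s + d / tot * (e - s) else seq(s, e, length.out = nrow(g))
  cbind(g, t = tt)
}

#' Remove residual artefacts from a stage track
#'
#' Emulates the manual track editing of the survey: vertices farther than
#' `corridor_m` from the reference (truth) polyline are dropped; when more
#' than half of the vertices would be dropped the reference polyline is
#' substituted wholesale (a full manual redraw).
#'
#' @param stage_polyline matrix (`lon`, `lat`[, `t`]).
#' @param truth_polyline reference polyline.
#' @param corridor_m corridor half-width (m).
#' @return cleaned polyline.
#' @export
clean_track <- function(stage_polyline, truth_polyline, corridor_m = 60) {
  stopifnot(nrow(stage_polyline) > 0, nrow(truth_polyline) > 0)
  d <- dist_to_polyline(stage_polyline[, 1:2, drop = FALSE], truth_polyline)
  keep <- d <= corridor_m
  if (mean(!keep) > 0.5 || sum(keep) < 2) {
    return(truth_polyline)
  }
  stage_polyline[keep, , drop = FALSE]
}

# jittered, order-preserving boundary timestamps
perturb_boundaries <- function(b, sd) {
  if (sd <= 0 || length(b) == 0) return(b)
  b2 <- b + rnorm(length(b), 0, sd)
  b2[1] <- max(b2[1], b[1] - 3 * sd)
  if (length(b2) > 1) {
    for (i in 2:length(b2)) b2[i] <- max(b2[i], b2[i - 1] + 0.5)
  }
  b2
}

#' Reconcile algorithm output with recall into a validated timetable
#'
#' Emulates the survey pass over the algorithm's segmentation: algorithm
#' trips with a ground-truth counterpart (interval intersection-over-union
#' >= `iou_min`) are kept with their GPS geometry clipped to the true stage
#' intervals, cleaned within `corridor_m` of the true itinerary, and given
#' the true modes and (optionally noise-perturbed) true boundary
#' timestamps; their source is `confirmed` when the imputed mode agreed
#' with recall and `corrected` otherwise. Algorithm trips with no truth
#' counterpart (e.g. pseudo-ambulation bursts) are removed. Truth trips the
#' algorithm missed are recalled with probability `recall$prob` and
#' recreated (`source = "recreated"`) with shortest street-network
#' itineraries for street modes and the surveyed itinerary for transit
#' rides; unrecalled missed trips dissolve into the surrounding visit.
#' Visits fill all remaining time, so each surveyed day is tiled exactly.
#'
#' @param algorithm_output segment data frame: visits plus labelled stages
#'   (and transfers) as produced by [detect_visits()] + [impute_modes()],
#'   or a previous timetable.
#' @param truth the participant's ground-truth diary.
#' @param recall a [recall_model()].
#' @param grid a [street_grid()] for recreating street itineraries (`NULL`
#'   falls back to the surveyed polyline).
#' @param corridor_m track-cleaning corridor (m).
#' @param iou_min interval intersection-over-union for trip matching.
#' @param seed optional integer seed for recall draws and timestamp noise.
#' @return timetable data frame: `participant_id`, `day`, `kind`
#'   (`visit`/`trip_stage`/`transfer`), `trip_id`, `mode`, `start`, `end`,
#'   `length_m`, `source`, `geometry`.
#' @export
reconcile <- function(algorithm_output, truth, recall = recall_model(),
                      grid = NULL, corridor_m = 60, iou_min = 0.5,
                      seed = NULL) {
  pa <- unique(algorithm_output$participant_id)
  pt <- unique(truth$participant_id)
  if (!setequal(pa[!is.na(pa)], pt)) {
    stop("identity error: algorithm output and truth cover different ",
         "participants")
  }
  if (!is.null(seed)) set.seed(seed)
  mv <- derive_moves(algorithm_output)
  track <- full_track(algorithm_output)
  stage_tab <- mv$stages[mv$stages$kind %in% c("stage", "trip_stage"), ,
                         drop = FALSE]
  truth <- truth[order(truth$start), , drop = FALSE]
  trip_ids <- unique(truth$trip_id[!is.na(truth$trip_id)])
  kept <- vector("list", length(trip_ids))
  for (k in seq_along(trip_ids)) {
    tid <- trip_ids[k]
    tt <- truth[!is.na(truth$trip_id) & truth$trip_id == tid, , drop = FALSE]
    ts <- min(tt$start); te <- max(tt$end)
    matched <- FALSE; mrow <- NULL
    if (nrow(mv$iv) > 0) {
      inter <- pmax(0, pmin(te, mv$iv$end) - pmax(ts, mv$iv$start))
      uni <- pmax(te, mv$iv$end) - pmin(ts, mv$iv$start)
      iou <- inter / uni
      if (max(iou) >= iou_min) {
        matched <- TRUE
        mrow <- which.max(iou)
      }
    }
    if (!matched && runif(1) >= recall$prob) next  # not recalled: dissolves
    b <- sort(unique(c(tt$start, tt$end)))
    b2 <- perturb_boundaries(b, recall$noise_sd_s)
    remap <- function(x) b2[match(x, b)]
    rows <- vector("list", nrow(tt))
    for (i in seq_len(nrow(tt))) {
      r <- tt[i, ]
      s2 <- remap(r$start); e2 <- remap(r$end)
      if (r$kind == "transfer") {
        g <- r$geometry[[1]][, 1:2, drop = FALSE]
        src <- if (matched) "confirmed" else "recreated"
        rows[[i]] <- timetable_row(r, "transfer", NA, s2, e2,
                                   add_time_col(g, s2, e2), src)
        next
      }
      truth_poly <- r$geometry[[1]][, 1:2, drop = FALSE]
      if (matched) {
        g <- clip_geometry(track, r$start, r$end)
        if (!is.null(g) && nrow(g) >= 2) {
          g <- clean_track(g, truth_poly, corridor_m)
          g <- complete_endpoints(g, truth_poly, s2, e2)
          g <- add_time_col(g, s2, e2)
          # did the imputation agree with recall over this stage?
          mid <- (r$start + r$end) / 2
          j <- which(stage_tab$start <= mid & stage_tab$end > mid)
          agreed <- length(j) > 0 && !is.na(stage_tab$mode[j[1]]) &&
            stage_tab$mode[j[1]] == mode_to_imputation(r$mode)
          src <- if (agreed) "confirmed" else "corrected"
        } else {  # matched trip but no GPS inside this stage: redrawn
          g <- add_time_col(recreate_geometry(r, grid, truth_poly), s2, e2)
          src <- "corrected"
        }
      } else {
        g <- add_time_col(recreate_geometry(r, grid, truth_poly), s2, e2)
        src <- "recreated"
      }
      rows[[i]] <- timetable_row(r, "trip_stage", r$mode, s2, e2, g, src)
    }
    kept[[k]] <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  }
  trips <- do.call(rbind, kept[!vapply(kept, is.null, logical(1))])
  fill_visits(trips, truth)
}

# complete a clipped track up to the surveyed stage endpoints (the survey
# recreated short missing segments, e.g. walks to/from transit stations)
complete_endpoints <- function(g, truth_poly, s, e, snap_m = 50) {
  if (ncol(g) < 3) g <- cbind(g, t = NA_real_)
  d0 <- hav1(g[1, 1], g[1, 2], truth_poly[1, 1], truth_poly[1, 2])
  if (d0 > 0.5 && d0 <= snap_m) {
    g <- rbind(c(truth_poly[1, 1], truth_poly[1, 2], s), g)
  }
  n <- nrow(truth_poly)
  d1 <- hav1(g[nrow(g), 1], g[nrow(g), 2], truth_poly[n, 1],
             truth_poly[n, 2])
  if (d1 > 0.5 && d1 <= snap_m) {
    g <- rbind(g, c(truth_poly[n, 1], truth_poly[n, 2], e))
  }
  colnames(g) <- c("lon", "lat", "t")
  g
}

recreate_geometry <- function(r, grid, truth_poly) {
  street <- !is.na(r$mode) &&
    r$mode %in% c("walk", "bike_roller_skateboard", "car_driver",
                  "car_passenger", "jogging", "dog_walking")
  if (street && !is.null(grid)) {
    p <- shortest_path_itinerary(truth_poly[1, 1:2],
                                 truth_poly[nrow(truth_poly), 1:2], grid)
    if (nrow(p) >= 2) return(p)
  }
  truth_poly
}

timetable_row <- function(r, kind, mode, s, e, g, src) {
  data.frame(participant_id = r$participant_id, day = r$day, kind = kind,
             trip_id = r$trip_id,
             mode = if (is.null(mode) || is.na(mode)) NA_character_ else mode,
             start = s, end = e,
             length_m = if (kind == "trip_stage") polyline_length(g) else 0,
             source = src, geometry = I(list(g)), stringsAsFactors = FALSE)
}

# tile each surveyed day: visits occupy everything outside kept trips
fill_visits <- function(trips, truth) {
  days <- sort(unique(truth$day))
  tv <- truth[truth$kind == "visit", , drop = FALSE]
  out <- list()
  for (d in days) {
    day0 <- (d - 1) * 86400
    dt <- if (is.null(trips)) NULL
          else trips[trips$day == d, , drop = FALSE]
    if (!is.null(dt) && nrow(dt) > 0) dt <- dt[order(dt$start), ]
    trip_bounds <- if (!is.null(dt) && nrow(dt) > 0) {
      # outer bounds of each trip (stages and transfers are contiguous)
      s <- tapply(dt$start, dt$trip_id, min)
      e <- tapply(dt$end, dt$trip_id, max)
      o <- order(s)
      as.vector(rbind(s[o], e[o]))
    } else NULL
    cuts <- c(day0, trip_bounds, day0 + 86400)
    gaps <- matrix(cuts, ncol = 2, byrow = TRUE)  # odd intervals are gaps
    for (gi in seq_len(nrow(gaps))) {
      s <- gaps[gi, 1]; e <- gaps[gi, 2]
      if (e - s <= 1e-9) next
      mid <- (s + e) / 2
      vj <- which(tv$start <= mid & tv$end > mid)
      loc <- if (length(vj) > 0) tv$geometry[[vj[1]]][1, 1:2]
             else c(NA_real_, NA_real_)
      row <- data.frame(participant_id = truth$participant_id[1], day = d,
                        kind = "visit", trip_id = NA_character_,
                        mode = NA_character_, start = s, end = e,
                        length_m = 0, source = "confirmed",
                        stringsAsFactors = FALSE)
      row$geometry <- list(cbind(lon = loc[1], lat = loc[2], t = s))
      out[[length(out) + 1]] <- row
    }
    if (!is.null(dt) && nrow(dt) > 0) out[[length(out) + 1]] <- dt
  }
  res <- do.call(rbind, out)
  res <- res[order(res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Per-day distances under the three measurement definitions
#'
#' Compares, per participant-day, (i) the quasi-raw GPS distance (speed
#' filter only), (ii) the algorithm-trip distance (sum of detected move
#' polylines), and (iii) the survey-corrected distance (sum of validated
#' trip-stage lengths), with median and interdecile summaries across
#' participant-days.
#'
#' @param raw_points speed-filtered points (all participants pooled).
#' @param algorithm_output detected/imputed segments (all participants).
#' @param timetable validated timetable ([reconcile()]).
#' @return list: `per_day` (participant, day, `raw_km`, `algorithm_km`,
#'   `survey_km`) and `summary` (rows raw/algorithm/survey with `median`,
#'   `p10`, `p90` in km).
#' @export
three_way_distance_report <- function(raw_points, algorithm_output,
                                      timetable) {
  raw <- raw_daily_distance(raw_points)
  algo <- algo_daily_distance(algorithm_output)
  st <- timetable[timetable$kind == "trip_stage", , drop = FALSE]
  surv <- stats::aggregate(
    data.frame(survey_m = st$length_m),
    by = list(participant_id = st$participant_id,
              day = floor(st$start / 86400) + 1), FUN = sum)
  days <- unique(timetable[c("participant_id", "day")])
  per <- merge(days, raw, all.x = TRUE)
  per <- merge(per, algo, all.x = TRUE)
  per <- merge(per, surv, all.x = TRUE)
  per[is.na(per)] <- 0
  per_day <- data.frame(participant_id = per$participant_id, day = per$day,
                        raw_km = per$distance_m / 1000,
                        algorithm_km = per$algo_m / 1000,
                        survey_km = per$survey_m / 1000)
  qs <- function(x) weighted_quantiles(x, rep(1, length(x)),
                                       c(0.5, 0.1, 0.9))
  summ <- data.frame(
    definition = c("raw", "algorithm", "survey"),
    rbind(qs(per_day$raw_km), qs(per_day$algorithm_km),
          qs(per_day$survey_km)))
  names(summ)[2:4] <- c("median", "p10", "p90")
  list(per_day = per_day[order(per_day$participant_id, per_day$day), ],
       summary = summ)
}

algo_daily_distance <- function(algorithm_output) {
  pids <- unique(algorithm_output$participant_id)
  out <- list()
  for (p in pids) {
    mv <- derive_moves(
      algorithm_output[algorithm_output$participant_id == p, , drop = FALSE])
    if (nrow(mv$iv) == 0) next
    len <- vapply(mv$geom, polyline_length, numeric(1))
    out[[p]] <- data.frame(participant_id = p,
                           day = floor(mv$iv$start / 86400) + 1,
                           algo_m = len)
  }
  if (length(out) == 0) {
    return(data.frame(participant_id = character(0), day = integer(0),
                      algo_m = numeric(0)))
  }
  all <- do.call(rbind, out)
  stats::aggregate(data.frame(algo_m = all$algo_m),
                   by = list(participant_id = all$participant_id,
                             day = all$day), FUN = sum)
}
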