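# GPS renderer: turns a ground-truth diary into a raw point stream with the
# artefacts a wearable receiver produces (indoor jitter, pseudo-ambulation
# bursts, whole-trip dropout).

# autocorrelated (AR1) noise with stationary sd `sd`
ar_noise <- function(n, sd, phi) {
  if (n == 0) return(numeric(0))
  if (sd <= 0) return(numeric(n))
  e <- rnorm(n, 0, sd * sqrt(max(1 - phi^2, 1e-9)))
  as.numeric(stats::filter(e, phi, method = "recursive"))
}

pid_number <- function(pid) {
  n <- suppressWarnings(as.integer(gsub("[^0-9]", "", pid)))
  if (is.na(n)) sum(utf8ToInt(pid)) else n
}

# sampling instants on the global gps grid inside [start, end)
grid_times <- function(start, end, period) {
  t0 <- ceiling(start / period) * period
  if (t0 >= end) return(numeric(0))
  seq(t0, end - 1e-9, by = period)
}

#' Render a raw GPS point stream from a diary
#'
#' Emits one fix every `cfg$gps_period_s` seconds (on a grid aligned to the
#' study origin). During trip stages fixes advance along the stage polyline
#' at the stage's constant speed, with autocorrelated track noise of
#' stationary sd `cfg$track_noise_m`. At visits and transfers the receiver
#' sits at the location with autocorrelated jitter (`cfg$jitter_sd_m`);
#' additionally, pseudo-ambulation bursts (spurious indoor random walks of
#' `cfg$pa_burst_points` fixes with per-coordinate step sd
#' `cfg$pa_step_sd_m`) occur as a Poisson process with rate
#' `cfg$pseudo_ambulation_rate` per visit-hour. With probability
#' `cfg$dropout_prob` a whole trip (stages and transfers) leaves no points,
#' emulating a receiver left behind.
#'
#' Deterministic given `(cfg$seed, participant)`.
#'
#' @param diary one participant's diary (see [generate_world()]).
#' @param cfg a [tw_config()].
#' @return data frame `participant_id`, `time` (s), `lon`, `lat`, sorted by
#'   time.
#' @export
render_gps <- function(diary, cfg = tw_config()) {
  stopifnot(nrow(diary) > 0)
  pid <- diary$participant_id[1]
  set.seed(stream_seed(cfg$seed, pid_number(pid), "gps"))
  P <- cfg$gps_period_s
  trip_ids <- unique(diary$trip_id[!is.na(diary$trip_id)])
  dropped <- trip_ids[runif(length(trip_ids)) < cfg$dropout_prob]
  out <- vector("list", nrow(diary))
  for (i in seq_len(nrow(diary))) {
    row <- diary[i, ]
    ts <- grid_times(row$start, row$end, P)
    if (length(ts) == 0) next
    g <- row$geometry[[1]]
    if (row$kind == "stage") {
      if (row$trip_id %in% dropped) next
      vehicle <- !row$mode %in% c("walk", "jogging", "dog_walking")
      loss_p <- cfg$signal_loss[row$mode]
      if (vehicle && !is.na(loss_p) && runif(1) < loss_p) next  # underground
      len <- polyline_length(g)
      d_along <- len * (ts - row$start) / max(row$end - row$start, 1e-9)
      if (vehicle && cfg$ride_progress_noise_m > 0) {
        d_along <- pmin(pmax(d_along +
          ar_noise(length(ts), cfg$ride_progress_noise_m,
                   cfg$ride_progress_ar), 0), len)
      }
      pos <- interpolate_along(g, d_along)
      dx <- ar_noise(length(ts), cfg$track_noise_m, cfg$track_noise_ar)
      dy <- ar_noise(length(ts), cfg$track_noise_m, cfg$track_noise_ar)
      pos <- offset_lonlat(pos[, "lon"], pos[, "lat"], dx, dy)
    } else {
      if (row$kind == "transfer" && row$trip_id %in% dropped) next
      base <- g[1, , drop = FALSE]
      dx <- ar_noise(length(ts), cfg$jitter_sd_m, cfg$jitter_ar)
      dy <- ar_noise(length(ts), cfg$jitter_sd_m, cfg$jitter_ar)
      if (row$kind == "visit" && cfg$pseudo_ambulation_rate > 0) {
        dur_h <- (row$end - row$start) / 3600
        nb <- rpois(1, cfg$pseudo_ambulation_rate * dur_h)
        for (b in seq_len(nb)) {
          m <- min(cfg$pa_burst_points, length(ts))
          s0 <- sample.int(max(length(ts) - m + 1, 1), 1)
          idx <- s0:(s0 + m - 1)
          dx[idx] <- dx[idx] + cumsum(rnorm(m, 0, cfg$pa_step_sd_m))
          dy[idx] <- dy[idx] + cumsum(rnorm(m, 0, cfg$pa_step_sd_m))
        }
      }
      pos <- offset_lonlat(rep(base[1, 1], length(ts)),
                           rep(base[1, 2], length(ts)), dx, dy)
    }
    out[[i]] <- data.frame(participant_id = pid, time = ts,
                           lon = pos[, "lon"], lat = pos[, "lat"])
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  res <- res[order(res$time), , drop = FALSE]
  # the diary tiles time, so grid instants are unique; drop any duplicates
  res <- res[!duplicated(res$time), , drop = FALSE]
  rownames(res) <- NULL
  res
}
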