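# Accelerometer link: nonwear detection from vector-magnitude counts and
# timestamp-joining of per-epoch steps onto timetable segments.

#' Detect accelerometer nonwear (Choi-style) from vector magnitude
#'
#' A nonwear bout is a run of zero-VM epochs of at least `window_min`
#' minutes, allowing nonzero interruptions of up to `spike_tolerance_min`
#' minutes when flanked on both sides by at least `flank_min` minutes of
#' zeros. Implemented on the epoch grid of the input (an approximation of
#' the ActiLife implementation, which re-integrates to 1-s data).
#'
#' @param epochs gapless epoch data frame (`participant_id`, `day`,
#'   `start`, `end`, `vm`, `steps`), e.g. from [render_accel()].
#' @param window_min minimum bout length (min).
#' @param spike_tolerance_min maximum tolerated interruption (min).
#' @param flank_min required zero flank around an interruption (min).
#' @return list of class `wear_mask`: `nonwear` and `wear` interval data
#'   frames (`participant_id`, `day`, `start`, `end`), `wear_seconds` per
#'   participant-day, and `epochs_cover` (the epoch grid coverage).
#' @export
detect_nonwear <- function(epochs, window_min = 90, spike_tolerance_min = 2,
                           flank_min = 30) {
  ep_s <- unique(epochs$end - epochs$start)
  if (length(ep_s) != 1) stop("grid error: mixed epoch lengths")
  keys <- unique(epochs[c("participant_id", "day")])
  nonwear <- list()
  wear <- list()
  wear_sec <- list()
  for (r in seq_len(nrow(keys))) {
    e <- epochs[epochs$participant_id == keys$participant_id[r] &
                  epochs$day == keys$day[r], , drop = FALSE]
    e <- e[order(e$start), , drop = FALSE]
    if (any(abs(diff(e$start) - ep_s) > 1e-9)) {
      stop("grid error: gaps in the epoch grid")
    }
    bouts <- nonwear_bouts(e$vm, ep_s, window_min * 60,
                           spike_tolerance_min * 60, flank_min * 60)
    lo <- min(e$start); hi <- max(e$end)
    nw <- if (nrow(bouts) > 0) {
      data.frame(participant_id = keys$participant_id[r], day = keys$day[r],
                 start = lo + bouts$from, end = lo + bouts$to)
    } else NULL
    nonwear[[r]] <- nw
    cuts <- c(lo, if (!is.null(nw)) as.vector(rbind(nw$start, nw$end)), hi)
    gp <- matrix(cuts, ncol = 2, byrow = TRUE)
    gp <- gp[gp[, 2] - gp[, 1] > 1e-9, , drop = FALSE]
    wear[[r]] <- if (nrow(gp) > 0) {
      data.frame(participant_id = keys$participant_id[r], day = keys$day[r],
                 start = gp[, 1], end = gp[, 2])
    } else NULL
    wear_sec[[r]] <- data.frame(
      participant_id = keys$participant_id[r], day = keys$day[r],
      wear_s = if (nrow(gp) > 0) sum(gp[, 2] - gp[, 1]) else 0)
  }
  rb <- function(x) {
    x <- x[!vapply(x, is.null, logical(1))]
    if (length(x) == 0) {
      data.frame(participant_id = character(0), day = integer(0),
                 start = numeric(0), end = numeric(0))
    } else do.call(rbind, x)
  }
  structure(list(nonwear = rb(nonwear), wear = rb(wear),
                 wear_seconds = do.call(rbind, wear_sec),
                 epochs_cover = keys),
            class = "wear_mask")
}

# zero-run/bout logic on one day's vm vector; offsets in seconds from the
# first epoch
nonwear_bouts <- function(vm, ep_s, window_s, spike_s, flank_s) {
  r <- rle(vm == 0)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(zero = r$values, from = (starts - 1) * ep_s,
                     to = ends * ep_s)
  # merge zero runs across tolerated spikes flanked by long-enough zeros
  repeat {
    zi <- which(runs$zero)
    merged <- FALSE
    for (k in seq_along(zi)) {
      if (k == length(zi)) break
      a <- zi[k]; b <- zi[k + 1]
      if (b - a == 2 && !runs$zero[a + 1]) {
        gap <- runs$to[a + 1] - runs$from[a + 1]
        left <- runs$to[a] - runs$from[a]
        right <- runs$to[b] - runs$from[b]
        if (gap <= spike_s && left >= flank_s && right >= flank_s) {
          runs <- rbind(
            if (a > 1) runs[1:(a - 1), ],
            data.frame(zero = TRUE, from = runs$from[a], to = runs$to[b]),
            if (b < nrow(runs)) runs[(b + 1):nrow(runs), ])
          merged <- TRUE
          break
        }
      }
    }
    if (!merged) break
  }
  b <- runs[runs$zero & (runs$to - runs$from) >= window_s, c("from", "to"),
            drop = FALSE]
  rownames(b) <- NULL
  b
}

#' Join per-epoch steps onto timetable segments
#'
#' Each epoch's steps are assigned to the segment containing the epoch
#' midpoint, so totals are conserved exactly: every epoch within the
#' timetable span contributes to exactly one segment.
#'
#' @param epochs accelerometer epochs.
#' @param timetable a segment table tiling each surveyed day.
#' @return `timetable` with a `steps` column.
#' @export
steps_per_segment <- function(epochs, timetable) {
  timetable$steps <- 0
  for (p in unique(timetable$participant_id)) {
    tt_i <- which(timetable$participant_id == p)
    tt <- timetable[tt_i, , drop = FALSE]
    e <- epochs[epochs$participant_id == p, , drop = FALSE]
    if (nrow(e) == 0 || min(e$start) > min(tt$start) ||
        max(e$end) < max(tt$end)) {
      stop("coverage error: timetable extends beyond the epoch grid for ",
           p)
    }
    o <- order(tt$start)
    mid <- (e$start + e$end) / 2
    idx <- findInterval(mid, tt$start[o])
    ok <- idx >= 1
    ok[ok] <- mid[ok] < tt$end[o][idx[ok]]
    s <- tapply(e$steps[ok], idx[ok], sum)
    add <- setNames(numeric(nrow(tt)), seq_len(nrow(tt)))
    add[names(s)] <- s
    timetable$steps[tt_i[o]] <- as.numeric(add)
  }
  timetable
}

#' Steps per unit of 8 h accelerometer wear
#'
#' The denominator is the number of 8-hour units of wear time, so days with
#' partial wear remain comparable.
#'
#' @param trip_steps total steps (count).
#' @param wear a `wear_mask`, or wear seconds directly.
#' @return steps per 8 h of wear.
#' @export
steps_per_8h_wear <- function(trip_steps, wear) {
  wear_s <- if (inherits(wear, "wear_mask")) {
    sum(wear$wear_seconds$wear_s)
  } else as.numeric(wear)
  if (wear_s <= 0) stop("undefined rate: zero wear time")
  trip_steps / (wear_s / 28800)
}
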