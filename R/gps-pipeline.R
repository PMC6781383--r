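# Algorithm-only GPS processing: speed filter, visited-place detection,
# trip extraction, and decomposition of moves into candidate unimodal
# stages.

#' Exclude GPS points below a speed limit
#'
#' Sequentially retains points whose speed relative to the previously
#' *retained* point is at least `threshold_kmh` (default 1 km/h); the first
#' point is always retained. The returned `speed_kmh` column holds the
#' speed against the retained predecessor (0 for the first point).
#'
#' The speed is a local estimate: displacement from the retained
#' predecessor divided by the elapsed time capped at `max_window_s`.
#' Without the cap, a receiver that sits still for hours (every fix
#' excluded) would need kilometres of displacement before any later fix
#' could reach 1 km/h, masking genuine movement onsets after long visits.
#'
#' @param points data frame with `time` (s, strictly increasing), `lon`,
#'   `lat` (and optionally `participant_id`).
#' @param threshold_kmh speed limit in km/h.
#' @param max_window_s cap (s) on the time base of the speed estimate.
#' @return the retained subset of `points` with a `speed_kmh` column.
#' @export
filter_low_speed <- function(points, threshold_kmh = 1.0,
                             max_window_s = 15) {
  n <- nrow(points)
  if (n == 0) {
    points$speed_kmh <- numeric(0)
    return(points)
  }
  t <- points$time
  if (is.unsorted(t, strictly = TRUE)) {
    stop("ordering error: timestamps must be strictly increasing")
  }
  p <- pi / 180
  lonr <- points$lon * p
  latr <- points$lat * p
  coslat <- cos(latr)
  keep <- logical(n)
  speed <- numeric(n)
  keep[1] <- TRUE
  li <- 1  # index of last retained point
  thr_ms <- threshold_kmh / 3.6
  for (i in 2:n) {
    dlat <- (latr[i] - latr[li]) / 2
    dlon <- (lonr[i] - lonr[li]) / 2
    a <- sin(dlat)^2 + coslat[i] * coslat[li] * sin(dlon)^2
    d <- 2 * EARTH_R * asin(sqrt(a))
    v <- d / min(t[i] - t[li], max_window_s)
    if (v >= thr_ms) {
      keep[i] <- TRUE
      speed[i] <- v * 3.6
      li <- i
    }
  }
  out <- points[keep, , drop = FALSE]
  out$speed_kmh <- speed[keep]
  rownames(out) <- NULL
  out
}

#' Detect visited places and moves in a filtered track
#'
#' Greedy running-centroid clustering: starting from the current point, the
#' cluster absorbs successive points while each stays within `radius_m` of
#' the running centroid. A cluster whose time span (first cluster point to
#' the first point after the cluster, since the receiver only logs movement
#' past the speed filter) reaches `dwell_min_s` becomes a visit; everything
#' between two visits becomes one move. Visits and moves tile the observed
#' time span.
#'
#' @param points speed-filtered points ([filter_low_speed()]).
#' @param dwell_min_s minimum dwell time for a visit (s).
#' @param radius_m cluster radius (m).
#' @return data frame of candidate segments: `participant_id`, `kind`
#'   (`visit`/`move`), `start`, `end`, `lon`, `lat` (representative location
#'   for visits), and a `geometry` list-column (columns `lon`, `lat`, `t`;
#'   move polylines are anchored at the neighbouring visit locations).
#' @export
detect_visits <- function(points, dwell_min_s = 300, radius_m = 50) {
  n <- nrow(points)
  empty <- data.frame(participant_id = character(0), kind = character(0),
                      start = numeric(0), end = numeric(0),
                      lon = numeric(0), lat = numeric(0))
  empty$geometry <- list()
  if (n == 0) return(empty)
  pid <- if ("participant_id" %in% names(points)) points$participant_id[1]
         else NA_character_
  t <- points$time
  lon <- points$lon
  lat <- points$lat
  lab <- integer(n)  # 0 = move point, k>0 = cluster k
  clus <- 0L
  i <- 1L
  while (i <= n) {
    cx <- lon[i]; cy <- lat[i]
    j <- i + 1L
    while (j <= n && hav1(lon[j], lat[j], cx, cy) <= radius_m) {
      m <- j - i + 1
      cx <- cx + (lon[j] - cx) / m
      cy <- cy + (lat[j] - cy) / m
      j <- j + 1L
    }
    span_end <- if (j <= n) t[j] else t[n]
    if (span_end - t[i] >= dwell_min_s) {
      clus <- clus + 1L
      lab[i:(j - 1L)] <- clus
      i <- j
    } else {
      i <- i + 1L
    }
  }
  # assemble alternating visit / move segments from the point labels
  r <- rle(lab > 0)
  idx_end <- cumsum(r$lengths)
  idx_start <- idx_end - r$lengths + 1L
  segs <- vector("list", length(r$values))
  for (k in seq_along(r$values)) {
    a <- idx_start[k]; b <- idx_end[k]
    nxt <- if (k < length(r$values)) t[idx_start[k + 1]] else t[n]
    if (r$values[k]) {  # visit: keep member fixes for later track editing
      segs[[k]] <- data.frame(
        participant_id = pid, kind = "visit", start = t[a], end = nxt,
        lon = mean(lon[a:b]), lat = mean(lat[a:b]))
      segs[[k]]$geometry <- list(cbind(lon = lon[a:b], lat = lat[a:b],
                                       t = t[a:b]))
    } else {            # move, anchored at the neighbouring visit points
      a2 <- max(a - 1L, 1L)
      b2 <- min(b + 1L, n)
      g <- cbind(lon = lon[a2:b2], lat = lat[a2:b2], t = t[a2:b2])
      segs[[k]] <- data.frame(
        participant_id = pid, kind = "move", start = t[a], end = nxt,
        lon = NA_real_, lat = NA_real_)
      segs[[k]]$geometry <- list(g)
    }
  }
  out <- do.call(rbind, segs)
  if (nrow(out) > 0) out$end[nrow(out)] <- t[n]
  rownames(out) <- NULL
  out
}

# per-vertex smoothed speed (km/h) of a move polyline with a time column
smoothed_speeds <- function(g, k = 5) {
  n <- nrow(g)
  if (n < 2) return(rep(0, n))
  d <- hav_m(g[-n, 1], g[-n, 2], g[-1, 1], g[-1, 2])
  dt <- pmax(diff(g[, 3]), 1e-9)
  v <- c(d[1], d) / c(dt[1], dt) * 3.6  # speed entering each vertex
  if (n >= k) as.numeric(stats::runmed(v, k)) else v
}

#' Split a move into candidate unimodal stages
#'
#' Splits where the smoothed point speed (centred rolling median over
#' `smooth_k` points) crosses the walk/vehicle band boundary
#' (`split_kmh`); each split vertex is snapped to a transit station when
#' one lies within `snap_m` of a vertex inside the smoothing window, since
#' true mode changes on public transport happen at stations. The output
#' intervals partition the move interval exactly.
#'
#' @param move one row of [detect_visits()] output with `kind == "move"`.
#' @param network a [transit_network()] (or `NULL` to skip station
#'   snapping).
#' @param split_kmh walk/vehicle boundary speed.
#' @param snap_m station snap radius (m).
#' @param smooth_k rolling-median window (points).
#' @param min_stage_s candidate stages shorter than this are merged into
#'   their neighbour (guards against single-fix speed flickers).
#' @return data frame of stage candidate segments with the same columns as
#'   [detect_visits()], `kind == "stage"`.
#' @export
split_stages <- function(move, network = NULL, split_kmh = 7,
                         snap_m = 75, smooth_k = 5, min_stage_s = 30) {
  g <- move$geometry[[1]]
  stopifnot(nrow(g) >= 2)
  v <- smoothed_speeds(g, smooth_k)
  band <- v >= split_kmh
  r <- rle(band)
  # absorb flickers shorter than min_stage_s into the preceding run
  if (length(r$lengths) > 1) {
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep_run <- (g[ends, 3] - g[starts, 3]) >= min_stage_s
    keep_run[1] <- TRUE
    bnd <- starts[-1][keep_run[-1]]
  } else {
    bnd <- integer(0)
  }
  # snap each split vertex to a nearby transit station within the window
  if (!is.null(network) && length(bnd) > 0) {
    for (q in seq_along(bnd)) {
      w <- max(1, bnd[q] - smooth_k):min(nrow(g), bnd[q] + smooth_k)
      dmin <- vapply(w, function(ii) {
        st <- stations_within(network, g[ii, 1], g[ii, 2], snap_m)
        if (nrow(st) == 0) Inf else min(hav_m(g[ii, 1], g[ii, 2],
                                              st$lon, st$lat))
      }, numeric(1))
      if (any(is.finite(dmin))) bnd[q] <- w[which.min(dmin)]
    }
    bnd <- sort(unique(bnd))
    bnd <- bnd[bnd > 1 & bnd <= nrow(g)]
  }
  cuts <- c(1L, bnd, nrow(g) + 1L)
  out <- vector("list", length(cuts) - 1)
  for (k in seq_len(length(cuts) - 1)) {
    a <- cuts[k]
    b <- cuts[k + 1] - 1L
    a0 <- if (k == 1) a else a - 1L  # share the boundary vertex
    gg <- g[a0:b, , drop = FALSE]
    s <- if (k == 1) move$start else g[a, 3]
    e <- if (k == length(cuts) - 1) move$end else g[cuts[k + 1], 3]
    out[[k]] <- data.frame(participant_id = move$participant_id,
                           kind = "stage", start = s, end = e,
                           lon = NA_real_, lat = NA_real_)
    out[[k]]$geometry <- list(gg)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Quasi-raw distance per participant-day
#'
#' Sum of haversine distances between consecutive retained points, grouped
#' by (participant, day); consecutive points on different days do not
#' contribute.
#'
#' @param points speed-filtered points.
#' @return data frame `participant_id`, `day`, `distance_m`.
#' @export
raw_daily_distance <- function(points) {
  if (nrow(points) < 2) {
    return(data.frame(participant_id = character(0), day = integer(0),
                      distance_m = numeric(0)))
  }
  pid <- if ("participant_id" %in% names(points)) points$participant_id
         else rep(NA_character_, nrow(points))
  day <- floor(points$time / 86400) + 1
  n <- nrow(points)
  d <- hav_m(points$lon[-n], points$lat[-n], points$lon[-1], points$lat[-1])
  same <- day[-n] == day[-1] & pid[-n] == pid[-1]
  if (!any(same)) {
    return(data.frame(participant_id = character(0), day = integer(0),
                      distance_m = numeric(0)))
  }
  agg <- stats::aggregate(
    data.frame(distance_m = d[same]),
    by = list(participant_id = pid[-n][same], day = day[-n][same]),
    FUN = sum)
  agg[order(agg$participant_id, agg$day), , drop = FALSE]
}
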