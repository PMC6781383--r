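# Headline metrics: distance walked, step attribution, walking intensity,
# weighted quantiles, urbanicity stratification, Kruskal-Wallis.

#' Weighted quantiles (inverse-CDF definition)
#'
#' Quantile `q` is the smallest value whose cumulative normalised weight
#' reaches `q`. With unit weights this is the ordinary type-1 empirical
#' quantile.
#'
#' @param values numeric vector.
#' @param weights nonnegative weights, positive total.
#' @param probs probabilities in `[0, 1]`.
#' @return numeric vector of quantiles, one per element of `probs`.
#' @export
weighted_quantiles <- function(values, weights = rep(1, length(values)),
                               probs = c(0.5, 0.1, 0.9)) {
  stopifnot(length(values) == length(weights))
  if (any(weights < 0)) stop("domain error: negative weight")
  if (any(probs < 0 | probs > 1)) stop("domain error: probs outside [0,1]")
  tot <- sum(weights)
  if (tot <= 0) stop("domain error: weights sum to zero")
  o <- order(values)
  v <- values[o]
  cw <- cumsum(weights[o]) / tot
  vapply(probs, function(p) v[which(cw >= p - 1e-12)[1]], numeric(1))
}

#' Median / 10th / 90th percentile summary
#'
#' @param values,weights as in [weighted_quantiles()].
#' @return list with `median`, `p10`, `p90`.
#' @export
quantile_summary <- function(values, weights = rep(1, length(values))) {
  q <- weighted_quantiles(values, weights, c(0.5, 0.1, 0.9))
  list(median = q[1], p10 = q[2], p90 = q[3])
}

#' Distance walked in one trip
#'
#' Sum of polyline lengths over the trip's walking stages; transfer
#' episodes are point locations and contribute no distance.
#'
#' @param trip segment data frame for one trip (`kind`, `mode`,
#'   `length_m`).
#' @return metres walked.
#' @export
distance_walked_per_trip <- function(trip) {
  st <- trip[trip$kind %in% c("stage", "trip_stage"), , drop = FALSE]
  sum(st$length_m[st$mode == "walk"])
}

#' Per-trip metrics table
#'
#' One row per retained trip with total and walked distance, walked
#' duration, trip steps (stages + transfers), classes and the
#' participant's urbanicity zone.
#'
#' @param segments retained trip segments (with `steps` if accelerometry is
#'   linked).
#' @param trips the [assemble_trips()] table for the same segments.
#' @param participants participant table (for `zone`), or `NULL`.
#' @return data frame keyed by `trip_id`.
#' @export
build_metrics_table <- function(segments, trips, participants = NULL) {
  has_steps <- "steps" %in% names(segments)
  rows <- lapply(seq_len(nrow(trips)), function(i) {
    g <- segments[segments$trip_id == trips$trip_id[i], , drop = FALSE]
    st <- g[g$kind %in% c("stage", "trip_stage"), , drop = FALSE]
    walk <- st[st$mode == "walk", , drop = FALSE]
    data.frame(
      trip_id = trips$trip_id[i],
      participant_id = trips$participant_id[i], day = trips$day[i],
      crude_class = trips$crude_class[i],
      detailed_class = trips$detailed_class[i],
      distance_total_km = sum(st$length_m) / 1000,
      distance_walked_km = sum(walk$length_m) / 1000,
      duration_walked_s = sum(walk$end - walk$start),
      steps_trip = if (has_steps) sum(g$steps) else NA_real_,
      stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (!is.null(participants)) {
    tab$zone <- participants$zone[
      match(tab$participant_id, participants$participant_id)]
  }
  tab
}

#' Percentage of a metric attributable to each trip class
#'
#' @param table a [build_metrics_table()] table.
#' @param metric `"distance_walked"` or `"steps"`.
#' @param scheme `"crude"` or `"detailed"`.
#' @return named percentages summing to 100.
#' @export
attribution_shares <- function(table, metric = c("distance_walked", "steps"),
                               scheme = c("crude", "detailed")) {
  metric <- match.arg(metric)
  scheme <- match.arg(scheme)
  if (nrow(table) == 0) stop("empty metrics table")
  x <- switch(metric, distance_walked = table$distance_walked_km,
              steps = table$steps_trip)
  cls <- table[[paste0(scheme, "_class")]]
  tot <- sum(x)
  if (!is.finite(tot) || tot <= 0) {
    stop("undefined share: metric total is zero")
  }
  s <- tapply(x, cls, sum) / tot * 100
  s <- setNames(as.numeric(s), names(s))
  s[order(names(s))]
}

#' Per-participant-day cumulations of a metric by class
#'
#' Every participant-day present in the table contributes a value for
#' every class, including zeros for classes the participant did not use
#' that day.
#'
#' @param table a [build_metrics_table()] table.
#' @param metric column to cumulate (`distance_walked_km`,
#'   `distance_total_km` or `steps_trip`).
#' @param scheme classification scheme.
#' @return data frame `participant_id`, `day`, `class`, `value`.
#' @export
daily_class_totals <- function(table, metric = "distance_walked_km",
                               scheme = "crude") {
  cls_col <- paste0(scheme, "_class")
  days <- unique(table[c("participant_id", "day")])
  classes <- sort(unique(table[[cls_col]]))
  out <- expand.grid(i = seq_len(nrow(days)), class = classes,
                     stringsAsFactors = FALSE)
  out <- data.frame(participant_id = days$participant_id[out$i],
                    day = days$day[out$i], class = out$class)
  key <- paste(table$participant_id, table$day, table[[cls_col]])
  agg <- tapply(table[[metric]], key, sum)
  out$value <- agg[paste(out$participant_id, out$day, out$class)]
  out$value[is.na(out$value)] <- 0
  out
}

#' Walking-intensity summaries
#'
#' Walking speed (km/h) and cadence (steps/min) for entirely walked trips
#' and for the walking stages of public-transport trips, overall and by PT
#' sub-mode. Speed summaries weight trips/stages by distance walked;
#' cadence summaries weight by duration walked. Zero-duration stages are
#' skipped with a warning.
#'
#' @param segments retained trip segments with `steps`.
#' @param trips classified trip table.
#' @return data frame: `group`, `n`, then speed and cadence
#'   median/p10/p90.
#' @export
walking_intensity <- function(segments, trips) {
  st <- segments[segments$kind %in% c("stage", "trip_stage") &
                   segments$mode == "walk", , drop = FALSE]
  dur <- st$end - st$start
  if (any(dur <= 0)) {
    warning("skipping ", sum(dur <= 0), " zero-duration walking stage(s)")
    st <- st[dur > 0, , drop = FALSE]
    dur <- st$end - st$start
  }
  st$speed_kmh <- st$length_m / dur * 3.6
  st$cadence_spm <- st$steps / (dur / 60)
  cls <- trips$detailed_class[match(st$trip_id, trips$trip_id)]
  crude <- trips$crude_class[match(st$trip_id, trips$trip_id)]
  groups <- list(
    entirely_walked = which(crude == "entirely_walked"),
    pt_all = which(crude == "public_transport"),
    bus_coach = which(cls == "bus_coach"),
    metro = which(cls == "metro"),
    suburban_train = which(cls == "suburban_train"),
    tramway = which(cls == "tramway"))
  out <- lapply(names(groups), function(g) {
    idx <- groups[[g]]
    if (length(idx) == 0) return(NULL)
    s <- st[idx, , drop = FALSE]
    sq <- weighted_quantiles(s$speed_kmh, s$length_m, c(0.5, 0.1, 0.9))
    cq <- weighted_quantiles(s$cadence_spm, s$end - s$start,
                             c(0.5, 0.1, 0.9))
    data.frame(group = g, n = length(idx),
               speed_median = sq[1], speed_p10 = sq[2], speed_p90 = sq[3],
               cadence_median = cq[1], cadence_p10 = cq[2],
               cadence_p90 = cq[3], stringsAsFactors = FALSE)
  })
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}

#' Kruskal-Wallis rank test across groups
#'
#' Tie-corrected H statistic with a chi-square reference on k-1 degrees of
#' freedom. The degenerate all-identical case returns H = 0, p = 1.
#'
#' @param groups list of >= 2 non-empty numeric samples.
#' @return list: `statistic` (H), `df`, `p.value`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(length(groups) >= 2, all(lengths(groups) > 0))
  x <- unlist(groups)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (length(unique(x)) == 1) {
    return(list(statistic = 0, df = length(groups) - 1, p.value = 1))
  }
  kt <- stats::kruskal.test(x, g)
  list(statistic = unname(kt$statistic), df = unname(kt$parameter),
       p.value = kt$p.value)
}

#' Urbanicity-stratified metrics
#'
#' Recomputes the headline metrics within each residence zone: the
#' participant-day median distance walked (all trips pooled, zero days
#' included), the attribution shares of distance walked and steps, and a
#' monotone-contrast flag for the public-transport share across
#' core city / close suburb / far suburb.
#'
#' @param table a [build_metrics_table()] table with a `zone` column.
#' @param scheme classification scheme for the shares.
#' @return list: `per_zone` (data frame of medians), `shares_walked`,
#'   `shares_steps` (class x zone matrices), `pt_share_decreasing`.
#' @export
urbanicity_strata <- function(table, scheme = "crude") {
  stopifnot("zone" %in% names(table))
  zones <- c("core_city", "close_suburb", "far_suburb")
  present <- zones[zones %in% table$zone]
  if (length(present) < length(zones)) {
    warning("zones with no participants omitted: ",
            paste(setdiff(zones, present), collapse = ", "))
  }
  per_zone <- list()
  shares_w <- list()
  shares_s <- list()
  for (z in present) {
    tz <- table[table$zone == z, , drop = FALSE]
    per_day <- tapply(tz$distance_walked_km,
                      paste(tz$participant_id, tz$day), sum)
    per_zone[[z]] <- data.frame(
      zone = z, n_trips = nrow(tz),
      median_daily_walked_km = unname(median(per_day)))
    shares_w[[z]] <- attribution_shares(tz, "distance_walked", scheme)
    if (!all(is.na(tz$steps_trip))) {
      shares_s[[z]] <- attribution_shares(tz, "steps", scheme)
    }
  }
  all_cls <- sort(unique(table[[paste0(scheme, "_class")]]))
  mat <- function(lst) {
    m <- sapply(lst, function(s) {
      v <- setNames(numeric(length(all_cls)), all_cls)
      v[names(s)] <- s
      v
    })
    if (is.null(dim(m))) m <- matrix(m, ncol = length(lst),
                                     dimnames = list(all_cls, names(lst)))
    m
  }
  sw <- mat(shares_w)
  pt_dec <- if ("public_transport" %in% rownames(sw) && ncol(sw) == 3) {
    all(diff(sw["public_transport", zones]) < 0)
  } else NA
  list(per_zone = do.call(rbind, per_zone),
       shares_walked = sw,
       shares_steps = if (length(shares_s) > 0) mat(shares_s) else NULL,
       pt_share_decreasing = pt_dec)
}
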