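# Mode imputation for candidate trip stages: linear score combining a
# speed-band match, transit-station proximity evidence, and the
# participant's habitual-mode prior.

#' Default imputation parameters
#'
#' Speed bands (km/h, half-open) per imputable mode, the evidence weights,
#' and the long-distance overrides. All exposed so sensitivity analyses can
#' move them.
#'
#' @return list with `bands`, `weights`, `long_distance_kmh`,
#'   `long_distance_min_m`, `snap_m`.
#' @export
imputation_params <- function() {
  list(
    bands = list(walk = c(0, 7), bike = c(7, 16), bus = c(7, 40),
                 tramway = c(7, 40), metro = c(15, 50),
                 suburban_train = c(30, 120), car = c(7, 130)),
    weights = c(speed = 0.5, station = 0.35, prior = 0.15),
    long_distance_kmh = 130, long_distance_min_m = 50000,
    snap_m = 75
  )
}

#' Uniform habitual-mode prior
#'
#' @return named weight vector over [imputation_modes()] summing to 1.
#' @export
uniform_prior <- function() {
  m <- imputation_modes()
  setNames(rep(1 / length(m), length(m)), m)
}

station_evidence <- function(network, g, mode, snap_m) {
  a <- stations_within(network, g[1, 1], g[1, 2], snap_m)
  b <- stations_within(network, g[nrow(g), 1], g[nrow(g), 2], snap_m)
  a <- a[a$mode == mode, , drop = FALSE]
  b <- b[b$mode == mode, , drop = FALSE]
  both <- nrow(a) > 0 && nrow(b) > 0
  same_line <- both && length(intersect(a$line_id, b$line_id)) > 0
  list(start = nrow(a) > 0, end = nrow(b) > 0, both = both,
       same_line = same_line,
       value = if (same_line) 1 else if (both) 0.6 else 0)
}

#' Score one candidate stage against all imputable modes
#'
#' `score(mode) = w_speed * [median smoothed speed in mode band] +
#' w_station * station_evidence(mode) + w_prior * prior(mode)`. Station
#' evidence applies to transit modes only: 0.6 when both stage endpoints
#' lie within the snap radius of stations of that mode, 1 when some such
#' pair shares a line. A stage faster than 130 km/h and longer than 50 km
#' is labelled `long_distance`. Ties break by the fixed order of
#' [imputation_modes()].
#'
#' @param stage one stage row ([split_stages()]).
#' @param prior named habitual-mode weights on [imputation_modes()]
#'   (normalised internally).
#' @param network a [transit_network()].
#' @param params see [imputation_params()].
#' @return list: `mode` (argmax label), `score` (named vector),
#'   `median_kmh`, and evidence `flags`.
#' @export
score_stage <- function(stage, prior = uniform_prior(), network,
                        params = imputation_params()) {
  g <- stage$geometry[[1]]
  if (is.null(g) || nrow(g) == 0) stop("invalid stage: empty polyline")
  v <- if (ncol(g) >= 3 && nrow(g) >= 2) {
    median(smoothed_speeds(g))
  } else if (!is.null(stage$start) && stage$end > stage$start) {
    polyline_length(g) / (stage$end - stage$start) * 3.6
  } else 0
  len <- polyline_length(g)
  pr <- prior[imputation_modes()]
  pr[is.na(pr)] <- 0
  pr <- pr / max(sum(pr), 1e-12)
  w <- params$weights
  score <- setNames(numeric(length(imputation_modes())), imputation_modes())
  flags <- list()
  for (m in imputation_modes()) {
    sp <- if (m %in% names(params$bands)) {
      b <- params$bands[[m]]
      as.numeric(v >= b[1] && v < b[2])
    } else 0
    ev <- 0
    if (m %in% transit_modes() && !is.null(network)) {
      e <- station_evidence(network, g, m, params$snap_m)
      ev <- e$value
      flags[[m]] <- e
    }
    score[m] <- w[["speed"]] * sp + w[["station"]] * ev +
      w[["prior"]] * pr[[m]]
  }
  if (v >= params$long_distance_kmh && len >= params$long_distance_min_m) {
    lab <- "long_distance"
  } else {
    lab <- imputation_modes()[which.max(score)]  # first max = fixed order
  }
  list(mode = lab, score = score, median_kmh = v, flags = flags)
}

#' Impute travel modes for a participant's candidate stages
#'
#' Labels every stage via [score_stage()] and inserts a zero-length,
#' zero-duration transfer placeholder at the shared endpoint between
#' consecutive differently-labelled stages of the same move.
#'
#' @param stages stage rows from [split_stages()] (one participant).
#' @param prior,network,params as in [score_stage()].
#' @param move_id optional vector grouping stages into moves; defaults to
#'   contiguity of intervals.
#' @return data frame of labelled stages (`kind == "stage"`, `mode`,
#'   `median_kmh`) interleaved with transfer placeholders
#'   (`kind == "transfer"`, zero-length geometry).
#' @export
impute_modes <- function(stages, prior = uniform_prior(), network = NULL,
                         params = imputation_params(), move_id = NULL) {
  if (nrow(stages) == 0) return(stages)
  if (is.null(move_id)) {
    brk <- c(FALSE, abs(stages$start[-1] - stages$end[-nrow(stages)]) > 1e-6)
    move_id <- cumsum(brk)
  }
  scored <- lapply(seq_len(nrow(stages)), function(i)
    score_stage(stages[i, ], prior, network, params))
  out <- vector("list", 2 * nrow(stages))
  for (i in seq_len(nrow(stages))) {
    row <- stages[i, ]
    row$mode <- scored[[i]]$mode
    row$median_kmh <- scored[[i]]$median_kmh
    out[[2 * i - 1]] <- row
    if (i < nrow(stages) && move_id[i] == move_id[i + 1] &&
        scored[[i]]$mode != scored[[i + 1]]$mode) {
      g <- row$geometry[[1]]
      pt <- g[nrow(g), , drop = FALSE]
      tr <- row
      tr$kind <- "transfer"
      tr$mode <- NA_character_
      tr$start <- tr$end
      tr$median_kmh <- NA_real_
      tr$geometry <- list(pt)
      out[[2 * i]] <- tr
    }
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(res) <- NULL
  res
}

# ---- time-weighted agreement ------------------------------------------

# labelled timeline -> (breaks, labels); label NA outside segments
timeline_label <- function(breaks, seg_start, seg_end, seg_lab) {
  mid <- (breaks[-length(breaks)] + breaks[-1]) / 2
  idx <- findInterval(mid, seg_start)
  lab <- rep(NA_character_, length(mid))
  ok <- idx >= 1
  ok[ok] <- mid[ok] < seg_end[idx[ok]]
  lab[ok] <- seg_lab[idx[ok]]
  lab
}

#' Time-weighted mode agreement between imputation and ground truth
#'
#' Compares the imputed labelling of time with the diary by interval
#' intersection, per participant-day. Reports (a) the fraction of true
#' transport time labelled transport, (b) the reciprocal fraction of
#' imputed transport time that is truly transport, and (c) among
#' jointly-transport time, the fraction with matching mode, overall and per
#' (true) mode. Transfer episodes are excluded from all denominators (the
#' report records this in `$transfers_excluded`).
#'
#' @param imputed labelled segments: visits from [detect_visits()] plus
#'   stages from [impute_modes()] (any rows with `kind == "stage"` count as
#'   transport, with their `mode`).
#' @param truth the ground-truth diary for the same participant-days.
#' @return list of class `mode_accuracy`: `transport_recall`,
#'   `transport_precision`, `mode_agreement`, `per_mode` (data frame with
#'   truth seconds, jointly-transport seconds, agreeing seconds, fraction),
#'   `joint_transport_s`, `transfers_excluded = TRUE`.
#' @export
mode_accuracy_report <- function(imputed, truth) {
  tr_t <- truth[truth$kind == "stage", , drop = FALSE]
  al_t <- imputed[imputed$kind %in% c("stage", "move"), , drop = FALSE]
  if (nrow(tr_t) == 0) stop("coverage error: truth contains no trip stages")
  span_lo <- max(min(truth$start), min(imputed$start))
  span_hi <- min(max(truth$end), max(imputed$end))
  if (span_lo >= span_hi) {
    stop("coverage error: imputed and truth time ranges are disjoint")
  }
  tr_t$imode <- mode_to_imputation(tr_t$mode)
  al_lab <- if ("mode" %in% names(al_t)) al_t$mode
            else rep("transport", nrow(al_t))
  breaks <- sort(unique(c(tr_t$start, tr_t$end, al_t$start, al_t$end,
                          span_lo, span_hi)))
  breaks <- breaks[breaks >= span_lo & breaks <= span_hi]
  dur <- diff(breaks)
  ltruth <- timeline_label(breaks, tr_t$start, tr_t$end, tr_t$imode)
  lalgo <- timeline_label(breaks, al_t$start, al_t$end, al_lab)
  truth_tr <- !is.na(ltruth)
  algo_tr <- !is.na(lalgo)
  joint <- truth_tr & algo_tr
  agree <- joint & !is.na(lalgo) & ltruth == lalgo
  per_mode <- do.call(rbind, lapply(sort(unique(ltruth[truth_tr])),
    function(m) {
      sel <- !is.na(ltruth) & ltruth == m
      data.frame(mode = m,
                 truth_s = sum(dur[sel]),
                 joint_s = sum(dur[sel & joint]),
                 agree_s = sum(dur[sel & agree]),
                 fraction = if (sum(dur[sel & joint]) > 0)
                   sum(dur[sel & agree]) / sum(dur[sel & joint])
                 else NA_real_)
    }))
  structure(list(
    transport_recall = sum(dur[joint]) / sum(dur[truth_tr]),
    transport_precision = if (sum(dur[algo_tr]) > 0)
      sum(dur[joint]) / sum(dur[algo_tr]) else NA_real_,
    mode_agreement = if (sum(dur[joint]) > 0)
      sum(dur[agree]) / sum(dur[joint]) else NA_real_,
    per_mode = per_mode,
    joint_transport_s = sum(dur[joint]),
    transfers_excluded = TRUE
  ), class = "mode_accuracy")
}

# pool per-participant accuracy reports by total durations
pool_mode_accuracy <- function(reports) {
  pm <- do.call(rbind, lapply(reports, `[[`, "per_mode"))
  agg <- stats::aggregate(pm[c("truth_s", "joint_s", "agree_s")],
                          by = list(mode = pm$mode), FUN = sum)
  agg$fraction <- ifelse(agg$joint_s > 0, agg$agree_s / agg$joint_s, NA)
  tot_truth <- sum(agg$truth_s)
  tot_joint <- sum(agg$joint_s)
  prec_num <- sum(vapply(reports, `[[`, numeric(1), "joint_transport_s"))
  prec_den <- sum(vapply(reports, function(r)
    r$joint_transport_s / max(r$transport_precision, 1e-12), numeric(1)))
  structure(list(
    transport_recall = tot_joint / tot_truth,
    transport_precision = prec_num / prec_den,
    mode_agreement = sum(agg$agree_s) / tot_joint,
    per_mode = agg,
    joint_transport_s = tot_joint,
    transfers_excluded = TRUE
  ), class = "mode_accuracy")
}
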