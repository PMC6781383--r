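# Accelerometer renderer: fixed-length epochs aligned to midnight carrying
# vector-magnitude counts and steps.

in_wear <- function(sec_of_day, schedule) {
  ok <- rep(FALSE, length(sec_of_day))
  for (iv in schedule) {
    ok <- ok | (sec_of_day >= iv[1] & sec_of_day < iv[2])
  }
  ok
}

#' Render an accelerometer epoch stream from a diary
#'
#' One epoch every `cfg$accel_epoch_s` seconds on a grid aligned to
#' midnight. Each epoch's context is the diary segment containing its
#' midpoint; steps are drawn from that context's cadence model (mean and sd
#' in steps/min from `cfg$cadence_spm`, scaled to the epoch, truncated at
#' zero, rounded) and vector-magnitude counts from a Poisson model
#' (`cfg$vm_lambda`). Epochs outside the wear schedule carry zero VM and
#' zero steps.
#'
#' Deterministic given `(cfg$seed, participant)`.
#'
#' @param diary one participant's diary.
#' @param cfg a [tw_config()].
#' @return data frame `participant_id`, `day`, `start`, `end`, `vm`,
#'   `steps` on a gapless per-day grid.
#' @export
render_accel <- function(diary, cfg = tw_config()) {
  stopifnot(nrow(diary) > 0)
  pid <- diary$participant_id[1]
  set.seed(stream_seed(cfg$seed, pid_number(pid), "accel"))
  ep <- cfg$accel_epoch_s
  days <- sort(unique(diary$day))
  diary <- diary[order(diary$start), , drop = FALSE]
  out <- vector("list", length(days))
  for (k in seq_along(days)) {
    d <- days[k]
    day0 <- (d - 1) * 86400
    starts <- seq(day0, day0 + 86400 - ep, by = ep)
    mids <- starts + ep / 2
    seg <- findInterval(mids, diary$start)
    seg[seg < 1] <- 1
    ctx <- ifelse(diary$kind[seg] == "stage", diary$mode[seg],
                  diary$kind[seg])
    ctx[mids >= diary$end[seg] | mids < diary$start[seg]] <- "visit"
    cad <- t(vapply(ctx, function(m) {
      cc <- cfg$cadence_spm[[m]]
      if (is.null(cc)) cc <- cfg$cadence_spm[["visit"]]
      cc
    }, numeric(2)))
    epm <- ep / 60
    steps <- round(pmax(0, rnorm(length(mids), cad[, 1] * epm,
                                 cad[, 2] * epm)))
    lam <- cfg$vm_lambda[ctx]
    lam[is.na(lam)] <- cfg$vm_lambda[["visit"]]
    vm <- rpois(length(mids), lam)
    wear <- in_wear(mids - day0, cfg$wear_schedule)
    steps[!wear] <- 0
    vm[!wear] <- 0
    out[[k]] <- data.frame(participant_id = pid, day = d, start = starts,
                           end = starts + ep, vm = vm, steps = steps)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
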