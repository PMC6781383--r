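# stage row with a synthetic timestamped polyline at constant speed
speed_stage <- function(speed_kmh, dur_s = 600, start = 36000,
                        from = c(2.35, 48.85), bearing_north = TRUE) {
  len <- speed_kmh / 3.6 * dur_s
  to <- tripwalk:::offset_lonlat(from[1], from[2],
                                 if (bearing_north) 0 else len,
                                 if (bearing_north) len else 0)[1, ]
  ts <- seq(start, start + dur_s, by = 5)
  pos <- tripwalk:::interpolate_along(rbind(from, to),
                                      len * (ts - start) / dur_s)
  s <- data.frame(participant_id = "p", kind = "stage", start = start,
                  end = start + dur_s, lon = NA_real_, lat = NA_real_)
  s$geometry <- list(cbind(lon = pos[, "lon"], lat = pos[, "lat"], t = ts))
  s
}

test_that("slow stages far from stations are labelled walking", {
  s <- speed_stage(4)
  sc <- score_stage(s, uniform_prior(), network = NULL)
  expect_equal(sc$mode, "walk")
  expect_equal(sc$median_kmh, 4, tolerance = 0.1)
})

test_that("station evidence lets transit outrank the car", {
  cfg <- tw_config()
  net <- transit_network(cfg)
  # ride along a real metro line between two of its stations
  line <- net[net$mode == "metro" & net$line_id == "metro_v01", ]
  from <- c(line$lon[1], line$lat[1])
  to <- c(line$lon[6], line$lat[6])
  dist <- tripwalk:::hav1(from[1], from[2], to[1], to[2])
  dur <- dist / (30 / 3.6)
  ts <- seq(36000, 36000 + dur, by = 5)
  pos <- tripwalk:::interpolate_along(rbind(from, to),
                                      dist * (ts - 36000) / dur)
  s <- data.frame(participant_id = "p", kind = "stage", start = 36000,
                  end = 36000 + dur, lon = NA_real_, lat = NA_real_)
  s$geometry <- list(cbind(lon = pos[, "lon"], lat = pos[, "lat"], t = ts))
  sc <- score_stage(s, uniform_prior(), net)
  expect_equal(sc$mode, "metro")
  expect_gt(sc$score[["metro"]], sc$score[["car"]])
  expect_true(sc$flags$metro$same_line)
})

test_that("support restriction: without transit evidence or prior, only
           street modes can win", {
  pr <- uniform_prior()
  pr[c("bus", "tramway", "metro", "suburban_train", "long_distance")] <- 0
  pr <- pr / sum(pr)
  for (v in c(4, 12, 25, 60)) {
    sc <- score_stage(speed_stage(v), pr, network = NULL)
    expect_true(sc$mode %in% c("walk", "bike", "car"))
  }
})

test_that("empty polylines are rejected", {
  s <- speed_stage(4)
  s$geometry <- list(s$geometry[[1]][0, , drop = FALSE])
  expect_error(score_stage(s, uniform_prior(), NULL), "empty polyline")
})

test_that("impute_modes inserts transfers between differing labels only", {
  one <- speed_stage(4)
  out1 <- impute_modes(one, uniform_prior(), NULL)
  expect_equal(nrow(out1), 1)
  expect_equal(out1$mode, "walk")
  # walk then fast vehicle then walk: 3 labels, 2 transfer placeholders
  s1 <- speed_stage(4, dur_s = 600, start = 36000)
  g1 <- s1$geometry[[1]]
  end1 <- g1[nrow(g1), ]
  s2 <- speed_stage(60, dur_s = 600, start = 36600,
                    from = end1[1:2], bearing_north = FALSE)
  g2 <- s2$geometry[[1]]
  s3 <- speed_stage(4, dur_s = 600, start = 37200,
                    from = g2[nrow(g2), 1:2])
  st <- rbind(s1, s2, s3)
  out <- impute_modes(st, uniform_prior(), NULL, move_id = c(1, 1, 1))
  expect_equal(sum(out$kind == "stage"), 3)
  expect_equal(sum(out$kind == "transfer"), 2)
  tf <- out[out$kind == "transfer", ]
  expect_true(all(tf$start == tf$end))
  expect_true(all(vapply(tf$geometry, nrow, integer(1)) == 1))
})

test_that("processing order does not change the labels", {
  s1 <- speed_stage(4, start = 36000)
  s2 <- speed_stage(25, start = 40000)
  a <- impute_modes(rbind(s1, s2), uniform_prior(), NULL,
                    move_id = c(1, 2))
  b <- impute_modes(rbind(s2, s1), uniform_prior(), NULL,
                    move_id = c(2, 1))
  expect_equal(sort(a$mode), sort(b$mode))
})

test_that("accuracy report reproduces hand-computed interval arithmetic", {
  # truth: walk [0,600), metro [600,1200); algorithm: walk [0,900),
  # car [900,1500). By hand: truth transport 1200 s, joint 1200 of it;
  # agreement 600+0 -> 0.5; precision 1200/1500.
  mk_seg <- function(kind, mode, s, e, lonlat = c(2.35, 48.85)) {
    d <- data.frame(participant_id = "p", day = 1, kind = kind,
                    trip_id = if (kind == "stage") "t1" else NA_character_,
                    mode = mode, start = s, end = e,
                    stringsAsFactors = FALSE)
    d$geometry <- list(matrix(lonlat, 1))
    d
  }
  truth <- rbind(mk_seg("stage", "walk", 0, 600),
                 mk_seg("stage", "metro", 600, 1200),
                 mk_seg("visit", NA, 1200, 1800))
  algo <- rbind(mk_seg("stage", "walk", 0, 900),
                mk_seg("stage", "car", 900, 1500),
                mk_seg("visit", NA, 1500, 1800))
  rep <- mode_accuracy_report(algo, truth)
  expect_equal(rep$transport_recall, 1)
  expect_equal(rep$transport_precision, 1200 / 1500)
  expect_equal(rep$mode_agreement, 0.5)
  pm <- rep$per_mode
  expect_equal(pm$fraction[pm$mode == "walk"], 1)
  expect_equal(pm$fraction[pm$mode == "metro"], 0)
  # per-mode agreeing seconds sum to the overall agreeing time
  expect_equal(sum(pm$agree_s), rep$mode_agreement * rep$joint_transport_s)
})

test_that("perfect labelling gives fractions of exactly one", {
  w <- clean_world_small()
  d <- w$diaries[[1]]
  d$mode[d$kind == "stage"] <- mode_to_imputation(
    d$mode[d$kind == "stage"])
  rep <- mode_accuracy_report(d, w$diaries[[1]])
  expect_equal(rep$transport_recall, 1)
  expect_equal(rep$transport_precision, 1)
  expect_equal(rep$mode_agreement, 1)
})

test_that("labelling everything as visits zeroes transport recall", {
  w <- clean_world_small()
  d <- w$diaries[[1]]
  v <- d
  v$kind <- "visit"
  v$mode <- NA_character_
  v$kind[1] <- "stage"  # keep one sliver so "transport" time is nonempty
  v$mode[1] <- "walk"
  v$end[1] <- v$start[1] + 1
  v$start[-1] <- pmax(v$start[-1], v$end[1])
  rep <- mode_accuracy_report(v, w$diaries[[1]])
  expect_lt(rep$transport_recall, 0.01)
})

test_that("disjoint coverage raises a coverage error", {
  w <- clean_world_small()
  d <- w$diaries[[1]]
  shifted <- d
  shifted$start <- shifted$start + 10 * 86400
  shifted$end <- shifted$end + 10 * 86400
  expect_error(mode_accuracy_report(shifted, d), "coverage")
})

test_that("well-separated noise-free scenario is labelled perfectly", {
  # constructed contrast: walk 4.8, metro 30 along a line, car 60 far from
  # stations; car-leaning prior as in the habitual-mode survey
  cfg <- tw_config()
  net <- transit_network(cfg)
  line <- net[net$mode == "metro" & net$line_id == "metro_h01", ]
  pr <- tripwalk:::prior_from_mix(cfg$mode_mix)
  s_walk <- speed_stage(4.8, start = 30000)
  from <- c(line$lon[2], line$lat[2]); to <- c(line$lon[8], line$lat[8])
  dist <- tripwalk:::hav1(from[1], from[2], to[1], to[2])
  ts <- seq(40000, 40000 + dist / (30 / 3.6), by = 5)
  pos <- tripwalk:::interpolate_along(
    rbind(from, to), dist * (ts - 40000) / (max(ts) - 40000))
  s_metro <- s_walk
  s_metro$start <- 40000; s_metro$end <- max(ts)
  s_metro$geometry <- list(cbind(lon = pos[, "lon"], lat = pos[, "lat"],
                                 t = ts))
  s_car <- speed_stage(60, start = 50000, from = c(2.55, 48.99))
  labs <- impute_modes(rbind(s_walk, s_metro, s_car), pr, net,
                       move_id = c(1, 2, 3))
  expect_equal(labs$mode[labs$kind == "stage"],
               c("walk", "metro", "car"))
})
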