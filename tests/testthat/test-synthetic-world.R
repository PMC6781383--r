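test_that("world generation is reproducible and insertion-order invariant", {
  cfg <- tw_config(seed = 5)
  w1 <- generate_world(cfg, n_participants = 2, n_days = 1)
  w2 <- generate_world(cfg, n_participants = 2, n_days = 1)
  expect_identical(w1$diaries, w2$diaries)
  expect_identical(w1$participants, w2$participants)
  # adding a third participant leaves the first two untouched
  w3 <- generate_world(cfg, n_participants = 3, n_days = 1)
  expect_identical(w3$diaries[["p002"]], w1$diaries[["p002"]])
})

test_that("diaries respect the requested horizon and home anchoring", {
  w <- generate_world(tw_config(seed = 6), n_participants = 1, n_days = 7)
  d <- w$diaries[[1]]
  expect_equal(sort(unique(d$day)), 1:7)
  home <- c(w$participants$home_lon[1], w$participants$home_lat[1])
  for (dd in 1:7) {
    dday <- d[d$day == dd, ]
    dday <- dday[order(dday$start), ]
    # starts and ends the day at the residence
    first <- dday$geometry[[1]][1, ]
    last <- dday$geometry[[nrow(dday)]][1, ]
    expect_lt(tripwalk:::hav1(first[1], first[2], home[1], home[2]), 1)
    expect_lt(tripwalk:::hav1(last[1], last[2], home[1], home[2]), 1)
    expect_equal(dday$start[1], (dd - 1) * 86400)
    expect_equal(dday$end[nrow(dday)], dd * 86400)
  }
  expect_true(w$participants$zone %in%
                c("core_city", "close_suburb", "far_suburb"))
})

test_that("each diary day tiles [0, 86400) with half-open segments", {
  w <- noisy_world_small()
  for (d in w$diaries) {
    for (dd in unique(d$day)) {
      x <- d[d$day == dd, ]
      x <- x[order(x$start), ]
      expect_true(all(abs(x$start[-1] - x$end[-nrow(x)]) < 1e-6))
      expect_true(all(x$end >= x$start))
    }
  }
})

test_that("ground-truth trip distance is the sum of its stage polylines", {
  w <- noisy_world_small()
  d <- w$diaries[[1]]
  tr <- d[!is.na(d$trip_id), ]
  for (tid in unique(tr$trip_id)) {
    g <- tr[tr$trip_id == tid, ]
    st_len <- vapply(g$geometry[g$kind == "stage"], polyline_length,
                     numeric(1))
    tf_len <- vapply(g$geometry[g$kind == "transfer"], polyline_length,
                     numeric(1))
    expect_true(all(tf_len == 0))  # transfers are punctual
    expect_equal(sum(st_len),
                 diary_trip_distances(g)$length_m |> sum())
  }
})

test_that("trip-mode shares track the configured mixture within 10 points", {
  cfg <- tw_config(seed = 1)
  w <- generate_world(cfg, n_participants = 20, n_days = 7)
  main_modes <- unlist(lapply(w$diaries, function(d) {
    st <- d[d$kind == "stage", ]
    vapply(split(st$mode, st$trip_id), function(m) {
      nw <- setdiff(m, "walk")
      if (length(nw) > 0) nw[1] else "walk"
    }, character(1))
  }))
  emp <- table(factor(main_modes, levels = names(cfg$mode_mix)))
  emp <- as.numeric(emp) / sum(emp)
  expected <- tripwalk:::expected_mode_shares(cfg)
  expect_true(all(abs(emp - expected) <= 0.10))
})

test_that("gps rendering is exact on an artefact-free straight trip", {
  cfg <- tw_config_clean(tw_config(seed = 3))
  d <- straight_trip_diary(len_m = 1000, speed_kmh = 4.8)
  pts <- render_gps(d, cfg)
  trip <- d[d$kind == "stage", ]
  on_trip <- pts[pts$time >= trip$start & pts$time < trip$end, ]
  n <- nrow(on_trip)
  cum <- sum(tripwalk:::hav_m(on_trip$lon[-n], on_trip$lat[-n],
                              on_trip$lon[-1], on_trip$lat[-1]))
  step_m <- 4.8 / 3.6 * cfg$gps_period_s
  expect_lt(abs(cum - 1000), step_m + 0.01)
})

test_that("full dropout leaves no points during trips", {
  cfg <- tw_config_clean(tw_config(seed = 3))
  cfg$dropout_prob <- 1
  w <- generate_world(cfg, n_participants = 1, n_days = 2)
  d <- w$diaries[[1]]
  pts <- render_gps(d, cfg)
  tr <- d[!is.na(d$trip_id), ]
  for (i in seq_len(nrow(tr))) {
    expect_equal(sum(pts$time >= tr$start[i] & pts$time < tr$end[i]), 0)
  }
})

test_that("pseudo-ambulation inflates raw distance beyond ground truth", {
  cfg <- tw_config(seed = 4, dropout_prob = 0)
  w <- generate_world(cfg, n_participants = 1, n_days = 1)
  d <- w$diaries[[1]]
  pts <- render_gps(d, cfg)
  n <- nrow(pts)
  raw <- sum(tripwalk:::hav_m(pts$lon[-n], pts$lat[-n],
                              pts$lon[-1], pts$lat[-1]))
  truth <- sum(diary_trip_distances(d)$length_m)
  expect_gt(raw, truth)
})

test_that("accelerometer rendering honours schedule and cadence model", {
  base <- tw_config(seed = 3)
  # all-day nonwear schedule: every epoch zero
  cfg <- base
  cfg$wear_schedule <- list()
  d <- straight_trip_diary()
  eps <- render_accel(d, cfg)
  expect_true(all(eps$vm == 0) && all(eps$steps == 0))
  # deterministic cadence: 100 steps/min over a 10-min walk, 60-s epochs
  cfg2 <- base
  cfg2$cadence_spm$walk <- c(100, 0)
  cfg2$wear_schedule <- list(c(0, 86400))
  d2 <- straight_trip_diary(len_m = 800, speed_kmh = 4.8, dep_s = 36000)
  d2$end[2] <- 36600  # force exactly 10 min of walking
  d2$start[3] <- 36600
  eps2 <- render_accel(d2, cfg2)
  in_stage <- eps2$start >= 36000 & eps2$end <= 36600
  expect_equal(sum(eps2$steps[in_stage]), 1000)
  # a car stage yields only truncated-noise steps (4-sigma bound)
  cfg3 <- base
  cfg3$wear_schedule <- list(c(0, 86400))
  d3 <- straight_trip_diary(len_m = 5000, speed_kmh = 30,
                            mode = "car_driver")
  eps3 <- render_accel(d3, cfg3)
  stage <- d3[d3$kind == "stage", ]
  in_st <- eps3$start >= stage$start & eps3$end <= stage$end
  n_ep <- sum(in_st)
  sd_ep <- cfg3$cadence_spm$car_driver[2]
  bound <- n_ep * sd_ep / sqrt(2 * pi) + 4 * sd_ep * sqrt(n_ep)
  expect_lte(sum(eps3$steps[in_st]), bound)
})

test_that("sensor rendering is deterministic for a fixed seed", {
  cfg <- tw_config(seed = 8)
  w <- generate_world(cfg, n_participants = 1, n_days = 1)
  d <- w$diaries[[1]]
  expect_identical(render_gps(d, cfg), render_gps(d, cfg))
  expect_identical(render_accel(d, cfg), render_accel(d, cfg))
})

test_that("transit network invariants hold", {
  cfg <- tw_config()
  net <- transit_network(cfg)
  grid <- street_grid(cfg)
  # every line has at least two stations
  expect_true(all(table(net$line_id) >= 2))
  # stations lie inside the region bounding box
  expect_true(all(tripwalk:::in_bbox(grid, net$lon, net$lat)))
  # station spacing per mode roughly matches the configured spacing
  one_line <- net[net$line_id == net$line_id[1], ]
  gaps <- tripwalk:::hav_m(one_line$lon[-nrow(one_line)],
                           one_line$lat[-nrow(one_line)],
                           one_line$lon[-1], one_line$lat[-1])
  expect_lt(max(abs(gaps - mean(gaps))), 1)
})
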