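test_that("stationary tracks reduce to their first fix", {
  pts <- data.frame(participant_id = "p", time = seq(0, 500, 5),
                    lon = 2.35, lat = 48.85)
  f <- filter_low_speed(pts)
  expect_equal(nrow(f), 1)
  expect_equal(f$time, 0)
  expect_equal(f$speed_kmh, 0)
})

test_that("unsorted input is rejected", {
  pts <- data.frame(time = c(0, 10, 5), lon = 2.35, lat = 48.85)
  expect_error(filter_low_speed(pts), "ordering")
})

test_that("speed filter matches an independent single-pass reference", {
  set.seed(42)
  # random walk with mixed slow/fast steps
  n <- 50
  step <- cumsum(rnorm(n, 0, 4))
  pts <- data.frame(participant_id = "p", time = seq(0, by = 5,
                                                     length.out = n))
  ll <- tripwalk:::offset_lonlat(2.35, 48.85, step,
                                 cumsum(rnorm(n, 0, 4)))
  pts$lon <- ll[, "lon"]; pts$lat <- ll[, "lat"]
  # reference: independent greedy pass written against the same rule
  ref_keep <- 1L
  li <- 1L
  for (i in 2:n) {
    d <- geosphere::distHaversine(c(pts$lon[li], pts$lat[li]),
                                  c(pts$lon[i], pts$lat[i]),
                                  r = 6378137)
    v <- d / min(pts$time[i] - pts$time[li], 15) * 3.6
    if (v >= 1) {
      ref_keep <- c(ref_keep, i)
      li <- i
    }
  }
  f <- filter_low_speed(pts, 1.0)
  expect_equal(f$time, pts$time[ref_keep])
})

test_that("the speed filter is idempotent", {
  w <- noisy_world_small()
  pts <- render_gps(w$diaries[[1]], w$config)
  f1 <- filter_low_speed(pts)
  f2 <- filter_low_speed(f1)
  expect_equal(f1$time, f2$time)
  expect_equal(f1$lon, f2$lon)
})

test_that("visit detection finds constructed clusters and moves", {
  # two clusters joined by a straight run -> 2 visits, 1 move
  mk <- function(n, lon0, lat0, t0) {
    jit <- tripwalk:::offset_lonlat(lon0, lat0, rnorm(n, 0, 5),
                                    rnorm(n, 0, 5))
    data.frame(participant_id = "p", time = t0 + seq_len(n) * 5,
               lon = jit[, "lon"], lat = jit[, "lat"])
  }
  set.seed(1)
  c1 <- mk(200, 2.35, 48.85, 0)
  far <- tripwalk:::offset_lonlat(2.35, 48.85, 2000, 0)
  run_ll <- tripwalk:::interpolate_along(
    rbind(c(2.35, 48.85), far), seq(0, 2000, by = 40))
  run <- data.frame(participant_id = "p",
                    time = max(c1$time) + seq_len(nrow(run_ll)) * 5,
                    lon = run_ll[, "lon"], lat = run_ll[, "lat"])
  c2 <- mk(200, far[1, 1], far[1, 2], max(run$time))
  segs <- detect_visits(rbind(c1, run, c2), dwell_min_s = 300,
                        radius_m = 50)
  expect_equal(sum(segs$kind == "visit"), 2)
  expect_equal(sum(segs$kind == "move"), 1)
  # a single stationary cluster spanning a day: one visit, no moves
  segs1 <- detect_visits(mk(500, 2.35, 48.85, 0), 300, 50)
  expect_equal(segs1$kind, "visit")
  # empty input: empty output
  expect_equal(nrow(detect_visits(mk(500, 2.35, 48.85, 0)[0, ])), 0)
})

test_that("visits and moves tile the observed span", {
  w <- noisy_world_small()
  f <- filter_low_speed(render_gps(w$diaries[[2]], w$config))
  segs <- detect_visits(f, 300, 50)
  segs <- segs[order(segs$start), ]
  expect_equal(segs$start[1], f$time[1])
  expect_equal(segs$end[nrow(segs)], f$time[nrow(f)])
  expect_true(all(abs(segs$start[-1] - segs$end[-nrow(segs)]) < 1e-9))
})

test_that("visit count on a clean rendered world matches ground truth", {
  w <- clean_world_small()
  for (pid in names(w$diaries)[1:2]) {
    d <- w$diaries[[pid]]
    f <- filter_low_speed(render_gps(d, w$config))
    segs <- detect_visits(f, w$config$dwell_min_s, w$config$visit_radius_m)
    # the trailing home episode has no retained fixes after the final
    # arrival, so every episode except that one is detectable
    expect_equal(sum(segs$kind == "visit"),
                 truth_visit_episodes(d) - 1)
  }
})

test_that("raising the dwell threshold never adds visits", {
  w <- noisy_world_small()
  f <- filter_low_speed(render_gps(w$diaries[[1]], w$config))
  counts <- vapply(c(120, 300, 900, 3600), function(dw)
    sum(detect_visits(f, dw, 50)$kind == "visit"), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("stage splitting partitions the move and finds mode changes", {
  w <- pt_world_small()
  cfg <- w$config
  # find a public-transport trip (walk + ride + walk) in the diaries
  pt_trip <- NULL
  for (d in w$diaries) {
    st <- d[d$kind == "stage", ]
    for (tid in unique(st$trip_id)) {
      m <- st$mode[st$trip_id == tid]
      if (length(m) >= 2 && any(m != "walk")) {
        pt_trip <- d[!is.na(d$trip_id) & d$trip_id == tid, ]
        diary <- d
        break
      }
    }
    if (!is.null(pt_trip)) break
  }
  expect_false(is.null(pt_trip))
  f <- filter_low_speed(render_gps(diary, cfg))
  segs <- detect_visits(f, cfg$dwell_min_s, cfg$visit_radius_m)
  mv <- segs[segs$kind == "move" &
               segs$start < max(pt_trip$end) &
               segs$end > min(pt_trip$start), ][1, ]
  st <- split_stages(mv, w$network, cfg$stage_split_kmh,
                     cfg$station_snap_m, cfg$smooth_k)
  # exact partition of the move interval
  expect_equal(st$start[1], mv$start)
  expect_equal(st$end[nrow(st)], mv$end)
  expect_true(all(abs(st$start[-1] - st$end[-nrow(st)]) < 1e-9))
  expect_equal(sum(st$end - st$start), mv$end - mv$start)
  # boundary within one smoothing window of a true mode change
  truth_bounds <- pt_trip$start[pt_trip$kind == "stage"][-1]
  win <- cfg$smooth_k * cfg$gps_period_s + 2 * cfg$gps_period_s
  found <- st$start[-1]
  expect_true(any(vapply(found, function(b)
    any(abs(b - truth_bounds) <= win + 200), logical(1))))
})

test_that("a constant-speed track far from stations is not split", {
  cfg <- tw_config_clean(tw_config(seed = 3))
  d <- straight_trip_diary(len_m = 2000, speed_kmh = 30,
                           mode = "car_driver",
                           lon0 = 2.45, lat0 = 48.95)
  f <- filter_low_speed(render_gps(d, cfg))
  segs <- detect_visits(f, 300, 50)
  mv <- segs[segs$kind == "move", ][1, ]
  st <- split_stages(mv, NULL)
  expect_equal(nrow(st), 1)
})

test_that("raw daily distance sums consecutive gaps within days", {
  a <- c(2.35, 48.85)
  b <- tripwalk:::offset_lonlat(a[1], a[2], 0, 1000)[1, ]
  pts <- data.frame(participant_id = "p", time = c(100, 200),
                    lon = c(a[1], b[1]), lat = c(a[2], b[2]))
  expect_equal(raw_daily_distance(pts)$distance_m, 1000, tolerance = 0.01)
  # closed triangle of three 1 km hops
  c_ <- tripwalk:::offset_lonlat(a[1], a[2], 1000, 0)[1, ]
  tri <- data.frame(participant_id = "p", time = c(0, 60, 120, 180),
                    lon = c(a[1], b[1], c_[1], a[1]),
                    lat = c(a[2], b[2], c_[2], a[2]))
  d3 <- raw_daily_distance(tri)$distance_m
  expect_equal(d3, 2000 + sqrt(2) * 1000, tolerance = 0.5)
  # points on different days never bridge
  two <- data.frame(participant_id = "p", time = c(86000, 87000),
                    lon = c(a[1], b[1]), lat = c(a[2], b[2]))
  expect_equal(nrow(raw_daily_distance(two)), 0)
})
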