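test_that("classification follows the crude/detailed multi-mode rule", {
  expect_equal(classify_trip("walk", "crude"), "entirely_walked")
  expect_equal(classify_trip(c("walk", "walk"), "detailed"),
               "entirely_walked")
  expect_equal(classify_trip(c("walk", "metro", "walk"), "crude"),
               "public_transport")
  expect_equal(classify_trip(c("walk", "metro", "walk"), "detailed"),
               "metro")
  # two PT sub-modes: one crude group but detailed multi-mode
  expect_equal(classify_trip(c("walk", "metro", "walk", "bus"), "crude"),
               "public_transport")
  expect_equal(classify_trip(c("walk", "metro", "walk", "bus"),
                             "detailed"), "multi_mode")
  # driver vs passenger splits only in the detailed scheme
  expect_equal(classify_trip(c("car_driver", "walk", "car_passenger"),
                             "crude"), "private_motorized")
  expect_equal(classify_trip(c("car_driver", "walk", "car_passenger"),
                             "detailed"), "multi_mode")
  expect_error(classify_trip("hoverboard", "crude"), "unknown mode")
})

test_that("crude class is derivable from the detailed class", {
  # enumerate single-mode and two-mode combinations over the full alphabet
  det_to_crude <- c(
    entirely_walked = "entirely_walked", other_active = "other_active",
    bus_coach = "public_transport", metro = "public_transport",
    suburban_train = "public_transport", tramway = "public_transport",
    private_motorized_driver = "private_motorized",
    private_motorized_passenger = "private_motorized",
    other_long_distance = "other_long_distance",
    non_transport = "non_transport")
  modes <- diary_modes()
  for (m in modes) {
    d <- classify_trip(c("walk", m), "detailed")
    cr <- classify_trip(c("walk", m), "crude")
    if (d != "multi_mode") expect_equal(unname(det_to_crude[d]), cr)
  }
  # detailed multi-mode count dominates crude multi-mode count
  set.seed(7)
  combos <- replicate(200, sample(modes, 2), simplify = FALSE)
  crude_mm <- sum(vapply(combos, function(x)
    classify_trip(x, "crude") == "multi_mode", logical(1)))
  det_mm <- sum(vapply(combos, function(x)
    classify_trip(x, "detailed") == "multi_mode", logical(1)))
  expect_gte(det_mm, crude_mm)
})

test_that("ski sequences are deleted whole; jogging only locally", {
  ski <- trip_segments("t_ski", c("walk", "ski_chairlift", "walk"))
  out <- apply_exclusions(ski)
  expect_true(all(out$segments$excluded))
  expect_true(all(out$segments$reason == "ski_chairlift"))
  expect_equal(nrow(out$trips), 0)
  # drive - transfer - jog: jog and its transfer go, the drive stays
  dj <- trip_segments("t_dj", c("car_driver", "jogging"))
  out2 <- apply_exclusions(dj)
  seg2 <- out2$segments
  expect_equal(seg2$excluded,
               c(FALSE, TRUE, TRUE))  # stage, transfer, jog-stage order
  expect_equal(out2$trips$crude_class, "private_motorized")
  # a walk-only remainder is reclassified as entirely walked
  wj <- trip_segments("t_wj", c("walk", "jogging"))
  out3 <- apply_exclusions(wj)
  expect_equal(out3$trips$crude_class, "entirely_walked")
  # long-distance stages are never excluded
  ld <- trip_segments("t_ld", c("walk", "long_distance_train"))
  out4 <- apply_exclusions(ld)
  expect_false(any(out4$segments$excluded))
  expect_equal(out4$trips$crude_class, "other_long_distance")
})

test_that("exclusions leave retained segment timing untouched", {
  dj <- rbind(trip_segments("a", c("car_driver", "jogging")),
              trip_segments("b", c("walk", "metro", "walk"), t0 = 30000))
  out <- apply_exclusions(dj)
  kept <- out$retained_segments
  orig <- dj[paste(dj$trip_id, dj$start) %in%
               paste(kept$trip_id, kept$start), ]
  expect_equal(kept$start, orig$start)
  expect_equal(kept$end, orig$end)
})

test_that("segment accounting reproduces the printed sample ledger", {
  # 5 ski trips of 19 segments each (10 stages, 9 transfers) = 95 segments;
  # 48 trips of drive-transfer-jog = 96 jogging-rule segments; filler
  # trips of 5 segments complete the 21,354-segment sample
  ski <- do.call(rbind, lapply(1:5, function(k)
    trip_segments(sprintf("ski%02d", k),
                  rep(c("walk", "ski_chairlift"), 5), t0 = k * 20000)))
  jog <- do.call(rbind, lapply(1:48, function(k)
    trip_segments(sprintf("jog%02d", k), c("car_driver", "jogging"),
                  t0 = 200000 + k * 2000)))
  filler <- do.call(rbind, lapply(1:4223, function(k)
    trip_segments(sprintf("f%04d", k), c("walk", "metro", "walk"),
                  t0 = 400000 + k * 2000)))
  all_seg <- rbind(ski, jog, filler)
  expect_equal(nrow(all_seg), 21354)
  out <- apply_exclusions(all_seg)
  expect_equal(unname(out$ledger["excluded_ski"]), 95)
  expect_equal(unname(out$ledger["excluded_jogging_dog"]), 96)
  expect_equal(unname(out$ledger["segments_retained"]), 21163)
})

test_that("nonwear flagging is trip-level and respects coverage", {
  trips <- data.frame(
    trip_id = c("a", "b", "c"), participant_id = "p001", day = 1,
    start = c(30000, 40000, 50000), end = c(31000, 41000, 51000),
    stringsAsFactors = FALSE)
  # one nonwear bout inside trip b's transfer window only, one far away
  wear <- structure(list(
    nonwear = data.frame(participant_id = "p001", day = 1,
                         start = c(40900, 60000), end = c(40960, 62000)),
    wear = data.frame(participant_id = "p001", day = 1,
                      start = 0, end = 40900),
    wear_seconds = data.frame(participant_id = "p001", day = 1,
                              wear_s = 83340),
    epochs_cover = data.frame(participant_id = "p001", day = 1)),
    class = "wear_mask")
  out <- flag_nonwear_trips(trips, wear)
  # a bout covering only one minute inside trip b excludes all of b
  expect_equal(out$accel_excluded, c(FALSE, TRUE, FALSE))
  trips2 <- trips
  trips2$participant_id <- "p999"
  expect_error(flag_nonwear_trips(trips2, wear), "coverage")
})

test_that("surveyed-day ledger reproduces the printed identity", {
  surveyed <- c(rep(7, 222), rep(4, 41), rep(3, 22))
  expect_equal(length(surveyed), 285)
  led <- surveyed_day_ledger(7, surveyed)
  expect_equal(unname(led["surveyed"]), 1784)
  expect_equal(unname(led["excluded"]), 211)
  expect_error(surveyed_day_ledger(1, c(2, 2)), "more surveyed")
})
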