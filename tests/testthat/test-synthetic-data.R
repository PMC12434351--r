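test_that("zero emergence rates produce a trackless season", {
  s <- generate_season(season_config(beach_length_m = 500, n_days = 20,
                                     neap_mean = 0, spring_mean = 0,
                                     seed = 3))
  expect_equal(nrow(s$tracks), 0)
  expect_true(all(s$days$n_tracks == 0))
})

test_that("hotspot profile restricts track positions to its support", {
  w <- c(rep(1, 100), rep(0, 400))
  s <- generate_season(season_config(beach_length_m = 500, n_days = 200,
                                     hotspot_profile = w, seed = 5))
  expect_gt(nrow(s$tracks), 0)
  expect_true(all(s$tracks$position_m < 100))
})

test_that("identical config and seed give identical seasons", {
  cfg <- season_config(beach_length_m = 300, n_days = 60, seed = 99)
  expect_identical(generate_season(cfg), generate_season(cfg))
})

test_that("phase-conditional daily means recover configured rates (3 SE)", {
  s <- generate_season(season_config(n_days = 3000, seed = 11))
  neap <- s$days$n_tracks[s$days$phase == "neap"]
  spring <- s$days$n_tracks[s$days$phase == "spring"]
  expect_lt(abs(mean(neap) - 5.0), 3 * sd(neap) / sqrt(length(neap)))
  expect_lt(abs(mean(spring) - 2.4), 3 * sd(spring) / sqrt(length(spring)))
})

test_that("truncated geometric matches its target mean and support", {
  # oracle: expectation computed directly from the renormalised pmf
  for (target in c(1.0, 2.8, 4.0)) {
    p <- truncated_geometric_param(target, 9)
    k <- 0:9
    w <- (1 - p)^k
    expect_equal(sum(k * w) / sum(w), target, tolerance = 1e-9)
  }
  set.seed(17)
  draws <- rtruncated_geometric(20000, 2.8, 9)
  expect_true(all(draws >= 0 & draws <= 9))
  expect_lt(abs(mean(draws) - 2.8), 3 * sd(draws) / sqrt(length(draws)))
  expect_error(truncated_geometric_param(5, 9), "unattainable")
})

test_that("a station counts a track exactly on its visible days in view", {
  tracks <- data.frame(day = 5L, position_m = 115L, longevity = 2L)
  s <- manual_season(tracks, n_days = 10, beach_length_m = 200)
  st <- camera_station("cam1", 100, 30)  # observes [100, 130)
  log <- simulate_camera_log(s, st)
  counted <- log$date[log$status == "ok" & log$track_count > 0]
  expect_equal(counted, c(5L, 6L, 7L))
  # same track one metre outside the window is never counted
  tracks2 <- data.frame(day = 5L, position_m = 130L, longevity = 2L)
  log2 <- simulate_camera_log(manual_season(tracks2, 10), st)
  expect_true(all(log2$track_count == 0))
})

test_that("full-coverage, failure-free camera log reproduces the truth", {
  s <- generate_season(season_config(beach_length_m = 400, n_days = 80,
                                     seed = 21))
  log <- simulate_camera_log(s, full_beach_station(400))
  expect_true(all(log$status == "ok"))
  # visible counts match brute-force visibility truth every day
  truth <- vapply(seq_len(80), function(d) {
    sum(s$tracks$day <= d & d <= s$tracks$day + s$tracks$longevity)
  }, numeric(1))
  expect_equal(log$track_count, as.integer(truth))
  # conservation: newly appearing tracks sum to the season's deposits
  expect_equal(sum(log$new_track_count), nrow(s$tracks))
})

test_that("certain fog blinds every station-day", {
  s <- generate_season(season_config(beach_length_m = 200, n_days = 15,
                                     seed = 2))
  log <- simulate_camera_log(s, full_beach_station(200),
                             camera_failure_model(p_fog_day = 1,
                                                  p_fall_day = 0),
                             seed = 4)
  expect_true(all(log$status == "fog"))
  expect_true(all(is.na(log$track_count)))
})

test_that("falling is absorbing until service; full cards stop the camera", {
  s <- generate_season(season_config(beach_length_m = 200, n_days = 30,
                                     seed = 2))
  log <- simulate_camera_log(s, full_beach_station(200),
                             camera_failure_model(p_fall_day = 1),
                             seed = 4)
  expect_true(all(log$status == "fallen"))
  log2 <- simulate_camera_log(s, full_beach_station(200),
                              camera_failure_model(p_fog_day = 0,
                                                   p_fall_day = 0,
                                                   capacity_days = 10),
                              seed = 4)
  expect_equal(log2$status, c(rep("ok", 10), rep("storage_full", 20)))
})

test_that("overlapping station intervals are rejected", {
  s <- generate_season(season_config(beach_length_m = 200, n_days = 5,
                                     seed = 1))
  st <- rbind(camera_station("a", 0, 30), camera_station("b", 20, 30))
  expect_error(simulate_camera_log(s, st), "overlap")
})

test_that("daily patrols see only fresh tracks, matching the truth", {
  s <- generate_season(season_config(beach_length_m = 400, n_days = 40,
                                     seed = 31))
  p <- simulate_patrols(s, 1:40)
  expect_true(all(p$stale == 0))
  expect_true(all(p$gap_days == 1))
  expect_equal(p$fresh, s$days$n_tracks)
})

test_that("gap patrols split fresh and stale by deposition day", {
  tracks <- data.frame(day = c(3L, 4L, 5L), position_m = c(10L, 20L, 30L),
                       longevity = c(5L, 5L, 5L))
  s <- manual_season(tracks, n_days = 6)
  p <- simulate_patrols(s, c(2L, 5L))  # gap of 3 days: unsurveyed 3, 4
  expect_equal(p$fresh, c(0L, 1L))   # only the day-5 track is < 24 h old
  expect_equal(p$stale, c(0L, 2L))   # day-3 and day-4 tracks persist
  expect_equal(p$gap_days, c(2L, 3L))
  # a track whose persistence expires before the survey is missed
  tracks$longevity <- c(0L, 5L, 5L)
  p2 <- simulate_patrols(manual_season(tracks, 6), c(2L, 5L))
  expect_equal(p2$stale, c(0L, 1L))
})

test_that("a trackless season yields all-zero patrol counts", {
  s <- generate_season(season_config(beach_length_m = 300, n_days = 30,
                                     neap_mean = 0, spring_mean = 0,
                                     seed = 8))
  p <- simulate_patrols(s, seq(1, 30, by = 3))
  expect_true(all(p$fresh == 0) && all(p$stale == 0))
})

test_that("invalid season configurations are rejected", {
  expect_error(season_config(beach_length_m = 0), "positive")
  expect_error(season_config(neap_mean = -1), ">= 0")
  expect_error(season_config(beach_length_m = 100,
                             hotspot_profile = rep(0, 100)), "positive sum")
  expect_error(
    generate_season(season_config(beach_length_m = 100, n_days = 2,
                                  neap_mean = 50,
                                  hotspot_profile = c(10, rep(0.1, 99)))),
    "exceeds 1"
  )
})
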