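test_that("tidal-day indices partition into spring and neap", {
  expect_equal(classify_phase(0), "spring")
  expect_equal(classify_phase(7), "neap")
  expect_equal(classify_phase(11), "neap")
  expect_equal(classify_phase(12), "spring")
  phases <- classify_phase(0:14)
  expect_equal(sum(phases == "neap"), 8)
  expect_equal(sum(phases == "spring"), 7)
  expect_error(classify_phase(15), "\\[0, 14\\]")
  expect_error(classify_phase(-1), "\\[0, 14\\]")
})

test_that("stale tracks spread evenly with the remainder nearest the survey", {
  expect_equal(allocate_stale_tracks(3, 2), c(2L, 1L))
  expect_equal(allocate_stale_tracks(4, 3), c(2L, 1L, 1L))
  expect_equal(allocate_stale_tracks(0, 4), rep(0L, 4))
  expect_error(allocate_stale_tracks(3, 0), ">= 1")
})

test_that("allocation conserves totals and never increases with distance", {
  set.seed(55)
  for (i in 1:200) {
    stale <- sample(0:40, 1)
    gap <- sample(1:10, 1)
    a <- allocate_stale_tracks(stale, gap)
    expect_length(a, gap)
    expect_equal(sum(a), stale)
    expect_true(all(diff(a) <= 0))
  }
})

test_that("daily surveys pass fresh counts through unchanged", {
  patrols <- data.frame(date = 1:5, fresh = c(2L, 0L, 3L, 1L, 4L),
                        stale = 0L, gap_days = 1L, tidal_day = 0:4)
  series <- build_allocated_series(patrols)
  expect_equal(series$count, patrols$fresh)
  expect_true(all(series$source == "surveyed"))
  expect_equal(series$tidal_day, 0:4)
})

test_that("gap surveys compose fresh assignment with back-allocation", {
  # one survey 4 days after an anchor: 3 unsurveyed days, fresh 2, stale 4
  patrols <- data.frame(date = c(1L, 5L), fresh = c(0L, 2L),
                        stale = c(0L, 4L), gap_days = c(1L, 4L),
                        tidal_day = c(0L, 4L))
  series <- build_allocated_series(patrols)
  got <- series$count[match(2:5, series$date)]
  expect_equal(got, c(1L, 1L, 2L, 2L))  # days -3, -2, -1, survey
  expect_equal(sum(series$count), sum(patrols$fresh) + sum(patrols$stale))
  expect_equal(series$tidal_day[match(2:5, series$date)], 1:4)
  # stale without a gap to absorb it is inconsistent
  bad <- data.frame(date = 1:2, fresh = 0L, stale = c(0L, 1L),
                    gap_days = 1L, tidal_day = 0:1)
  expect_error(build_allocated_series(bad), "unsurveyed")
  # gap_days disagreeing with the calendar is inconsistent
  bad2 <- data.frame(date = c(1L, 5L), fresh = 0L, stale = 0L,
                     gap_days = c(1L, 2L), tidal_day = c(0L, 4L))
  expect_error(build_allocated_series(bad2), "day difference")
})

test_that("allocated series conserves synthetic deposits when tracks outlive gaps", {
  s <- generate_season(season_config(beach_length_m = 400, n_days = 45,
                                     seed = 61))
  s$tracks$longevity <- 9L  # every track outlives every 3-day gap
  patrols <- simulate_patrols(s, seq(3, 45, by = 3))
  series <- build_allocated_series(patrols)
  expect_equal(sum(series$count), sum(patrols$fresh) + sum(patrols$stale))
  expect_equal(sum(series$count), nrow(s$tracks))
})

test_that("two-day bins average across days and cycles", {
  bins <- two_day_bin_means(1:15, 0:14)
  expect_equal(bins$mean_count,
               c(1.5, 3.5, 5.5, 7.5, 9.5, 11.5, 13.5, 15))
  expect_equal(bins$bin[8], "14")
  # constant counts give constant bins
  expect_true(all(two_day_bin_means(rep(4, 30),
                                    rep(0:14, 2))$mean_count == 4))
  # two cycles pool four observations per two-day bin
  b2 <- two_day_bin_means(c(1:15, 16:30), rep(0:14, 2))
  expect_equal(b2$n_obs, c(rep(4L, 7), 2L))
  expect_equal(b2$mean_count[1], mean(c(1, 2, 16, 17)))
  # an unobserved bin is missing, not zero
  b3 <- two_day_bin_means(c(1, 2), c(0, 1))
  expect_true(is.na(b3$mean_count[2]))
  expect_warning(two_day_bin_means(1, 15), "clamped")
})

test_that("phase summaries report mean, SD and summed tracks", {
  ps <- phase_summary(c(3, 5), c(4, 6))
  expect_equal(ps$mean[ps$phase == "neap"], 4)
  expect_equal(ps$n_tracks[ps$phase == "neap"], 8)
  zeros <- phase_summary(rep(0, 15), 0:14)
  expect_true(all(zeros$mean == 0) && all(zeros$n_tracks == 0))
  # parameter recovery over a long synthetic campaign
  s <- generate_season(season_config(n_days = 3000, seed = 77))
  ps2 <- phase_summary(s$days$n_tracks, s$days$tidal_day)
  for (ph in c("neap", "spring")) {
    row <- ps2[ps2$phase == ph, ]
    target <- if (ph == "neap") 5.0 else 2.4
    expect_lt(abs(row$mean - target), 3 * row$sd / sqrt(row$n_days))
  }
})
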