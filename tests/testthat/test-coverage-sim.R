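test_that("per-metre probability is mean over length, printed truncated", {
  expect_equal(per_metre_probability(1000, 5), 0.005)
  expect_equal(per_metre_probability(100, 0), 0)
  expect_equal(format_probability(per_metre_probability(2800, 6)),
               "0.0021428")
  expect_error(per_metre_probability(100, 200), "cannot exceed")
  expect_error(beach_model(0, 6), "positive")
})

test_that("simulate_day draws honest per-metre Bernoulli indicators", {
  expect_true(all(simulate_day(beach_model(500, 0)) == 0))
  expect_true(all(simulate_day(beach_model(500, 500)) == 1))
  set.seed(12)
  b <- beach_model(2000, 2000 * 0.0021428)
  draws <- replicate(500, sum(simulate_day(b)))  # 10^6 metre-days
  phat <- sum(draws) / 1e6
  se <- sqrt(b$q * (1 - b$q) / 1e6)
  expect_lt(abs(phat - b$q), 3 * se)
})

test_that("closed-form SD evaluates and scales correctly", {
  b <- beach_model(2800, 6)
  # direct evaluation: sqrt(6 * 0.9978572 / 90) and /9
  expect_equal(coverage_sd_closed_form(b, 1, 90), 0.2579221,
               tolerance = 1e-6)
  expect_equal(coverage_sd_closed_form(b, 0.10, 90), 0.8156213,
               tolerance = 1e-6)
  # doubling coverage divides the SD by sqrt(2)
  expect_equal(coverage_sd_closed_form(b, 0.2, 90) * sqrt(2),
               coverage_sd_closed_form(b, 0.1, 90))
  # halving beach length at the same daily mean leaves the SD unchanged
  # up to the (1 - q) finite-population factor (q doubles)
  b2 <- beach_model(1400, 6)
  expect_equal(coverage_sd_closed_form(b2, 0.1, 90),
               coverage_sd_closed_form(b, 0.1, 90), tolerance = 2e-3)
})

test_that("full coverage gives factor-1 extrapolation near the true mean", {
  b <- beach_model(2800, 6)
  r <- run_coverage_simulation(b, 100, n_days = 90, n_reps = 50, seed = 5)
  expect_equal(r$covered_m, 2800L)
  se <- coverage_sd_closed_form(b, 1, 90)
  expect_true(all(abs(r$rep_means - 6) < 5 * se))
  expect_lt(abs(r$mean_of_means - 6), 3 * se / sqrt(50))
})

test_that("fixed seed makes the simulation bit-identical", {
  b <- beach_model(2800, 6)
  expect_identical(run_coverage_simulation(b, 10, seed = 7),
                   run_coverage_simulation(b, 10, seed = 7))
  expect_identical(sweep_coverage(b, seed = 7), sweep_coverage(b, seed = 7))
})

test_that("thinned covered-count path matches explicit per-metre simulation", {
  # dual route on a small beach: covered-count per day drawn directly as
  # Binomial(m, q) vs. summing an explicit per-metre day over chosen metres
  b <- beach_model(100, 2)
  m <- 50L
  set.seed(33)
  explicit <- replicate(400, {
    covered <- sample.int(100, m)
    mean(vapply(1:30, function(d) sum(simulate_day(b)[covered]) * 100 / m,
                numeric(1)))
  })
  thinned <- run_coverage_simulation(b, 50, n_days = 30, n_reps = 400,
                                     seed = 34)
  oracle_sd <- coverage_sd_closed_form(b, 0.5, 30)
  tol <- 3 * oracle_sd / sqrt(2 * 399)
  expect_lt(abs(sd(explicit) - oracle_sd), tol)
  expect_lt(abs(thinned$sd_of_means - oracle_sd), tol)
  expect_lt(abs(mean(explicit) - thinned$mean_of_means),
            6 * oracle_sd / sqrt(400))
})

test_that("simulated spread matches the analytic oracle across the grid", {
  b <- beach_model(2800, 6)
  sw <- sweep_coverage(b, seed = 19)
  tab <- coverage_summary(sw)
  for (i in seq_len(nrow(tab))) {
    oracle <- coverage_sd_closed_form(b, tab$coverage_percent[i] / 100, 90)
    mc_tol <- 3 * oracle / sqrt(2 * 99)  # sampling SD of an SD, 100 reps
    expect_lt(abs(tab$sd_of_means[i] - oracle), mc_tol)
    se_mean <- oracle / sqrt(100)
    expect_lt(abs(tab$mean_of_means[i] - 6), 3 * se_mean)
  }
  # closed-form SDs decrease with coverage
  oracle_sds <- coverage_sd_closed_form(b, tab$coverage_percent / 100, 90)
  expect_true(all(diff(oracle_sds) < 0))
})

test_that("camera-count planning arithmetic matches hand calculation", {
  x <- cameras_needed(2800, 0.20, 30)
  expect_equal(x$covered_m, 560)
  expect_equal(x$exact_quotient_1dp, 18.6)
  expect_equal(x$recommended_count, 19L)
  expect_equal(cameras_needed(2800, 0.20, 30, round_up_to = 10)$recommended_count,
               20L)
  expect_equal(cameras_needed(2800, 1.0, 2800)$recommended_count, 1L)
  y <- cameras_needed(1000, 0.10, 25)
  expect_equal(y$covered_m, 100)
  expect_equal(y$exact_quotient, 4)
  expect_error(cameras_needed(2800, 0.2, 0), "positive")
})
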