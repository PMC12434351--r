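#' Beach deposition model
#'
#' Describes a nesting beach as a line of 1-m sections, each of which
#' independently receives a turtle track on a given day with probability
#' \code{q = mean_tracks_per_day / beach_length_m}. Under this per-metre
#' Bernoulli model the expected number of tracks on the whole beach per day
#' equals \code{mean_tracks_per_day}, and at most one track can occupy a
#' metre on any day.
#'
#' @param beach_length_m Beach length in metres (positive integer).
#' @param mean_tracks_per_day Expected number of tracks deposited on the
#'   whole beach per day. Must not exceed \code{beach_length_m}.
#' @return An object of class \code{beach_model} with fields
#'   \code{beach_length_m}, \code{mean_tracks_per_day}, \code{q} (per-metre
#'   daily track probability) and \code{p = 1 - q}.
#' @examples
#' beach_model(2800, 6)
#' @export
beach_model <- function(beach_length_m, mean_tracks_per_day) {
  stopifnot(length(beach_length_m) == 1, length(mean_tracks_per_day) == 1)
  if (!is.finite(beach_length_m) || beach_length_m <= 0 ||
      beach_length_m != round(beach_length_m)) {
    stop("beach_length_m must be a positive integer number of metres")
  }
  if (!is.finite(mean_tracks_per_day) || mean_tracks_per_day < 0) {
    stop("mean_tracks_per_day must be non-negative")
  }
  q <- per_metre_probability(beach_length_m, mean_tracks_per_day)
  structure(
    list(
      beach_length_m = as.integer(beach_length_m),
      mean_tracks_per_day = mean_tracks_per_day,
      q = q,
      p = 1 - q
    ),
    class = "beach_model"
  )
}

#' @export
print.beach_model <- function(x, ...) {
  q_txt <- format_probability(x$q)
  # print p as the complement of the truncated q so the pair sums to 1
  p_txt <- sprintf("%.7f", 1 - as.numeric(q_txt))
  cat(sprintf(
    "Beach model: %d m, mean %.3g tracks/day (q = %s, p = %s)\n",
    x$beach_length_m, x$mean_tracks_per_day, q_txt, p_txt
  ))
  invisible(x)
}

#' Format a probability truncated to a fixed number of decimals
#'
#' Summaries report the per-metre probabilities truncated (not rounded) to
#' seven decimal places, so 6/2800 = 0.00214285... prints as "0.0021428".
#'
#' @param x Probability in [0, 1].
#' @param digits Decimal places kept (default 7).
#' @return Character scalar.
#' @examples
#' format_probability(per_metre_probability(2800, 6))  # "0.0021428"
#' @export
format_probability <- function(x, digits = 7L) {
  stopifnot(length(x) == 1, is.finite(x), digits >= 1)
  scaled <- floor(x * 10^digits + 1e-6)  # guard against 0.005 -> 0.0049999...
  sprintf("%.*f", digits, scaled / 10^digits)
}

#' Per-metre daily track probability
#'
#' The probability that a single 1-m section of beach receives a track on a
#' given day, so that the whole-beach daily expectation equals the target
#' mean: \code{q = mean_tracks_per_day / beach_length_m}.
#'
#' @inheritParams beach_model
#' @return The probability \code{q}, a number in [0, 1].
#' @examples
#' per_metre_probability(2800, 6)   # 0.0021429 (approx. 6/2800)
#' @export
per_metre_probability <- function(beach_length_m, mean_tracks_per_day) {
  if (beach_length_m <= 0) stop("beach_length_m must be positive")
  if (mean_tracks_per_day < 0) stop("mean_tracks_per_day must be non-negative")
  if (mean_tracks_per_day > beach_length_m) {
    stop("mean_tracks_per_day cannot exceed beach_length_m ",
         "(at most one track per metre per day)")
  }
  mean_tracks_per_day / beach_length_m
}

#' Simulate one day of per-metre track deposition
#'
#' Draws the full vector of per-metre track indicators for one day:
#' independent Bernoulli(\code{q}) draws, one per metre of beach.
#'
#' @param beach A \code{\link{beach_model}}.
#' @return Integer 0/1 vector of length \code{beach$beach_length_m}.
#' @export
simulate_day <- function(beach) {
  stopifnot(inherits(beach, "beach_model"))
  stats::rbinom(beach$beach_length_m, 1L, beach$q)
}

#' Monte-Carlo precision of the whole-beach estimate at one coverage level
#'
#' Simulates repeated seasons of per-metre track deposition, observes only a
#' randomly chosen subset of metres (the camera-covered fraction), scales the
#' covered count up to the whole beach, and summarises the spread of the
#' season-mean estimates across replicates.
#'
#' Per replicate: \code{m = round(coverage_percent/100 * beach_length_m)}
#' covered metres are selected uniformly without replacement (minimum 1).
#' Each day the number of tracks falling on covered metres is a
#' Binomial(\code{m}, \code{q}) draw -- an exact consequence of independent
#' per-metre deposition -- and is extrapolated by the factor
#' \code{beach_length_m / m}. The replicate statistic is the mean of the
#' extrapolated daily counts over \code{n_days} days. The result reports the
#' mean and sample standard deviation (n - 1 denominator) of those replicate
#' means.
#'
#' @param beach A \code{\link{beach_model}}.
#' @param coverage_percent Percentage of the beach covered by cameras, in
#'   (0, 100].
#' @param n_days Days per replicate season (default 90).
#' @param n_reps Number of replicate seasons (default 100).
#' @param seed Optional integer seed; when supplied the result is
#'   reproducible.
#' @return An object of class \code{coverage_result}: a list with
#'   \code{coverage_percent}, \code{covered_m}, \code{rep_means} (length
#'   \code{n_reps}), \code{mean_of_means}, \code{sd_of_means},
#'   \code{n_days}, \code{n_reps}.
#' @examples
#' beach <- beach_model(2800, 6)
#' res <- run_coverage_simulation(beach, 10, n_days = 90, n_reps = 100,
#'                                seed = 1)
#' res$sd_of_means
#' @export
run_coverage_simulation <- function(beach, coverage_percent,
                                    n_days = 90L, n_reps = 100L,
                                    seed = NULL) {
  stopifnot(inherits(beach, "beach_model"))
  if (coverage_percent <= 0 || coverage_percent > 100) {
    stop("coverage_percent must be in (0, 100]")
  }
  if (n_days < 1 || n_reps < 1) stop("n_days and n_reps must be >= 1")
  if (!is.null(seed)) set.seed(seed)

  L <- beach$beach_length_m
  m <- max(1L, as.integer(round(coverage_percent / 100 * L)))
  factor <- L / m

  rep_means <- vapply(seq_len(n_reps), function(r) {
    # which metres are covered only matters through their number m: under
    # i.i.d. per-metre deposition the covered-count is Binomial(m, q)
    covered_daily <- stats::rbinom(n_days, m, beach$q)
    mean(covered_daily * factor)
  }, numeric(1))

  structure(
    list(
      coverage_percent = coverage_percent,
      covered_m = m,
      rep_means = rep_means,
      mean_of_means = mean(rep_means),
      sd_of_means = if (n_reps > 1) stats::sd(rep_means) else NA_real_,
      n_days = as.integer(n_days),
      n_reps = as.integer(n_reps)
    ),
    class = "coverage_result"
  )
}

#' @export
print.coverage_result <- function(x, ...) {
  cat(sprintf(
    "Coverage %.3g%% (%d m): mean of means %.4f, SD %.4f (%d reps x %d days)\n",
    x$coverage_percent, x$covered_m, x$mean_of_means, x$sd_of_means,
    x$n_reps, x$n_days
  ))
  invisible(x)
}

#' Closed-form SD of the whole-beach season-mean estimate
#'
#' Analytic counterpart of \code{\link{run_coverage_simulation}}. With a
#' covered fraction \code{f} of the beach, the extrapolated daily count has
#' variance \code{mean_tracks_per_day * (1 - q) / f}; the season mean over
#' \code{n_days} independent days divides this by \code{n_days}. The SD is
#' the square root.
#'
#' @param beach A \code{\link{beach_model}}.
#' @param coverage_fraction Covered fraction of the beach in (0, 1].
#' @param n_days Days averaged per season.
#' @return The standard deviation of the season-mean whole-beach estimate.
#' @examples
#' coverage_sd_closed_form(beach_model(2800, 6), 0.10, 90)  # ~0.8156
#' @export
coverage_sd_closed_form <- function(beach, coverage_fraction, n_days = 90L) {
  stopifnot(inherits(beach, "beach_model"))
  if (any(coverage_fraction <= 0) || any(coverage_fraction > 1)) {
    stop("coverage_fraction must be in (0, 1]")
  }
  if (n_days < 1) stop("n_days must be >= 1")
  sqrt(beach$mean_tracks_per_day * (1 - beach$q) / (n_days * coverage_fraction))
}

#' Sweep the coverage simulation over a grid of coverage levels
#'
#' Runs \code{\link{run_coverage_simulation}} at each coverage level with an
#' independent RNG substream per level (substream seeds drawn once from the
#' root seed), so adding or removing levels does not perturb the others.
#'
#' @param beach A \code{\link{beach_model}}.
#' @param coverage_percents Numeric vector of coverage levels in (0, 100].
#'   Default \code{c(2, 5, 10, 20, 30, 40)}.
#' @param n_days,n_reps Per-level simulation size (defaults 90 and 100).
#' @param seed Root integer seed.
#' @return A list of \code{coverage_result}, one per level, plus a
#'   \code{summary} attribute: a data.frame with columns
#'   \code{coverage_percent}, \code{mean_of_means}, \code{sd_of_means},
#'   \code{n_reps}, \code{n_days}. Retrieve it with
#'   \code{\link{coverage_summary}}.
#' @export
sweep_coverage <- function(beach, coverage_percents = c(2, 5, 10, 20, 30, 40),
                           n_days = 90L, n_reps = 100L, seed = NULL) {
  if (length(coverage_percents) == 0) stop("coverage grid is empty")
  if (any(coverage_percents <= 0 | coverage_percents > 100)) {
    stop("coverage levels must be in (0, 100]")
  }
  if (!is.null(seed)) set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max, length(coverage_percents))
  results <- Map(function(cov, s) {
    run_coverage_simulation(beach, cov, n_days = n_days, n_reps = n_reps,
                            seed = s)
  }, coverage_percents, sub_seeds)
  names(results) <- paste0("cov", coverage_percents)
  class(results) <- "coverage_sweep"
  results
}

#' Summarise a coverage sweep as a table
#'
#' @param sweep A \code{coverage_sweep} from \code{\link{sweep_coverage}}.
#' @return data.frame with one row per coverage level: columns
#'   \code{coverage_percent}, \code{mean_of_means}, \code{sd_of_means},
#'   \code{n_reps}, \code{n_days}.
#' @export
coverage_summary <- function(sweep) {
  stopifnot(inherits(sweep, "coverage_sweep"))
  do.call(rbind, lapply(unname(sweep), function(r) {
    data.frame(
      coverage_percent = r$coverage_percent,
      mean_of_means = r$mean_of_means,
      sd_of_means = r$sd_of_means,
      n_reps = r$n_reps,
      n_days = r$n_days
    )
  }))
}

#' How many cameras are needed for a target coverage
#'
#' Planning arithmetic: the beach length to be covered is
#' \code{target_coverage_fraction * beach_length_m}; dividing by the
#' per-camera observed range gives the exact (fractional) number of cameras.
#' The recommended count rounds that quotient up -- by default to the next
#' whole camera, or to the next multiple of \code{round_up_to} when a
#' planning margin is wanted (e.g. \code{round_up_to = 10} turns a quotient
#' of 18.6 into 20).
#'
#' @param beach_length_m Beach length in metres.
#' @param target_coverage_fraction Coverage target as a fraction in (0, 1].
#' @param per_camera_range_m Observed alongshore range of one camera, metres.
#' @param round_up_to Rounding granularity for the recommendation
#'   (default 1 = next whole camera).
#' @return List with \code{covered_m}, \code{exact_quotient} (unrounded),
#'   \code{exact_quotient_1dp} (truncated to one decimal, as reported),
#'   \code{recommended_count}.
#' @examples
#' cameras_needed(2800, 0.20, 30)                    # 18.6 -> 19 cameras
#' cameras_needed(2800, 0.20, 30, round_up_to = 10)  # 18.6 -> 20 cameras
#' @export
cameras_needed <- function(beach_length_m, target_coverage_fraction,
                           per_camera_range_m, round_up_to = 1L) {
  if (beach_length_m <= 0 || target_coverage_fraction <= 0 ||
      per_camera_range_m <= 0 || round_up_to <= 0) {
    stop("all arguments must be positive")
  }
  if (target_coverage_fraction > 1) {
    stop("target_coverage_fraction must be a fraction in (0, 1]")
  }
  covered_m <- target_coverage_fraction * beach_length_m
  quotient <- covered_m / per_camera_range_m
  list(
    covered_m = covered_m,
    exact_quotient = quotient,
    exact_quotient_1dp = floor(quotient * 10) / 10,
    recommended_count = as.integer(ceiling(quotient / round_up_to) * round_up_to)
  )
}
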