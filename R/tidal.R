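#' Classify a tidal day as spring or neap
#'
#' The tidal calendar is a repeating 15-day cycle indexed 0-14, with day 0
#' the spring tide (the highest tide on or after the most recent full or new
#' moon). Days 0-3 and 12-14 are classified as spring-tide days, days 4-11
#' as neap-tide days.
#'
#' @param tidal_day Integer(s) in [0, 14].
#' @return Character vector, "spring" or "neap".
#' @examples
#' classify_phase(0)    # "spring"
#' classify_phase(7)    # "neap"
#' classify_phase(0:14)
#' @export
classify_phase <- function(tidal_day) {
  if (any(!is.finite(tidal_day)) || any(tidal_day != round(tidal_day)) ||
      any(tidal_day < 0) || any(tidal_day > 14)) {
    stop("tidal_day must be integers in [0, 14]")
  }
  ifelse(tidal_day >= 4 & tidal_day <= 11, "neap", "spring")
}

#' Back-allocate stale tracks across a survey gap
#'
#' When surveys are not daily, tracks found that are visibly more than 24 h
#' old must have been deposited on one of the unsurveyed gap days. They are
#' spread as evenly as possible: every gap day gets floor(stale/gap), and
#' the remainder goes one-per-day to the gap days nearest the survey.
#'
#' @param stale_count Number of >24-h-old tracks observed (>= 0).
#' @param gap_days Number of unsurveyed days they must be spread over (>= 1).
#' @return Integer vector of length \code{gap_days}, ordered from the day
#'   nearest the survey to the farthest, summing to \code{stale_count}.
#' @examples
#' allocate_stale_tracks(3, 2)  # c(2, 1)
#' allocate_stale_tracks(4, 3)  # c(2, 1, 1)
#' @export
allocate_stale_tracks <- function(stale_count, gap_days) {
  if (gap_days < 1) stop("gap_days must be >= 1")
  if (stale_count < 0) stop("stale_count must be >= 0")
  base <- stale_count %/% gap_days
  remainder <- stale_count %% gap_days
  alloc <- rep(base, gap_days)
  if (remainder > 0) alloc[seq_len(remainder)] <- alloc[seq_len(remainder)] + 1L
  as.integer(alloc)
}

#' Build a per-calendar-day track series from a patrol table
#'
#' Fresh counts (tracks < 24 h old) are assigned to their survey date; stale
#' counts are back-allocated over the preceding gap days with
#' \code{\link{allocate_stale_tracks}}. The total allocated count always
#' equals the total of fresh plus stale counts.
#'
#' The \code{gap_days} column is the calendar-day difference to the previous
#' survey: 1 for daily surveys (no unsurveyed days, so \code{stale} must be
#' 0), and \code{k} when \code{k - 1} unsurveyed days separate the surveys;
#' stale tracks are spread over those \code{k - 1} days.
#'
#' @param patrols data.frame with columns \code{date} (Date or integer day
#'   index, strictly increasing), \code{fresh}, \code{stale},
#'   \code{gap_days} (days since the previous survey, >= 1), and optionally
#'   \code{tidal_day}.
#' @return data.frame with one row per calendar day carrying allocated
#'   tracks: columns \code{date}, \code{count}, \code{source}
#'   ("surveyed" or "back-allocated"), and \code{tidal_day} when the input
#'   has it (back-filled along the calendar, modulo the 15-day cycle).
#' @export
build_allocated_series <- function(patrols) {
  req <- c("date", "fresh", "stale", "gap_days")
  if (!all(req %in% names(patrols))) {
    stop("patrol table needs columns: ", paste(req, collapse = ", "))
  }
  if (nrow(patrols) == 0) stop("empty patrol table")
  if (is.unsorted(as.numeric(patrols$date), strictly = TRUE)) {
    stop("patrol dates must be strictly increasing")
  }
  if (any(patrols$gap_days < 1)) stop("gap_days must be >= 1")
  if (any(patrols$fresh < 0) || any(patrols$stale < 0)) {
    stop("counts must be non-negative")
  }
  d <- as.numeric(patrols$date) - as.numeric(patrols$date[1])
  if (nrow(patrols) > 1 && any(diff(d) != patrols$gap_days[-1])) {
    stop("gap_days must equal the day difference to the previous survey")
  }

  has_tide <- "tidal_day" %in% names(patrols)
  rows <- vector("list", nrow(patrols))
  for (i in seq_len(nrow(patrols))) {
    n_unsurveyed <- patrols$gap_days[i] - 1L
    date_i <- patrols$date[i]
    if (n_unsurveyed == 0L && patrols$stale[i] > 0) {
      stop("row ", i, ": stale tracks reported but no unsurveyed gap days")
    }
    alloc <- if (n_unsurveyed > 0L) {
      allocate_stale_tracks(patrols$stale[i], n_unsurveyed)
    } else {
      integer(0)
    }
    # survey day gets the fresh count; unsurveyed days d-1, d-2, ... the
    # back-allocation (zero-count gap days stay in the series: they are
    # observed zero days for downstream means)
    day_offsets <- c(0L, seq_len(n_unsurveyed))
    counts <- c(patrols$fresh[i], alloc)
    src <- c("surveyed", rep("back-allocated", n_unsurveyed))
    td <- if (has_tide) {
      (patrols$tidal_day[i] - day_offsets) %% 15L
    } else {
      rep(NA_integer_, length(day_offsets))
    }
    rows[[i]] <- data.frame(
      date = date_i - day_offsets,
      count = as.integer(counts),
      source = src,
      tidal_day = as.integer(td)
    )
  }
  out <- do.call(rbind, rows)
  out <- out[order(as.numeric(out$date)), , drop = FALSE]
  rownames(out) <- NULL
  if (!has_tide) out$tidal_day <- NULL
  out
}

#' Mean track count in two-day tidal bins
#'
#' Averages daily counts over two-day bins of the tidal cycle:
#' (0,1), (2,3), ..., (12,13), with day 14 its own singleton bin.
#' Observations from multiple cycles pool into the same bin. Tidal-day
#' labels above 14 are clamped to 14 with a warning (cycles occasionally
#' run a day long).
#'
#' @param counts Numeric vector of daily track counts.
#' @param tidal_days Integer vector of tidal-day indices (same length).
#' @return data.frame with columns \code{bin} (label such as "0-1"),
#'   \code{days} (first day of the bin), \code{mean_count} (NA for bins with
#'   no observations), \code{n_obs}.
#' @examples
#' two_day_bin_means(1:15, 0:14)$mean_count  # 1.5 3.5 ... 13.5 15
#' @export
two_day_bin_means <- function(counts, tidal_days) {
  if (length(counts) != length(tidal_days)) stop("lengths differ")
  if (any(tidal_days < 0)) stop("tidal_days must be >= 0")
  if (any(tidal_days > 14)) {
    warning("tidal_day > 14 clamped to 14")
    tidal_days <- pmin(tidal_days, 14L)
  }
  bin_start <- ifelse(tidal_days >= 14, 14L, (tidal_days %/% 2L) * 2L)
  starts <- seq(0L, 14L, by = 2L)
  labels <- c(paste(starts[-8], starts[-8] + 1L, sep = "-"), "14")
  means <- vapply(starts, function(s) {
    v <- counts[bin_start == s]
    if (length(v) == 0) NA_real_ else mean(v)
  }, numeric(1))
  ns <- vapply(starts, function(s) sum(bin_start == s), integer(1))
  data.frame(bin = labels, days = starts, mean_count = means, n_obs = ns)
}

#' Per-phase summary of daily track counts
#'
#' @param counts Numeric vector of daily track counts.
#' @param tidal_days Integer vector of tidal-day indices in [0, 14] (same
#'   length), classified with \code{\link{classify_phase}}.
#' @return data.frame with one row per phase ("neap", "spring"):
#'   \code{mean} and sample \code{sd} of the daily counts, \code{n_days},
#'   and \code{n_tracks} (summed counts). Phases with no days are dropped.
#' @examples
#' phase_summary(c(3, 5), c(4, 6))  # neap mean 4, n_tracks 8
#' @export
phase_summary <- function(counts, tidal_days) {
  if (length(counts) != length(tidal_days)) stop("lengths differ")
  if (length(counts) == 0) stop("no observations")
  phase <- classify_phase(tidal_days)
  out <- do.call(rbind, lapply(c("neap", "spring"), function(ph) {
    v <- counts[phase == ph]
    if (length(v) == 0) return(NULL)
    data.frame(
      phase = ph,
      mean = mean(v),
      sd = if (length(v) > 1) stats::sd(v) else NA_real_,
      n_days = length(v),
      n_tracks = sum(v)
    )
  }))
  rownames(out) <- NULL
  out
}
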