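#' Define a camera station along the beach
#'
#' A station observes a half-open alongshore interval
#' \code{[position_m, position_m + observed_range_m)}, metres measured
#' 0-based from the southern end of the beach. A track is attributed to the
#' station whose interval contains its metre index.
#'
#' @param station_id Identifier (character or integer).
#' @param position_m Start of the observed interval, metres (>= 0).
#' @param observed_range_m Alongshore distance observed by the camera,
#'   metres (> 0; 5-30 m is typical for a trunk-mounted trail camera).
#' @return data.frame row with columns \code{station_id}, \code{start_m},
#'   \code{end_m}, \code{observed_range_m}.
#' @export
camera_station <- function(station_id, position_m, observed_range_m) {
  if (position_m < 0) stop("position_m must be >= 0")
  if (observed_range_m <= 0) stop("observed_range_m must be > 0")
  data.frame(
    station_id = station_id,
    start_m = position_m,
    end_m = position_m + observed_range_m,
    observed_range_m = observed_range_m
  )
}

#' Calibrate a station's observed range from marker tracks
#'
#' In the field, artificial "turtle tracks" are drawn in the sand at fixed
#' spacing away from the camera until they are no longer visible in the
#' image; the observed range is the distance to the farthest visible marker.
#'
#' @param n_visible_markers Number of marker tracks visible in the image
#'   (>= 0; 0 means the station sees nothing and should be excluded).
#' @param marker_spacing_m Spacing between consecutive markers, metres
#'   (default 5).
#' @return Observed range in metres: \code{n_visible_markers *
#'   marker_spacing_m}.
#' @examples
#' calibrate_station_range(6)      # 30 m
#' calibrate_station_range(1, 5)   # 5 m
#' @export
calibrate_station_range <- function(n_visible_markers, marker_spacing_m = 5) {
  if (any(n_visible_markers < 0)) stop("marker count must be >= 0")
  if (marker_spacing_m <= 0) stop("marker spacing must be > 0")
  n_visible_markers * marker_spacing_m
}

#' Extrapolate a raw camera count to the whole beach
#'
#' Assuming track density on the camera-covered sections reflects density
#' across the whole beach, the whole-beach daily estimate is
#' \code{beach_length_m / covered_m * raw_count}. The result is real-valued
#' and deliberately not rounded: season totals of such estimates are
#' non-integer.
#'
#' A day with zero covered metres has no defined estimate: it must be
#' flagged and excluded from means, never treated as a zero-track day --
#' pass \code{covered_m = 0} and the function returns \code{NA} with a
#' warning rather than an error so day-wise pipelines can carry the flag.
#'
#' @param raw_count Raw track count from the cameras that day (>= 0).
#' @param covered_m Metres of beach observed by working cameras that day.
#' @param beach_length_m Total beach length, metres.
#' @return Whole-beach daily estimate (numeric), or \code{NA_real_} when
#'   \code{covered_m} is 0.
#' @examples
#' extrapolate_daily_count(1, 124.9, 2800)  # 22.418
#' @export
extrapolate_daily_count <- function(raw_count, covered_m, beach_length_m) {
  if (beach_length_m <= 0) stop("beach_length_m must be > 0")
  if (any(raw_count < 0)) stop("raw_count must be >= 0")
  if (any(covered_m < 0) || any(covered_m > beach_length_m)) {
    stop("covered_m must be in [0, beach_length_m]")
  }
  out <- beach_length_m / covered_m * raw_count
  if (any(covered_m == 0)) {
    warning("day(s) with zero covered metres: estimate undefined (NA), ",
            "exclude from means")
    out[covered_m == 0] <- NA_real_
  }
  out
}

#' Daily coverage and raw counts from a camera log
#'
#' Collapses a station-day camera log into one row per date: metres observed
#' by working stations, working/failed station counts (failures broken out
#' by cause), and the summed raw track count over working stations.
#'
#' @param camera_log data.frame with columns \code{date}, \code{station_id},
#'   \code{status} (one of "ok", "fog", "fallen", "storage_full"),
#'   \code{observed_m}, \code{track_count} (NA on failed days).
#' @return data.frame with one row per date: \code{date}, \code{covered_m},
#'   \code{raw_count}, \code{n_working}, \code{n_fog}, \code{n_fallen},
#'   \code{n_storage_full}.
#' @export
daily_coverage <- function(camera_log) {
  req <- c("date", "station_id", "status", "observed_m", "track_count")
  if (!all(req %in% names(camera_log))) {
    stop("camera log needs columns: ", paste(req, collapse = ", "))
  }
  bad <- setdiff(unique(camera_log$status), camera_log_statuses())
  if (length(bad) > 0) stop("unknown status: ", paste(bad, collapse = ", "))
  has_new <- "new_track_count" %in% names(camera_log)
  split_days <- split(camera_log, camera_log$date)
  out <- do.call(rbind, lapply(split_days, function(day) {
    ok <- day$status == "ok"
    data.frame(
      date = day$date[1],
      covered_m = sum(day$observed_m[ok]),
      raw_count = if (any(ok)) sum(day$track_count[ok]) else NA_integer_,
      raw_new_count = if (!has_new) NA_integer_
        else if (any(ok)) sum(day$new_track_count[ok]) else NA_integer_,
      n_working = sum(ok),
      n_fog = sum(day$status == "fog"),
      n_fallen = sum(day$status == "fallen"),
      n_storage_full = sum(day$status == "storage_full")
    )
  }))
  rownames(out) <- NULL
  out[order(as.numeric(out$date)), , drop = FALSE]
}

#' Whole-beach daily estimates from a camera log
#'
#' Runs \code{\link{daily_coverage}} and extrapolates each day's raw count
#' by that day's covered metres (coverage varies day to day as cameras fail
#' and recover). Days with no working camera get \code{NA} estimates.
#'
#' By default the newly appearing tracks per day are extrapolated when the
#' log carries a \code{new_track_count} column (emergences, comparable to
#' patrol counts); otherwise the all-visible \code{track_count} is used,
#' which measures track-days (each track counted on every day it persists).
#'
#' @param camera_log Station-day log (see \code{\link{daily_coverage}}).
#' @param beach_length_m Total beach length, metres.
#' @param count Which raw count to extrapolate: "new" (default when
#'   available) or "visible".
#' @return The \code{daily_coverage} table with an added \code{estimate}
#'   column.
#' @export
extrapolate_camera_log <- function(camera_log, beach_length_m,
                                   count = c("new", "visible")) {
  count <- match.arg(count)
  cov <- daily_coverage(camera_log)
  raw <- if (count == "new" && !all(is.na(cov$raw_new_count))) {
    cov$raw_new_count
  } else {
    cov$raw_count
  }
  cov$estimate <- suppressWarnings(
    extrapolate_daily_count(ifelse(is.na(raw), 0, raw),
                            cov$covered_m, beach_length_m)
  )
  cov$estimate[cov$covered_m == 0 | is.na(raw)] <- NA_real_
  cov
}

#' Summarise whole-beach daily estimates
#'
#' Mean, sample SD, range and total of daily estimates over defined days
#' (days flagged \code{NA} -- no working camera -- are excluded from every
#' statistic and counted separately). With phase labels supplied, one
#' summary row per phase is returned as well as the overall row.
#'
#' @param estimates Numeric vector of daily whole-beach estimates, \code{NA}
#'   for undefined days.
#' @param phases Optional character vector of phase labels (same length).
#' @return data.frame with columns \code{phase} ("all" plus any labels),
#'   \code{mean}, \code{sd}, \code{min}, \code{max},
#'   \code{total_extrapolated}, \code{n_days}, \code{n_undefined_days}.
#' @examples
#' summarize_estimates(c(0, 0, 6))  # mean 2, total 6
#' @export
summarize_estimates <- function(estimates, phases = NULL) {
  if (length(estimates) == 0) stop("no days supplied")
  if (all(is.na(estimates))) stop("all days undefined (no working cameras)")
  one <- function(label, v) {
    ok <- !is.na(v)
    data.frame(
      phase = label,
      mean = mean(v[ok]),
      sd = if (sum(ok) > 1) stats::sd(v[ok]) else NA_real_,
      min = min(v[ok]),
      max = max(v[ok]),
      total_extrapolated = sum(v[ok]),
      n_days = sum(ok),
      n_undefined_days = sum(!ok)
    )
  }
  out <- one("all", estimates)
  if (!is.null(phases)) {
    stopifnot(length(phases) == length(estimates))
    for (ph in unique(phases)) {
      v <- estimates[phases == ph]
      if (any(!is.na(v))) out <- rbind(out, one(ph, v))
    }
  }
  rownames(out) <- NULL
  out
}
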