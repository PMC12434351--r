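#' Allowed station-day status tokens in a camera log
#' @return Character vector: "ok", "fog", "fallen", "storage_full".
#' @export
camera_log_statuses <- function() c("ok", "fog", "fallen", "storage_full")

stop_rows <- function(msg, rows) {
  stop(msg, " (row", if (length(rows) > 1) "s", " ",
       paste(rows, collapse = ", "), ")", call. = FALSE)
}

#' Read a patrol-survey CSV
#'
#' Expected columns: \code{date}, \code{fresh}, \code{stale},
#' \code{gap_days}, \code{tidal_day}. Dates are ISO-8601 or integer day
#' indices. Validation errors name the offending rows.
#'
#' @param path CSV file path.
#' @return Validated data.frame of patrol days.
#' @export
read_patrol_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("date", "fresh", "stale", "gap_days", "tidal_day")
  missing_cols <- setdiff(req, names(x))
  if (length(missing_cols) > 0) {
    stop("patrol CSV missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(x) == 0) return(x)
  x$date <- parse_date_col(x$date)
  bad <- which(x$fresh < 0 | x$stale < 0)
  if (length(bad) > 0) stop_rows("negative track counts", bad)
  bad <- which(x$gap_days < 1)
  if (length(bad) > 0) stop_rows("gap_days must be >= 1", bad)
  bad <- which(x$tidal_day < 0 | x$tidal_day > 14)
  if (length(bad) > 0) stop_rows("tidal_day outside [0, 14]", bad)
  x
}

#' Write a patrol-survey CSV
#' @param patrols Patrol data.frame.
#' @param path Output path.
#' @export
write_patrol_csv <- function(patrols, path) {
  utils::write.csv(patrols, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a camera daily-log CSV
#'
#' Expected columns: \code{date}, \code{station_id}, \code{status},
#' \code{observed_m}, \code{track_count}. The status vocabulary is
#' enforced (\code{\link{camera_log_statuses}}); failed days carry an empty
#' \code{track_count}.
#'
#' @param path CSV file path.
#' @return Validated data.frame.
#' @export
read_camera_log_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("date", "station_id", "status", "observed_m", "track_count")
  missing_cols <- setdiff(req, names(x))
  if (length(missing_cols) > 0) {
    stop("camera log CSV missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(x) == 0) return(x)
  x$date <- parse_date_col(x$date)
  bad <- which(!x$status %in% camera_log_statuses())
  if (length(bad) > 0) stop_rows("unknown status token", bad)
  bad <- which(!is.na(x$track_count) & x$track_count < 0)
  if (length(bad) > 0) stop_rows("negative track counts", bad)
  bad <- which(x$observed_m < 0)
  if (length(bad) > 0) stop_rows("negative observed_m", bad)
  x
}

#' Write a camera daily-log CSV
#' @param camera_log Camera-log data.frame.
#' @param path Output path.
#' @export
write_camera_log_csv <- function(camera_log, path) {
  utils::write.csv(camera_log, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a per-track daily-presence CSV into track records
#'
#' Long format: one row per sighting, columns \code{track_id}, \code{day},
#' and per-track (constant within track) flag columns
#' \code{present_at_camera_start}, \code{camera_stopped_while_visible},
#' \code{vegetation_line_out_of_view}, plus optional \code{phase}.
#'
#' @param path CSV file path.
#' @return List of \code{\link{track_record}} objects.
#' @export
read_track_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("track_id", "day", "present_at_camera_start",
           "camera_stopped_while_visible", "vegetation_line_out_of_view")
  missing_cols <- setdiff(req, names(x))
  if (length(missing_cols) > 0) {
    stop("track CSV missing columns: ", paste(missing_cols, collapse = ", "))
  }
  lapply(split(x, x$track_id), function(tr) {
    track_record(
      track_id = tr$track_id[1],
      visible_days = tr$day,
      present_at_camera_start = as.logical(tr$present_at_camera_start[1]),
      camera_stopped_while_visible =
        as.logical(tr$camera_stopped_while_visible[1]),
      vegetation_line_out_of_view =
        as.logical(tr$vegetation_line_out_of_view[1]),
      phase = if ("phase" %in% names(tr)) tr$phase[1] else NA_character_
    )
  })
}

#' Write track records as a per-track daily-presence CSV
#' @param records List of \code{\link{track_record}} objects.
#' @param path Output path.
#' @export
write_track_csv <- function(records, path) {
  rows <- do.call(rbind, lapply(records, function(r) {
    data.frame(
      track_id = r$track_id,
      day = r$visible_days,
      present_at_camera_start = r$present_at_camera_start,
      camera_stopped_while_visible = r$camera_stopped_while_visible,
      vegetation_line_out_of_view = r$vegetation_line_out_of_view,
      phase = r$phase
    )
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write the true synthetic season (oracle table)
#' @param season A \code{\link{generate_season}} result.
#' @param path Output path for the per-track CSV.
#' @export
write_season_csv <- function(season, path) {
  utils::write.csv(season$tracks, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

parse_date_col <- function(x) {
  if (is.numeric(x)) return(as.integer(x))
  parsed <- as.Date(x, format = "%Y-%m-%d")
  if (any(is.na(parsed))) {
    stop_rows("unparsable dates (expect ISO-8601 or integer day index)",
              which(is.na(parsed)))
  }
  parsed
}

#' Derive observable track records from a season and its camera log
#'
#' Recreates what an image analyst would extract: for each true track lying
#' in a station's view, the sighting days are the days the track persisted
#' and the station recorded an \code{ok} image. Censoring flags follow the
#' field rules: a track first sighted after its deposition day was already
#' present when the camera (re)started recording; a track whose camera
#' never operated again while it persisted (including persistence past the
#' season end) is right-censored; stations whose frame misses the
#' vegetation line censor all their tracks.
#'
#' @param season A \code{\link{generate_season}} result.
#' @param camera_log Station-day log from \code{\link{simulate_camera_log}}.
#' @param stations The station table used for the log; an optional logical
#'   column \code{vegetation_in_view} (default TRUE) marks frame adequacy.
#' @return List of \code{\link{track_record}} objects (tracks never sighted
#'   are absent, as in the field).
#' @export
derive_track_records <- function(season, camera_log, stations) {
  stopifnot(inherits(season, "true_season"))
  veg_ok <- if ("vegetation_in_view" %in% names(stations)) {
    stations$vegetation_in_view
  } else {
    rep(TRUE, nrow(stations))
  }
  records <- list()
  for (i in seq_len(nrow(stations))) {
    st <- stations[i, ]
    ok_days <- camera_log$date[camera_log$station_id == st$station_id &
                                 camera_log$status == "ok"]
    tr <- season$tracks[season$tracks$position_m >= st$start_m &
                          season$tracks$position_m < st$end_m, , drop = FALSE]
    for (j in seq_len(nrow(tr))) {
      span <- seq.int(tr$day[j], tr$day[j] + tr$longevity[j])
      sightings <- intersect(span, ok_days)
      if (length(sightings) == 0) next
      records[[length(records) + 1L]] <- track_record(
        track_id = tr$track_id[j],
        visible_days = sightings,
        present_at_camera_start = min(sightings) > tr$day[j],
        camera_stopped_while_visible =
          max(sightings) < tr$day[j] + tr$longevity[j],
        vegetation_line_out_of_view = !veg_ok[i],
        phase = tr$phase[j]
      )
    }
  }
  records
}
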