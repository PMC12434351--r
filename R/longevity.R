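#' Build a per-track visibility record
#'
#' @param track_id Identifier.
#' @param visible_days Integer vector of day indices on which the track was
#'   seen (need not be consecutive: a fog day does not erase a track, so
#'   sightings are bridged from first to last).
#' @param present_at_camera_start Track already on the beach the first day
#'   the camera recorded (left-censored).
#' @param camera_stopped_while_visible Camera failed for good while the
#'   track was still visible (right-censored).
#' @param vegetation_line_out_of_view Landward end of the track not in
#'   frame, so disappearance cannot be judged (censored).
#' @param phase Optional tidal phase at deposition ("neap"/"spring").
#' @return List of class \code{track_record}.
#' @export
track_record <- function(track_id, visible_days,
                         present_at_camera_start = FALSE,
                         camera_stopped_while_visible = FALSE,
                         vegetation_line_out_of_view = FALSE,
                         phase = NA_character_) {
  if (length(visible_days) == 0) stop("visibility series is empty")
  if (any(visible_days != round(visible_days))) {
    stop("visible_days must be whole day indices")
  }
  structure(
    list(
      track_id = track_id,
      visible_days = sort(unique(as.integer(visible_days))),
      present_at_camera_start = isTRUE(present_at_camera_start),
      camera_stopped_while_visible = isTRUE(camera_stopped_while_visible),
      vegetation_line_out_of_view = isTRUE(vegetation_line_out_of_view),
      phase = phase
    ),
    class = "track_record"
  )
}

#' Track longevity in days, or NA when censored
#'
#' Longevity is the number of days a track persists on the beach: last
#' visible day minus first visible day, so a track seen on a single morning
#' has longevity 0. Gaps in the sighting series (e.g. a fog day between two
#' sightings) are bridged -- only the first and last sightings matter.
#'
#' A record is censored -- no longevity value -- when the track was already
#' present when the camera started, when the camera stopped for good while
#' the track was still visible, or when the vegetation line is out of view.
#'
#' @param record A \code{\link{track_record}}.
#' @return Integer days, or \code{NA_integer_} if censored.
#' @examples
#' track_longevity(track_record("t1", 5))       # 0
#' track_longevity(track_record("t2", 5:14))    # 9
#' @export
track_longevity <- function(record) {
  stopifnot(inherits(record, "track_record"))
  if (record$present_at_camera_start ||
      record$camera_stopped_while_visible ||
      record$vegetation_line_out_of_view) {
    return(NA_integer_)
  }
  as.integer(max(record$visible_days) - min(record$visible_days))
}

#' Summarise track longevity over uncensored records
#'
#' @param records List of \code{\link{track_record}} objects.
#' @param phase "all" (default), "neap" or "spring"; filters on each
#'   record's deposition phase before summarising.
#' @return data.frame with \code{phase}, \code{mean}, \code{sd},
#'   \code{min}, \code{max}, \code{n} (uncensored records),
#'   \code{n_censored}.
#' @examples
#' recs <- list(track_record("a", 1), track_record("b", c(2, 11)))
#' longevity_summary(recs)  # mean 4.5, range 0-9, n 2
#' @export
longevity_summary <- function(records, phase = "all") {
  stopifnot(phase %in% c("all", "neap", "spring"))
  if (phase != "all") {
    records <- Filter(function(r) identical(r$phase, phase), records)
  }
  if (length(records) == 0) stop("no records in phase '", phase, "'")
  long <- vapply(records, track_longevity, integer(1))
  kept <- long[!is.na(long)]
  if (length(kept) == 0) {
    stop("all records censored: longevity cannot be summarised")
  }
  data.frame(
    phase = phase,
    mean = mean(kept),
    sd = if (length(kept) > 1) stats::sd(kept) else NA_real_,
    min = min(kept),
    max = max(kept),
    n = length(kept),
    n_censored = sum(is.na(long))
  )
}
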