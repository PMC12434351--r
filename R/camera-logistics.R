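#' Camera duty cycle
#'
#' A daily time-lapse window with a fixed capture interval. Two endpoint
#' conventions exist in practice and both appear on real cameras:
#' \code{"exclude_end"} counts intervals (a 90-min window at 30 s gives
#' 180 images), \code{"include_both"} counts fence posts (a 60-min window
#' at 30-min intervals gives 3 images). The convention is an explicit
#' parameter; the default \code{"exclude_end"} matches the 180-images/day
#' behaviour observed at 30-s intervals.
#'
#' @param window_start,window_end Clock times as "HHMM" strings (e.g.
#'   "0700", "0830") or minutes-since-midnight numerics.
#' @param interval_seconds Capture interval in seconds (> 0, not exceeding
#'   the window).
#' @param endpoint_convention "exclude_end" (default) or "include_both".
#' @return List of class \code{duty_cycle} with the parsed fields and
#'   \code{window_seconds}.
#' @examples
#' duty_cycle("0700", "0830", 30)
#' @export
duty_cycle <- function(window_start, window_end, interval_seconds,
                       endpoint_convention = c("exclude_end", "include_both")) {
  endpoint_convention <- match.arg(endpoint_convention)
  start_min <- parse_clock(window_start)
  end_min <- parse_clock(window_end)
  if (end_min <= start_min) stop("window_end must be after window_start")
  if (interval_seconds <= 0) stop("interval must be positive")
  window_seconds <- (end_min - start_min) * 60
  if (interval_seconds > window_seconds) {
    stop("interval exceeds the capture window")
  }
  structure(
    list(
      window_start = window_start,
      window_end = window_end,
      window_seconds = window_seconds,
      interval_seconds = interval_seconds,
      endpoint_convention = endpoint_convention
    ),
    class = "duty_cycle"
  )
}

parse_clock <- function(x) {
  if (is.numeric(x)) return(x)
  if (!grepl("^[0-2][0-9][0-5][0-9]$", x)) {
    stop("clock time must be an HHMM string, got '", x, "'")
  }
  as.integer(substr(x, 1, 2)) * 60 + as.integer(substr(x, 3, 4))
}

#' Images captured per day under a duty cycle
#'
#' @param duty A \code{\link{duty_cycle}}.
#' @return Integer image count: \code{floor(window / interval)} intervals,
#'   plus one when both endpoints are captured.
#' @examples
#' images_per_day(duty_cycle("0700", "0830", 30))                   # 180
#' images_per_day(duty_cycle("0700", "0800", 1800, "include_both")) # 3
#' @export
images_per_day <- function(duty) {
  stopifnot(inherits(duty, "duty_cycle"))
  n <- duty$window_seconds %/% duty$interval_seconds
  if (duty$endpoint_convention == "include_both") n <- n + 1
  as.integer(n)
}

#' Days until the memory card fills
#'
#' @param capacity_images Card capacity in images (> 0).
#' @param images_per_day Daily capture rate (> 0).
#' @return Whole days of operation before capacity is reached:
#'   \code{floor(capacity / rate)}.
#' @examples
#' days_to_capacity(6480, 180)  # 36
#' @export
days_to_capacity <- function(capacity_images, images_per_day) {
  if (capacity_images <= 0 || images_per_day <= 0) {
    stop("capacity and rate must be positive")
  }
  as.integer(capacity_images %/% images_per_day)
}

#' Is a deployment duration feasible on one card?
#'
#' @param capacity_images Card capacity in images.
#' @param duty A \code{\link{duty_cycle}}.
#' @param target_days Intended deployment length in days (>= 0).
#' @return List with \code{feasible} (TRUE iff the card holds the whole
#'   deployment), \code{images_needed}, and \code{headroom_images}
#'   (capacity minus need; negative when infeasible).
#' @examples
#' # an image every 2 h around the clock for a year fits on a 6480-image card
#' feasible_duration(6480, duty_cycle("0000", "2400", 7200), 365)
#' @export
feasible_duration <- function(capacity_images, duty, target_days) {
  stopifnot(inherits(duty, "duty_cycle"))
  if (target_days < 0) stop("target_days must be >= 0")
  need <- images_per_day(duty) * target_days
  list(
    feasible = need <= capacity_images,
    images_needed = need,
    headroom_images = capacity_images - need
  )
}
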