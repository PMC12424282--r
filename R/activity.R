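#' Resultant acceleration from two axes
#'
#' Magnitude `sqrt(x^2 + y^2)` of the X-heave/Y-surge pair, after an
#' optional affine raw-count to m/s^2 conversion applied to each axis
#' (`offset + scale * value`). The manufacturer's conversion is device
#' specific; the default is the identity, i.e. inputs already in m/s^2.
#'
#' @param x,y Axis values (m/s^2, or raw counts with a non-identity
#'   conversion).
#' @param scale,offset Affine conversion coefficients.
#' @return Non-negative magnitudes.
#' @examples
#' resultant(3, 4)  # 5
#' @export
resultant <- function(x, y, scale = 1, offset = 0) {
  sqrt((offset + scale * x)^2 + (offset + scale * y)^2)
}

#' Flag per-minute movement from acceleration changes
#'
#' A minute is flagged as moved when its mean resultant acceleration
#' differs from the previous minute's by more than `epsilon` (movement is
#' "any change in acceleration from the previous value", assessed on the
#' 1-min averages; a strictly zero threshold would flag floating-point
#' jitter, so the threshold is explicit). The first record, and any record
#' whose predecessor minute is missing (gap > 1 minute), has `moved = NA`.
#'
#' @param minutes A `minute_records` data frame (sorted, unique minutes).
#' @param epsilon Change threshold, m/s^2 (default `1e-6`).
#' @return `minutes` with a logical `moved` column added.
#' @export
detect_moved <- function(minutes, epsilon = 1e-6) {
  stopifnot(epsilon >= 0)
  n <- nrow(minutes)
  if (n == 0L) {
    minutes$moved <- logical(0)
    return(minutes)
  }
  t <- as.numeric(minutes$minute)
  if (is.unsorted(t, strictly = TRUE)) {
    stop("minute records must be sorted with unique minutes")
  }
  moved <- c(NA, abs(diff(minutes$accel_mean)) > epsilon)
  gap <- c(NA, diff(t)) > 60
  moved[which(gap)] <- NA
  minutes$moved <- moved
  minutes
}

#' Hourly activity budget (minutes moved per hour)
#'
#' Counts moved minutes per clock hour and stores the `log(x + 1)`
#' transform used for analysis (activity data are zero-inflated by long
#' sedentary periods). Hours with fewer observed minutes than
#' `min_minutes` are flagged incomplete; by convention they are excluded
#' from seasonal summaries.
#'
#' @param minutes Output of [detect_moved()].
#' @param min_minutes Minimum observed minutes for a complete hour
#'   (default 30).
#' @return An `activity_series` data frame: `lizard_id`, `date`, `hour`,
#'   `minutes_moved` (0--60), `log_minutes`, `n_minutes_observed`,
#'   `complete`.
#' @export
hourly_activity <- function(minutes, min_minutes = 30L) {
  if (!"moved" %in% names(minutes)) {
    stop("run detect_moved() before hourly_activity()")
  }
  lt <- as.POSIXlt(minutes$minute, tz = "UTC")
  key <- paste(format(minutes$minute, "%Y-%m-%d", tz = "UTC"),
               sprintf("%02d", lt$hour))
  moved_n <- tapply(minutes$moved, key, function(m) sum(m, na.rm = TRUE))
  obs_n <- tapply(minutes$moved, key, length)
  k <- sort(unique(key))
  parts <- strsplit(k, " ")
  out <- data.frame(
    lizard_id = minutes$lizard_id[1L],
    date = as.Date(vapply(parts, `[`, "", 1L)),
    hour = as.integer(vapply(parts, `[`, "", 2L)),
    minutes_moved = as.integer(moved_n[k]),
    row.names = NULL)
  out$log_minutes <- log(out$minutes_moved + 1)
  out$n_minutes_observed <- as.integer(obs_n[k])
  out$complete <- out$n_minutes_observed >= min_minutes
  class(out) <- c("activity_series", "data.frame")
  out
}
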