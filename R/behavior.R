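#' Per-minute standard deviation of acceleration
#'
#' The sample SD of all samples whose time falls in
#' \eqn{[60m, 60(m+1))} on the deployment clock, one value per complete
#' minute; an incomplete trailing (or leading) minute is excluded. The
#' short-window SD of longitudinal acceleration indexes locomotor
#' activity: flipper strokes raise it, quiescence leaves only sensor
#' noise.
#'
#' @param accel an acceleration \code{\link{channel}} with rate >= 1 Hz.
#' @return an object of class \code{minute_sd_series}: a data frame with
#'   columns \code{minute} (0-based index from record start) and \code{sd}
#'   (m s-2). A record shorter than one minute yields an empty series with
#'   a warning.
#' @export
minute_sd <- function(accel) {
  stopifnot(inherits(accel, "channel"))
  if (accel$rate < 1)
    stop_validation("minute_sd needs a channel sampled at >= 1 Hz")
  n <- length(accel$values)
  tt <- channel_times(accel)
  m <- floor(tt / 60)
  per_min <- round(60 * accel$rate)
  cnt <- table(m)
  complete <- as.integer(names(cnt))[cnt == per_min]
  if (!length(complete)) {
    warning("record shorter than one complete minute; empty minute-SD series")
    out <- data.frame(minute = integer(0), sd = numeric(0))
  } else {
    keep <- m %in% complete
    sds <- vapply(split(accel$values[keep], m[keep]), stats::sd, 0)
    out <- data.frame(minute = as.integer(names(sds)), sd = unname(sds))
    out <- out[order(out$minute), , drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("minute_sd_series", "data.frame")
  attr(out, "rate") <- accel$rate
  out
}

#' Classify minutes as resting or moving
#'
#' Minutes whose acceleration SD is strictly below the threshold are
#' resting; all others (including SD exactly at the threshold) are moving.
#' The boundary convention follows the "lower than ... otherwise" reading
#' of the activity rule, so an SD of exactly 0.5 m s-2 is moving.
#'
#' @param sds a \code{minute_sd_series} from \code{\link{minute_sd}}, or a
#'   bare numeric vector of per-minute SDs.
#' @param threshold activity threshold in m s-2 (> 0, default 0.5).
#' @return character vector of \code{"resting"} / \code{"moving"}, one per
#'   minute, in minute order.
#' @export
classify_minutes <- function(sds, threshold = 0.5) {
  if (!is_scalar_number(threshold) || threshold <= 0)
    stop_validation("threshold must be a positive number")
  v <- if (inherits(sds, "minute_sd_series")) sds$sd else as.numeric(sds)
  if (any(v < 0, na.rm = TRUE)) stop_validation("minute SDs must be >= 0")
  ifelse(v < threshold, "resting", "moving")
}

#' Segment a status sequence into minimum-duration phases
#'
#' Maximal runs of identical status with length at least
#' \code{min_minutes} become phases; shorter runs belong to no phase (they
#' are unclassified, not merged into neighbours). A 5-minute run is one
#' 5-minute phase, never stacked shorter phases.
#'
#' @param statuses character vector of per-minute statuses
#'   (\code{"resting"} / \code{"moving"}), minutes
#'   \code{start_minute, start_minute + 1, ...}.
#' @param min_minutes minimum run length in minutes (>= 1, default 2).
#' @param start_minute minute index of \code{statuses[1]} on the
#'   deployment clock (default 0).
#' @return a data frame of class \code{phase_table} with columns
#'   \code{status}, \code{start_min} (inclusive), \code{end_min}
#'   (exclusive) and \code{duration_min}, ordered by start. Empty input
#'   yields an empty table.
#' @export
segment_phases <- function(statuses, min_minutes = 2, start_minute = 0) {
  if (!is_scalar_number(min_minutes) || min_minutes < 1)
    stop_validation("min_minutes must be >= 1")
  empty <- data.frame(status = character(0), start_min = integer(0),
                      end_min = integer(0), duration_min = integer(0))
  if (!length(statuses)) {
    class(empty) <- c("phase_table", "data.frame")
    return(empty)
  }
  if (!all(statuses %in% c("resting", "moving")))
    stop_validation("statuses must be 'resting' or 'moving'")
  r <- rle(statuses)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$lengths >= min_minutes
  out <- data.frame(status = r$values[keep],
                    start_min = as.integer(start_minute + starts[keep]),
                    end_min = as.integer(start_minute + ends[keep]),
                    duration_min = as.integer(r$lengths[keep]))
  rownames(out) <- NULL
  class(out) <- c("phase_table", "data.frame")
  out
}
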