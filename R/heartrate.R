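#' Exclude the post-handling window
#'
#' Handling and instrumentation transiently disturb heart rate, so the
#' first \code{hours} (default 12) of each record are discarded: R waves
#' before the cutoff are removed, and any phase starting before the
#' cutoff — including one straddling it — is dropped entirely (truncating
#' a straddler could create a sub-minimum phase).
#'
#' @param train an \code{\link{rwave_train}}.
#' @param phases a \code{phase_table} from \code{\link{segment_phases}}.
#' @param hours exclusion window length in hours (>= 0, default 12).
#' @param record_end_s optional record span (s) used to warn when the
#'   whole record falls inside the exclusion window.
#' @return list with elements \code{train} and \code{phases}, trimmed.
#' @export
exclude_handling <- function(train, phases, hours = 12,
                             record_end_s = NULL) {
  stopifnot(inherits(train, "rwave_train"))
  if (!is_scalar_number(hours) || hours < 0)
    stop_validation("hours must be >= 0")
  cutoff_s <- hours * 3600
  new_train <- rwave_train(train$times[train$times >= cutoff_s],
                           source = train$source, params = train$params)
  keep <- phases$start_min * 60 >= cutoff_s
  new_phases <- phases[keep, , drop = FALSE]
  rownames(new_phases) <- NULL
  if (!is.null(record_end_s) && record_end_s <= cutoff_s)
    warning(sprintf("record (%.1f h) lies entirely within the %.1f-h handling-exclusion window; no analyzable data",
                    record_end_s / 3600, hours))
  else if (nrow(phases) > 0 && nrow(new_phases) == 0)
    warning("no phases remain after the handling exclusion")
  list(train = new_train, phases = new_phases)
}

#' Per-phase heart rate
#'
#' Heart rate of each phase is the number of R waves whose time falls in
#' the half-open interval \eqn{[start, end)} of the phase (an event
#' exactly at the phase end belongs to the next interval), divided by the
#' phase duration in minutes.
#'
#' @param train an \code{\link{rwave_train}}.
#' @param phases a \code{phase_table}.
#' @return a data frame of class \code{phase_hr_table}: the phase columns
#'   plus \code{count} (R waves in the phase) and \code{hr}
#'   (beats min-1).
#' @export
phase_heart_rates <- function(train, phases) {
  stopifnot(inherits(train, "rwave_train"))
  if (nrow(phases)) {
    count <- vapply(seq_len(nrow(phases)), function(i) {
      sum(train$times >= phases$start_min[i] * 60 &
            train$times < phases$end_min[i] * 60)
    }, 0L)
  } else count <- integer(0)
  out <- cbind(as.data.frame(phases),
               data.frame(count = count,
                          hr = if (length(count)) count / phases$duration_min
                               else numeric(0)))
  rownames(out) <- NULL
  class(out) <- c("phase_hr_table", "data.frame")
  out
}

#' Grand-mean heart rate by status
#'
#' Per-phase heart rates are averaged, unweighted, to a grand mean per
#' status, with the sample SD and the number of contributing phases. Two
#' pooling modes are provided because "mean of n individuals" wording is
#' ambiguous when phases from several animals are combined:
#' \code{"pooled"} (default) averages all phases together, matching the
#' large printed phase counts; \code{"individual"} first averages phases
#' within each animal, then averages those per-animal means (n is then
#' the number of animals).
#'
#' @param phase_hr a \code{phase_hr_table} from
#'   \code{\link{phase_heart_rates}}, optionally with a \code{turtle_id}
#'   column when pooling across animals.
#' @param by pooling mode, \code{"pooled"} or \code{"individual"}.
#' @return a data frame of class \code{hr_summary} with one row per
#'   status: \code{status}, \code{mean_hr}, \code{sd_hr} (NA when
#'   n < 2), \code{n}. Empty input yields an empty summary.
#' @export
summarize_heart_rates <- function(phase_hr, by = c("pooled", "individual")) {
  by <- match.arg(by)
  empty <- data.frame(status = character(0), mean_hr = numeric(0),
                      sd_hr = numeric(0), n = integer(0))
  if (!nrow(phase_hr)) {
    class(empty) <- c("hr_summary", "data.frame")
    return(empty)
  }
  if (by == "individual") {
    if (is.null(phase_hr$turtle_id))
      stop_validation("pooling by individual needs a turtle_id column")
    per <- stats::aggregate(hr ~ status + turtle_id, data = phase_hr, FUN = mean)
    values <- split(per$hr, per$status)
  } else {
    values <- split(phase_hr$hr, phase_hr$status)
  }
  out <- data.frame(
    status = names(values),
    mean_hr = vapply(values, mean, 0),
    sd_hr = vapply(values, function(v) if (length(v) < 2) NA_real_ else stats::sd(v), 0),
    n = vapply(values, length, 0L))
  out <- out[order(match(out$status, c("resting", "moving"))), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("hr_summary", "data.frame")
  attr(out, "pooling") <- by
  out
}

#' @export
print.hr_summary <- function(x, ...) {
  cat(sprintf("Heart-rate summary (%s pooling):\n",
              attr(x, "pooling") %||% "pooled"))
  if (!nrow(x)) {
    cat("  (no phases)\n")
    return(invisible(x))
  }
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %-8s %5.1f +/- %s beats min-1  (n = %d phases)\n",
                x$status[i], x$mean_hr[i],
                ifelse(is.na(x$sd_hr[i]), "NA ", sprintf("%4.1f", x$sd_hr[i])),
                x$n[i]))
  invisible(x)
}
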