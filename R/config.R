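#' Analysis run configuration
#'
#' Collects every tunable parameter of the heart-rate pipeline, with the
#' published analysis defaults: a 0.5 m s-2 activity threshold on
#' per-minute acceleration SD, a 2-min minimum phase duration, a 12-h
#' post-handling exclusion, and quality-grade cut points at 30% and 70% of
#' the record. Filter and detector parameters default to values suited to
#' the slow (5-20 beats min-1) heart rates of ectothermic sea turtles.
#'
#' @param band_low_hz,band_high_hz band-pass edges for the ECG (Hz);
#'   must satisfy 0 < low < high < Nyquist of the ECG channel.
#' @param filter_order Butterworth order per pass (applied forward-backward,
#'   so the effective attenuation is doubled).
#' @param refractory_s minimum spacing between detected R waves (s). The
#'   default 1 s caps detectable heart rate at 60 beats min-1, far above
#'   any reported turtle heart rate.
#' @param threshold_quantile quantile of |filtered signal| within each
#'   detector window used as the adaptive detection threshold.
#' @param window_s detector threshold window length (s).
#' @param behavior_threshold activity threshold on per-minute acceleration
#'   SD (m s-2); minutes with SD strictly below it are resting, otherwise
#'   moving.
#' @param min_phase_min minimum run length (minutes) for a run of equal
#'   statuses to count as a phase.
#' @param exclude_hours post-handling exclusion window (h) dropped from the
#'   start of the record.
#' @param quality_window_s quality-grading window length (s);
#'   non-overlapping windows aligned to the record start, trailing partial
#'   window discarded.
#' @param quality_cuts two increasing fractions in (0, 1) splitting the
#'   detectable fraction into undetectable / unclear / clear.
#' @param quality_snr_min minimum peak-to-surround amplitude ratio for a
#'   detected R wave to count as detectable.
#' @param hr_bounds_bpm physiologically plausible heart-rate range
#'   (beats min-1) for the local-RR plausibility check in quality grading.
#' @param seed optional RNG seed recorded for provenance.
#' @return an object of class \code{run_config} (a validated named list).
#' @export
run_config <- function(band_low_hz = 5, band_high_hz = 30, filter_order = 4,
                       refractory_s = 1, threshold_quantile = 0.997,
                       window_s = 10, behavior_threshold = 0.5,
                       min_phase_min = 2, exclude_hours = 12,
                       quality_window_s = 60, quality_cuts = c(0.30, 0.70),
                       quality_snr_min = 3, hr_bounds_bpm = c(1, 60),
                       seed = NULL) {
  cfg <- list(band_low_hz = band_low_hz, band_high_hz = band_high_hz,
              filter_order = as.integer(filter_order),
              refractory_s = refractory_s,
              threshold_quantile = threshold_quantile, window_s = window_s,
              behavior_threshold = behavior_threshold,
              min_phase_min = as.integer(min_phase_min),
              exclude_hours = exclude_hours,
              quality_window_s = quality_window_s,
              quality_cuts = quality_cuts,
              quality_snr_min = quality_snr_min,
              hr_bounds_bpm = hr_bounds_bpm, seed = seed)
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

validate_run_config <- function(cfg) {
  with(cfg, {
    if (!is_scalar_number(band_low_hz) || !is_scalar_number(band_high_hz) ||
        band_low_hz <= 0 || band_high_hz <= band_low_hz)
      stop_validation("filter band must satisfy 0 < low < high")
    for (nm in c("refractory_s", "window_s", "behavior_threshold",
                 "exclude_hours", "quality_window_s", "quality_snr_min")) {
      v <- cfg[[nm]]
      if (!is_scalar_number(v) || v < 0)
        stop_validation("%s must be a non-negative number", nm)
    }
    if (refractory_s <= 0) stop_validation("refractory_s must be positive")
    if (behavior_threshold <= 0)
      stop_validation("behavior_threshold must be positive")
    if (!is_scalar_number(threshold_quantile) || threshold_quantile <= 0 ||
        threshold_quantile >= 1)
      stop_validation("threshold_quantile must lie in (0, 1)")
    if (min_phase_min < 1) stop_validation("min_phase_min must be >= 1")
    if (length(quality_cuts) != 2 || any(quality_cuts <= 0) ||
        any(quality_cuts >= 1) || diff(quality_cuts) <= 0)
      stop_validation("quality_cuts must be two strictly increasing fractions in (0, 1)")
    if (length(hr_bounds_bpm) != 2 || any(hr_bounds_bpm <= 0) ||
        diff(hr_bounds_bpm) <= 0)
      stop_validation("hr_bounds_bpm must be an increasing positive pair")
  })
  invisible(cfg)
}

#' Read a run configuration file
#'
#' A YAML file mirroring the \code{\link{run_config}} fields; every field
#' is optional and missing fields take the defaults, so an empty file is a
#' valid configuration. Unknown fields are an error (they are usually
#' typos).
#'
#' @param path path to a YAML config file.
#' @return a \code{run_config}.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_validation("config file not found: %s", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  known <- names(formals(run_config))
  unknown <- setdiff(names(user), known)
  if (length(unknown))
    stop_validation("unknown config field(s): %s",
                    paste(unknown, collapse = ", "))
  do.call(run_config, user)
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-20s %s\n", nm,
                if (is.null(v)) "NULL" else paste(format(v), collapse = ", ")))
  }
  invisible(x)
}
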