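#' Run the full heart-rate pipeline on one deployment
#'
#' Executes the analysis stages in fixed order: band-pass filter the ECG,
#' detect R waves, grade signal quality, compute per-minute acceleration
#' SD, classify minutes as resting/moving, segment minimum-duration
#' phases, apply the post-handling exclusion, compute per-phase heart
#' rates, and summarize grand means by status. The pipeline draws no
#' random numbers, so identical inputs and configuration reproduce
#' identical results.
#'
#' When the quality grade is \code{"undetectable"} the summary is still
#' produced but the result is flagged (\code{flagged = TRUE}): heart
#' rates computed from an undetectable record are not usable.
#'
#' @param x a \code{\link{deployment_record}}, or the path to a
#'   deployment manifest (see \code{\link{load_deployment}}).
#' @param config a \code{\link{run_config}}.
#' @param verbose print per-stage record counts?
#' @return an object of class \code{turtlehr_result}: a list with the
#'   deployment metadata, the fully resolved \code{config}, the
#'   \code{quality} assessment, \code{minute_sd}, \code{statuses},
#'   \code{phases} (before exclusion), \code{train} (detected R waves
#'   after exclusion), \code{phase_hr}, the per-status \code{summary},
#'   \code{flagged}, and a per-stage \code{log} of record counts.
#'   Methods: \code{print}, \code{summary}, \code{coef} (per-status
#'   grand means), \code{plot}.
#' @examples
#' \donttest{
#' dep <- generate_deployment(behavior_model(duration_min = 120),
#'                            seed = 42)
#' res <- run_pipeline(dep$record)
#' coef(res)
#' }
#' @export
run_pipeline <- function(x, config = run_config(), verbose = FALSE) {
  record <- if (inherits(x, "deployment_record")) x else load_deployment(x)
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  ecg <- record$channels$ecg
  if (config$band_high_hz >= ecg$rate / 2)
    stop_validation("band_high_hz (%g) violates the ECG Nyquist limit (%g Hz)",
                    config$band_high_hz, ecg$rate / 2)
  say("input: %d ECG samples @ %g Hz, %d accel samples @ %g Hz",
      length(ecg$values), ecg$rate,
      length(record$channels$accel_long$values),
      record$channels$accel_long$rate)

  filtered <- stage("filter", bandpass_filter(
    ecg, config$band_low_hz, config$band_high_hz, config$filter_order))
  train <- stage("detect", detect_r_waves(
    filtered, config$refractory_s, config$threshold_quantile,
    config$window_s))
  say("detected %d R waves", length(train$times))
  quality <- stage("quality", assess_quality(
    filtered, train, config$quality_window_s, config$quality_snr_min,
    config$hr_bounds_bpm, config$quality_cuts))
  say("quality: %s (%.1f%% detectable)", quality$grade,
      100 * quality$fraction)

  sds <- stage("minute_sd", minute_sd(record$channels$accel_long))
  statuses <- stage("classify",
                    classify_minutes(sds, config$behavior_threshold))
  start_min <- if (nrow(sds)) sds$minute[1] else 0L
  phases <- stage("segment", segment_phases(statuses, config$min_phase_min,
                                            start_minute = start_min))
  say("%d minutes classified, %d phases kept", length(statuses),
      nrow(phases))

  trimmed <- stage("exclude", exclude_handling(
    train, phases, config$exclude_hours,
    record_end_s = deployment_end_s(record)))
  say("%d R waves and %d phases after the %g-h exclusion",
      length(trimmed$train$times), nrow(trimmed$phases),
      config$exclude_hours)

  phase_hr <- stage("phase_hr",
                    phase_heart_rates(trimmed$train, trimmed$phases))
  summary_tab <- stage("summarize", summarize_heart_rates(phase_hr))

  structure(list(
    turtle_id = record$turtle_id, placement = record$placement,
    config = config, quality = quality, minute_sd = sds,
    statuses = statuses, phases = phases, train = trimmed$train,
    phase_hr = phase_hr, summary = summary_tab,
    flagged = identical(quality$grade, "undetectable"),
    log = list(n_ecg_samples = length(ecg$values),
               n_rwaves_detected = length(train$times),
               n_minutes_classified = length(statuses),
               n_phases = nrow(phases),
               n_phases_analyzed = nrow(trimmed$phases),
               n_rwaves_analyzed = length(trimmed$train$times))),
    class = "turtlehr_result")
}

#' @export
print.turtlehr_result <- function(x, ...) {
  cat(sprintf("Heart-rate analysis: turtle %s, placement %s%s\n",
              x$turtle_id, x$placement,
              if (x$flagged) "  [FLAGGED: undetectable ECG]" else ""))
  cat(sprintf("  ECG quality: %s (detectable %.1f%% of record)\n",
              x$quality$grade, 100 * x$quality$fraction))
  cat(sprintf("  %d R waves, %d phases analyzed (%d before the %g-h exclusion)\n",
              x$log$n_rwaves_analyzed, x$log$n_phases_analyzed,
              x$log$n_phases, x$config$exclude_hours))
  print(x$summary)
  invisible(x)
}

#' @export
summary.turtlehr_result <- function(object, ...) object$summary

#' Per-status grand-mean heart rates of a pipeline result
#'
#' @param object a \code{turtlehr_result}.
#' @param ... unused.
#' @return named numeric vector of grand means (beats min-1), e.g.
#'   \code{c(resting = 8.6, moving = 12.2)}.
#' @export
coef.turtlehr_result <- function(object, ...) {
  stats::setNames(object$summary$mean_hr, object$summary$status)
}

#' Diagnostic plot of a pipeline result
#'
#' Three base-graphics panels: per-minute acceleration SD with the
#' activity threshold, the detected per-phase heart rates coloured by
#' status, and the per-window detectability flags.
#'
#' @param x a \code{turtlehr_result}.
#' @param ... passed to \code{plot.default}.
#' @export
plot.turtlehr_result <- function(x, ...) {
  op <- graphics::par(mfrow = c(3, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  cols <- c(resting = "steelblue", moving = "tomato")

  graphics::plot(x$minute_sd$minute, x$minute_sd$sd, type = "h",
                 col = cols[x$statuses], xlab = "minute",
                 ylab = "accel SD (m s-2)",
                 main = sprintf("turtle %s: activity", x$turtle_id), ...)
  graphics::abline(h = x$config$behavior_threshold, lty = 2)

  if (nrow(x$phase_hr)) {
    graphics::plot((x$phase_hr$start_min + x$phase_hr$end_min) / 2,
                   x$phase_hr$hr, col = cols[x$phase_hr$status], pch = 16,
                   xlab = "minute", ylab = "heart rate (beats min-1)",
                   main = "per-phase heart rate")
    graphics::legend("topright", legend = names(cols), col = cols,
                     pch = 16, bty = "n")
  } else {
    graphics::plot.new()
    graphics::title("per-phase heart rate (no phases)")
  }

  qa <- x$quality
  graphics::plot(seq_along(qa$window_detectable) - 1,
                 as.integer(qa$window_detectable), type = "h",
                 xlab = sprintf("%g-s window", qa$window_s),
                 ylab = "detectable",
                 main = sprintf("ECG quality: %s (%.1f%%)", qa$grade,
                                100 * qa$fraction), yaxt = "n")
  graphics::axis(2, at = c(0, 1))
  invisible(x)
}

#' Write pipeline outputs as plain text
#'
#' Emits the per-phase table and per-status summary as tab-separated
#' text, the detected R-wave times one per line, a quality report, and
#' the fully resolved configuration as YAML (no default is applied
#' silently: every configurable value appears in the output).
#'
#' @param result a \code{turtlehr_result}.
#' @param dir destination directory.
#' @param force overwrite existing files?
#' @return the directory, invisibly.
#' @export
write_pipeline_result <- function(result, dir, force = FALSE) {
  stopifnot(inherits(result, "turtlehr_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("phases.tsv", "summary.tsv", "r_times.txt",
                            "quality.txt", "config.yml"))
  if (!force && any(file.exists(paths)))
    stop_validation("refusing to overwrite results in %s (use force = TRUE)", dir)
  utils::write.table(as.data.frame(result$phase_hr), paths[1], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(result$summary), paths[2], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(format_full(result$train$times), paths[3])
  writeLines(c(sprintf("turtle_id\t%s", result$turtle_id),
               sprintf("placement\t%s", result$placement),
               sprintf("detectable_fraction\t%s",
                       format_full(result$quality$fraction)),
               sprintf("grade\t%s", result$quality$grade),
               sprintf("flagged\t%s", result$flagged)), paths[4])
  cfg <- result$config
  cfg <- lapply(unclass(cfg), function(v) if (is.null(v)) "null" else v)
  yaml::write_yaml(cfg, paths[5])
  invisible(dir)
}
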