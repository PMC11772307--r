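#' Zero-phase band-pass filter for ECG
#'
#' Butterworth band-pass applied forward and backward
#' (\code{signal::filtfilt}), so peaks are not shifted in time — essential
#' here because heart rate is computed from event counts in fixed minute
#' windows. The default 5-30 Hz band keeps the QRS energy of a slow
#' ectotherm heart while rejecting baseline wander (~0.1 Hz) below and
#' most EMG energy above.
#'
#' @param ecg a \code{\link{channel}}.
#' @param low,high band edges (Hz), 0 < low < high < rate / 2.
#' @param order Butterworth order per pass (default 4; the
#'   forward-backward application doubles the effective roll-off).
#' @return a \code{channel} of the same length, rate and clock.
#' @export
bandpass_filter <- function(ecg, low = 5, high = 30, order = 4) {
  stopifnot(inherits(ecg, "channel"))
  nyq <- ecg$rate / 2
  if (!(low > 0 && high > low && high < nyq))
    stop_validation("band [%g, %g] Hz violates 0 < low < high < Nyquist (%g Hz)",
                    low, high, nyq)
  warmup <- ceiling(3 * ecg$rate / low)
  if (length(ecg$values) < warmup)
    stop_validation("record too short for filtering: %d samples < %d needed for filter warm-up",
                    length(ecg$values), warmup)
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  # odd-reflection padding absorbs the forward-backward edge transients
  # (the padding must cover the settle time of the lowest band edge)
  x <- ecg$values
  n <- length(x)
  pad <- min(n - 1L, ceiling(3 * ecg$rate / low))
  xp <- c(2 * x[1] - x[(pad + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - pad)])
  out <- signal::filtfilt(bf, xp)[(pad + 1L):(pad + n)]
  channel(out, rate = ecg$rate, units = ecg$units,
          name = paste0(ecg$name, "_filtered"), t0 = ecg$t0)
}

#' Detected R-wave train
#'
#' Event times in seconds on the deployment clock, strictly increasing,
#' with every consecutive gap at least the refractory period.
#'
#' @param times numeric vector of event times (s).
#' @param source source channel label.
#' @param params named list of detector parameters used.
#' @return an object of class \code{rwave_train}.
#' @export
rwave_train <- function(times, source = "", params = list()) {
  times <- as.double(times)
  if (is.unsorted(times, strictly = TRUE))
    stop_validation("R-wave times must be strictly increasing")
  refr <- params$refractory_s
  if (!is.null(refr) && length(times) > 1 &&
      any(diff(times) < refr - 1e-9))
    stop_validation("R-wave train violates the refractory period")
  structure(list(times = times, source = source, params = params),
            class = "rwave_train")
}

#' @export
print.rwave_train <- function(x, ...) {
  cat(sprintf("<rwave_train> %d events", length(x$times)))
  if (length(x$times) > 1)
    cat(sprintf(", span %.1f min, median RR %.2f s",
                diff(range(x$times)) / 60, stats::median(diff(x$times))))
  cat("\n")
  invisible(x)
}

#' @export
length.rwave_train <- function(x) length(x$times)

#' Detect R waves with an adaptive windowed-quantile threshold
#'
#' Candidate peaks are strict local maxima of the filtered signal lying
#' above an adaptive threshold: the given quantile of \eqn{|signal|}
#' computed per non-overlapping window of \code{window_s} seconds. Because
#' a window holding no beat would otherwise set its threshold from noise
#' alone, the per-window threshold is floored at one quarter of the global
#' 99.9th percentile of \eqn{|signal|} — a robust proxy for the R-peak
#' amplitude scale that tolerates up to about four-fold amplitude drift
#' (plus a 0.1%-of-maximum floor that suppresses numerical ripple in
#' silent stretches). Candidates are then accepted greedily in
#' order of descending amplitude (ties broken by earlier time), subject to
#' a minimum spacing of \code{refractory_s} to any already-accepted peak.
#' Times are reported at the local-maximum sample.
#'
#' @param filtered band-pass-filtered ECG \code{\link{channel}}.
#' @param refractory_s minimum inter-event spacing (s, > 0). The default
#'   1 s caps detectable heart rate at 60 beats min-1.
#' @param threshold_quantile quantile of |signal| per window used as the
#'   detection threshold (in (0, 1)).
#' @param window_s threshold window length (s).
#' @return an \code{\link{rwave_train}}; a flat (all-zero) signal yields
#'   an empty train, not an error.
#' @export
detect_r_waves <- function(filtered, refractory_s = 1,
                           threshold_quantile = 0.997, window_s = 10) {
  stopifnot(inherits(filtered, "channel"))
  if (!is_scalar_number(refractory_s) || refractory_s <= 0)
    stop_validation("refractory_s must be positive")
  if (!is_scalar_number(threshold_quantile) || threshold_quantile <= 0 ||
      threshold_quantile >= 1)
    stop_validation("threshold_quantile must lie in (0, 1)")
  x <- filtered$values
  n <- length(x)
  params <- list(refractory_s = refractory_s,
                 threshold_quantile = threshold_quantile,
                 window_s = window_s)
  if (n < 3)
    return(rwave_train(numeric(0), source = filtered$name, params = params))

  ax <- abs(x)
  wlen <- max(3L, round(window_s * filtered$rate))
  win <- (seq_len(n) - 1L) %/% wlen
  thr_by_win <- vapply(split(ax, win), stats::quantile, 0,
                       probs = threshold_quantile, names = FALSE)
  peak_scale <- stats::quantile(ax, 0.999, names = FALSE)
  thr <- pmax(thr_by_win[win + 1L], 0.25 * peak_scale, 1e-3 * max(ax))

  # strict local maxima of the signal above the threshold
  core <- 2:(n - 1L)
  cand <- core[x[core] > x[core - 1L] & x[core] >= x[core + 1L] &
                 x[core] > thr[core] & x[core] > 0]
  if (!length(cand))
    return(rwave_train(numeric(0), source = filtered$name, params = params))

  # greedy by descending amplitude with refractory spacing; bins of width
  # refractory hold at most one accepted peak each, giving O(n) conflict
  # checks
  ord <- cand[order(-x[cand], cand)]
  refr_n <- refractory_s * filtered$rate
  nbin <- floor((n - 1) / refr_n) + 1L
  bin_of <- function(i) floor((i - 1) / refr_n) + 1L
  bin_peak <- rep(NA_real_, nbin + 2L)
  accepted <- numeric(length(ord))
  na <- 0L
  for (i in ord) {
    b <- bin_of(i)
    nb <- bin_peak[c(b, b + 1L, if (b > 1L) b - 1L)]
    if (any(!is.na(nb) & abs(nb - i) < refr_n)) next
    bin_peak[b] <- i
    na <- na + 1L
    accepted[na] <- i
  }
  idx <- sort(accepted[seq_len(na)])
  rwave_train(filtered$t0 + (idx - 1) / filtered$rate,
              source = filtered$name, params = params)
}

#' Map a detectable fraction to the three-level quality grade
#'
#' A record is graded \code{"undetectable"} when R waves are detectable
#' for less than the lower cut (default 30%) of the record,
#' \code{"unclear"} from the lower cut up to and including the upper cut
#' (30%-70% inclusive at both ends), and \code{"clear"} strictly above
#' the upper cut.
#'
#' @param fraction detectable fraction in \[0, 1\].
#' @param cuts two increasing cut points in (0, 1), default
#'   \code{c(0.30, 0.70)}.
#' @return \code{"undetectable"}, \code{"unclear"} or \code{"clear"}
#'   (vectorised over \code{fraction}).
#' @export
quality_grade <- function(fraction, cuts = c(0.30, 0.70)) {
  if (any(fraction < 0 | fraction > 1, na.rm = TRUE))
    stop_validation("fraction must lie in [0, 1]")
  ifelse(fraction < cuts[1], "undetectable",
         ifelse(fraction <= cuts[2], "unclear", "clear"))
}

#' Grade ECG signal quality from per-window detectability
#'
#' Operationalizes "visually detectable" per non-overlapping window
#' (default 60 s, aligned to the record start; a trailing partial window
#' is discarded). A detected R wave counts as beat-like when (i) its
#' local RR interval (smallest gap to an adjacent detection) implies a
#' heart rate within \code{hr_bounds_bpm}; (ii) its peak amplitude
#' exceeds \code{snr_min} times the window's ambient level (median
#' \eqn{|signal|} excluding \eqn{\pm 0.15} s around every detected
#' peak); and (iii) its waveform is a single smooth deflection at the
#' QRS timescale — correlation of the \code{beat_width_s} neighbourhood
#' with a biphasic (Ricker) kernel of that width of at least 0.8. The
#' shape condition is amplitude-invariant and separates R waves from the
#' largest excursions of oscillatory EMG bursts, which no amplitude
#' ratio can do. A window is detectable when it holds at least one
#' beat-like detection and the majority of its detections are
#' beat-like, so a trace dominated by artifact peaks does not read as
#' ECG. The detectable fraction is the share of detectable windows; the
#' grade follows \code{\link{quality_grade}}.
#'
#' @param filtered band-pass-filtered ECG \code{\link{channel}} (the one
#'   the train was detected on).
#' @param train the \code{\link{rwave_train}} from
#'   \code{\link{detect_r_waves}}.
#' @param window_s grading window length (s).
#' @param snr_min minimum peak-to-ambient amplitude ratio.
#' @param hr_bounds_bpm plausible heart-rate range (beats min-1).
#' @param cuts grade cut points, see \code{\link{quality_grade}}.
#' @param beat_width_s QRS timescale (s) of the shape kernel; the
#'   default 0.12 s suits the slow ventricular depolarization of
#'   ectothermic hearts.
#' @return an object of class \code{quality_assessment}: \code{fraction},
#'   \code{grade}, \code{window_detectable} (logical per window),
#'   \code{window_s}, \code{n_windows}.
#' @export
assess_quality <- function(filtered, train, window_s = 60, snr_min = 3,
                           hr_bounds_bpm = c(1, 60), cuts = c(0.30, 0.70),
                           beat_width_s = 0.12) {
  stopifnot(inherits(filtered, "channel"), inherits(train, "rwave_train"))
  n <- length(filtered$values)
  if (n == 0)
    stop_validation("cannot assess quality of a zero-length record")
  wlen <- round(window_s * filtered$rate)
  nwin <- as.integer(n %/% wlen)
  if (nwin == 0)
    stop_validation("record shorter than one quality window (%g s)", window_s)

  times <- train$times
  flags <- logical(nwin)
  if (length(times)) {
    ax <- abs(filtered$values)
    # noise floor: median |signal| per window, excluding the vicinity of
    # every detected peak
    guard <- round(0.15 * filtered$rate)
    pk_idx <- round((times - filtered$t0) * filtered$rate) + 1L
    excl_idx <- unique(pmax(1L, pmin(n, rep(pk_idx, each = 2L * guard + 1L) +
                                       (-guard):guard)))
    keep <- rep(TRUE, n)
    keep[excl_idx] <- FALSE
    win_of <- (seq_len(n) - 1L) %/% wlen
    ambient_by_win <- rep(0, nwin)
    used <- win_of < nwin & keep
    if (any(used)) {
      med <- vapply(split(ax[used], win_of[used]), stats::median, 0)
      ambient_by_win[as.integer(names(med)) + 1L] <- med
    }

    amp <- ax[pmax(1L, pmin(n, pk_idx))]
    gap_prev <- c(Inf, diff(times))
    gap_next <- c(diff(times), Inf)
    local_rr <- pmin(gap_prev, gap_next)
    rr_lo <- 60 / hr_bounds_bpm[2]
    rr_hi <- 60 / hr_bounds_bpm[1]
    plausible <- is.finite(local_rr) & local_rr >= rr_lo & local_rr <= rr_hi
    pk_win <- floor((times - filtered$t0) / window_s) + 1L
    in_rec <- pk_win >= 1L & pk_win <= nwin
    amb <- ambient_by_win[pmax(1L, pmin(nwin, pk_win))]

    # shape: correlation with a biphasic kernel at the QRS timescale
    half <- max(2L, round(beat_width_s / 2 * filtered$rate))
    kt <- (-half:half) / filtered$rate
    ks <- beat_width_s / 6
    kernel <- (1 - (kt / ks)^2) * exp(-kt^2 / (2 * ks^2))
    shape <- vapply(pk_idx, function(i) {
      if (i - half < 1L || i + half > n) return(0)
      suppressWarnings(stats::cor(filtered$values[(i - half):(i + half)],
                                  kernel))
    }, 0)
    shape[is.na(shape)] <- 0

    beat_like <- in_rec & plausible & shape >= 0.8 &
      (amb == 0 & amp > 0 | amb > 0 & amp / amb > snr_min)
    n_in_win <- tabulate(pk_win[in_rec], nbins = nwin)
    n_good <- tabulate(pk_win[in_rec & beat_like], nbins = nwin)
    flags <- n_good >= 1L & n_good > 0.5 * n_in_win
  }
  fraction <- mean(flags)
  structure(list(fraction = fraction,
                 grade = quality_grade(fraction, cuts),
                 window_detectable = flags, window_s = window_s,
                 n_windows = nwin),
            class = "quality_assessment")
}

#' @export
print.quality_assessment <- function(x, ...) {
  cat(sprintf("<quality_assessment> grade '%s': detectable in %.1f%% of %d x %g s windows\n",
              x$grade, 100 * x$fraction, x$n_windows, x$window_s))
  invisible(x)
}
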