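#' Behaviour model for synthetic deployments
#'
#' A two-state alternating-renewal process over whole minutes: the animal
#' dwells in \code{resting} or \code{moving} for a geometric number of
#' minutes (support >= 1) with the stated means, then switches. Geometric
#' dwells are the minimal-assumption choice and produce runs both shorter
#' and longer than the 2-min phase minimum, so the phase rule is exercised.
#'
#' @param rest_dwell_min,move_dwell_min mean dwell time in each state
#'   (minutes, >= 1; \code{Inf} pins the process in its initial state).
#' @param initial initial state, \code{"resting"} or \code{"moving"}.
#' @param duration_min record length in whole minutes (default 2880 = 48 h).
#' @return an object of class \code{behavior_model}.
#' @export
behavior_model <- function(rest_dwell_min = 20, move_dwell_min = 10,
                           initial = c("resting", "moving"),
                           duration_min = 2880) {
  initial <- match.arg(initial)
  for (v in c(rest_dwell_min, move_dwell_min))
    if (!(is.numeric(v) && length(v) == 1L && !is.na(v) && v >= 1))
      stop_validation("dwell means must be >= 1 minute")
  if (!is_scalar_number(duration_min) || duration_min < 1)
    stop_validation("duration_min must be >= 1")
  structure(list(rest_dwell_min = rest_dwell_min,
                 move_dwell_min = move_dwell_min, initial = initial,
                 duration_min = as.integer(duration_min)),
            class = "behavior_model")
}

#' Cardiac model for synthetic ECG
#'
#' Beat-to-beat RR intervals are drawn around \code{60 / HR(status)}
#' seconds with a given coefficient of variation, and each R wave is
#' rendered as a low-amplitude biphasic (Ricker) template. Defaults follow
#' the heart-rate regimes reported for green turtles in tank deployments:
#' 8.6 beats min-1 resting and 12.2 beats min-1 moving, with an R-wave
#' amplitude about one tenth of a conventional (implanted-electrode)
#' recording.
#'
#' @param rest_hr,move_hr per-state heart rates (beats min-1, > 0).
#' @param rr_cv coefficient of variation of RR intervals (>= 0). The
#'   beat-level variability of real records is unreported; this is a
#'   scaffold parameter, not a physiological claim.
#' @param template_width_s full support of the beat template (s); must be
#'   shorter than the shortest plausible RR interval.
#' @param r_amplitude R-wave peak amplitude (mV).
#' @return an object of class \code{cardiac_model}.
#' @export
cardiac_model <- function(rest_hr = 8.6, move_hr = 12.2, rr_cv = 0.1,
                          template_width_s = 0.12, r_amplitude = 0.1) {
  if (!is_scalar_number(rest_hr) || rest_hr <= 0 ||
      !is_scalar_number(move_hr) || move_hr <= 0)
    stop_validation("heart rates must be positive")
  if (!is_scalar_number(rr_cv) || rr_cv < 0)
    stop_validation("rr_cv must be >= 0")
  if (!is_scalar_number(template_width_s) || template_width_s <= 0)
    stop_validation("template_width_s must be positive")
  if (template_width_s >= 60 / max(rest_hr, move_hr))
    stop_validation("beat template (%g s) is wider than the mean RR interval (%g s): implausible parameters",
                    template_width_s, 60 / max(rest_hr, move_hr))
  structure(list(rest_hr = rest_hr, move_hr = move_hr, rr_cv = rr_cv,
                 template_width_s = template_width_s,
                 r_amplitude = r_amplitude),
            class = "cardiac_model")
}

#' Noise model for synthetic ECG
#'
#' Three additive terms: broadband white noise; slow sinusoidal baseline
#' wander (seawater-intrusion / electrode drift); and band-limited
#' (20-60 Hz) EMG bursts with Poisson onsets placed only inside moving
#' minutes, mimicking muscle-contraction artifacts that contaminate the
#' ECG specifically while the animal is swimming.
#'
#' @param white_sd white-noise standard deviation (mV).
#' @param wander_amp,wander_freq baseline-wander amplitude (mV) and
#'   frequency (Hz, default 0.1).
#' @param emg_amp EMG burst core standard deviation (mV).
#' @param emg_rate_per_min expected burst onsets per moving minute.
#' @param emg_burst_s burst duration (s).
#' @return an object of class \code{noise_model}.
#' @export
noise_model <- function(white_sd = 0.01, wander_amp = 0.05,
                        wander_freq = 0.1, emg_amp = 0.05,
                        emg_rate_per_min = 10, emg_burst_s = 0.5) {
  vals <- c(white_sd = white_sd, wander_amp = wander_amp,
            wander_freq = wander_freq, emg_amp = emg_amp,
            emg_rate_per_min = emg_rate_per_min, emg_burst_s = emg_burst_s)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop_validation("all noise parameters must be finite and non-negative")
  structure(as.list(vals), class = "noise_model")
}

#' Silent noise model (all terms zero)
#' @rdname noise_model
#' @export
noise_model_none <- function() {
  noise_model(white_sd = 0, wander_amp = 0, emg_amp = 0,
              emg_rate_per_min = 0)
}

# geometric dwell with mean m on support {1, 2, ...}
draw_dwell <- function(m) {
  if (!is.finite(m)) return(Inf)
  if (m == 1) return(1L)
  stats::rgeom(1L, prob = 1 / m) + 1L
}

#' Simulate a per-minute behaviour status sequence
#'
#' Alternating-renewal simulation of the \code{\link{behavior_model}}:
#' dwell lengths are geometric with the stated means, truncated at the
#' record end. Reproducible under a fixed seed.
#'
#' @param bm a \code{\link{behavior_model}}.
#' @param seed optional integer seed.
#' @return character vector of length \code{duration_min} with values
#'   \code{"resting"} / \code{"moving"}, one per whole minute.
#' @export
simulate_status_sequence <- function(bm, seed = NULL) {
  stopifnot(inherits(bm, "behavior_model"))
  if (!is.null(seed)) set.seed(seed)
  n <- bm$duration_min
  out <- character(n)
  state <- bm$initial
  i <- 1L
  while (i <= n) {
    mean_dwell <- if (state == "resting") bm$rest_dwell_min else bm$move_dwell_min
    d <- draw_dwell(mean_dwell)
    j <- if (is.finite(d)) min(n, i + d - 1L) else n
    out[i:j] <- state
    i <- j + 1L
    state <- if (state == "resting") "moving" else "resting"
  }
  out
}

# Ricker (Mexican-hat) beat template, peak 1 at t = 0, support ~ [-w/2, w/2]
ricker <- function(t, width_s) {
  s <- width_s / 6
  (1 - (t / s)^2) * exp(-t^2 / (2 * s^2))
}

#' Simulate RR intervals and render a synthetic ECG channel
#'
#' Draws successive RR intervals around \code{60 / HR} seconds for the
#' state of the minute containing each interval's start (truncated
#' normal, truncated below at the template width), renders each R wave as
#' a Ricker template centred at its exact event time, and adds the noise
#' terms. EMG bursts are placed only within moving minutes. The returned
#' true R times are exactly the drawn event times.
#'
#' @param statuses per-minute status sequence (\code{"resting"} /
#'   \code{"moving"}), as from \code{\link{simulate_status_sequence}}.
#' @param cm a \code{\link{cardiac_model}}.
#' @param nm a \code{\link{noise_model}}.
#' @param rate ECG sampling rate in Hz (>= 100 so the template is
#'   resolvable; loggers record at 250 Hz).
#' @param seed optional integer seed.
#' @return list with elements \code{ecg} (a \code{\link{channel}} named
#'   \code{"ecg"}, units mV) and \code{r_times} (numeric, seconds).
#' @export
simulate_rr_and_ecg <- function(statuses, cm, nm = noise_model(),
                                rate = 250, seed = NULL) {
  stopifnot(inherits(cm, "cardiac_model"), inherits(nm, "noise_model"))
  if (!is_scalar_number(rate) || rate < 100)
    stop_validation("ECG rate must be >= 100 Hz for the beat template to be resolvable")
  if (!length(statuses)) stop_validation("empty status sequence")
  if (!is.null(seed)) set.seed(seed)
  dur_s <- 60 * length(statuses)
  hr_of <- function(t) {
    m <- min(length(statuses), floor(t / 60) + 1)
    if (statuses[m] == "resting") cm$rest_hr else cm$move_hr
  }

  # sequential RR draws; interval rate set by the minute holding its start
  r_times <- numeric(ceiling(dur_s / 60 * max(cm$rest_hr, cm$move_hr)) + 16L)
  k <- 0L
  t <- 0
  repeat {
    mu <- 60 / hr_of(t)
    rr <- if (cm$rr_cv > 0) stats::rnorm(1L, mu, cm$rr_cv * mu) else mu
    rr <- max(rr, cm$template_width_s)
    t <- t + rr
    if (t >= dur_s) break
    k <- k + 1L
    if (k > length(r_times)) r_times <- c(r_times, numeric(1024L))
    r_times[k] <- t
  }
  r_times <- r_times[seq_len(k)]

  n <- round(dur_s * rate)
  sig <- numeric(n)
  half <- cm$template_width_s / 2
  for (rt in r_times) {
    i0 <- max(1L, ceiling((rt - half) * rate) + 1L)
    i1 <- min(n, floor((rt + half) * rate) + 1L)
    if (i1 < i0) next
    idx <- i0:i1
    sig[idx] <- sig[idx] +
      cm$r_amplitude * ricker((idx - 1) / rate - rt, cm$template_width_s)
  }

  # noise terms drawn unit-scale then multiplied, so a fixed seed yields
  # the same realization across amplitude settings
  if (nm$white_sd > 0 || nm$wander_amp > 0 || nm$emg_amp > 0 ||
      nm$emg_rate_per_min > 0) {
    tt <- (seq_len(n) - 1) / rate
    sig <- sig + nm$white_sd * stats::rnorm(n)
    phase <- stats::runif(1L, 0, 2 * pi)
    sig <- sig + nm$wander_amp * sin(2 * pi * nm$wander_freq * tt + phase)
    sig <- sig + nm$emg_amp * emg_track(statuses, nm, rate, n)
  }

  list(ecg = channel(sig, rate = rate, units = "mV", name = "ecg"),
       r_times = r_times)
}

# unit-SD band-limited (20-60 Hz) EMG bursts, Poisson onsets inside moving
# minutes only; zero elsewhere
emg_track <- function(statuses, nm, rate, n) {
  track <- numeric(n)
  if (nm$emg_rate_per_min <= 0 || nm$emg_burst_s <= 0) return(track)
  bl <- max(4L, round(nm$emg_burst_s * rate))
  hi <- min(60, 0.45 * rate)
  bf <- signal::butter(2, c(20, hi) / (rate / 2), type = "pass")
  env <- 0.5 - 0.5 * cos(2 * pi * (seq_len(bl) - 1) / (bl - 1))  # Hann
  moving <- which(statuses == "moving")
  for (m in moving) {
    nb <- stats::rpois(1L, nm$emg_rate_per_min)
    if (nb == 0L) next
    onsets <- (m - 1) * 60 + stats::runif(nb, 0, 60 - nm$emg_burst_s)
    for (on in onsets) {
      i0 <- floor(on * rate) + 1L
      i1 <- min(n, i0 + bl - 1L)
      if (i1 <= i0 + 4L) next
      raw <- as.numeric(signal::filter(bf, stats::rnorm(i1 - i0 + 1L)))
      s <- stats::sd(raw)
      if (s > 0) raw <- raw / s
      track[i0:i1] <- track[i0:i1] + raw * env[seq_len(i1 - i0 + 1L)]
    }
  }
  track
}

#' Simulate a longitudinal-acceleration channel
#'
#' Moving minutes contain a flipper-stroke sinusoid plus sensor noise;
#' resting minutes contain noise only. The per-minute SD of a pure
#' sinusoid of amplitude A is A / sqrt(2), so with the default geometry
#' (stroke amplitude 1.0 m s-2, resting noise SD 0.1 m s-2) moving minutes
#' exceed and resting minutes fall below the 0.5 m s-2 activity threshold
#' by construction.
#'
#' @param statuses per-minute status sequence.
#' @param stroke_freq_hz flipper-stroke frequency (Hz).
#' @param stroke_amp stroke sinusoid amplitude (m s-2).
#' @param resting_sd sensor/body noise SD (m s-2), present in all minutes.
#' @param rate sampling rate in Hz (loggers use 16 or 50 Hz; any positive
#'   rate is accepted).
#' @param seed optional integer seed.
#' @return a \code{\link{channel}} named \code{"accel_long"}, units m s-2.
#' @export
simulate_accel <- function(statuses, stroke_freq_hz = 0.4, stroke_amp = 1.0,
                           resting_sd = 0.1, rate = 16, seed = NULL) {
  if (!is_scalar_number(rate) || rate <= 0)
    stop_validation("rate must be positive")
  if (stroke_amp < 0 || resting_sd < 0)
    stop_validation("amplitudes must be non-negative")
  if (!length(statuses)) stop_validation("empty status sequence")
  if (!is.null(seed)) set.seed(seed)
  n <- round(60 * length(statuses) * rate)
  tt <- (seq_len(n) - 1) / rate
  minute <- pmin(length(statuses), floor(tt / 60) + 1)
  moving <- statuses[minute] == "moving"
  sig <- numeric(n)
  if (resting_sd > 0) sig <- resting_sd * stats::rnorm(n)
  sig[moving] <- sig[moving] + stroke_amp * sin(2 * pi * stroke_freq_hz * tt[moving])
  channel(sig, rate = rate, units = "m s-2", name = "accel_long")
}

#' Generate a full synthetic deployment with ground truth
#'
#' Composes the behaviour, cardiac and acceleration generators on a shared
#' deployment clock and returns both the loadable
#' \code{\link{deployment_record}} and a ground-truth object holding the
#' true R-wave times, the true minute statuses, every model parameter and
#' the seed. A constant-temperature 1 Hz channel is included for realism;
#' it is carried but never analyzed.
#'
#' @param bm,cm,nm behaviour, cardiac and noise models.
#' @param ecg_rate,accel_rate sampling rates (Hz) for the ECG and
#'   acceleration channels.
#' @param stroke_freq_hz,stroke_amp,resting_sd acceleration-generator
#'   parameters, see \code{\link{simulate_accel}}.
#' @param seed integer seed (mandatory: ground truth must be reproducible).
#'   Component generators use seeds derived from it.
#' @param turtle_id,placement deployment metadata.
#' @return list with elements \code{record} (a
#'   \code{\link{deployment_record}}) and \code{truth} (class
#'   \code{ground_truth}: \code{r_times}, \code{statuses}, \code{params},
#'   \code{seed}).
#' @export
generate_deployment <- function(bm = behavior_model(), cm = cardiac_model(),
                                nm = noise_model(), ecg_rate = 250,
                                accel_rate = 16, stroke_freq_hz = 0.4,
                                stroke_amp = 1.0, resting_sd = 0.1,
                                seed, turtle_id = "SYN01", placement = "C") {
  if (missing(seed) || !is_scalar_number(seed))
    stop_validation("a numeric seed is required for a reproducible deployment")
  seed <- as.integer(seed) %% 1000000L
  statuses <- simulate_status_sequence(bm, seed = seed)
  ec <- simulate_rr_and_ecg(statuses, cm, nm, rate = ecg_rate,
                            seed = seed + 1L)
  accel <- simulate_accel(statuses, stroke_freq_hz, stroke_amp, resting_sd,
                          rate = accel_rate, seed = seed + 2L)
  temp <- channel(rep(23.4, 60 * length(statuses)), rate = 1, units = "degC",
                  name = "temperature")
  record <- deployment_record(turtle_id, placement,
                              channels = list(ecg = ec$ecg,
                                              accel_long = accel,
                                              temperature = temp))
  truth <- structure(
    list(r_times = ec$r_times, statuses = statuses,
         params = list(behavior = unclass(bm), cardiac = unclass(cm),
                       noise = unclass(nm), ecg_rate = ecg_rate,
                       accel_rate = accel_rate,
                       stroke_freq_hz = stroke_freq_hz,
                       stroke_amp = stroke_amp, resting_sd = resting_sd),
         seed = seed),
    class = "ground_truth")
  list(record = record, truth = truth)
}

#' Write / read ground truth as plain text
#'
#' R times one per line (seconds, full precision), minute statuses one per
#' line, and the generator parameters plus seed as YAML.
#'
#' @param truth a \code{ground_truth} object.
#' @param dir destination directory.
#' @param force overwrite existing files?
#' @return the directory, invisibly.
#' @export
write_ground_truth <- function(truth, dir, force = FALSE) {
  stopifnot(inherits(truth, "ground_truth"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("r_times.txt", "statuses.txt", "params.yml"))
  if (!force && any(file.exists(paths)))
    stop_validation("refusing to overwrite ground truth in %s (use force = TRUE)", dir)
  writeLines(format_full(truth$r_times), paths[1])
  writeLines(truth$statuses, paths[2])
  yaml::write_yaml(c(truth$params, list(seed = truth$seed)), paths[3])
  invisible(dir)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(dir) {
  p <- yaml::read_yaml(file.path(dir, "params.yml"))
  structure(list(r_times = as.numeric(readLines(file.path(dir, "r_times.txt"))),
                 statuses = readLines(file.path(dir, "statuses.txt")),
                 params = p[setdiff(names(p), "seed")], seed = p$seed),
            class = "ground_truth")
}
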