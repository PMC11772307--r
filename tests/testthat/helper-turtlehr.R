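# Shared fixtures and independent oracles for the test suite.

# Greedy one-to-one matching of detected event times to true event times
# within a tolerance; returns tp/fp/fn counts and the F1 score.
match_events <- function(detected, truth, tol_s = 0.1) {
  used <- logical(length(detected))
  tp <- 0L
  for (t in truth) {
    i <- which(!used & abs(detected - t) <= tol_s)
    if (length(i)) {
      used[i[which.min(abs(detected[i] - t))]] <- TRUE
      tp <- tp + 1L
    }
  }
  fp <- length(detected) - tp
  fn <- length(truth) - tp
  f1 <- if (tp == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  list(tp = tp, fp = fp, fn = fn, f1 = f1)
}

# Independent brute-force oracle for phase segmentation: walk the sequence
# element by element, enumerate maximal runs, keep those meeting the
# minimum length. Deliberately naive (no rle, no vectorization).
brute_force_phases <- function(statuses, min_minutes) {
  out <- data.frame(status = character(0), start_min = integer(0),
                    end_min = integer(0), duration_min = integer(0))
  n <- length(statuses)
  if (n == 0) return(out)
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && statuses[j + 1L] == statuses[i]) j <- j + 1L
    len <- j - i + 1L
    if (len >= min_minutes)
      out <- rbind(out, data.frame(status = statuses[i],
                                   start_min = i - 1L, end_min = j,
                                   duration_min = len))
    i <- j + 1L
  }
  rownames(out) <- NULL
  out
}

# Per-status event rates implied by ground truth: events assigned to the
# minute containing them, rates in beats per minute of that status.
truth_state_rates <- function(truth) {
  minute <- floor(truth$r_times / 60) + 1L
  minute <- pmin(minute, length(truth$statuses))
  ev_status <- truth$statuses[minute]
  vapply(c(resting = "resting", moving = "moving"), function(s) {
    n_min <- sum(truth$statuses == s)
    if (n_min == 0) NA_real_ else sum(ev_status == s) / n_min
  }, 0)
}

# A clean single-beat-template train channel for detector tests: spikes of
# unit amplitude shaped as 3-sample triangles at the given times.
spike_channel <- function(times_s, rate = 250, dur_s = NULL, amp = 1) {
  dur_s <- dur_s %||% (max(times_s) + 1)
  n <- round(dur_s * rate)
  x <- numeric(n)
  for (t in times_s) {
    i <- round(t * rate) + 1L
    if (i >= 2 && i < n) {
      x[i] <- x[i] + amp
      x[c(i - 1L, i + 1L)] <- x[c(i - 1L, i + 1L)] + amp / 2
    }
  }
  channel(x, rate = rate, units = "mV", name = "ecg")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Expand per-placement grade counts into one evaluation row per animal.
evals_from_counts <- function(counts) {
  rows <- do.call(rbind, lapply(names(counts), function(p) {
    cc <- counts[[p]]
    data.frame(placement = p,
               grade = rep(names(cc), cc),
               stringsAsFactors = FALSE)
  }))
  rows$turtle_id <- paste0("T", seq_len(nrow(rows)), "_", rows$placement)
  rows[, c("turtle_id", "placement", "grade")]
}
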