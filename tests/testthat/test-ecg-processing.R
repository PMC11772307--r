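make_sine <- function(freq, rate = 250, dur_s = 60, amp = 1) {
  channel(amp * sin(2 * pi * freq * (0:(dur_s * rate - 1)) / rate),
          rate = rate, units = "mV", name = "ecg")
}

# steady-state amplitude, ignoring filter edge transients
mid_amp <- function(ch) {
  n <- length(ch$values)
  max(abs(ch$values[round(n * 0.25):round(n * 0.75)]))
}

test_that("band-pass filter rejects DC and baseline wander, passes the band", {
  dc <- channel(rep(1, 250 * 30), 250, "mV", "ecg")
  expect_lt(max(abs(bandpass_filter(dc)$values)), 0.01)

  # unit sinusoid at the geometric band centre passes near unity
  centre <- make_sine(sqrt(5 * 30))
  expect_lt(abs(mid_amp(bandpass_filter(centre)) - 1), 0.1)

  # 0.1 Hz baseline wander attenuated by at least 95%
  wander <- make_sine(0.1)
  expect_lt(mid_amp(bandpass_filter(wander)), 0.05)

  # filtering an in-band sinusoid twice changes amplitude < 2% vs once
  once <- bandpass_filter(centre)
  twice <- bandpass_filter(once)
  expect_lt(abs(mid_amp(twice) - mid_amp(once)) / mid_amp(once), 0.02)
})

test_that("band-pass filter preserves length, clock and peak timing", {
  st <- rep("resting", 3)
  out <- simulate_rr_and_ecg(st, cardiac_model(rest_hr = 10, rr_cv = 0),
                             noise_model_none(), rate = 250, seed = 1)
  f <- bandpass_filter(out$ecg)
  expect_identical(length(f$values), length(out$ecg$values))
  expect_identical(f$rate, out$ecg$rate)
  expect_identical(f$t0, out$ecg$t0)
  # zero phase: the filtered peak stays within one sample of the raw peak
  for (rt in out$r_times[2:4]) {
    i <- round(rt * 250) + 1
    win <- (i - 50):(i + 50)
    expect_lte(abs(which.max(f$values[win]) - which.max(out$ecg$values[win])),
               1)
  }
})

test_that("band-pass filter validates its band and input length", {
  ch <- make_sine(10, dur_s = 10)
  expect_error(bandpass_filter(ch, 5, 130), "Nyquist")
  expect_error(bandpass_filter(ch, 0, 30), "Nyquist|band")
  expect_error(bandpass_filter(channel(stats::rnorm(50), 250), 5, 30),
               "too short")
})

test_that("R-wave detection recovers a clean synthetic train", {
  st <- rep("resting", 10)
  out <- simulate_rr_and_ecg(st, cardiac_model(rest_hr = 10, rr_cv = 0),
                             noise_model_none(), rate = 250, seed = 2)
  f <- bandpass_filter(out$ecg)
  tr <- detect_r_waves(f, refractory_s = 1)
  expect_identical(length(tr$times), length(out$r_times))
  expect_true(all(abs(tr$times - out$r_times) <= 1 / 250 + 1e-9))
})

test_that("detection handles degenerate inputs and enforces the refractory", {
  flat <- channel(rep(0, 250 * 20), 250, "mV", "ecg")
  expect_identical(length(detect_r_waves(flat)$times), 0L)

  expect_error(detect_r_waves(flat, refractory_s = 0), "refractory")

  # two equal peaks 0.5 s apart with refractory 1 s -> exactly one kept
  two <- spike_channel(c(3.0, 3.5), dur_s = 10)
  tr <- detect_r_waves(two, refractory_s = 1)
  expect_identical(length(tr$times), 1L)
  expect_equal(tr$times, 3.0, tolerance = 1e-9)

  # refractory invariant holds on arbitrary noisy signals
  set.seed(13)
  for (i in 1:10) {
    x <- channel(stats::rnorm(250 * 30), 250, "mV", "ecg")
    tr <- detect_r_waves(x, refractory_s = 0.8)
    if (length(tr$times) > 1)
      expect_true(all(diff(tr$times) >= 0.8 - 1e-9))
  }
  expect_error(rwave_train(c(3, 3.1), params = list(refractory_s = 1)),
               "refractory")
  expect_error(rwave_train(c(2, 1)), "increasing")
})

test_that("detection keeps F1 >= 0.99 across slow heart rates", {
  for (hr in c(5, 12, 20)) {
    st <- rep("resting", 20)
    out <- simulate_rr_and_ecg(st, cardiac_model(rest_hr = hr,
                                                 move_hr = hr + 1),
                               noise_model_none(), rate = 250,
                               seed = round(hr * 10))
    tr <- detect_r_waves(bandpass_filter(out$ecg))
    m <- match_events(tr$times, out$r_times, tol_s = 0.1)
    expect_gte(m$f1, 0.99)
  }
})

test_that("quality grades follow the cut-point wording exactly", {
  fractions <- c(0.00, 0.29, 0.30, 0.50, 0.70, 0.71, 0.75, 1.00)
  expect_identical(quality_grade(fractions),
                   c("undetectable", "undetectable", "unclear", "unclear",
                     "unclear", "clear", "clear", "clear"))
  expect_error(quality_grade(1.2), "fraction")
})

test_that("quality assessment flags windows and grades the record", {
  # clean record: every complete window detectable -> clear
  st <- rep("resting", 10)
  out <- simulate_rr_and_ecg(st, cardiac_model(), noise_model_none(),
                             rate = 250, seed = 4)
  f <- bandpass_filter(out$ecg)
  tr <- detect_r_waves(f)
  qa <- assess_quality(f, tr)
  expect_identical(qa$n_windows, 10L)
  expect_equal(qa$fraction, 1)
  expect_identical(qa$grade, "clear")

  # empty train -> fraction 0 -> undetectable
  qa0 <- assess_quality(f, rwave_train(numeric(0)))
  expect_equal(qa0$fraction, 0)
  expect_identical(qa0$grade, "undetectable")

  expect_error(assess_quality(channel(numeric(0), 250), tr),
               "zero-length")
})
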