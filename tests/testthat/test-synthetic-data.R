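test_that("generators are deterministic under a fixed seed", {
  bm <- behavior_model(duration_min = 30)
  a <- generate_deployment(bm, seed = 99)
  b <- generate_deployment(bm, seed = 99)
  expect_identical(a$truth$statuses, b$truth$statuses)
  expect_identical(a$truth$r_times, b$truth$r_times)
  expect_identical(a$record$channels$ecg$values, b$record$channels$ecg$values)
  expect_identical(a$record$channels$accel_long$values,
                   b$record$channels$accel_long$values)

  # byte-identical channel files on re-generation
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_deployment(a$record, d1)
  write_deployment(b$record, d2)
  for (f in c("ecg.csv", "accel_long.csv", "manifest.yml"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
})

test_that("status sequences follow the alternating-renewal model", {
  # degenerate limit: infinite moving dwell pins the process in moving
  bm <- behavior_model(move_dwell_min = Inf, initial = "moving",
                       duration_min = 50)
  expect_identical(unique(simulate_status_sequence(bm, seed = 1)), "moving")

  # long-run resting fraction matches renewal expectation 20/(20+10) = 2/3
  # within 3 standard errors (ratio-estimator s.e. over dwell cycles)
  bm <- behavior_model(rest_dwell_min = 20, move_dwell_min = 10,
                       duration_min = 10000)
  st <- simulate_status_sequence(bm, seed = 5)
  frac <- mean(st == "resting")
  r <- rle(st)
  cyc <- tapply(r$lengths, cumsum(r$values == "resting") -
                  (r$values == "resting") + 1, sum)
  rest <- tapply(r$lengths * (r$values == "resting"),
                 cumsum(r$values == "resting") -
                   (r$values == "resting") + 1, sum)
  k <- length(cyc)
  resid <- rest - frac * cyc
  se <- sqrt(sum(resid^2) / (k - 1) / k) / mean(cyc)
  expect_lt(abs(frac - 2 / 3), 3 * se)

  expect_error(behavior_model(duration_min = 0), "duration")
  expect_error(behavior_model(rest_dwell_min = 0.5), "dwell")
})

test_that("RR intervals and rendered ECG honour the cardiac model", {
  # CV = 0, all resting, HR 10 -> R times exactly 6 s apart
  st <- rep("resting", 5)
  out <- simulate_rr_and_ecg(st, cardiac_model(rest_hr = 10, rr_cv = 0),
                             noise_model_none(), rate = 250, seed = 1)
  expect_equal(diff(out$r_times), rep(6, length(out$r_times) - 1),
               tolerance = 1e-12)

  # noiseless signal is exactly the template train: peak = R amplitude,
  # and one local maximum above half amplitude per true beat
  st <- rep("resting", 10)
  cm <- cardiac_model()
  out <- simulate_rr_and_ecg(st, cm, noise_model_none(), rate = 250,
                             seed = 2)
  x <- out$ecg$values
  expect_equal(max(abs(x)), cm$r_amplitude, tolerance = 1e-3)
  core <- 2:(length(x) - 1)
  n_peaks <- sum(x[core] > x[core - 1] & x[core] >= x[core + 1] &
                   x[core] > cm$r_amplitude / 2)
  expect_identical(n_peaks, length(out$r_times))

  expect_error(simulate_rr_and_ecg(st, cm, noise_model_none(), rate = 50),
               "100 Hz")
  expect_error(cardiac_model(rest_hr = 8.6, move_hr = 12.2,
                             template_width_s = 8), "wider")
})

test_that("empirical event rate converges to the configured heart rate", {
  # 24 h all-resting at HR 8.6, CV 0.1: count / 1440 within 2% of 8.6
  st <- rep("resting", 1440)
  out <- simulate_rr_and_ecg(st, cardiac_model(), noise_model_none(),
                             rate = 100, seed = 11)
  rate_bpm <- length(out$r_times) / 1440
  expect_lt(abs(rate_bpm - 8.6) / 8.6, 0.02)
})

test_that("EMG bursts land only inside moving minutes", {
  st <- rep(c("resting", "moving"), times = 10)
  nm0 <- noise_model(white_sd = 0, wander_amp = 0, emg_amp = 0,
                     emg_rate_per_min = 8)
  nm1 <- noise_model(white_sd = 0, wander_amp = 0, emg_amp = 1,
                     emg_rate_per_min = 8)
  a <- simulate_rr_and_ecg(st, cardiac_model(), nm0, rate = 250, seed = 6)
  b <- simulate_rr_and_ecg(st, cardiac_model(), nm1, rate = 250, seed = 6)
  emg <- b$ecg$values - a$ecg$values
  minute <- floor(channel_times(b$ecg) / 60) + 1
  expect_true(any(emg != 0))
  expect_true(all(st[minute[emg != 0]] == "moving"))
})

test_that("acceleration straddles the activity threshold by construction", {
  st <- rep(c("resting", "moving"), times = 5)
  acc <- simulate_accel(st, stroke_amp = 1.0, resting_sd = 0.1, rate = 16,
                        seed = 3)
  sds <- minute_sd(acc)
  expect_true(all(sds$sd[st == "moving"] > 0.5))
  expect_true(all(sds$sd[st == "resting"] < 0.5))

  # silent generator: all-zero channel
  acc0 <- simulate_accel(st, stroke_amp = 0, resting_sd = 0, rate = 16)
  expect_true(all(acc0$values == 0))
  expect_true(all(minute_sd(acc0)$sd == 0))

  # pure sinusoid amplitude 0.8 -> minute SD ~ 0.8 / sqrt(2)
  acc8 <- simulate_accel(rep("moving", 3), stroke_amp = 0.8,
                         resting_sd = 0, rate = 50)
  expect_equal(minute_sd(acc8)$sd, rep(0.8 / sqrt(2), 3), tolerance = 0.01)

  expect_error(simulate_accel(st, stroke_amp = -1), "non-negative")
})

test_that("generated deployments have consistent clocks and sizes", {
  bm <- behavior_model(duration_min = 60)  # 1 h
  dep <- generate_deployment(bm, seed = 8)
  expect_identical(length(dep$record$channels$ecg$values), 3600L * 250L)
  expect_identical(length(dep$record$channels$accel_long$values),
                   3600L * 16L)
  expect_true(is.unsorted(dep$truth$r_times) == FALSE)
  expect_identical(length(dep$truth$statuses), 60L)

  # write -> load round trip leaves ground truth unchanged
  dir <- withr::local_tempdir()
  write_deployment(dep$record, dir)
  write_ground_truth(dep$truth, dir)
  back <- load_deployment(file.path(dir, "manifest.yml"))
  truth <- read_ground_truth(dir)
  expect_identical(truth$r_times, dep$truth$r_times)
  expect_identical(truth$statuses, dep$truth$statuses)
  expect_identical(back$channels$ecg$values,
                   dep$record$channels$ecg$values)
  expect_error(generate_deployment(bm), "seed")
})
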