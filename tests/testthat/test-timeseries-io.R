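test_that("channel files round-trip bit-for-bit", {
  set.seed(41)
  for (i in 1:20) {
    rate <- sample(c(1, 16, 50, 250), 1)
    n <- sample(0:500, 1)
    ch <- channel(stats::rnorm(n) * 10^sample(-6:6, 1), rate = rate,
                  units = sample(c("mV", "m s-2", "degC"), 1),
                  name = sprintf("ch%02d", i),
                  t0 = stats::runif(1, 0, 100))
    path <- withr::local_tempfile(fileext = ".csv")
    write_channel(ch, path, force = TRUE)
    back <- read_channel(path)
    expect_identical(back$values, ch$values)
    expect_identical(back$rate, ch$rate)
    expect_identical(back$t0, ch$t0)
    expect_identical(back$units, ch$units)
    expect_identical(back$name, ch$name)
  }
})

test_that("read_channel echoes headers and rejects malformed files", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# name: ecg", "# rate_hz: 250", "# units: mV", "# t0_s: 0",
               "0.1", "0.2", "0.1"), path)
  ch <- read_channel(path)
  expect_s3_class(ch, "channel")
  expect_equal(ch$values, c(0.1, 0.2, 0.1))
  expect_equal(ch$rate, 250)
  expect_equal(ch$units, "mV")

  writeLines(c("# name: ecg", "# rate_hz: 0", "# units: mV", "# t0_s: 0",
               "0.1"), path)
  expect_error(read_channel(path), "rate")

  writeLines(c("# name: ecg", "# rate_hz: 250", "# units: mV", "# t0_s: 0",
               "0.1", "zap", "0.2"), path)
  expect_error(read_channel(path), "line 6")

  writeLines(c("# name: ecg", "# rate_hz: 250", "# rate_hz: 16",
               "# units: mV", "# t0_s: 0", "0.1"), path)
  expect_error(read_channel(path), "duplicate")

  writeLines(c("# name: ecg", "# rate_hz: 250", "0.1"), path)
  expect_error(read_channel(path), "missing header")
})

test_that("channels refuse non-finite samples and invalid rates", {
  expect_error(channel(c(1, NaN, 2), 250), "non-finite")
  expect_error(channel(c(1, NA, 2), 250), "non-finite")
  expect_error(channel(1:3, 0), "rate")
  expect_error(channel(1:3, -5), "rate")
  expect_silent(channel(numeric(0), 16))
})

test_that("write_channel refuses to overwrite without force", {
  ch <- channel(1:5, 16, name = "accel_long")
  path <- withr::local_tempfile(fileext = ".csv")
  write_channel(ch, path)
  expect_error(write_channel(ch, path), "overwrite")
  expect_silent(write_channel(ch, path, force = TRUE))

  # empty channel writes a valid file with 0 data rows
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_channel(channel(numeric(0), 1, name = "empty"), p2)
  expect_identical(length(read_channel(p2)$values), 0L)
})

test_that("deployments load and validate required channels and placement", {
  ecg <- channel(stats::rnorm(500), 250, "mV", "ecg")
  acc <- channel(stats::rnorm(32), 16, "m s-2", "accel_long")
  rec <- deployment_record("G001", "C", list(ecg = ecg, accel_long = acc),
                           body_mass_kg = 25.3)
  dir <- withr::local_tempdir()
  manifest <- write_deployment(rec, dir)
  back <- load_deployment(manifest)
  expect_identical(back$turtle_id, "G001")
  expect_identical(back$placement, "C")
  expect_identical(back$body_mass_kg, 25.3)
  # loading never alters sample values
  expect_identical(back$channels$ecg$values, ecg$values)
  expect_identical(back$channels$accel_long$values, acc$values)

  expect_error(deployment_record("G001", "C", list(ecg = ecg)),
               "incomplete deployment")
  expect_error(deployment_record("G001", "D",
                                 list(ecg = ecg, accel_long = acc)),
               "placement")

  # manifest missing a required channel fails on load
  m <- yaml::read_yaml(manifest)
  m$channels$accel_long <- NULL
  m2 <- file.path(dir, "manifest2.yml")
  yaml::write_yaml(m, m2)
  expect_error(load_deployment(m2), "incomplete deployment")
})

test_that("run configs apply defaults and reject bad fields", {
  cfg <- run_config()
  expect_equal(cfg$behavior_threshold, 0.5)
  expect_equal(cfg$min_phase_min, 2L)
  expect_equal(cfg$exclude_hours, 12)
  expect_equal(cfg$quality_cuts, c(0.30, 0.70))

  path <- withr::local_tempfile(fileext = ".yml")
  writeLines("exclude_hours: 6", path)
  expect_equal(read_run_config(path)$exclude_hours, 6)
  expect_equal(read_run_config(path)$behavior_threshold, 0.5)
  writeLines("exclud_hours: 6", path)
  expect_error(read_run_config(path), "unknown config field")

  expect_error(run_config(band_low_hz = 30, band_high_hz = 5), "band")
  expect_error(run_config(quality_cuts = c(0.7, 0.3)), "quality_cuts")
  expect_error(run_config(min_phase_min = 0), "min_phase_min")
})
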