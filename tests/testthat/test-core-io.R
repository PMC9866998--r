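test_that("unit conversion is the exact standard-gravity bijection", {
  t <- seq(0, 0.03, by = 0.01)
  rec <- accel_recording(t, rep(0, 4), rep(0, 4), rep(1, 4), fs = 100,
                         units = "g")
  ms2 <- convert_units(rec, "m_per_s2")
  expect_equal(ms2$az, rep(9.80665, 4))
  expect_identical(recording_units(ms2), "m_per_s2")
  # full-scale +-8 g maps to +-78.4532 m/s^2
  rec8 <- accel_recording(t, rep(0, 4), rep(0, 4), c(8, -8, 8, -8),
                          fs = 100, units = "g")
  expect_equal(convert_units(rec8, "m_per_s2")$az,
               c(78.4532, -78.4532, 78.4532, -78.4532))
  # inverse identity and idempotence
  back <- convert_units(ms2, "g")
  expect_equal(back$az, rec$az, tolerance = 1e-12)
  expect_identical(convert_units(rec, "g"), rec)
})

test_that("accelerometer CSV round trip preserves data and infers fs", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  # 4-row CSV at 0.01 s spacing infers 100 Hz
  readr::write_csv(tibble::tibble(time = c(0, 0.01, 0.02, 0.03),
                                  ax = 1:4, ay = 0, az = 9.8), tmp)
  rec <- read_accel_csv(tmp)
  expect_equal(recording_fs(rec), 100)

  sim <- simulate_walk(sim_params(duration_s = 8, noise_sd = 0.3, seed = 9))
  write_accel_csv(sim$recording, tmp)
  back <- read_accel_csv(tmp, fs = 100)
  expect_equal(nrow(back), nrow(sim$recording))
  expect_equal(back$time, sim$recording$time, tolerance = 1e-9)
  expect_equal(back$az, sim$recording$az, tolerance = 1e-9)
  expect_equal(back$ax, sim$recording$ax, tolerance = 1e-9)
})

test_that("malformed accelerometer input is rejected", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(time = c(0, 0.01), ax = 0, ay = 0), tmp)
  expect_error(read_accel_csv(tmp), class = "freegait_format_error")
  readr::write_csv(tibble::tibble(time = c(0, 0.02, 0.01), ax = 0, ay = 0,
                                  az = 0), tmp)
  expect_error(read_accel_csv(tmp), class = "freegait_data_error")
  # drop-out gaps beyond 1% raise the gap warning
  tt <- seq(0, 9.99, by = 0.01)
  keep <- !(tt > 2 & tt < 2.5) & !(tt > 5 & tt < 5.4)
  readr::write_csv(tibble::tibble(time = tt[keep], ax = 0, ay = 0, az = 9.8),
                   tmp)
  expect_warning(read_accel_csv(tmp, fs = 100),
                 class = "freegait_gap_warning")
})

test_that("context tracks validate tokens and reject overlap", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(start = 0, end = 30, terrain = "asphalt",
                                  environment = "outdoor", task = "single"),
                   tmp)
  trk <- read_context_csv(tmp)
  expect_equal(nrow(trk), 1L)
  expect_error(context_track(c(0, 20), c(30, 40), c("a", "b")),
               class = "freegait_validation_error")
  expect_error(context_track(0, 30, "asphalt", environment = "outside"),
               class = "freegait_validation_error")
  expect_error(context_track(0, 30, "asphalt", task = "triple"),
               class = "freegait_validation_error")
  # the six study terrain classes stay distinct strings
  six <- context_track(seq(0, 150, by = 30), seq(30, 180, by = 30),
                       c("lab", "asphalt", "asphalt_paving", "paving",
                         "stairs_up", "stairs_down"))
  expect_equal(dplyr::n_distinct(six$terrain), 6L)
})

test_that("overlap rejection holds over random interval sets", {
  set.seed(7)
  for (i in 1:20) {
    n <- sample(2:8, 1)
    len <- runif(n, 0.5, 5)
    gap <- runif(n, 0.01, 3)
    start <- cumsum(gap + dplyr::lag(len, default = 0))
    trk <- context_track(start, start + len, sample(letters, n, TRUE))
    expect_equal(nrow(trk), n)
    # shrink one gap into an overlap: must be rejected
    j <- sample(n - 1, 1)
    bad_start <- start
    bad_start[j + 1] <- start[j] + len[j] / 2
    expect_error(context_track(bad_start, bad_start + len,
                               sample(letters, n, TRUE)),
                 class = "freegait_validation_error")
  }
})

test_that("pipeline config round-trips through JSON identically", {
  cfg <- gait_config(leg_length_m = 0.95, anomaly_k = 2.5,
                     scale_policy = 1.8)
  tmp <- withr::local_tempfile(fileext = ".json")
  write_gait_config(cfg, tmp)
  expect_equal(read_gait_config(tmp), cfg)
  expect_error(gait_config(window_s = -1), class = "freegait_config_error")
  expect_error(gait_config(first_side = "C"),
               class = "freegait_config_error")
})
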