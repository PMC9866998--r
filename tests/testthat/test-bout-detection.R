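cfg <- gait_config()

test_that("posture masks separate standing, lying and moving", {
  p <- sim_params(noise_sd = 0.3, seed = 21)
  stand <- simulate_recording(tibble::tibble(activity = "stand",
                                             duration_s = 20), p)
  expect_true(all(upright_mask(stand$recording, cfg)))
  # sensor noise may tick the threshold on isolated samples only
  expect_lt(mean(movement_mask(stand$recording, cfg)), 0.05)
  quiet <- simulate_recording(tibble::tibble(activity = "stand",
                                             duration_s = 20),
                              sim_params(noise_sd = 0, seed = 21))
  expect_false(any(movement_mask(quiet$recording, cfg)))
  lie <- simulate_recording(tibble::tibble(activity = "lie",
                                           duration_s = 20), p)
  expect_false(any(upright_mask(lie$recording, cfg)))
  # stand -> lie transition localised within 1 s of the boundary
  mix <- simulate_recording(tibble::tibble(activity = c("stand", "lie"),
                                           duration_s = c(15, 15)), p)
  um <- upright_mask(mix$recording, cfg)
  tt <- mix$recording$time
  expect_true(all(um[tt < 14]))
  expect_false(any(um[tt > 16]))
  # short recordings are refused
  short <- simulate_walk(sim_params(duration_s = 1, noise_sd = 0), margin_s = 0.2)
  expect_error(upright_mask(short$recording, cfg),
               class = "freegait_input_error")
})

test_that("movement mask is monotone non-increasing in its threshold", {
  p <- sim_params(duration_s = 10, noise_sd = 0.3, seed = 22)
  rec <- simulate_walk(p)$recording
  thresholds <- c(0.05, 0.1, 0.3, 1, 5, 50)
  counts <- vapply(thresholds,
                   function(th) sum(movement_mask(rec, cfg, sd_thresh = th)),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
  # a threshold above the signal SD yields an empty mask
  expect_equal(counts[length(counts)], 0)
  # noise-free walking is fully above the default threshold
  rec0 <- simulate_walk(sim_params(duration_s = 10, noise_sd = 0),
                        margin_s = 0)$recording
  expect_true(all(movement_mask(rec0, cfg)))
})

test_that("walking bouts are recovered with accurate boundaries", {
  p <- sim_params(step_time_mean_L = 0.5, step_time_mean_R = 0.5,
                  step_time_sd = 0.01, noise_sd = 0.3, seed = 23)
  sim <- simulate_recording(
    tibble::tibble(activity = c("stand", "walk", "stand"),
                   duration_s = c(10, 30, 10)), p)
  bouts <- extract_walking_bouts(sim$recording, cfg)
  expect_equal(nrow(bouts), 1L)
  expect_lt(abs(bouts$start - 10), 1.5)
  expect_lt(abs(bouts$end - 40), 1.5)
  # lying only: no bouts
  lie <- simulate_recording(tibble::tibble(activity = "lie",
                                           duration_s = 60), p)
  expect_equal(nrow(extract_walking_bouts(lie$recording, cfg)), 0L)
  # two walks split by a 1 s stand merge into one bout (gap <= 2 s)
  split <- simulate_recording(
    tibble::tibble(activity = c("walk", "stand", "walk"),
                   duration_s = c(15, 1, 15)), p)
  expect_equal(nrow(extract_walking_bouts(split$recording, cfg)), 1L)
})

test_that("bout recall and precision exceed 95% on random schedules", {
  set.seed(31)
  hits <- 0L; total <- 0L; false_pos <- 0L
  for (i in 1:6) {
    p <- sim_params(step_time_mean_L = runif(1, 0.45, 0.6),
                    step_time_mean_R = runif(1, 0.45, 0.6),
                    step_time_sd = 0.02, noise_sd = runif(1, 0.1, 0.4),
                    seed = 300 + i)
    sch <- tibble::tibble(
      activity = c("stand", "walk", "stand", "walk", "stand"),
      duration_s = c(runif(1, 5, 10), runif(1, 15, 40), runif(1, 5, 10),
                     runif(1, 15, 40), runif(1, 5, 10)))
    sim <- simulate_recording(sch, p)
    bouts <- extract_walking_bouts(sim$recording, cfg)
    truth <- tibble::tibble(start = sim$truth$walk_start,
                            end = sim$truth$walk_end)
    for (j in seq_len(nrow(truth))) {
      total <- total + 1L
      ov <- pmin(bouts$end, truth$end[j]) - pmax(bouts$start, truth$start[j])
      if (any(ov / (truth$end[j] - truth$start[j]) >= 0.8)) hits <- hits + 1L
    }
    for (j in seq_len(nrow(bouts))) {
      ov <- pmin(bouts$end[j], truth$end) - pmax(bouts$start[j], truth$start)
      if (!any(ov / (bouts$end[j] - bouts$start[j]) >= 0.8)) {
        false_pos <- false_pos + 1L
      }
    }
  }
  expect_gte(hits / total, 0.95)
  expect_lte(false_pos / max(total, 1), 0.05)
})

test_that("windowing tiles bouts and discards short tails", {
  b <- function(start, end) {
    tibble::tibble(bout_id = 1L, start = start, end = end)
  }
  expect_equal(nrow(window_bouts(b(0, 65), 30)), 2L)
  expect_equal(nrow(window_bouts(b(0, 29), 30)), 0L)
  w <- window_bouts(b(100, 190), 30)
  expect_equal(w$start, c(100, 130, 160))
  expect_equal(w$end, c(130, 160, 190))
  # time conservation: total window time never exceeds total bout time
  set.seed(5)
  for (i in 1:10) {
    bouts <- tibble::tibble(bout_id = 1:3, start = c(0, 100, 300),
                            end = c(0, 100, 300) + runif(3, 5, 120))
    w <- window_bouts(bouts, 30)
    expect_lte(sum(w$end - w$start), sum(bouts$end - bouts$start))
  }
})
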