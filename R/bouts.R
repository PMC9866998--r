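# Rolling helpers. Centered moving average with edge padding so masks have
# full length; rolling SD via the moment identity.

roll_mean <- function(x, n) {
  n <- max(1L, as.integer(n))
  if (n %% 2L == 0L) n <- n + 1L
  half <- (n - 1L) %/% 2L
  xp <- c(rep(x[1L], half), x, rep(x[length(x)], half))
  as.numeric(stats::filter(xp, rep(1 / n, n), sides = 2))[half + seq_along(x)]
}

roll_sd <- function(x, n) {
  m1 <- roll_mean(x, n)
  m2 <- roll_mean(x^2, n)
  sqrt(pmax(m2 - m1^2, 0))
}

#' Posture and movement masks
#'
#' `upright_mask()` is TRUE where the low-pass component of the nominally
#' vertical axis exceeds `cos(tilt_max_deg) * g`, i.e. the device is tilted
#' less than `tilt_max_deg` from vertical. `movement_mask()` is TRUE where
#' the sliding-window SD of the (pre-smoothed) acceleration magnitude
#' exceeds `sd_thresh`; it is monotone non-increasing in `sd_thresh`.
#'
#' @param rec An [accel_recording()].
#' @param cfg A [gait_config()].
#' @param win_s Sliding-SD window (s); defaults to `cfg$move_win_s`.
#' @param sd_thresh Movement threshold (m/s^2); defaults to
#'   `cfg$move_sd_thresh`.
#' @return A logical vector, one element per sample.
#' @export
upright_mask <- function(rec, cfg = gait_config(), win_s = NULL) {
  rec <- convert_units(rec, "m_per_s2")
  win_s <- win_s %||% (1 / cfg$upright_lowpass_hz)
  if (recording_duration(rec) < win_s) {
    abort("recording shorter than the mask window",
          class = "freegait_input_error")
  }
  lp <- roll_mean(rec$az, round(win_s * recording_fs(rec)))
  lp > cos(cfg$tilt_max_deg * pi / 180) * STANDARD_GRAVITY
}

#' @rdname upright_mask
#' @export
movement_mask <- function(rec, cfg = gait_config(), win_s = NULL,
                          sd_thresh = NULL) {
  rec <- convert_units(rec, "m_per_s2")
  win_s <- win_s %||% cfg$move_win_s
  sd_thresh <- sd_thresh %||% cfg$move_sd_thresh
  if (recording_duration(rec) < win_s) {
    abort("recording shorter than the mask window",
          class = "freegait_input_error")
  }
  fs <- recording_fs(rec)
  mag <- sqrt(rec$ax^2 + rec$ay^2 + rec$az^2)
  mag <- roll_mean(mag, max(1L, round(cfg$move_smooth_s * fs)))
  roll_sd(mag, round(win_s * fs)) > sd_thresh
}

# Maximal TRUE runs of a mask as (start, end) times, half-open on the grid.
mask_runs <- function(mask, time, fs) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  tibble(start = time[starts[keep]], end = time[ends[keep]] + 1 / fs)
}

#' Extract walking bouts
#'
#' Walking bouts are maximal runs that are simultaneously upright and
#' moving; runs separated by gaps of at most `gap_merge_s` are merged, runs
#' shorter than `min_bout_s` are dropped, and each surviving candidate is
#' confirmed by running event detection on it and requiring at least
#' `min_ic_per_bout` initial contacts.
#'
#' @param rec An [accel_recording()].
#' @param cfg A [gait_config()].
#' @return A `walking_bouts` tibble with columns `bout_id`, `start`, `end`
#'   (s, half-open, sorted, non-overlapping).
#' @export
#' @examples
#' sim <- simulate_walk(sim_params(duration_s = 15, noise_sd = 0))
#' extract_walking_bouts(sim$recording)
extract_walking_bouts <- function(rec, cfg = gait_config()) {
  rec <- convert_units(rec, "m_per_s2")
  mask <- upright_mask(rec, cfg) & movement_mask(rec, cfg)
  runs <- mask_runs(mask, rec$time, recording_fs(rec))
  empty <- tibble(bout_id = integer(0), start = numeric(0), end = numeric(0))
  if (nrow(runs) == 0L) return(new_walking_bouts(empty))
  # merge gaps <= gap_merge_s
  merged <- runs[1, , drop = FALSE]
  for (i in seq_len(nrow(runs))[-1]) {
    if (runs$start[i] - merged$end[nrow(merged)] <= cfg$gap_merge_s) {
      merged$end[nrow(merged)] <- runs$end[i]
    } else {
      merged <- dplyr::bind_rows(merged, runs[i, ])
    }
  }
  merged <- merged[merged$end - merged$start >= cfg$min_bout_s, ,
                   drop = FALSE]
  if (nrow(merged) == 0L) return(new_walking_bouts(empty))
  confirmed <- purrr::map_lgl(seq_len(nrow(merged)), function(i) {
    ic <- tryCatch({
      v <- vertical_component(rec, bout = merged[i, ], cfg = cfg)
      detect_ic(cwt_chain(v, cfg), cfg)
    }, error = function(e) numeric(0))
    length(ic) >= cfg$min_ic_per_bout
  })
  out <- merged[confirmed, , drop = FALSE]
  out$bout_id <- seq_len(nrow(out))
  new_walking_bouts(out[, c("bout_id", "start", "end")])
}

new_walking_bouts <- function(x) {
  class(x) <- c("walking_bouts", class(tibble()))
  x
}

#' Tile bouts into fixed-length analysis windows
#'
#' Consecutive non-overlapping windows of `window_s` from each bout's start;
#' a tail shorter than `window_s` is discarded.
#'
#' @param bouts A `walking_bouts` tibble.
#' @param window_s Window length (s).
#' @return An `analysis_windows` tibble with columns `window_id`, `bout_id`,
#'   `start`, `end`.
#' @export
window_bouts <- function(bouts, window_s = 30) {
  stopifnot(window_s > 0)
  rows <- purrr::map(seq_len(nrow(bouts)), function(i) {
    k <- floor((bouts$end[i] - bouts$start[i]) / window_s + 1e-9)
    if (k < 1) return(NULL)
    tibble(bout_id = bouts$bout_id[i],
           start = bouts$start[i] + (seq_len(k) - 1) * window_s,
           end = bouts$start[i] + seq_len(k) * window_s)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble(bout_id = integer(0), start = numeric(0), end = numeric(0))
  }
  out <- dplyr::mutate(out, window_id = dplyr::row_number(),
                       .before = "bout_id")
  class(out) <- c("analysis_windows", class(tibble()))
  out
}
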