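#' Pipeline configuration
#'
#' Collects every tunable parameter of the bout -> event -> characteristic
#' pipeline in one validated list. All defaults are stated in the units of the
#' field: seconds, metres, Hz, m/s^2. The configuration round-trips through
#' JSON unchanged, so a run can always be reproduced from its serialized
#' config snapshot.
#'
#' @param fs_expected Nominal sampling frequency (Hz).
#' @param window_s Analysis window length (s). Windows tile each walking bout
#'   from its start; a tail shorter than `window_s` is discarded.
#' @param leg_length_m Pendulum length: sensor (approximately centre of mass)
#'   height, used by the inverted-pendulum step-length model.
#' @param scale_policy Wavelet scale policy: `"auto"` matches the wavelet
#'   centre frequency to the dominant spectral peak of the integrated vertical
#'   acceleration in 0.5--3 Hz; a positive number fixes the centre frequency
#'   (Hz) directly.
#' @param tilt_max_deg Maximum tilt from vertical (degrees) for a sample to
#'   count as upright.
#' @param upright_lowpass_hz Cut-off of the low-pass applied to the vertical
#'   axis before the tilt test.
#' @param move_sd_thresh Movement threshold: sliding SD of the (pre-smoothed)
#'   acceleration magnitude above this (m/s^2) counts as moving.
#' @param move_win_s Sliding-SD window (s) for the movement mask.
#' @param move_smooth_s Moving-average pre-smoothing (s) applied to the
#'   acceleration magnitude before the sliding SD, so white sensor noise does
#'   not masquerade as movement.
#' @param gap_merge_s Candidate bouts separated by gaps at most this long (s)
#'   are merged.
#' @param min_bout_s Minimum retained bout duration (s).
#' @param min_ic_per_bout Minimum number of alternating initial contacts event
#'   detection must find for a candidate bout to be confirmed as walking.
#' @param edge_trim_s Signal edge (s) excluded from event detection, where the
#'   wavelet response is unreliable.
#' @param min_ic_separation_s Minimum separation (s) between detected events.
#' @param prominence_frac Minimum peak prominence as a fraction of the robust
#'   signal amplitude.
#' @param pair_lo,pair_hi An initial contact is matched to the first final
#'   contact between `pair_lo * T` and `pair_hi * T` later, `T` the median
#'   inter-IC interval.
#' @param first_side Side label assigned to the first detected step; a single
#'   lumbar sensor cannot observe laterality, so sides are assigned by
#'   alternation from this (asymmetry is invariant to the choice).
#' @param min_steps_per_window Windows with fewer steps are dropped.
#' @param sd_mode `"sample"` (n-1 denominator, default) or `"population"` for
#'   the variability characteristics.
#' @param anomaly_k Robust-z threshold for step anomaly flagging
#'   (median/MAD rule).
#' @param min_steps_anomaly Minimum steps required before anomaly flagging.
#' @param sync_offset_s Constant offset (s) added to manifest timestamps to
#'   align the sensor clock with an external video timeline.
#'
#' @return An object of class `gait_config` (a named list).
#' @export
#' @examples
#' cfg <- gait_config(leg_length_m = 0.95)
#' cfg$window_s
gait_config <- function(fs_expected = 100,
                        window_s = 30,
                        leg_length_m = 0.9,
                        scale_policy = "auto",
                        tilt_max_deg = 45,
                        upright_lowpass_hz = 0.5,
                        move_sd_thresh = 0.1,
                        move_win_s = 1,
                        move_smooth_s = 0.25,
                        gap_merge_s = 2,
                        min_bout_s = 10,
                        min_ic_per_bout = 4,
                        edge_trim_s = 0.5,
                        min_ic_separation_s = 0.25,
                        prominence_frac = 0.2,
                        pair_lo = 0.1,
                        pair_hi = 0.9,
                        first_side = "L",
                        min_steps_per_window = 10,
                        sd_mode = "sample",
                        anomaly_k = 3,
                        min_steps_anomaly = 10,
                        sync_offset_s = 0) {
  cfg <- list(
    fs_expected = fs_expected, window_s = window_s,
    leg_length_m = leg_length_m, scale_policy = scale_policy,
    tilt_max_deg = tilt_max_deg, upright_lowpass_hz = upright_lowpass_hz,
    move_sd_thresh = move_sd_thresh, move_win_s = move_win_s,
    move_smooth_s = move_smooth_s, gap_merge_s = gap_merge_s,
    min_bout_s = min_bout_s, min_ic_per_bout = min_ic_per_bout,
    edge_trim_s = edge_trim_s, min_ic_separation_s = min_ic_separation_s,
    prominence_frac = prominence_frac, pair_lo = pair_lo, pair_hi = pair_hi,
    first_side = first_side, min_steps_per_window = min_steps_per_window,
    sd_mode = sd_mode, anomaly_k = anomaly_k,
    min_steps_anomaly = min_steps_anomaly, sync_offset_s = sync_offset_s
  )
  validate_gait_config(structure(cfg, class = "gait_config"))
}

validate_gait_config <- function(cfg) {
  num_pos <- c(
    "fs_expected", "window_s", "leg_length_m", "tilt_max_deg",
    "upright_lowpass_hz", "move_sd_thresh", "move_win_s", "move_smooth_s",
    "min_bout_s", "min_ic_per_bout", "edge_trim_s", "min_ic_separation_s",
    "prominence_frac", "anomaly_k", "min_steps_per_window",
    "min_steps_anomaly"
  )
  for (f in num_pos) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      abort(sprintf("config field `%s` must be a positive number", f),
            class = "freegait_config_error")
    }
  }
  if (!is.numeric(cfg$gap_merge_s) || cfg$gap_merge_s < 0) {
    abort("config field `gap_merge_s` must be >= 0",
          class = "freegait_config_error")
  }
  if (!(is.numeric(cfg$scale_policy) && cfg$scale_policy > 0) &&
      !identical(cfg$scale_policy, "auto")) {
    abort("`scale_policy` must be \"auto\" or a positive centre frequency",
          class = "freegait_config_error")
  }
  if (!cfg$first_side %in% c("L", "R")) {
    abort("`first_side` must be \"L\" or \"R\"",
          class = "freegait_config_error")
  }
  if (!cfg$sd_mode %in% c("sample", "population")) {
    abort("`sd_mode` must be \"sample\" or \"population\"",
          class = "freegait_config_error")
  }
  if (!(cfg$pair_lo > 0 && cfg$pair_hi < 1 && cfg$pair_lo < cfg$pair_hi)) {
    abort("pairing window must satisfy 0 < pair_lo < pair_hi < 1",
          class = "freegait_config_error")
  }
  cfg
}

#' Read / write a pipeline configuration as JSON
#'
#' @param path File path.
#' @return `read_gait_config()` returns a validated [gait_config()];
#'   `write_gait_config()` returns `path` invisibly.
#' @export
read_gait_config <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("config file not found: ", path),
          class = "freegait_io_error")
  }
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- gait_config()
  unknown <- setdiff(names(raw), names(cfg))
  if (length(unknown)) {
    abort(paste0("unknown config fields: ", paste(unknown, collapse = ", ")),
          class = "freegait_config_error")
  }
  cfg[names(raw)] <- raw
  validate_gait_config(cfg)
}

#' @rdname read_gait_config
#' @param cfg A [gait_config()].
#' @export
write_gait_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "gait_config"))
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @export
print.gait_config <- function(x, ...) {
  cat("<gait_config>\n")
  for (f in names(x)) cat(sprintf("  %-22s %s\n", f, format(x[[f]])))
  invisible(x)
}
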