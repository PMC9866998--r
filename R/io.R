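#' Construct an accelerometer recording
#'
#' A recording is a tibble with columns `time`, `ax`, `ay`, `az` (time in
#' seconds relative to recording start, uniformly sampled) and attributes
#' `fs` (Hz), `units` (`"g"` or `"m_per_s2"`) and `start_time` (UTC seconds,
#' informational). All downstream stages consume this class.
#'
#' @param time Strictly increasing time vector (s).
#' @param ax,ay,az Acceleration on the three device axes. By device
#'   convention `az` is the nominally vertical (longitudinal) axis when the
#'   sensor is worn upright at the lower back.
#' @param fs Sampling frequency (Hz).
#' @param units `"g"` or `"m_per_s2"`.
#' @param start_time Recording start (UTC seconds), default 0.
#' @return An `accel_recording` tibble.
#' @export
#' @examples
#' t <- seq(0, 1, by = 0.01)
#' rec <- accel_recording(t, 0 * t, 0 * t, rep(1, length(t)), fs = 100,
#'                        units = "g")
#' recording_fs(rec)
accel_recording <- function(time, ax, ay, az, fs, units = c("m_per_s2", "g"),
                            start_time = 0) {
  units <- match.arg(units)
  n <- length(time)
  if (n < 1L || length(ax) != n || length(ay) != n || length(az) != n) {
    abort("time, ax, ay, az must be equal-length, non-empty",
          class = "freegait_data_error")
  }
  if (!all(is.finite(time)) || !all(is.finite(ax)) || !all(is.finite(ay)) ||
      !all(is.finite(az))) {
    abort("recording contains non-finite values",
          class = "freegait_data_error")
  }
  if (n > 1L && any(diff(time) <= 0)) {
    abort("time must be strictly increasing", class = "freegait_data_error")
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    abort("fs must be a positive scalar", class = "freegait_config_error")
  }
  out <- tibble(time = as.numeric(time), ax = as.numeric(ax),
                ay = as.numeric(ay), az = as.numeric(az))
  attr(out, "fs") <- as.numeric(fs)
  attr(out, "units") <- units
  attr(out, "start_time") <- as.numeric(start_time)
  class(out) <- c("accel_recording", class(tibble()))
  out
}

#' Recording metadata accessors
#' @param rec An [accel_recording()].
#' @return Sampling frequency (Hz), unit tag, or duration (s).
#' @export
recording_fs <- function(rec) attr(rec, "fs")

#' @rdname recording_fs
#' @export
recording_units <- function(rec) attr(rec, "units")

#' @rdname recording_fs
#' @export
recording_duration <- function(rec) {
  if (nrow(rec) < 2L) return(0)
  rec$time[nrow(rec)] - rec$time[1L] + 1 / recording_fs(rec)
}

#' @export
print.accel_recording <- function(x, ...) {
  cat(sprintf("<accel_recording> %d samples @ %g Hz [%s], %.1f s\n",
              nrow(x), recording_fs(x), recording_units(x),
              recording_duration(x)))
  NextMethod()
}

#' Convert a recording between g and m/s^2
#'
#' Exact bijection with the standard-gravity factor 9.80665; converting to
#' the current unit is the identity.
#'
#' @param rec An [accel_recording()].
#' @param target `"g"` or `"m_per_s2"`.
#' @return The converted recording.
#' @export
#' @examples
#' t <- seq(0, 0.03, by = 0.01)
#' rec <- accel_recording(t, 0 * t, 0 * t, rep(1, 4), fs = 100, units = "g")
#' convert_units(rec, "m_per_s2")$az[1]  # 9.80665
convert_units <- function(rec, target = c("m_per_s2", "g")) {
  stopifnot(inherits(rec, "accel_recording"))
  target <- match.arg(target)
  cur <- recording_units(rec)
  if (!cur %in% c("g", "m_per_s2")) {
    abort(paste0("unknown unit tag: ", cur), class = "freegait_config_error")
  }
  if (cur == target) return(rec)
  k <- if (target == "m_per_s2") STANDARD_GRAVITY else 1 / STANDARD_GRAVITY
  out <- rec
  out$ax <- rec$ax * k
  out$ay <- rec$ay * k
  out$az <- rec$az * k
  attr(out, "units") <- target
  out
}

#' Read / write accelerometer CSV
#'
#' The on-disk format is a plain comma-separated file with a header row and
#' columns `time,ax,ay,az` (time in seconds). On read, timestamps must be
#' strictly increasing; the samples are placed on a uniform grid at `fs` by
#' linear interpolation, and a warning is recorded if more than 1% of grid
#' points had no sample within 1.5 nominal intervals (sensor drop-outs).
#'
#' @param path CSV file path.
#' @param units Unit tag of the stored values.
#' @param fs Sampling frequency (Hz), or `"infer"` to use the median
#'   reciprocal inter-sample interval.
#' @return An [accel_recording()].
#' @export
read_accel_csv <- function(path, units = c("m_per_s2", "g"), fs = "infer") {
  units <- match.arg(units)
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "freegait_io_error")
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("time", "ax", "ay", "az")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    abort(paste0("accelerometer CSV is missing columns: ",
                 paste(missing, collapse = ", ")),
          class = "freegait_format_error")
  }
  if (nrow(df) < 2L) {
    abort("accelerometer CSV needs at least 2 rows",
          class = "freegait_format_error")
  }
  if (any(diff(df$time) <= 0)) {
    abort("timestamps are not strictly increasing",
          class = "freegait_data_error")
  }
  dt <- diff(df$time)
  if (identical(fs, "infer")) fs <- 1 / median(dt)
  fs <- as.numeric(fs)
  grid <- seq(df$time[1L], df$time[nrow(df)], by = 1 / fs)
  gap_frac <- 1 - nrow(df) / length(grid)
  if (gap_frac > 0.01) {
    warn(sprintf(
      "%.1f%% of expected samples are missing at %g Hz; gaps filled by linear interpolation",
      100 * gap_frac, fs), class = "freegait_gap_warning")
  }
  interp <- function(y) approx(df$time, y, xout = grid)$y
  accel_recording(grid - grid[1L], interp(df$ax), interp(df$ay),
                  interp(df$az), fs = fs, units = units,
                  start_time = df$time[1L])
}

#' @rdname read_accel_csv
#' @param rec An [accel_recording()].
#' @export
write_accel_csv <- function(rec, path) {
  stopifnot(inherits(rec, "accel_recording"))
  readr::write_csv(as_tibble(rec)[, c("time", "ax", "ay", "az")], path,
                   progress = FALSE)
  invisible(path)
}

#' Construct a context track
#'
#' Interval labels (half-open `[start, end)`, seconds on the recording
#' timeline) carrying terrain, environment and task annotations, e.g. from a
#' manually coded video timeline. Intervals within one track must not
#' overlap.
#'
#' @param start,end Interval bounds (s).
#' @param terrain Free-text terrain class (e.g. `"lab"`, `"asphalt"`,
#'   `"paving"`, `"stairs_up"`, `"stairs_down"`).
#' @param environment `"indoor"` or `"outdoor"` (NA allowed).
#' @param task `"single"` or `"dual"` (NA allowed).
#' @param notes Optional free text.
#' @return A `context_track` tibble sorted by `start`.
#' @export
context_track <- function(start, end, terrain, environment = NA_character_,
                          task = NA_character_, notes = NA_character_) {
  out <- tibble(start = as.numeric(start), end = as.numeric(end),
                terrain = as.character(terrain),
                environment = as.character(environment),
                task = as.character(task), notes = as.character(notes))
  validate_context_track(out)
}

validate_context_track <- function(out) {
  if (any(!is.finite(out$start)) || any(!is.finite(out$end)) ||
      any(out$end <= out$start)) {
    abort("context labels must have finite end > start",
          class = "freegait_validation_error")
  }
  bad_env <- !is.na(out$environment) &
    !out$environment %in% c("indoor", "outdoor")
  if (any(bad_env)) {
    abort(paste0("unknown environment token(s): ",
                 paste(unique(out$environment[bad_env]), collapse = ", ")),
          class = "freegait_validation_error")
  }
  bad_task <- !is.na(out$task) & !out$task %in% c("single", "dual")
  if (any(bad_task)) {
    abort(paste0("unknown task token(s): ",
                 paste(unique(out$task[bad_task]), collapse = ", ")),
          class = "freegait_validation_error")
  }
  out <- out[order(out$start), , drop = FALSE]
  if (nrow(out) > 1L) {
    overlap <- which(out$start[-1L] < out$end[-nrow(out)])
    if (length(overlap)) {
      abort(paste0(
        "overlapping context intervals at rows (sorted by start): ",
        paste(sprintf("%d/%d", overlap, overlap + 1L), collapse = ", ")),
        class = "freegait_validation_error")
    }
  }
  class(out) <- c("context_track", class(tibble()))
  out
}

#' Read / write context labels as CSV
#'
#' Columns: `start,end,terrain,environment,task` (optionally `notes`).
#' Overlapping intervals or unknown environment/task tokens are rejected.
#'
#' @param path CSV file path.
#' @return A `context_track` tibble.
#' @export
read_context_csv <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "freegait_io_error")
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("start", "end", "terrain", "environment", "task")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    abort(paste0("context CSV is missing columns: ",
                 paste(missing, collapse = ", ")),
          class = "freegait_format_error")
  }
  context_track(df$start, df$end, df$terrain, df$environment, df$task,
                if ("notes" %in% names(df)) df$notes else NA_character_)
}

#' @rdname read_context_csv
#' @param track A `context_track`.
#' @export
write_context_csv <- function(track, path) {
  readr::write_csv(as_tibble(track), path, progress = FALSE)
  invisible(path)
}

#' Write a per-step table as CSV
#'
#' Column order: `ic_time,side,step_time,stance_time,swing_time,step_length,
#' step_velocity`.
#'
#' @param tbl A step table (see [temporal_characteristics()]).
#' @param path CSV file path.
#' @export
write_step_csv <- function(tbl, path) {
  cols <- c("ic_time", "side", GAIT_CHARACTERISTICS)
  readr::write_csv(as_tibble(tbl)[, intersect(cols, names(tbl))], path,
                   progress = FALSE)
  invisible(path)
}
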