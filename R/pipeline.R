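#' Analyse a recording end to end
#'
#' Full signal chain: walking-bout extraction, per-bout CWT event detection,
#' per-step temporal and inverted-pendulum spatial characteristics, 30 s
#' window summaries, four-domain stratification, anomaly flagging, and (when
#' a context track is supplied) context alignment, stratified summaries and
#' a review manifest. Anomalies are scored against the whole recording's
#' median/MAD so atypical terrain stands out from the participant's habitual
#' gait.
#'
#' @param rec An [accel_recording()].
#' @param context Optional `context_track`.
#' @param cfg A [gait_config()].
#' @return A `gait_analysis` object: list with `bouts`, `windows`, `events`
#'   (per-bout `gait_events`), `steps` (pooled `step_table` with `bout_id`),
#'   `window_summary`, `domain_table`, `anomalies`, `contextual`,
#'   `context_summary`, `manifest`, `config`, `counts`.
#' @export
#' @examples
#' sim <- simulate_walk(sim_params(duration_s = 35, seed = 7))
#' an <- analyze_gait(sim$recording)
#' glance(an)
analyze_gait <- function(rec, context = NULL, cfg = gait_config()) {
  rec <- convert_units(rec, "m_per_s2")
  bouts <- extract_walking_bouts(rec, cfg)
  windows <- window_bouts(bouts, cfg$window_s)
  events <- list()
  steps <- list()
  for (i in seq_len(nrow(bouts))) {
    b <- bouts[i, ]
    v <- vertical_component(rec, bout = b, cfg = cfg)
    ev <- detect_gait_events(rec, bout = b, cfg = cfg)
    events[[i]] <- ev
    if (nrow(ev) >= 2L) {
      st <- step_characteristics(ev, v, cfg)
      st$bout_id <- b$bout_id
      steps[[i]] <- st
    }
  }
  steps <- if (length(steps)) new_step_table(dplyr::bind_rows(steps)) else {
    new_step_table(tibble(ic_time = numeric(0), side = character(0),
                          step_time = numeric(0), stance_time = numeric(0),
                          swing_time = numeric(0), step_length = numeric(0),
                          step_velocity = numeric(0),
                          bout_id = integer(0)))
  }
  ws <- summarize_windows(steps, windows, cfg)
  anomalies <- flag_anomalies(steps, cfg)
  cws <- align_context(ws, context)
  ctx_summary <- if (nrow(cws) > 0L) contextual_summary(cws) else NULL
  manifest <- review_manifest(cws, anomalies, top_n = 10, cfg = cfg)
  counts <- list(
    n_samples = nrow(rec),
    n_bouts = nrow(bouts),
    n_windows = nrow(windows),
    n_windows_retained = nrow(ws),
    n_windows_dropped = nrow(attr(ws, "dropped") %||% tibble()),
    n_events = sum(purrr::map_int(events, nrow)),
    n_unmatched_ic = sum(purrr::map_int(events,
                                        ~ attr(.x, "n_unmatched_ic") %||% 0L)),
    n_unmatched_fc = sum(purrr::map_int(events,
                                        ~ attr(.x, "n_unmatched_fc") %||% 0L)),
    n_steps = nrow(steps),
    n_anomalies = nrow(anomalies)
  )
  structure(list(bouts = bouts, windows = windows, events = events,
                 steps = steps, window_summary = ws,
                 domain_table = stratify_domains(ws), anomalies = anomalies,
                 contextual = cws, context_summary = ctx_summary,
                 manifest = manifest, config = cfg, counts = counts),
            class = "gait_analysis")
}

#' @export
print.gait_analysis <- function(x, ...) {
  cat(sprintf(
    "<gait_analysis> %d bout(s), %d window(s) (%d retained), %d steps, %d anomalous value(s)\n",
    x$counts$n_bouts, x$counts$n_windows, x$counts$n_windows_retained,
    x$counts$n_steps, x$counts$n_anomalies))
  invisible(x)
}

#' Tidy a gait analysis
#'
#' `tidy()` returns the long per-window domain table (one row per window and
#' characteristic, with context when available); `glance()` returns a
#' one-row recording-level summary.
#'
#' @param x A `gait_analysis`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy gait_analysis
#' @export
tidy.gait_analysis <- function(x, ...) {
  dt <- as_tibble(x$domain_table)
  if (nrow(x$contextual) > 0L && nrow(dt) > 0L) {
    dt <- dplyr::left_join(
      dt, dplyr::select(as_tibble(x$contextual), "window_id", "terrain",
                        "environment", "task"), by = "window_id")
  }
  dt
}

#' @rdname tidy.gait_analysis
#' @method glance gait_analysis
#' @export
glance.gait_analysis <- function(x, ...) {
  tibble(
    n_bouts = x$counts$n_bouts,
    n_windows = x$counts$n_windows_retained,
    n_steps = x$counts$n_steps,
    n_anomalies = x$counts$n_anomalies,
    mean_step_time = if (nrow(x$steps)) mean(x$steps$step_time, na.rm = TRUE)
                     else NA_real_,
    mean_step_length = if (nrow(x$steps))
      mean(x$steps$step_length, na.rm = TRUE) else NA_real_,
    mean_step_velocity = if (nrow(x$steps))
      mean(x$steps$step_velocity, na.rm = TRUE) else NA_real_
  )
}

#' Run the pipeline from files to an output directory
#'
#' Reads an accelerometer CSV (and optionally a context CSV and JSON
#' config), runs [analyze_gait()], and writes: `step_table.csv`,
#' `window_summary.csv`, `domain_table.csv`, `bouts.csv`,
#' `review_manifest.csv` + `.json`, `contextual_summary.csv` (when context
#' given), and `run_record.json` (config snapshot, package version, input
#' checksums, per-stage counts, warnings). On failure partial outputs are
#' removed and the run record retains the failure reason; reruns with
#' identical inputs and config reproduce identical outputs.
#'
#' @param accel_path Accelerometer CSV path.
#' @param context_path Optional context CSV path.
#' @param config_path Optional config JSON path.
#' @param out_dir Output directory (created if needed).
#' @param units Units of the accelerometer CSV.
#' @return The `gait_analysis`, invisibly.
#' @export
run_gait_pipeline <- function(accel_path, context_path = NULL,
                              config_path = NULL, out_dir,
                              units = "m_per_s2") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- if (is.null(config_path)) gait_config() else
    read_gait_config(config_path)
  checksums <- as.list(tools::md5sum(c(accel_path, context_path,
                                       config_path)))
  warnings <- character(0)
  record <- list(package_version = as.character(utils::packageVersion("freegait")),
                 config = unclass(cfg), input_md5 = checksums)
  outputs <- character(0)
  res <- withCallingHandlers(
    tryCatch({
      rec <- read_accel_csv(accel_path, units = units, fs = cfg$fs_expected)
      context <- if (!is.null(context_path)) read_context_csv(context_path)
      an <- analyze_gait(rec, context = context, cfg = cfg)
      emit <- function(df, name) {
        p <- file.path(out_dir, name)
        readr::write_csv(as_tibble(df), p, progress = FALSE)
        outputs <<- c(outputs, p)
      }
      emit(an$steps, "step_table.csv")
      emit(an$window_summary, "window_summary.csv")
      emit(an$domain_table, "domain_table.csv")
      emit(an$bouts, "bouts.csv")
      emit(an$manifest, "review_manifest.csv")
      jsonlite::write_json(an$manifest,
                           file.path(out_dir, "review_manifest.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      if (!is.null(context)) emit(an$context_summary,
                                  "contextual_summary.csv")
      record$counts <- an$counts
      record$status <- "ok"
      an
    }, error = function(e) {
      unlink(outputs)
      record$status <<- "failed"
      record$failure_reason <<- conditionMessage(e)
      e
    }),
    warning = function(w) {
      warnings <<- c(warnings, conditionMessage(w))
      record$warnings <<- warnings
      invokeRestart("muffleWarning")
    }
  )
  jsonlite::write_json(record, file.path(out_dir, "run_record.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  if (inherits(res, "error")) stop(res)
  invisible(res)
}

#' Write a simulated dataset to disk
#'
#' Writes the accelerometer CSV, ground-truth JSON and context CSV for a
#' simulated schedule, fully determined by the seed in `params`.
#'
#' @param params A [sim_params()].
#' @param out_dir Output directory.
#' @param schedule Optional activity schedule (see [simulate_recording()]);
#'   default is a single walk with standing margins.
#' @return Paths of the written files, invisibly.
#' @export
simulate_dataset <- function(params, out_dir, schedule = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(schedule)) {
    sim <- simulate_walk(params)
    context <- context_track(c(0, sim$truth$walk_start, sim$truth$walk_end),
                             c(sim$truth$walk_start, sim$truth$walk_end,
                               recording_duration(sim$recording)),
                             c("stand", "walk", "stand"))
  } else {
    sim <- simulate_recording(schedule, params)
    context <- sim$context
  }
  paths <- c(accel = file.path(out_dir, "accel.csv"),
             truth = file.path(out_dir, "ground_truth.json"),
             context = file.path(out_dir, "context.csv"))
  write_accel_csv(sim$recording, paths[["accel"]])
  truth <- sim$truth
  truth$steps <- as.data.frame(truth$steps)
  jsonlite::write_json(unclass(truth), paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  write_context_csv(context, paths[["context"]])
  invisible(paths)
}
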