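# Canonical terrain ordering for stratified tables (study-circuit order);
# unrecognised terrains follow alphabetically, "unknown" always last.
TERRAIN_ORDER <- c("lab", "asphalt", "asphalt_paving", "paving",
                   "stairs_up", "stairs_down")

order_terrains <- function(x) {
  known <- TERRAIN_ORDER[TERRAIN_ORDER %in% x]
  rest <- sort(setdiff(x, c(known, "unknown")))
  c(known, rest, intersect("unknown", x))
}

#' Attach context labels to analysis windows
#'
#' Each window receives the label with the largest temporal overlap
#' (half-open intervals); ties are broken deterministically in favour of the
#' later-starting label. `coverage` is the winning overlap divided by the
#' window length; windows covered less than half are labelled `"unknown"`.
#' Every window receives exactly one label.
#'
#' @param windows A `window_summary` (or `analysis_windows`) tibble with
#'   `start`/`end` columns.
#' @param track A `context_track`, or `NULL` (all windows `"unknown"`).
#' @return The input with `terrain`, `environment`, `task`, `coverage`
#'   columns appended (class `contextual_windows`).
#' @export
align_context <- function(windows, track = NULL) {
  n <- nrow(windows)
  terrain <- rep("unknown", n)
  environment <- rep(NA_character_, n)
  task <- rep(NA_character_, n)
  coverage <- rep(0, n)
  if (!is.null(track) && nrow(track) > 0L) {
    for (i in seq_len(n)) {
      ov <- pmin(windows$end[i], track$end) - pmax(windows$start[i],
                                                   track$start)
      ov[ov < 0] <- 0
      if (all(ov <= 0)) next
      best <- max(ov)
      j <- max(which(ov == best))  # later-starting label wins ties
      cov <- best / (windows$end[i] - windows$start[i])
      coverage[i] <- cov
      if (cov >= 0.5) {
        terrain[i] <- track$terrain[j]
        environment[i] <- track$environment[j]
        task[i] <- track$task[j]
      }
    }
  }
  out <- dplyr::mutate(as_tibble(windows), terrain = terrain,
                       environment = environment, task = task,
                       coverage = coverage)
  class(out) <- c("contextual_windows", class(tibble()))
  out
}

#' Context-stratified characteristic summary
#'
#' Averages every window-level statistic across the windows of each
#' terrain. Terrains are ordered lab first, then outdoor level surfaces,
#' then stairs; unrecognised labels follow and `"unknown"` comes last.
#'
#' @param cws A `contextual_windows` tibble from [align_context()].
#' @return A tibble, one row per terrain, with `n_windows` and the averaged
#'   statistics.
#' @export
contextual_summary <- function(cws) {
  stopifnot(nrow(cws) >= 1L)
  stat_cols <- grep("^(mean|sd|asy)_", names(cws), value = TRUE)
  out <- dplyr::summarise(
    dplyr::group_by(as_tibble(cws), .data$terrain),
    n_windows = dplyr::n(),
    dplyr::across(dplyr::all_of(stat_cols), ~ mean(.x, na.rm = TRUE)),
    .groups = "drop"
  )
  out[match(order_terrains(out$terrain), out$terrain), , drop = FALSE]
}

#' Review manifest of anomalous windows
#'
#' Ranks windows by anomaly count, then by maximal anomaly score, ties
#' broken by start time, and emits the top `top_n` with human-readable
#' reasons and video-timeline timestamps (`sync_offset_s` applied). Windows
#' without anomalies are omitted; an empty manifest is valid.
#'
#' @param cws A `contextual_windows` tibble.
#' @param anomalies Output of [flag_anomalies()] for the same recording.
#' @param top_n Maximum rows to emit.
#' @param cfg A [gait_config()] (for `sync_offset_s`).
#' @return A tibble `start_s`, `end_s`, `reason`, `terrain`, `environment`,
#'   `task`, `n_anomalies`, `max_score`.
#' @export
review_manifest <- function(cws, anomalies, top_n = 10,
                            cfg = gait_config()) {
  empty <- tibble(start_s = numeric(0), end_s = numeric(0),
                  reason = character(0), terrain = character(0),
                  environment = character(0), task = character(0),
                  n_anomalies = integer(0), max_score = numeric(0))
  if (nrow(cws) == 0L || nrow(anomalies) == 0L) return(empty)
  rows <- purrr::map(seq_len(nrow(cws)), function(i) {
    a <- anomalies[anomalies$ic_time >= cws$start[i] &
                     anomalies$ic_time < cws$end[i], , drop = FALSE]
    if (nrow(a) == 0L) return(NULL)
    chars <- sort(unique(a$characteristic))
    tibble(start_s = cws$start[i] + cfg$sync_offset_s,
           end_s = cws$end[i] + cfg$sync_offset_s,
           reason = sprintf("%d anomalous step value(s) in %s (max score %.1f)",
                            nrow(a), paste(chars, collapse = ", "),
                            max(a$score)),
           terrain = cws$terrain[i], environment = cws$environment[i],
           task = cws$task[i], n_anomalies = nrow(a),
           max_score = max(a$score))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) return(empty)
  out <- dplyr::arrange(out, dplyr::desc(.data$n_anomalies),
                        dplyr::desc(.data$max_score), .data$start_s)
  head(out, top_n)
}
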