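char_sd <- function(x, mode) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) return(NA_real_)
  s <- sd(x)
  if (mode == "population") s * sqrt((length(x) - 1) / length(x)) else s
}

char_asy <- function(x, side) {
  ok <- !is.na(x)
  xl <- x[ok & side == "L"]
  xr <- x[ok & side == "R"]
  if (!length(xl) || !length(xr)) return(NA_real_)
  abs(mean(xl) - mean(xr))
}

#' Summarise one analysis window
#'
#' For every characteristic (step/stance/swing time, step length, step
#' velocity) over the steps whose initial contact falls inside the window:
#' the mean, the standard deviation across all detected steps (the
#' variability), and the absolute difference between the left-step and
#' right-step means (the asymmetry, sides assigned as every other step).
#' Undefined per-step values are excluded characteristic by characteristic.
#'
#' @param tbl A `step_table`.
#' @param window A single-row window (columns `start`, `end`, optionally
#'   `window_id`, `bout_id`).
#' @param cfg A [gait_config()]; windows with fewer than
#'   `min_steps_per_window` steps return `NULL` (dropped, reason logged by
#'   the pipeline).
#' @return A one-row `window_summary` tibble (`window_id`, `bout_id`,
#'   `start`, `end`, `n_steps`, then `mean_`/`sd_`/`asy_` for each
#'   characteristic), or `NULL`.
#' @export
#' @examples
#' tbl <- tibble::tibble(
#'   ic_time = seq(0, 4, by = 1), side = rep(c("L", "R"), length.out = 5),
#'   step_time = c(0.5, 0.6, 0.5, 0.6, 0.5))
#' cfg <- gait_config(min_steps_per_window = 3)
#' s <- summarize_window(tbl, tibble::tibble(start = 0, end = 30), cfg)
#' c(s$mean_step_time, s$asy_step_time)  # 0.54, 0.10
summarize_window <- function(tbl, window, cfg = gait_config()) {
  steps <- tbl[tbl$ic_time >= window$start[1] & tbl$ic_time < window$end[1], ,
               drop = FALSE]
  if (nrow(steps) < cfg$min_steps_per_window) return(NULL)
  out <- tibble(
    window_id = if ("window_id" %in% names(window)) window$window_id[1]
                else NA_integer_,
    bout_id = if ("bout_id" %in% names(window)) window$bout_id[1]
              else NA_integer_,
    start = window$start[1], end = window$end[1], n_steps = nrow(steps)
  )
  for (ch in intersect(GAIT_CHARACTERISTICS, names(steps))) {
    x <- steps[[ch]]
    out[[paste0("mean_", ch)]] <- if (all(is.na(x))) NA_real_ else
      mean(x, na.rm = TRUE)
    out[[paste0("sd_", ch)]] <- char_sd(x, cfg$sd_mode)
    out[[paste0("asy_", ch)]] <- char_asy(x, steps$side)
  }
  class(out) <- c("window_summary", class(tibble()))
  out
}

#' Summarise all windows of a step table
#'
#' @param tbl A `step_table` (pooled across bouts is fine; windows select
#'   their own steps by `ic_time`).
#' @param windows An `analysis_windows` tibble from [window_bouts()].
#' @param cfg A [gait_config()].
#' @return A `window_summary` tibble, one row per retained window; an
#'   attribute `dropped` records windows dropped for too few steps.
#' @export
summarize_windows <- function(tbl, windows, cfg = gait_config()) {
  rows <- purrr::map(seq_len(nrow(windows)), function(i) {
    summarize_window(tbl, windows[i, ], cfg)
  })
  dropped <- windows[purrr::map_lgl(rows, is.null), , drop = FALSE]
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- summarize_window(
      new_step_table(tibble(ic_time = 0, side = "L", step_time = 1,
                            stance_time = 1, swing_time = 1, step_length = 1,
                            step_velocity = 1)),
      tibble(start = 0, end = 1), gait_config(min_steps_per_window = 1))
    out <- out[0, , drop = FALSE]
  }
  attr(out, "dropped") <- dropped
  class(out) <- c("window_summary", class(tibble()))
  out
}

# The 13-row four-domain model: which summary statistic of which
# characteristic belongs to which mobility domain.
DOMAIN_MAP <- tibble::tibble(
  domain = c("Pace", "Pace", "Rhythm", "Rhythm",
             rep("Variability", 5), rep("Asymmetry", 4)),
  characteristic = c(
    "mean_step_velocity", "mean_step_length",
    "mean_step_time", "mean_swing_time",
    paste0("sd_", GAIT_CHARACTERISTICS),
    paste0("asy_", c("step_time", "stance_time", "swing_time", "step_length"))
  )
)

#' Stratify window summaries into the four-domain model
#'
#' Maps the per-window statistics into the 13-row pace / rhythm /
#' variability / asymmetry table: pace holds mean step velocity and mean
#' step length; rhythm mean step and swing time; variability the five SDs;
#' asymmetry the four time/length asymmetries. Values are relabelled, never
#' altered, so the mapping is invertible.
#'
#' @param ws A `window_summary` tibble.
#' @return A `domain_table` tibble with columns `window_id`, `domain`,
#'   `characteristic`, `value` (13 rows per window, in domain order).
#' @export
stratify_domains <- function(ws) {
  rows <- purrr::map(seq_len(nrow(ws)), function(i) {
    tibble(window_id = ws$window_id[i],
           domain = DOMAIN_MAP$domain,
           characteristic = DOMAIN_MAP$characteristic,
           value = as.numeric(ws[i, DOMAIN_MAP$characteristic]))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble(window_id = integer(0), domain = character(0),
                  characteristic = character(0), value = numeric(0))
  }
  class(out) <- c("domain_table", class(tibble()))
  out
}

#' Flatten a domain table back to wide window summaries
#'
#' Inverse of [stratify_domains()] for the 13 mapped statistics.
#'
#' @param dt A `domain_table`.
#' @return A wide tibble, one row per window.
#' @export
flatten_domains <- function(dt) {
  tidyr::pivot_wider(dplyr::select(as_tibble(dt), -"domain"),
                     names_from = "characteristic", values_from = "value")
}

#' Flag anomalous steps
#'
#' A step is flagged on a characteristic when its robust z-score — absolute
#' deviation from the median in units of the scaled MAD (1.4826 * median
#' absolute deviation) — exceeds `k`. Constant characteristics (zero MAD)
#' produce no flags; scores are invariant to unit rescaling. Intended to
#' mark time periods worth targeted (e.g. video) review.
#'
#' @param tbl A `step_table`.
#' @param cfg A [gait_config()]; uses `anomaly_k` and `min_steps_anomaly`.
#' @return A tibble with columns `step`, `ic_time`, `characteristic`,
#'   `value`, `score`, sorted by descending score.
#' @export
flag_anomalies <- function(tbl, cfg = gait_config()) {
  empty <- tibble(step = integer(0), ic_time = numeric(0),
                  characteristic = character(0), value = numeric(0),
                  score = numeric(0))
  if (nrow(tbl) < cfg$min_steps_anomaly) return(empty)
  rows <- purrr::map(intersect(GAIT_CHARACTERISTICS, names(tbl)),
                     function(ch) {
    x <- tbl[[ch]]
    ok <- which(!is.na(x))
    if (length(ok) < cfg$min_steps_anomaly) return(NULL)
    m <- median(x[ok])
    s <- mad(x[ok])  # 1.4826-scaled by default
    if (s == 0) return(NULL)
    score <- abs(x[ok] - m) / s
    hit <- score > cfg$anomaly_k
    if (!any(hit)) return(NULL)
    tibble(step = ok[hit], ic_time = tbl$ic_time[ok[hit]],
           characteristic = ch, value = x[ok[hit]], score = score[hit])
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) return(empty)
  dplyr::arrange(out, dplyr::desc(.data$score))
}
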