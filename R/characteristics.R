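#' Temporal gait characteristics
#'
#' One row per step (the interval between consecutive initial contacts).
#' For the step starting at IC_i: `step_time = IC_{i+1} - IC_i`,
#' `stance_time = FC_i - IC_i` (the final contact paired with IC_i) and
#' `swing_time = IC_{i+2} - FC_i` (next same-side initial contact minus the
#' final contact). Components that cannot be formed are `NA`, never zero,
#' and are excluded from summaries.
#'
#' @param ev A `gait_events` tibble from [pair_events()].
#' @return A `step_table` tibble with columns `ic_time`, `side`,
#'   `step_time`, `stance_time`, `swing_time`.
#' @export
#' @examples
#' ev <- pair_events(c(0, 0.5, 1.0), numeric(0))
#' ev$fc_time <- c(0.65, 1.15, NA)  # externally matched pairs
#' temporal_characteristics(ev)
temporal_characteristics <- function(ev) {
  stopifnot(inherits(ev, "gait_events"))
  n <- nrow(ev)
  empty <- tibble(ic_time = numeric(0), side = character(0),
                  step_time = numeric(0), stance_time = numeric(0),
                  swing_time = numeric(0))
  if (n < 2L) return(new_step_table(empty))
  if (n > 1L && any(ev$side[-1L] == ev$side[-n])) {
    abort("event sides do not alternate", class = "freegait_internal_error")
  }
  i <- seq_len(n - 1L)
  step_time <- ev$ic_time[i + 1L] - ev$ic_time[i]
  stance_time <- ev$fc_time[i] - ev$ic_time[i]
  next_same <- c(ev$ic_time[-(1:2)], NA_real_, NA_real_)[i]
  swing_time <- next_same - ev$fc_time[i]
  bad_stance <- !is.na(stance_time) & stance_time <= 0
  stance_time[bad_stance] <- NA_real_
  swing_time[bad_stance | (!is.na(swing_time) & swing_time <= 0)] <- NA_real_
  new_step_table(tibble(ic_time = ev$ic_time[i], side = ev$side[i],
                        step_time = step_time, stance_time = stance_time,
                        swing_time = swing_time))
}

new_step_table <- function(x) {
  class(x) <- c("step_table", class(tibble()))
  x
}

#' Per-step vertical displacement of the centre of mass
#'
#' Doubly integrates the vertical acceleration over each step interval
#' `[IC_i, IC_{i+1}]` (cumulative trapezoid). The velocity samples at the
#' two step boundaries straddle the heel-strike impact transient and are
#' not representative of the pendular motion, so they are replaced by
#' quadratic extrapolation of the adjacent interior samples before the
#' second integration. The integration constant is fixed by the zero-mean-velocity
#' assumption: the mean vertical velocity over a step is removed, which
#' controls drift without distorting the within-step height profile. The
#' height change `h` is the range (max - min) of the resulting
#' displacement.
#'
#' @param v A `vertical_series` from [vertical_component()].
#' @param ev A `gait_events` tibble.
#' @param min_samples Steps spanning fewer samples get `NA` height.
#' @return A `com_trace` tibble with columns `ic_time`, `h` (m) and a
#'   list-column `displacement` holding each step's displacement series.
#' @export
com_vertical_displacement <- function(v, ev, min_samples = 5L) {
  stopifnot(inherits(v, "vertical_series"))
  n <- nrow(ev)
  if (n < 2L) {
    out <- tibble(ic_time = numeric(0), h = numeric(0),
                  displacement = list())
    class(out) <- c("com_trace", class(tibble()))
    return(out)
  }
  res <- purrr::map(seq_len(n - 1L), function(i) {
    sel <- v$t >= ev$ic_time[i] & v$t <= ev$ic_time[i + 1L]
    if (sum(sel) < min_samples) {
      return(list(h = NA_real_, d = numeric(0)))
    }
    tt <- v$t[sel]
    vel <- as.numeric(pracma::cumtrapz(tt, v$a_v[sel]))
    m <- length(vel)
    vel[1L] <- 3 * vel[2L] - 3 * vel[3L] + vel[4L]
    vel[m] <- 3 * vel[m - 1L] - 3 * vel[m - 2L] + vel[m - 3L]
    # integral (trapezoid) mean, so the step's net displacement is zero
    vel <- vel - pracma::trapz(tt, vel) / (tt[m] - tt[1L])
    d <- as.numeric(pracma::cumtrapz(tt, vel))
    list(h = max(d) - min(d), d = d)
  })
  out <- tibble(ic_time = ev$ic_time[seq_len(n - 1L)],
                h = purrr::map_dbl(res, "h"),
                displacement = purrr::map(res, "d"))
  class(out) <- c("com_trace", class(tibble()))
  out
}

#' Inverted-pendulum step length
#'
#' Step length from the centre-of-mass height change `h` and pendulum length
#' `l`: `2 * sqrt(2 * l * h - h^2)` — the chord of a circular arc of radius
#' `l` whose apex rises `h` above the chord. No correction factor is
#' applied. `h >= l` violates the geometry and yields `NA`.
#'
#' @param h Per-step height changes (m), e.g. `com_trace$h`.
#' @param leg_length_m Pendulum length (m).
#' @return Numeric vector of step lengths (m).
#' @export
#' @examples
#' step_lengths(0.05, leg_length_m = 0.9)  # 0.5916 m
step_lengths <- function(h, leg_length_m) {
  stopifnot(leg_length_m > 0)
  if (inherits(h, "com_trace")) h <- h$h
  bad <- !is.na(h) & (h < 0 | h >= leg_length_m)
  out <- 2 * sqrt(pmax(2 * leg_length_m * h - h^2, 0))
  out[bad] <- NA_real_
  out
}

#' Add step velocity to a step table
#'
#' `step_velocity = step_length / step_time` row by row; `NA` propagates.
#'
#' @param tbl A `step_table` with `step_length` and `step_time` columns.
#' @return The table with a `step_velocity` column.
#' @export
step_velocities <- function(tbl) {
  stopifnot(all(c("step_length", "step_time") %in% names(tbl)))
  dplyr::mutate(tbl,
                step_velocity = ifelse(!is.na(.data$step_length) &
                                         !is.na(.data$step_time) &
                                         .data$step_time > 0,
                                       .data$step_length / .data$step_time,
                                       NA_real_))
}

#' Full per-step characteristic table for one bout
#'
#' Composes [temporal_characteristics()], [com_vertical_displacement()],
#' [step_lengths()] and [step_velocities()] into the five-characteristic
#' step table.
#'
#' @param ev A `gait_events` tibble.
#' @param v The `vertical_series` the events were detected on.
#' @param cfg A [gait_config()].
#' @return A `step_table` with columns `ic_time`, `side`, `step_time`,
#'   `stance_time`, `swing_time`, `step_length`, `step_velocity`.
#' @export
step_characteristics <- function(ev, v, cfg = gait_config()) {
  tbl <- temporal_characteristics(ev)
  if (nrow(tbl) == 0L) {
    tbl$step_length <- numeric(0)
    tbl$step_velocity <- numeric(0)
    return(tbl)
  }
  trace <- com_vertical_displacement(v, ev)
  tbl$step_length <- step_lengths(trace$h, cfg$leg_length_m)
  step_velocities(tbl)
}
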