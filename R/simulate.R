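#' Simulation parameters
#'
#' Parameters of the synthetic gait generator. Defaults reproduce the
#' level-asphalt walking condition the package is benchmarked against:
#' 0.524 s mean step time with 0.045 s per-step SD and 0.562 m mean step
#' length on both sides, a 0.9 m pendulum (sensor height), and 0.3 m/s^2
#' white sensor noise.
#'
#' @param duration_s Walking duration (s).
#' @param step_time_mean_L,step_time_mean_R Mean step duration per side (s).
#' @param step_time_sd Per-step duration SD (s).
#' @param step_length_mean_L,step_length_mean_R Step length (chord of the
#'   stance arc) per side (m). Must be < 2 * `leg_length_m`.
#' @param leg_length_m Pendulum (leg) length (m).
#' @param com_excursion_m Optional override of the mean per-step peak-to-peak
#'   vertical excursion of the centre of mass (m). `NULL` (default) derives
#'   the excursion from the arc geometry, which makes the inverted-pendulum
#'   reconstruction an exact inverse; overriding rescales the vertical
#'   trajectory and deliberately breaks that identity.
#' @param noise_sd White sensor-noise SD per axis (m/s^2).
#' @param ds_s Double-support interval (s): ground-truth final contacts are
#'   placed this long after the preceding initial contact.
#' @param first_side Side of the first step, `"L"` or `"R"`.
#' @param seed Integer seed; every random draw in the generator flows from it.
#' @return A `sim_params` list.
#' @export
sim_params <- function(duration_s = 30,
                       step_time_mean_L = 0.524,
                       step_time_mean_R = 0.524,
                       step_time_sd = 0.045,
                       step_length_mean_L = 0.562,
                       step_length_mean_R = 0.562,
                       leg_length_m = 0.9,
                       com_excursion_m = NULL,
                       noise_sd = 0.3,
                       ds_s = 0.12,
                       first_side = "L",
                       seed = 1L) {
  p <- list(duration_s = duration_s,
            step_time_mean_L = step_time_mean_L,
            step_time_mean_R = step_time_mean_R,
            step_time_sd = step_time_sd,
            step_length_mean_L = step_length_mean_L,
            step_length_mean_R = step_length_mean_R,
            leg_length_m = leg_length_m,
            com_excursion_m = com_excursion_m,
            noise_sd = noise_sd, ds_s = ds_s,
            first_side = first_side, seed = as.integer(seed))
  for (f in c("duration_s", "step_time_mean_L", "step_time_mean_R",
              "step_length_mean_L", "step_length_mean_R", "leg_length_m",
              "ds_s")) {
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1L || p[[f]] <= 0) {
      abort(sprintf("sim_params field `%s` must be a positive number", f),
            class = "freegait_param_error")
    }
  }
  if (p$step_time_sd < 0 || p$noise_sd < 0) {
    abort("step_time_sd and noise_sd must be >= 0",
          class = "freegait_param_error")
  }
  if (max(p$step_length_mean_L, p$step_length_mean_R) >= 2 * p$leg_length_m) {
    abort("inverted-pendulum geometry requires step_length < 2 * leg_length",
          class = "freegait_param_error")
  }
  if (!p$first_side %in% c("L", "R")) {
    abort("first_side must be \"L\" or \"R\"", class = "freegait_param_error")
  }
  structure(p, class = "sim_params")
}

# Evaluate/restore RNG state so simulator seeds never disturb the caller's
# random stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Arc apex height for chord s and pendulum length l.
arc_height <- function(s, l) l - sqrt(l^2 - (s / 2)^2)

# Draw the step sequence (sides, durations, chords) filling duration_s.
draw_steps <- function(p) {
  mean_T <- c(L = p$step_time_mean_L, R = p$step_time_mean_R)
  mean_s <- c(L = p$step_length_mean_L, R = p$step_length_mean_R)
  sides <- character(0)
  Tk <- numeric(0)
  side <- p$first_side
  total <- 0
  repeat {
    Tn <- if (p$step_time_sd > 0) {
      max(0.5 * mean_T[[side]], rnorm(1, mean_T[[side]], p$step_time_sd))
    } else {
      mean_T[[side]]
    }
    if (total + Tn > p$duration_s + 1e-9) break
    total <- total + Tn
    sides <- c(sides, side)
    Tk <- c(Tk, Tn)
    side <- if (side == "L") "R" else "L"
  }
  tibble(side = sides, step_time = Tk, step_length = unname(mean_s[sides]))
}

# Analytic piecewise-arc vertical CoM velocity at arbitrary times.
# contacts: step boundary times (length K+1); steps: tibble from draw_steps;
# hscale: multiplicative rescaling of the height trajectory.
arc_velocity <- function(t, contacts, steps, l, hscale) {
  v <- numeric(length(t))
  K <- nrow(steps)
  if (K == 0L) return(v)
  idx <- findInterval(t, contacts, left.open = FALSE)
  inside <- idx >= 1L & idx <= K & t < contacts[K + 1L]
  if (!any(inside)) return(v)
  j <- idx[inside]
  s <- steps$step_length[j]
  Tj <- steps$step_time[j]
  u <- s * ((t[inside] - contacts[j]) / Tj) - s / 2
  v[inside] <- -u / sqrt(l^2 - u^2) * (s / Tj) * hscale
  v
}

#' Simulate a single walking bout
#'
#' Generates a tri-axial recording of one continuous walk embedded between
#' short standing margins, together with exact ground truth. The vertical
#' centre-of-mass trajectory is a chain of inverted-pendulum circular arcs
#' (radius `leg_length_m`, chord = step length) traversed at constant
#' horizontal speed; vertical acceleration is obtained by dense finite
#' differencing of the analytic vertical velocity, which places a one-sample
#' contact impulse at each initial contact (the heel-strike signature event
#' detection keys on) and makes trapezoidal double integration an almost
#' exact inverse of the constructed trajectory.
#'
#' @param params A [sim_params()].
#' @param margin_s Standing margin placed before and after the walk (s).
#' @param fs Sampling frequency (Hz).
#' @return A list with elements `recording` (an [accel_recording()] in
#'   m/s^2) and `truth` (class `gait_ground_truth`: `ic_times`, `fc_times`,
#'   `sides`, per-step tibble `steps` with true side, step time, step length
#'   and vertical excursion, and the walking interval `walk_start`/
#'   `walk_end`).
#' @export
#' @examples
#' sim <- simulate_walk(sim_params(duration_s = 10, noise_sd = 0))
#' nrow(sim$truth$steps)
simulate_walk <- function(params, margin_s = 3, fs = 100) {
  stopifnot(inherits(params, "sim_params"))
  with_seed(params$seed, {
    steps <- draw_steps(params)
    sim_assemble(params, steps, margin_s = margin_s, fs = fs)
  })
}

# Shared assembly: given the drawn steps, build the recording + truth.
# Called inside an established RNG context.
sim_assemble <- function(params, steps, margin_s, fs, lead_angle = NULL) {
  l <- params$leg_length_m
  K <- nrow(steps)
  contacts <- margin_s + cumsum(c(0, steps$step_time))
  H <- arc_height(steps$step_length, l)
  hscale <- if (is.null(params$com_excursion_m)) 1 else {
    params$com_excursion_m / mean(H)
  }
  total_s <- margin_s + params$duration_s + margin_s
  n <- round(total_s * fs)
  t <- seq_len(n) / fs - 1 / fs
  dt <- 1 / fs
  vfun <- function(tt) arc_velocity(tt, contacts, steps, l, hscale)
  a_v <- (vfun(t + dt / 2) - vfun(t - dt / 2)) / dt
  az <- STANDARD_GRAVITY + a_v
  ax <- 0.15 * a_v  # small anterior-posterior echo of the gait cycle
  ay <- numeric(n)
  if (params$noise_sd > 0) {
    ax <- ax + rnorm(n, 0, params$noise_sd)
    ay <- ay + rnorm(n, 0, params$noise_sd)
    az <- az + rnorm(n, 0, params$noise_sd)
  }
  rec <- accel_recording(t, ax, ay, az, fs = fs, units = "m_per_s2")
  # Side of contact k = side of the step it starts; the final landing (the
  # opposite foot) closes the last step.
  if (K > 0L) {
    sides_contacts <- c(steps$side, other_side(steps$side[K]))
  } else {
    sides_contacts <- character(0)
  }
  truth <- structure(list(
    ic_times = if (K > 0L) contacts else numeric(0),
    fc_times = if (K > 0L) contacts[seq_len(K)] + params$ds_s else numeric(0),
    sides = sides_contacts,
    steps = tibble(side = steps$side, step_time = steps$step_time,
                   step_length = steps$step_length, step_h = H * hscale),
    walk_start = margin_s,
    walk_end = if (K > 0L) contacts[K + 1L] else margin_s
  ), class = "gait_ground_truth")
  list(recording = rec, truth = truth)
}

other_side <- function(s) ifelse(s == "L", "R", "L")

#' Simulate a multi-activity recording
#'
#' Concatenates standing, lying and walking segments into one continuous
#' recording with ground-truth events and a context track. Orientation
#' changes (lying puts gravity on the mediolateral axis) are blended with a
#' 1 s raised-cosine taper so posture transitions carry no synthetic
#' discontinuity; walks start and end through ordinary contact impulses and
#' need no taper.
#'
#' @param schedule A data frame (or tibble) with columns `activity`
#'   (`"stand"`, `"lie"`, `"walk"`) and `duration_s`.
#' @param params A [sim_params()]; `duration_s` is taken from the schedule
#'   for each walk segment.
#' @param fs Sampling frequency (Hz).
#' @return A list `recording`, `truth` (as in [simulate_walk()], events from
#'   all walk segments pooled), and `context` (a `context_track` labelling
#'   each segment by activity).
#' @export
simulate_recording <- function(schedule, params, fs = 100) {
  stopifnot(inherits(params, "sim_params"))
  schedule <- as_tibble(schedule)
  if (nrow(schedule) == 0L) {
    abort("schedule must be non-empty", class = "freegait_param_error")
  }
  bad <- setdiff(schedule$activity, c("stand", "lie", "walk"))
  if (length(bad)) {
    abort(paste0("unknown activity token(s): ", paste(bad, collapse = ", ")),
          class = "freegait_param_error")
  }
  with_seed(params$seed, {
    seg_start <- cumsum(c(0, schedule$duration_s))[seq_len(nrow(schedule))]
    seg_end <- seg_start + schedule$duration_s
    total_s <- sum(schedule$duration_s)
    n <- round(total_s * fs)
    t <- seq_len(n) / fs - 1 / fs
    dt <- 1 / fs

    # Draw all walk segments and lay their arcs on the global timeline.
    all_contacts <- numeric(0)
    all_fc <- numeric(0)
    all_steps <- list()
    a_v <- numeric(n)
    for (i in seq_len(nrow(schedule))) {
      if (schedule$activity[i] != "walk") next
      p_i <- params
      p_i$duration_s <- schedule$duration_s[i]
      steps <- draw_steps(p_i)
      if (nrow(steps) == 0L) next
      contacts <- seg_start[i] + cumsum(c(0, steps$step_time))
      vfun <- function(tt) {
        arc_velocity(tt, contacts, steps, params$leg_length_m, 1)
      }
      a_v <- a_v + (vfun(t + dt / 2) - vfun(t - dt / 2)) / dt
      all_contacts <- c(all_contacts, contacts)
      all_fc <- c(all_fc, contacts[seq_len(nrow(steps))] + params$ds_s)
      all_steps[[length(all_steps) + 1L]] <- steps
    }
    steps_tbl <- if (length(all_steps)) dplyr::bind_rows(all_steps) else {
      tibble(side = character(0), step_time = numeric(0),
             step_length = numeric(0))
    }

    # Gravity orientation: angle 0 = upright (gravity on az), pi/2 = lying
    # (gravity on ay); 1 s raised-cosine blend at posture changes.
    ang_target <- ifelse(schedule$activity == "lie", pi / 2, 0)
    seg_idx <- findInterval(t, seg_start)
    ang <- ang_target[seg_idx]
    kern_n <- max(1L, round(1 * fs))
    kern <- 0.5 * (1 - cos(2 * pi * seq_len(kern_n) / (kern_n + 1)))
    kern <- kern / sum(kern)
    ang <- as.numeric(stats::filter(c(rep(ang[1], kern_n), ang,
                                      rep(ang[length(ang)], kern_n)),
                                    kern, sides = 2))
    ang <- ang[kern_n + seq_len(n)]

    az <- STANDARD_GRAVITY * cos(ang) + a_v
    ay <- STANDARD_GRAVITY * sin(ang)
    ax <- 0.15 * a_v
    if (params$noise_sd > 0) {
      ax <- ax + rnorm(n, 0, params$noise_sd)
      ay <- ay + rnorm(n, 0, params$noise_sd)
      az <- az + rnorm(n, 0, params$noise_sd)
    }
    rec <- accel_recording(t, ax, ay, az, fs = fs, units = "m_per_s2")
    K <- nrow(steps_tbl)
    truth <- structure(list(
      ic_times = all_contacts,
      fc_times = all_fc,
      sides = if (K > 0L) c(steps_tbl$side[1],
                            other_side(steps_tbl$side))[seq_along(all_contacts)]
              else character(0),
      steps = tibble(side = steps_tbl$side, step_time = steps_tbl$step_time,
                     step_length = steps_tbl$step_length,
                     step_h = arc_height(steps_tbl$step_length,
                                         params$leg_length_m)),
      walk_start = seg_start[schedule$activity == "walk"],
      walk_end = seg_end[schedule$activity == "walk"]
    ), class = "gait_ground_truth")
    context <- context_track(seg_start, seg_end, schedule$activity)
    list(recording = rec, truth = truth, context = context)
  })
}

#' Add white sensor noise to a recording
#'
#' Adds i.i.d. Gaussian noise independently to each axis; `noise_sd = 0` is
#' the identity.
#'
#' @param rec An [accel_recording()].
#' @param noise_sd Noise SD in the recording's units.
#' @param seed Integer seed.
#' @return The noisy recording.
#' @export
add_sensor_noise <- function(rec, noise_sd, seed = 1L) {
  stopifnot(inherits(rec, "accel_recording"))
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || noise_sd < 0) {
    abort("noise_sd must be >= 0", class = "freegait_param_error")
  }
  if (noise_sd == 0) return(rec)
  with_seed(seed, {
    n <- nrow(rec)
    out <- rec
    out$ax <- rec$ax + rnorm(n, 0, noise_sd)
    out$ay <- rec$ay + rnorm(n, 0, noise_sd)
    out$az <- rec$az + rnorm(n, 0, noise_sd)
    out
  })
}
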