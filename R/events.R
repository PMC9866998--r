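#' Construct a vertical-acceleration series
#'
#' Container for gravity-removed vertical acceleration on a uniform time
#' base; normally produced by [vertical_component()], exposed for feeding
#' synthetic signals straight into [cwt_chain()].
#'
#' @param t Strictly increasing time vector (s).
#' @param a_v Vertical acceleration (m/s^2, gravity removed).
#' @param fs Sampling frequency (Hz).
#' @return A `vertical_series` tibble.
#' @export
vertical_series <- function(t, a_v, fs) {
  stopifnot(length(t) == length(a_v), all(diff(t) > 0), fs > 0)
  out <- tibble(t = as.numeric(t), a_v = as.numeric(a_v))
  attr(out, "fs") <- as.numeric(fs)
  attr(out, "axis") <- NA_character_
  class(out) <- c("vertical_series", class(tibble()))
  out
}

#' Vertical acceleration of a bout
#'
#' Estimates the gravity-aligned axis as the axis whose bout mean is closest
#' in magnitude to 1 g (sign-corrected if the device is inverted), removes
#' gravity by subtracting the bout mean, and returns the vertical
#' acceleration in m/s^2 on a time base relative to recording start.
#'
#' @param rec An [accel_recording()].
#' @param bout Optional single-row bout (columns `start`, `end`); default is
#'   the whole recording.
#' @param cfg A [gait_config()].
#' @return A `vertical_series` tibble with columns `t`, `a_v` and attributes
#'   `fs` and `axis`.
#' @export
vertical_component <- function(rec, bout = NULL, cfg = gait_config()) {
  rec <- convert_units(rec, "m_per_s2")
  fs <- recording_fs(rec)
  if (!is.null(bout)) {
    sel <- rec$time >= bout$start[1] & rec$time < bout$end[1]
    rec <- rec[sel, , drop = FALSE]
  }
  if (nrow(rec) < 2L) {
    abort("bout contains too few samples", class = "freegait_input_error")
  }
  means <- c(ax = mean(rec$ax), ay = mean(rec$ay), az = mean(rec$az))
  axis <- names(means)[which.max(abs(means))]
  m <- means[[axis]]
  if (abs(m) < cos(30 * pi / 180) * STANDARD_GRAVITY) {
    abort("no axis within 30 degrees of gravity; device orientation invalid",
          class = "freegait_orientation_error")
  }
  a_v <- sign(m) * rec[[axis]] - abs(m)
  out <- tibble(t = rec$time, a_v = a_v)
  attr(out, "fs") <- fs
  attr(out, "axis") <- axis
  class(out) <- c("vertical_series", class(tibble()))
  out
}

# Gaussian-derivative CWT at one scale, correlation convention: the output
# is the NEGATIVE of the Gaussian-smoothed time derivative, so contact
# impulses (maxima of smoothed a_v) appear as minima of the transformed
# integrated signal. sigma is the Gaussian scale in seconds.
cwt_gauss1 <- function(x, sigma, fs) {
  half <- max(2L, ceiling(4 * sigma * fs))
  tt <- (-half:half) / fs
  g <- exp(-tt^2 / (2 * sigma^2)) / (sigma * sqrt(2 * pi))
  kern <- (tt / sigma^2) * g / fs  # = -G'(t) dt
  n <- length(x)
  xp <- c(rep(x[1L], half), x, rep(x[n], half))
  y <- as.numeric(stats::filter(xp, kern, sides = 2))
  y[half + seq_len(n)]
}

# Dominant frequency (Hz) of a signal in [lo, hi], or NA if no power there.
dominant_frequency <- function(x, fs, lo = 0.5, hi = 3) {
  x <- x - mean(x)
  if (all(x == 0)) return(NA_real_)
  sp <- stats::spec.pgram(stats::ts(x, frequency = fs), taper = 0.1,
                          plot = FALSE, detrend = TRUE)
  band <- sp$freq >= lo & sp$freq <= hi
  if (!any(band) || all(sp$spec[band] <= 0)) return(NA_real_)
  sp$freq[band][which.max(sp$spec[band])]
}

#' Gaussian-CWT signal chain
#'
#' Implements the event-detection transform: the vertical acceleration is
#' integrated (cumulative trapezoid, linearly detrended to suppress
#' integration drift), then differentiated with a Gaussian-derivative CWT;
#' the result is differentiated once more with the same wavelet. Initial
#' contacts are minima of the first transform, final contacts maxima of the
#' second. The wavelet scale is matched to the dominant spectral peak of the
#' integrated signal in 0.5--3 Hz (`scale_policy = "auto"`), falling back to
#' 2 Hz with a warning when no peak exists in the band.
#'
#' @param v A `vertical_series` from [vertical_component()].
#' @param cfg A [gait_config()].
#' @return A `cwt_signals` tibble with columns `t`, `y_int`, `d1`, `d2` and
#'   attributes `fs`, `centre_freq` (Hz) and `sigma` (s).
#' @export
cwt_chain <- function(v, cfg = gait_config()) {
  stopifnot(inherits(v, "vertical_series"))
  fs <- attr(v, "fs")
  if (nrow(v) < 4 * fs) {
    abort("need at least 4 s of signal for the CWT chain",
          class = "freegait_input_error")
  }
  y_int <- as.numeric(pracma::cumtrapz(v$t, v$a_v))
  fit <- stats::lm.fit(cbind(1, v$t), y_int)
  y_int <- y_int - as.numeric(cbind(1, v$t) %*% fit$coefficients)
  if (identical(cfg$scale_policy, "auto")) {
    f0 <- dominant_frequency(y_int, fs)
    if (is.na(f0)) {
      warn("no spectral peak in 0.5-3 Hz; falling back to 2 Hz wavelet scale",
           class = "freegait_scale_warning")
      f0 <- 2
    }
  } else {
    f0 <- as.numeric(cfg$scale_policy)
  }
  sigma <- 1 / (2 * pi * f0)
  d1 <- cwt_gauss1(y_int, sigma, fs)
  d2 <- cwt_gauss1(d1, sigma, fs)
  out <- tibble(t = v$t, y_int = y_int, d1 = d1, d2 = d2)
  attr(out, "fs") <- fs
  attr(out, "centre_freq") <- f0
  attr(out, "sigma") <- sigma
  class(out) <- c("cwt_signals", class(tibble()))
  out
}

# Robust amplitude: 95th percentile of absolute deviation from the median.
robust_amplitude <- function(x) {
  as.numeric(quantile(abs(x - median(x)), 0.95, names = FALSE))
}

# Local maxima of x with prominence >= min_prom and separation >= min_sep
# (in t units); returns times. Prominence is the classical definition:
# height above the higher of the two key saddles.
find_peaks <- function(x, t, min_prom, min_sep) {
  n <- length(x)
  if (n < 3L) return(numeric(0))
  cand <- which(diff(sign(diff(x))) < 0) + 1L
  cand <- cand[x[cand] > x[cand - 1L] & x[cand] >= x[cand + 1L]]
  if (!length(cand)) return(numeric(0))
  prom <- vapply(cand, function(i) {
    left <- x[seq_len(i - 1L)]
    higher_l <- which(left > x[i])
    lo_l <- if (length(higher_l)) {
      min(x[(max(higher_l) + 1L):(i - 1L)])
    } else min(left)
    right <- x[(i + 1L):n]
    higher_r <- which(right > x[i])
    lo_r <- if (length(higher_r)) {
      min(right[seq_len(min(higher_r) - 1L)])
    } else min(right)
    x[i] - max(lo_l, lo_r)
  }, numeric(1))
  keep <- cand[prom >= min_prom & prom > 0]
  if (!length(keep)) return(numeric(0))
  # enforce separation, strongest first
  ord <- keep[order(x[keep], decreasing = TRUE)]
  chosen <- numeric(0)
  for (i in ord) {
    if (!length(chosen) || all(abs(t[i] - chosen) >= min_sep)) {
      chosen <- c(chosen, t[i])
    }
  }
  sort(chosen)
}

#' Detect initial / final contacts
#'
#' Initial contacts are the times of the minima of the once-differentiated
#' integrated vertical acceleration (`d1`); final contacts are the maxima of
#' the twice-differentiated signal (`d2`). Extrema must clear a prominence
#' of `prominence_frac` times the robust signal amplitude, be separated by
#' at least `min_ic_separation_s`, and lie outside the `edge_trim_s` signal
#' edges.
#'
#' Initial-contact minima are located coarse-to-fine: candidate minima are
#' found at the gait scale, then each is refined to the minimum of the same
#' transform at a quarter of the scale within half the minimum event
#' separation, so the sharp contact transient is timed without the
#' neighbourhood bias of the broad wavelet.
#'
#' @param sig A `cwt_signals` from [cwt_chain()].
#' @param cfg A [gait_config()].
#' @return Numeric vector of event times (s); empty when fewer than two
#'   qualifying extrema exist.
#' @export
detect_ic <- function(sig, cfg = gait_config()) {
  coarse <- detect_extrema(-sig$d1, sig$t, cfg)
  if (!length(coarse)) return(coarse)
  d1f <- cwt_gauss1(sig$y_int, attr(sig, "sigma") / 4, attr(sig, "fs"))
  half <- cfg$min_ic_separation_s / 2
  refined <- vapply(coarse, function(t0) {
    sel <- which(sig$t >= t0 - half & sig$t <= t0 + half)
    sig$t[sel[which.min(d1f[sel])]]
  }, numeric(1))
  sort(unique(refined))
}

#' @rdname detect_ic
#' @export
detect_fc <- function(sig, cfg = gait_config()) {
  detect_extrema(sig$d2, sig$t, cfg)
}

detect_extrema <- function(x, t, cfg) {
  lo <- t[1L] + cfg$edge_trim_s
  hi <- t[length(t)] - cfg$edge_trim_s
  sel <- t >= lo & t <= hi
  if (sum(sel) < 3L) return(numeric(0))
  xs <- x[sel]
  ts <- t[sel]
  amp <- robust_amplitude(xs)
  if (amp == 0) return(numeric(0))
  out <- find_peaks(xs, ts, min_prom = cfg$prominence_frac * amp,
                    min_sep = cfg$min_ic_separation_s)
  if (length(out) < 2L) numeric(0) else out
}

#' Pair initial and final contacts into gait events
#'
#' Each initial contact is matched to the first unused final contact
#' occurring between `pair_lo * T` and `pair_hi * T` later, where `T` is the
#' median inter-IC interval; unmatched events on either side are dropped and
#' counted. Sides are assigned by strict alternation starting from
#' `cfg$first_side` (a single lumbar sensor cannot observe laterality; the
#' asymmetry characteristics are invariant to the starting choice).
#'
#' @param ic,fc Sorted event-time vectors from [detect_ic()] / [detect_fc()].
#' @param cfg A [gait_config()].
#' @param source_bout Optional bout identifier stored on the result.
#' @return A `gait_events` tibble with columns `ic_time`, `fc_time` (NA when
#'   unmatched), `side`, and attributes `n_unmatched_ic`, `n_unmatched_fc`,
#'   `low_quality` (TRUE when more than 25% of events went unmatched) and
#'   `source_bout`.
#' @export
#' @examples
#' ev <- pair_events(c(1.0, 1.5, 2.0), c(1.65, 2.15))
#' ev$fc_time  # NA, 1.65, 2.15
pair_events <- function(ic, fc, cfg = gait_config(), source_bout = NA) {
  ic <- sort(as.numeric(ic))
  fc <- sort(as.numeric(fc))
  n <- length(ic)
  fc_match <- rep(NA_real_, n)
  if (n >= 2L && length(fc)) {
    T_med <- median(diff(ic))
    used <- logical(length(fc))
    for (i in seq_len(n)) {
      ok <- which(!used & fc > ic[i] + cfg$pair_lo * T_med &
                    fc < ic[i] + cfg$pair_hi * T_med)
      if (length(ok)) {
        fc_match[i] <- fc[ok[1L]]
        used[ok[1L]] <- TRUE
      }
    }
    n_unmatched_fc <- sum(!used)
  } else {
    n_unmatched_fc <- length(fc)
  }
  sides <- rep(c(cfg$first_side, other_side(cfg$first_side)), length.out = n)
  out <- tibble(ic_time = ic, fc_time = fc_match, side = sides)
  n_un_ic <- sum(is.na(fc_match))
  attr(out, "n_unmatched_ic") <- n_un_ic
  attr(out, "n_unmatched_fc") <- n_unmatched_fc
  attr(out, "low_quality") <-
    (n + length(fc)) > 0 &&
    (n_un_ic + n_unmatched_fc) / (n + length(fc)) > 0.25
  attr(out, "source_bout") <- source_bout
  class(out) <- c("gait_events", class(tibble()))
  out
}

#' Detect gait events within a bout
#'
#' Convenience composition: [vertical_component()] -> [cwt_chain()] ->
#' [detect_ic()] / [detect_fc()] -> [pair_events()].
#'
#' @param rec An [accel_recording()].
#' @param bout Optional single-row bout (columns `start`, `end`).
#' @param cfg A [gait_config()].
#' @return A `gait_events` tibble (see [pair_events()]).
#' @export
detect_gait_events <- function(rec, bout = NULL, cfg = gait_config()) {
  v <- vertical_component(rec, bout = bout, cfg = cfg)
  sig <- cwt_chain(v, cfg)
  pair_events(detect_ic(sig, cfg), detect_fc(sig, cfg), cfg,
              source_bout = if (!is.null(bout) && "bout_id" %in% names(bout))
                bout$bout_id[1] else NA)
}
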