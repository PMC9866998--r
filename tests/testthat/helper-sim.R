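# Shared fixtures. Simulations are cheap but some are reused across tests;
# cache them once per test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, .fixtures)) assign(name, force(expr), .fixtures)
  get(name, .fixtures)
}

# The benchmark condition: noise-free 30 s walk at 0.524 s step time.
walk_0524 <- function() {
  fixture("walk_0524", simulate_walk(sim_params(
    duration_s = 30, step_time_mean_L = 0.524, step_time_mean_R = 0.524,
    step_time_sd = 0, noise_sd = 0, seed = 42)))
}

# A pure sinusoidal vertical acceleration, amplitude A, frequency f.
sine_series <- function(A = 1, f = 2, duration = 30, fs = 100) {
  t <- seq(0, duration, by = 1 / fs)
  vertical_series(t, A * sin(2 * pi * f * t), fs)
}

# Gait events with externally supplied matched FC times (bypasses pairing).
events_with_fc <- function(ic, fc, sides) {
  ev <- pair_events(ic, numeric(0))
  ev$fc_time <- fc
  ev$side <- sides
  ev
}
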