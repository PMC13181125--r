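# Shared fixtures, built in code. Sessions are kept short (a few minutes at
# 30 Hz) so the whole suite runs quickly; amplitudes are set well above the
# noise floor where a test targets the high-SNR regime.

high_snr_config <- function(n_neurons = 40, frac_tuned = 0.5,
                            duration_s = 300, seed = 7, ...) {
  sim_config(duration_s = duration_s, n_neurons = n_neurons,
             frac_tuned = frac_tuned, field_amplitude_hz = 5,
             seed = seed, ...)
}

# Full place-cell session through the preprocessing chain.
make_place_session <- function(cfg) {
  behavior <- simulate_behavior(cfg)
  sim <- simulate_place_cells(behavior, cfg)
  f_corr <- neuropil_correct(sim$traces, 0.7)
  dff <- compute_dff(f_corr, estimate_baseline(f_corr, cfg$rate_hz))
  events <- deconvolve(dff, cfg$rate_hz, cfg$decay_s)
  epochs <- detect_running_epochs(behavior)
  list(cfg = cfg, behavior = behavior, truth = sim$truth,
       traces = sim$traces, dff = dff, events = events$events,
       epochs = epochs)
}

# Deterministic constant-speed track (no pauses, no speed noise).
constant_track <- function(speed = 15, duration_s = 100, rate_hz = 30,
                           L = 150) {
  cfg <- sim_config(duration_s = duration_s, rate_hz = rate_hz,
                    track_length_cm = L, speed_mean_cm_s = speed,
                    speed_sd_cm_s = 0, pause_dwell_s = 0, seed = 1)
  simulate_behavior(cfg)
}

# Forward AR(1) synthesis: calcium trace from an event train.
ar1_forward <- function(s, gamma) {
  as.numeric(stats::filter(s, gamma, method = "recursive"))
}
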