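# Synthetic-session generator. Emulates the study conditions: a 150 cm
# circular treadmill with cues at 50 and 100 cm and reward at 0 cm, 30 Hz
# imaging, Gaussian position fields convolved with a 1.5 s exponential
# calcium kernel plus shared neuropil and Gaussian noise, a pseudo-randomized
# grating protocol (12 directions x 3 SF x 2 TF, 3 s on / 2 s gray), periodic
# widefield movies, and multinomial region-count tables.

#' Simulation configuration
#'
#' Bundles the behavioral and cellular parameters of a synthetic treadmill
#' session. Defaults reproduce the study conditions: a 15 min session at
#' 30 Hz on a 150 cm belt with cues at 50 and 100 cm, reward at 0 cm, and a
#' 1.5 s calcium decay constant.
#'
#' @param duration_s session duration (s).
#' @param rate_hz imaging sampling rate (samples/s). A volumetric acquisition
#'   preset is available via [sim_config_volumetric()].
#' @param track_length_cm belt length (cm).
#' @param cue_positions_cm positions of the tactile cues (cm).
#' @param reward_position_cm reward location (cm).
#' @param n_neurons number of simulated neurons.
#' @param frac_tuned fraction of neurons given a position field (or, for
#'   visual sessions, a grating preference), in `[0, 1]`.
#' @param field_width_cm Gaussian field width, expressed as FWHM (cm).
#' @param field_amplitude_hz event-rate amplitude at the field center
#'   (events/s) above baseline.
#' @param baseline_rate_hz position-independent event rate (events/s).
#' @param decay_s calcium indicator decay constant (s).
#' @param neuropil_gain fraction of the shared neuropil trace leaking into
#'   the cell channel, in `[0, 1)`.
#' @param noise_sd additive Gaussian noise SD in \eqn{\Delta F/F_0} units.
#' @param event_dff_amp \eqn{\Delta F/F_0} amplitude of a single deconvolved
#'   event (unitless).
#' @param speed_mean_cm_s mean running speed during run bouts (cm/s).
#' @param speed_sd_cm_s SD of the slow speed fluctuation during run bouts.
#' @param run_dwell_s mean dwell time of the running state (s); bouts are
#'   generated by a two-state (run/pause) Markov model.
#' @param pause_dwell_s mean dwell time of the paused state (s); 0 disables
#'   pausing entirely.
#' @param seed master seed for the session.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(duration_s = 900, rate_hz = 30, track_length_cm = 150,
                       cue_positions_cm = c(50, 100), reward_position_cm = 0,
                       n_neurons = 100, frac_tuned = 0.45,
                       field_width_cm = 30, field_amplitude_hz = 3,
                       baseline_rate_hz = 0.05, decay_s = 1.5,
                       neuropil_gain = 0.7, noise_sd = 0.05,
                       event_dff_amp = 0.25,
                       speed_mean_cm_s = 15, speed_sd_cm_s = 3,
                       run_dwell_s = 30, pause_dwell_s = 5, seed = 1L) {
  if (duration_s <= 0) stop_invalid("duration_s must be positive")
  if (rate_hz <= 0) stop_invalid("rate_hz must be positive")
  if (track_length_cm <= 0) stop_invalid("track_length_cm must be positive")
  if (frac_tuned < 0 || frac_tuned > 1) stop_invalid("frac_tuned must be in [0, 1]")
  if (decay_s <= 0) stop_invalid("decay_s must be positive")
  if (neuropil_gain < 0 || neuropil_gain >= 1) stop_invalid("neuropil_gain must be in [0, 1)")
  cfg <- list(duration_s = duration_s, rate_hz = rate_hz,
              track_length_cm = track_length_cm,
              cue_positions_cm = cue_positions_cm,
              reward_position_cm = reward_position_cm,
              n_neurons = n_neurons, frac_tuned = frac_tuned,
              field_width_cm = field_width_cm,
              field_amplitude_hz = field_amplitude_hz,
              baseline_rate_hz = baseline_rate_hz, decay_s = decay_s,
              neuropil_gain = neuropil_gain, noise_sd = noise_sd,
              event_dff_amp = event_dff_amp,
              speed_mean_cm_s = speed_mean_cm_s,
              speed_sd_cm_s = speed_sd_cm_s,
              run_dwell_s = run_dwell_s, pause_dwell_s = pause_dwell_s,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' Volumetric-acquisition preset
#'
#' [sim_config()] with the 7.5 Hz effective frame rate of electrically
#' tunable lens (volumetric) acquisition.
#'
#' @param ... passed to [sim_config()].
#' @export
sim_config_volumetric <- function(...) sim_config(rate_hz = 7.5, ...)

#' Simulate treadmill behavior
#'
#' Generates a time base at `rate_hz` (endpoint included, so a constant-speed
#' session covers exactly `speed * duration` cm of belt), a circular position
#' on `[0, track_length_cm)`, a non-negative speed trace with two-state
#' run/pause bouts, and a lap index that increments at every belt wrap.
#'
#' @param config a [sim_config()].
#' @return a [behavior_track()] data frame.
#' @export
simulate_behavior <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 1L))
  dt <- 1 / config$rate_hz
  t <- seq(0, config$duration_s, by = dt)
  n <- length(t)
  if (config$pause_dwell_s > 0) {
    # two-state Markov chain sampled at the frame rate
    p_stop <- min(1, dt / config$run_dwell_s)
    p_go <- min(1, dt / config$pause_dwell_s)
    running <- logical(n)
    running[1] <- TRUE
    u <- runif(n)
    for (i in 2:n) {
      running[i] <- if (running[i - 1]) u[i] > p_stop else u[i] <= p_go
    }
  } else {
    running <- rep(TRUE, n)
  }
  speed <- rep(0, n)
  if (config$speed_sd_cm_s > 0) {
    fluct <- smooth_rows_gaussian(rnorm(n, 0, config$speed_sd_cm_s),
                                  sigma = config$rate_hz)    # ~1 s smoothing
    speed[running] <- pmax(0, config$speed_mean_cm_s + fluct[running] *
                              sqrt(config$rate_hz))          # restore SD lost to smoothing
  } else {
    speed[running] <- config$speed_mean_cm_s
  }
  pos <- cumsum(c(0, speed[-n] * dt)) %% config$track_length_cm
  behavior_track(t_s = t, position_cm = pos,
                 track_length_cm = config$track_length_cm,
                 speed_cm_s = speed, rate_hz = config$rate_hz,
                 cue_positions_cm = config$cue_positions_cm,
                 reward_position_cm = config$reward_position_cm)
}

# Internal: Poisson events -> calcium signal -> two-channel fluorescence.
build_traces <- function(rate_mat, config, seed_offset) {
  set.seed(derive_seed(config$seed, seed_offset))
  n <- nrow(rate_mat)
  nt <- ncol(rate_mat)
  dt <- 1 / config$rate_hz
  gamma <- exp(-1 / (config$rate_hz * config$decay_s))
  ev <- matrix(rpois(n * nt, lambda = as.vector(rate_mat) * dt), n, nt)
  sig <- t(apply(ev, 1, function(s)
    as.numeric(stats::filter(s, gamma, method = "recursive")))) *
    config$event_dff_amp
  if (n == 1) sig <- matrix(sig, 1, nt)
  f0 <- rlnorm(n, log(100), 0.1)
  np_base <- 30
  np <- np_base * (1 + 0.5 * colMeans(sig)) +
    smooth_rows_gaussian(rnorm(nt, 0, 1), sigma = 5)
  f_np <- matrix(rep(np, each = n), n, nt)
  noise <- matrix(rnorm(n * nt), n, nt) * (config$noise_sd * f0)
  f_cell <- f0 * (1 + sig) + config$neuropil_gain * f_np + noise
  list(traces = trace_set(f_cell, f_np, config$rate_hz),
       events_true = ev, signal_true = sig)
}

#' Simulate position-tuned neurons on a behavior track
#'
#' Tuned neurons fire inhomogeneous-Poisson events at
#' `baseline_rate_hz + field_amplitude_hz * G(d)`, where `G` is a Gaussian in
#' the circular distance `d` to the field center (FWHM `field_width_cm`);
#' untuned neurons fire at the baseline rate everywhere. Events are convolved
#' with an exponential kernel `exp(-t / decay_s)` and embedded in a
#' two-channel fluorescence model: `F_cell = F0 (1 + signal) +
#' neuropil_gain * neuropil + noise`, with the shared neuropil trace returned
#' as its own channel.
#'
#' @param behavior a [behavior_track()] produced at the same `rate_hz`.
#' @param config a [sim_config()].
#' @return list with `traces` (a [trace_set()]), `truth` (per-neuron ground
#'   truth data frame) and `events_true` (the latent event-count matrix).
#' @export
simulate_place_cells <- function(behavior, config) {
  stopifnot(inherits(config, "sim_config"))
  rate_hz <- attr(behavior, "rate_hz")
  if (!isTRUE(all.equal(rate_hz, config$rate_hz)))
    stop_invalid("behavior and config sampling rates differ")
  set.seed(derive_seed(config$seed, 2L))
  n <- config$n_neurons
  n_tuned <- round(config$frac_tuned * n)
  is_tuned <- rep(FALSE, n)
  is_tuned[sample.int(n, n_tuned)] <- TRUE
  centers <- runif(n, 0, config$track_length_cm)
  centers[!is_tuned] <- NA_real_
  sigma_cm <- config$field_width_cm / (2 * sqrt(2 * log(2)))
  pos <- behavior$position_cm
  L <- config$track_length_cm
  rate <- matrix(config$baseline_rate_hz, n, length(pos))
  for (i in which(is_tuned)) {
    d <- abs(pos - centers[i])
    d <- pmin(d, L - d)
    rate[i, ] <- config$baseline_rate_hz +
      config$field_amplitude_hz * exp(-d^2 / (2 * sigma_cm^2))
  }
  built <- build_traces(rate, config, seed_offset = 3L)
  truth <- data.frame(
    neuron_id = seq_len(n),
    is_tuned = is_tuned,
    field_center_cm = centers,
    field_width_cm = ifelse(is_tuned, config$field_width_cm, NA_real_),
    peak_rate_hz = ifelse(is_tuned,
                          config$baseline_rate_hz + config$field_amplitude_hz,
                          config$baseline_rate_hz))
  list(traces = built$traces, truth = truth, events_true = built$events_true)
}

#' Simulate a drifting-grating session
#'
#' Builds a pseudo-randomized trial table (each repetition is a fresh
#' permutation of all direction x SF x TF conditions; 3 s stimulus followed
#' by 2 s gray) and simulates neurons whose event rate during the stimulus
#' follows a von Mises-like direction profile scaled by an SF/TF preference
#' gain. Ground-truth OSI/DSI are computed by applying the selectivity
#' formulas to each neuron's noiseless discrete direction curve.
#'
#' @param config a [sim_config()]; `frac_tuned` sets the fraction of
#'   grating-responsive neurons.
#' @param directions stimulus directions (deg).
#' @param sfs spatial frequencies (cycles/deg).
#' @param tfs temporal frequencies (Hz).
#' @param n_rep repetitions per condition (must be >= 2 so that reliability
#'   is defined).
#' @param kappa von Mises concentration of the direction profile.
#' @param nonpref_gain response gain for non-preferred SF/TF combinations.
#' @param dsi_range range of the null/preferred response ratio `g` sampled
#'   per neuron; `g = 0` gives DSI ~ 1.
#' @return list with `traces`, `stim` (the stimulus table), `truth`, and
#'   `events_true`.
#' @export
simulate_visual_session <- function(config,
                                    directions = seq(0, 330, by = 30),
                                    sfs = c(0.04, 0.08, 0.16),
                                    tfs = c(1, 4),
                                    n_rep = 5, kappa = 4,
                                    nonpref_gain = 0.25,
                                    dsi_range = c(0, 0.6)) {
  stopifnot(inherits(config, "sim_config"))
  if (n_rep < 2) stop_invalid("n_rep must be >= 2 (reliability undefined otherwise)")
  set.seed(derive_seed(config$seed, 4L))
  conds <- expand.grid(direction_deg = directions, sf_cpd = sfs, tf_hz = tfs,
                       KEEP.OUT.ATTRS = FALSE)
  conds <- conds[order(conds$sf_cpd, conds$tf_hz, conds$direction_deg), ]
  rownames(conds) <- NULL
  n_cond <- nrow(conds)
  order_idx <- unlist(lapply(seq_len(n_rep), function(r) sample.int(n_cond)))
  stim <- conds[order_idx, ]
  stim$repetition <- rep(seq_len(n_rep), each = n_cond)
  pre_s <- 2
  stim$onset_s <- pre_s + (seq_len(nrow(stim)) - 1) * 5
  rownames(stim) <- NULL
  duration <- pre_s + nrow(stim) * 5
  dt <- 1 / config$rate_hz
  t <- seq(0, duration, by = dt)
  nt <- length(t)

  n <- config$n_neurons
  n_resp <- round(config$frac_tuned * n)
  is_tuned <- rep(FALSE, n)
  is_tuned[sample.int(n, n_resp)] <- TRUE
  pref_dir <- sample(directions, n, replace = TRUE)
  combo <- unique(conds[, c("sf_cpd", "tf_hz")])
  pref_combo <- sample.int(nrow(combo), n, replace = TRUE)
  g_null <- runif(n, dsi_range[1], dsi_range[2])

  # discrete direction profiles (rows: neurons, cols: canonical directions)
  dir_curve <- matrix(0, n, length(directions))
  for (i in seq_len(n)) {
    dd <- (directions - pref_dir[i]) * pi / 180
    dir_curve[i, ] <- exp(kappa * (cos(dd) - 1)) +
      g_null[i] * exp(kappa * (cos(dd - pi) - 1))
  }

  rate <- matrix(config$baseline_rate_hz, n, nt)
  stim_len <- round(3 * config$rate_hz)
  dir_idx <- match(stim$direction_deg, directions)
  combo_idx <- match(paste(stim$sf_cpd, stim$tf_hz),
                     paste(combo$sf_cpd, combo$tf_hz))
  for (k in seq_len(nrow(stim))) {
    i0 <- round(stim$onset_s[k] * config$rate_hz) + 1
    idx <- i0:min(nt, i0 + stim_len - 1)
    gain <- ifelse(combo_idx[k] == pref_combo, 1, nonpref_gain)
    amp <- config$field_amplitude_hz * dir_curve[, dir_idx[k]] * gain
    amp[!is_tuned] <- 0
    rate[, idx] <- config$baseline_rate_hz + amp
  }
  built <- build_traces(rate, config, seed_offset = 5L)

  osi_true <- dsi_true <- rep(NA_real_, n)
  for (i in which(is_tuned)) {
    sel <- osi_dsi(dir_curve[i, ], directions)
    osi_true[i] <- sel$osi
    dsi_true[i] <- sel$dsi
  }
  truth <- data.frame(
    neuron_id = seq_len(n), is_tuned = is_tuned,
    preferred_direction_deg = ifelse(is_tuned, pref_dir, NA_real_),
    preferred_sf_cpd = ifelse(is_tuned, combo$sf_cpd[pref_combo], NA_real_),
    preferred_tf_hz = ifelse(is_tuned, combo$tf_hz[pref_combo], NA_real_),
    osi_true = osi_true, dsi_true = dsi_true)
  list(traces = built$traces, stim = stim, truth = truth,
       events_true = built$events_true)
}

#' Simulate a periodic-stimulus widefield movie
#'
#' Each pixel follows `baseline + amplitude * cos(2 pi f t - phase) + noise`
#' with per-pixel amplitude and phase maps, emulating trial-averaged
#' responses to a periodically sweeping stimulus.
#'
#' @param phase_map,amplitude_map numeric matrices of identical shape
#'   (pixel grid); phase in radians.
#' @param n_frames number of frames.
#' @param rate_hz frame rate (default 10, the widefield acquisition rate).
#' @param stim_freq_hz stimulus frequency; must be below Nyquist.
#' @param baseline constant offset.
#' @param noise_sd additive Gaussian noise SD.
#' @param seed optional seed.
#' @return array `n_frames x nrow x ncol` with attributes `rate_hz` and
#'   `stim_freq_hz`.
#' @export
simulate_widefield_movie <- function(phase_map, amplitude_map, n_frames,
                                     rate_hz = 10, stim_freq_hz,
                                     baseline = 1, noise_sd = 0,
                                     seed = NULL) {
  if (!all(dim(phase_map) == dim(amplitude_map)))
    stop_invalid("phase_map and amplitude_map shapes differ")
  if (stim_freq_hz >= rate_hz / 2)
    stop_invalid("stim_freq_hz is at or above Nyquist (%g Hz)", rate_hz / 2)
  if (!is.null(seed)) set.seed(seed)
  t <- (seq_len(n_frames) - 1) / rate_hz
  h <- nrow(phase_map); w <- ncol(phase_map)
  movie <- array(0, c(n_frames, h, w))
  for (j in seq_len(w)) for (i in seq_len(h)) {
    movie[, i, j] <- baseline +
      amplitude_map[i, j] * cos(2 * pi * stim_freq_hz * t - phase_map[i, j])
  }
  if (noise_sd > 0) movie <- movie + array(rnorm(length(movie), 0, noise_sd),
                                           dim(movie))
  attr(movie, "rate_hz") <- rate_hz
  attr(movie, "stim_freq_hz") <- stim_freq_hz
  movie
}

#' Simulate retrograde-labeling count tables
#'
#' Draws, for each injection target, a multinomial sample over source regions
#' with the target's fractional composition, emulating anterior/posterior
#' input biases.
#'
#' @param totals_per_target named integer vector of total labeled cells per
#'   injection target (e.g. `c(anterior = 5000, posterior = 5000)`).
#' @param bias_map named list, one named fraction vector per target; each
#'   must sum to 1 within 1e-9.
#' @param seed optional seed.
#' @return data frame with columns `region`, `target`, `count`.
#' @export
simulate_anatomy_counts <- function(totals_per_target, bias_map, seed = NULL) {
  stopifnot(!is.null(names(totals_per_target)), is.list(bias_map))
  if (!is.null(seed)) set.seed(seed)
  out <- list()
  for (tg in names(totals_per_target)) {
    p <- bias_map[[tg]]
    if (is.null(p)) stop_invalid("bias_map lacks target '%s'", tg)
    if (abs(sum(p) - 1) > 1e-9)
      stop_invalid("fractions for target '%s' sum to %.12f, not 1", tg, sum(p))
    tot <- totals_per_target[[tg]]
    cnt <- if (tot > 0) drop(rmultinom(1, tot, p)) else rep(0L, length(p))
    out[[tg]] <- data.frame(region = names(p), target = tg, count = cnt,
                            row.names = NULL)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Expand a region-count table into labeled-cell records with coordinates
#'
#' Convenience generator for topography analyses: each counted cell receives
#' jittered stereotaxic coordinates, with per-target dorsoventral offsets to
#' emulate a DV gradient of projection origin.
#'
#' @param counts data frame from [simulate_anatomy_counts()].
#' @param dv_mean named numeric, mean DV coordinate (mm) per target.
#' @param dv_sd SD of the DV jitter (mm).
#' @param seed optional seed.
#' @return data frame `cell_id, acronym, target, ap_mm, dv_mm, ml_mm`.
#' @export
simulate_labeled_cells <- function(counts, dv_mean = NULL, dv_sd = 0.3,
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- sum(counts$count)
  if (n == 0)
    return(data.frame(cell_id = integer(), acronym = character(),
                      target = character(), ap_mm = numeric(),
                      dv_mm = numeric(), ml_mm = numeric()))
  acronym <- rep(counts$region, counts$count)
  target <- rep(counts$target, counts$count)
  dv0 <- if (is.null(dv_mean)) rep(2, n) else unname(dv_mean[target])
  data.frame(cell_id = seq_len(n), acronym = acronym, target = target,
             ap_mm = rnorm(n, -2, 0.5),
             dv_mm = rnorm(n, dv0, dv_sd),
             ml_mm = rnorm(n, 1.5, 0.4))
}
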