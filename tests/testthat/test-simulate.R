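test_that("constant-speed behavior completes exactly distance/track laps", {
  b <- constant_track(speed = 15, duration_s = 100)
  expect_true(all(b$position_cm >= 0 & b$position_cm < 150))
  expect_identical(max(b$lap_id) - 1L, 10L)  # 1500 cm / 150 cm = 10 wraps
  expect_true(all(diff(b$lap_id) %in% c(0L, 1L)))
})

test_that("zero-speed behavior stays put with a single lap", {
  b <- constant_track(speed = 0, duration_s = 50)
  expect_true(all(b$position_cm == b$position_cm[1]))
  expect_identical(unique(b$lap_id), 1L)
})

test_that("seeded simulation is bit-for-bit reproducible", {
  cfg <- sim_config(duration_s = 60, n_neurons = 8, seed = 42)
  b1 <- simulate_behavior(cfg); b2 <- simulate_behavior(cfg)
  expect_identical(b1, b2)
  s1 <- simulate_place_cells(b1, cfg); s2 <- simulate_place_cells(b2, cfg)
  expect_identical(s1$traces$F_cell, s2$traces$F_cell)
  expect_identical(s1$truth, s2$truth)
  cfg2 <- sim_config(duration_s = 60, n_neurons = 8, seed = 43)
  expect_false(identical(simulate_behavior(cfg2)$position_cm, b1$position_cm))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(duration_s = 0), "duration")
  expect_error(sim_config(rate_hz = -1), "rate")
  expect_error(sim_config(frac_tuned = 1.2), "frac_tuned")
})

test_that("frac_tuned = 0 marks every neuron untuned", {
  cfg <- sim_config(duration_s = 30, n_neurons = 10, frac_tuned = 0, seed = 2)
  sim <- simulate_place_cells(simulate_behavior(cfg), cfg)
  expect_false(any(sim$truth$is_tuned))
  expect_true(all(is.na(sim$truth$field_center_cm)))
})

test_that("session event counts match the Poisson expectation", {
  cfg <- sim_config(duration_s = 200, n_neurons = 30, frac_tuned = 0,
                    baseline_rate_hz = 0.5, seed = 5)
  b <- simulate_behavior(cfg)
  sim <- simulate_place_cells(b, cfg)
  lambda <- 0.5 * 30 * (nrow(b) / cfg$rate_hz)  # total expected events
  total <- sum(sim$events_true)
  expect_lt(abs(total - lambda), 3 * sqrt(lambda))
})

test_that("a noiseless tuned neuron peaks on passes through its field", {
  cfg <- sim_config(duration_s = 120, n_neurons = 1, frac_tuned = 1,
                    field_amplitude_hz = 20, baseline_rate_hz = 0,
                    noise_sd = 0, neuropil_gain = 0, seed = 9,
                    speed_sd_cm_s = 0, pause_dwell_s = 0)
  b <- simulate_behavior(cfg)
  sim <- simulate_place_cells(b, cfg)
  center <- sim$truth$field_center_cm[1]
  ev <- sim$events_true[1, ]
  d <- abs(b$position_cm[ev > 0] - center)
  d <- pmin(d, 150 - d)
  # all events within a few field widths of the center
  expect_true(all(d < 2 * cfg$field_width_cm))
  expect_gt(sum(ev), 0)
})

test_that("grating trial tables are balanced and pseudo-randomized", {
  cfg <- sim_config(duration_s = 10, n_neurons = 4, seed = 3)
  vs <- simulate_visual_session(cfg, n_rep = 5)
  expect_identical(nrow(vs$stim), 360L)
  key <- paste(vs$stim$direction_deg, vs$stim$sf_cpd, vs$stim$tf_hz)
  expect_true(all(table(key) == 5))
  expect_true(all(diff(vs$stim$onset_s) > 0))
  # each repetition block holds every condition exactly once
  expect_true(all(table(key, vs$stim$repetition) == 1))
  vs2 <- simulate_visual_session(cfg, n_rep = 5)
  expect_identical(vs$stim, vs2$stim)
  expect_error(simulate_visual_session(cfg, n_rep = 1), "n_rep")
})

test_that("widefield movie follows the cosine construction", {
  ph <- matrix(c(0, pi / 2), 1, 2)
  am <- matrix(c(1, 2), 1, 2)
  mv <- simulate_widefield_movie(ph, am, n_frames = 40, rate_hz = 10,
                                 stim_freq_hz = 1, baseline = 3, noise_sd = 0)
  t <- (0:39) / 10
  expect_equal(mv[, 1, 1], 3 + cos(2 * pi * t), tolerance = 1e-12)
  expect_equal(mv[, 1, 2], 3 + 2 * cos(2 * pi * t - pi / 2), tolerance = 1e-12)
  mv0 <- simulate_widefield_movie(ph, 0 * am, 40, 10, 1, baseline = 3)
  expect_true(all(mv0 == 3))
  expect_error(simulate_widefield_movie(ph, am, 40, 10, stim_freq_hz = 6),
               "Nyquist")
  n1 <- simulate_widefield_movie(ph, am, 40, 10, 1, noise_sd = 0.5, seed = 1)
  n2 <- simulate_widefield_movie(ph, am, 40, 10, 1, noise_sd = 0.5, seed = 1)
  expect_identical(n1, n2)
})

test_that("multinomial anatomy counts respect totals and composition", {
  bias <- list(anterior = c(A = 0.5, B = 0.5), posterior = c(A = 0.2, B = 0.8))
  cnt <- simulate_anatomy_counts(c(anterior = 10000, posterior = 4000),
                                 bias, seed = 11)
  expect_identical(sum(cnt$count[cnt$target == "anterior"]), 10000L)
  expect_identical(sum(cnt$count[cnt$target == "posterior"]), 4000L)
  a <- cnt$count[cnt$target == "anterior" & cnt$region == "A"]
  expect_lt(abs(a - 5000), 3 * sqrt(10000 * 0.25))  # binomial SD oracle
  one <- simulate_anatomy_counts(c(anterior = 100),
                                 list(anterior = c(X = 1)), seed = 1)
  expect_identical(one$count, 100L)
  zero <- simulate_anatomy_counts(c(anterior = 0),
                                  list(anterior = c(X = 1)), seed = 1)
  expect_identical(sum(zero$count), 0L)
  expect_error(simulate_anatomy_counts(c(anterior = 10),
                                       list(anterior = c(X = 0.6, Y = 0.3))),
               "sum")
})
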