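# Build a deterministic grating session where the response during each
# trial is a known function of its condition, under an arbitrary trial order.
toy_visual <- function(order_within_rep, n_rep = 2, rate_hz = 10) {
  conds <- expand.grid(direction_deg = seq(0, 330, 30),
                       sf_cpd = c(0.04, 0.08, 0.16), tf_hz = c(1, 4))
  conds <- conds[order(conds$sf_cpd, conds$tf_hz, conds$direction_deg), ]
  n_cond <- nrow(conds)
  rows <- do.call(rbind, lapply(seq_len(n_rep), function(r) {
    o <- order_within_rep[[r]]
    cbind(conds[o, ], repetition = r)
  }))
  rows$onset_s <- 2 + (seq_len(nrow(rows)) - 1) * 5
  nt <- (2 + nrow(rows) * 5) * rate_hz + 1
  dff <- matrix(0, 1, nt)
  cond_id <- as.integer(interaction(rows$direction_deg, rows$sf_cpd,
                                    rows$tf_hz, drop = TRUE))
  for (k in seq_len(nrow(rows))) {
    i0 <- round(rows$onset_s[k] * rate_hz) + 1
    dff[1, i0:(i0 + 3 * rate_hz - 1)] <- cond_id[k] / n_cond
  }
  list(dff = dff, stim = rows, rate_hz = rate_hz)
}

test_that("de-randomization is invariant to presentation order", {
  set.seed(23)
  ordered <- toy_visual(list(1:72, 1:72))
  shuffled <- toy_visual(list(sample(72), sample(72)))
  p1 <- derandomize(ordered$dff, ordered$stim, ordered$rate_hz)
  p2 <- derandomize(shuffled$dff, shuffled$stim, shuffled$rate_hz)
  expect_equal(p1$resp, p2$resp, tolerance = 1e-12)
  expect_equal(reliability_index(p1), reliability_index(p2))
})

test_that("baseline correction subtracts the 5-frame pre-stimulus median", {
  tv <- toy_visual(list(1:72, 1:72))
  flat <- derandomize(0 * tv$dff + 3, tv$stim, tv$rate_hz)
  expect_true(all(flat$resp == 0))               # constant trace corrects to 0
  step <- derandomize(tv$dff, tv$stim, tv$rate_hz)
  # during each stimulus the corrected snippet equals the condition response
  expect_equal(drop(step$resp[1, 72, 1, ]), rep(1, 30), tolerance = 1e-12)
  # a trial too close to the trace start is dropped with a warning
  early <- tv$stim; early$onset_s[1] <- 0.1
  expect_warning(derandomize(tv$dff, early, tv$rate_hz), "dropped")
})

test_that("reliability index is the 75th percentile of pair correlations", {
  a <- array(rnorm(72 * 4 * 10), c(72, 4, 10))
  a[, 2, ] <- a[, 1, ]; a[, 3, ] <- a[, 1, ]; a[, 4, ] <- a[, 1, ]
  expect_equal(reliability_index(a), 1)
  set.seed(31)
  b <- array(rnorm(72 * 4 * 10), c(72, 4, 10))
  tc <- sapply(1:4, function(r) as.vector(t(b[, r, ])))
  rs <- cor(tc)[lower.tri(cor(tc))]
  expect_equal(reliability_index(b), quantile(rs, 0.75, names = FALSE),
               tolerance = 1e-12)
  # independent long noise repetitions decorrelate
  big <- array(rnorm(72 * 3 * 100), c(72, 3, 100))
  expect_lt(abs(reliability_index(big)), 0.1)
})

test_that("visual classification uses a strict 0.3 threshold", {
  expect_true(classify_visual(0.31))
  expect_false(classify_visual(0.3))
  expect_false(classify_visual(-0.2))
  expect_false(classify_visual(NA_real_))
})

test_that("SF/TF preference takes the direction-averaged argmax", {
  cm <- matrix(0.1, 12, 6)
  combos <- expand.grid(sf_cpd = c(0.04, 0.08, 0.16), tf_hz = c(1, 4))
  combos <- combos[order(combos$sf_cpd, combos$tf_hz), ]
  attr(cm, "combos") <- combos
  cm[, 2] <- 1  # (0.04 cpd, 4 Hz) in canonical SF-then-TF order
  pref <- sf_tf_preference(cm)
  expect_equal(pref$pref_sf_cpd, 0.04)
  expect_equal(pref$pref_tf_hz, 4)
  expect_false(pref$tie)
  cm2 <- cm; cm2[, ] <- 0.5
  attr(cm2, "combos") <- combos
  pref2 <- sf_tf_preference(cm2)
  expect_true(pref2$tie)
  expect_identical(pref2$combo_index, 1L)         # canonical-first tie-break
  expect_equal(sum(sf_tf_fractions(c(1, 1, 2, 6))), 1)
})

test_that("OSI/DSI follow their closed forms and scale invariance", {
  dirs <- seq(0, 330, 30)
  curve <- rep(0, 12); curve[1] <- 1
  sel <- osi_dsi(curve, dirs)
  expect_equal(sel$dsi, 1)                         # R_p = 1, R_null = 0
  flat <- rep(0.4, 12)
  expect_equal(osi_dsi(flat, dirs)$osi, 0)         # R_p = R_ortho
  curve2 <- rep(0, 12)
  curve2[dirs == 0] <- 1; curve2[dirs %in% c(90, 270)] <- 0.2
  curve2[dirs == 180] <- 0.5
  sel2 <- osi_dsi(curve2, dirs)
  expect_equal(sel2$osi, (1 - 0.2) / (1 + 0.2), tolerance = 1e-12)
  expect_equal(sel2$dsi, (1 - 0.5) / (1 + 0.5), tolerance = 1e-12)
  expect_equal(sel2$pref_dir_deg, 0)
  sel2s <- osi_dsi(13 * curve2, dirs)
  expect_equal(sel2s$osi, sel2$osi, tolerance = 1e-12)
  expect_equal(sel2s$dsi, sel2$dsi, tolerance = 1e-12)
  expect_true(is.na(osi_dsi(rep(0, 12), dirs)$dsi))
  expect_true(osi_dsi(curve, dirs)$direction_selective)
})

test_that("peak amplitude is the 95th percentile of trial maxima in percent", {
  expect_equal(peak_amplitude(rep(1.1, 20)), 110)
  expect_equal(peak_amplitude(0.7), 70)
  set.seed(7)
  tm <- runif(100, 0, 2)
  expect_equal(peak_amplitude(tm),
               100 * quantile(tm, 0.95, names = FALSE))
})

test_that("simulated selective neurons are recovered from traces", {
  cfg <- sim_config(duration_s = 10, n_neurons = 30, frac_tuned = 1,
                    field_amplitude_hz = 8, noise_sd = 0.03, seed = 37)
  vs <- simulate_visual_session(cfg, n_rep = 3, dsi_range = c(0, 0))
  f_corr <- neuropil_correct(vs$traces, 0.7)
  dff <- compute_dff(f_corr, estimate_baseline(f_corr, cfg$rate_hz))
  pr <- derandomize(dff, vs$stim, cfg$rate_hz)
  st <- visual_tuning_stats(pr)
  expect_gte(mean(st$is_visual), 0.9)
  # dsi_true ~ 1 by construction (g = 0): nearly all classified selective
  expect_gte(mean(st$dsi > 0.33, na.rm = TRUE), 0.95)
  expect_gte(mean(st$pref_dir_deg == vs$truth$preferred_direction_deg), 0.9)
})
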