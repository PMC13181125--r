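# Deterministic map fixture: constant-speed track with events placed at a
# chosen position bin.
bin_event_session <- function(event_bin, n_bins = 100, amp = 1) {
  b <- constant_track(speed = 15, duration_s = 200, rate_hz = 30)
  bins <- floor(b$position_cm / 150 * n_bins) + 1
  ev <- matrix(0, 1, nrow(b))
  ev[1, bins == event_bin] <- amp
  list(b = b, ev = ev)
}

test_that("tuning maps localize activity at the emitting bin", {
  s <- bin_event_session(40)
  pr <- tuning_map(s$ev, s$b, n_bins = 100, smooth_sd_bins = 3)
  expect_equal(which.max(pr$mean_map[1, ]), 40)
  far <- c(1:20, 60:100)
  expect_true(all(pr$mean_map[1, far] < 1e-6, na.rm = TRUE))
  # linearity: doubling amplitudes doubles the map
  s2 <- bin_event_session(40, amp = 2)
  pr2 <- tuning_map(s2$ev, s2$b)
  expect_equal(pr2$mean_map, 2 * pr$mean_map, tolerance = 1e-12)
})

test_that("synthetic place-cell peaks land within one bin of ground truth", {
  cfg <- sim_config(duration_s = 240, n_neurons = 12, frac_tuned = 1,
                    field_amplitude_hz = 10, baseline_rate_hz = 0,
                    noise_sd = 0, seed = 21)
  ses <- make_place_session(cfg)
  pr <- tuning_map(ses$events, ses$behavior, ses$epochs)
  peak <- pr$bin_centers_cm[max.col(ifelse(is.na(pr$mean_map), -1, pr$mean_map))]
  d <- abs(peak - ses$truth$field_center_cm)
  d <- pmin(d, 150 - d)
  expect_true(all(d <= 1.5 * pr$bin_width_cm))
})

test_that("spatial information obeys its closed forms", {
  p <- rep(0.01, 100)
  expect_equal(spatial_information(p, rep(2, 100)), 0)
  for (N in c(2, 10, 100)) {
    p <- rep(1 / N, N)
    f <- c(5, rep(0, N - 1))
    expect_equal(spatial_information(p, f), log2(N), tolerance = 1e-9)
  }
})

test_that("spatial information matches direct summation and is a KL divergence", {
  set.seed(13)
  for (k in 1:50) {
    n <- sample(5:100, 1)
    p <- runif(n); p <- p / sum(p)
    f <- runif(n) * rbinom(n, 1, 0.8)
    fbar <- sum(p * f)
    oracle <- sum(ifelse(f > 0, p * (f / fbar) * log2(f / fbar), 0))
    expect_equal(spatial_information(p, f), oracle, tolerance = 1e-12)
    expect_gte(spatial_information(p, f), 0)
    # invariant to positive scaling of activity
    expect_equal(spatial_information(p, 7.3 * f), spatial_information(p, f),
                 tolerance = 1e-12)
  }
  expect_true(is.na(spatial_information(rep(0.5, 2), c(0, 0))))
})

test_that("trial correlation is the median over all pairs", {
  m <- matrix(rep(runif(20), 3), 3, byrow = TRUE)
  expect_equal(trial_correlation(m), 1)
  x <- runif(20)
  expect_equal(trial_correlation(rbind(x, -x)), -1)
  set.seed(5)
  tmpl <- sin(seq(0, 2 * pi, length.out = 30))
  m4 <- t(replicate(4, tmpl + rnorm(30, 0, 0.3)))
  rs <- c()
  for (i in 1:3) for (j in (i + 1):4) rs <- c(rs, cor(m4[i, ], m4[j, ]))
  expect_equal(trial_correlation(m4), median(rs), tolerance = 1e-12)
})

test_that("field detection recovers the analytic 30% crossing width", {
  n_bins <- 100; bw <- 1.5
  x <- (1:n_bins - 50)
  sd_bins <- 8
  bump <- exp(-x^2 / (2 * sd_bins^2))          # flat floor at 0
  per_trial <- rbind(bump, bump, bump)
  f <- detect_fields(bump, per_trial, bw)
  expect_identical(nrow(f), 1L)
  # analytic half-width where the Gaussian crosses 0.3 of its peak
  w_analytic <- 2 * sd_bins * sqrt(2 * log(1 / 0.3)) * bw
  expect_lt(abs(f$width_cm - w_analytic), 2 * bw)
  expect_equal(f$peak_bin, 50)
  # scale invariance
  f10 <- detect_fields(10 * bump, 10 * per_trial, bw)
  expect_equal(f10$width_cm, f$width_cm)
})

test_that("field width bounds and multi-field detection are enforced", {
  n_bins <- 100; bw <- 1.5
  x <- 1:n_bins
  narrow <- exp(-(x - 50)^2 / (2 * 1.2^2))      # ~9 cm at 30% crossing
  expect_identical(nrow(detect_fields(narrow, rbind(narrow, narrow), bw)), 0L)
  two <- exp(-(x - 25)^2 / (2 * 5^2)) + exp(-(x - 75)^2 / (2 * 5^2))
  expect_identical(nrow(detect_fields(two, rbind(two, two), bw)), 2L)
  flat <- rep(1, n_bins)
  expect_identical(nrow(detect_fields(flat, rbind(flat, flat), bw)), 0L)
})

test_that("fields may straddle the 0 cm seam", {
  n_bins <- 100; bw <- 1.5
  d <- pmin(abs(1:n_bins - 1), n_bins - abs(1:n_bins - 1))
  bump <- exp(-d^2 / (2 * 6^2))
  f <- detect_fields(bump, rbind(bump, bump), bw)
  expect_identical(nrow(f), 1L)
  expect_gt(f$start_bin, f$end_bin)  # wraps across the seam
})

test_that("a field absent from most trials is rejected by the presence rule", {
  n_bins <- 100; bw <- 1.5
  bump <- exp(-((1:n_bins) - 50)^2 / (2 * 6^2))
  per_trial <- rbind(bump, 0 * bump, 0 * bump, 0 * bump)  # 1 of 4 trials
  expect_identical(nrow(detect_fields(bump, per_trial, bw)), 0L)
})

test_that("shuffle test separates tuned from position-independent neurons", {
  cfg <- high_snr_config(n_neurons = 24, frac_tuned = 0.5, duration_s = 240,
                         seed = 31)
  ses <- make_place_session(cfg)
  sh <- shuffle_test(ses$events, ses$behavior, ses$epochs, n_shuffles = 100,
                     seed = 1)
  tuned <- ses$truth$is_tuned
  expect_gte(mean(sh$significant[tuned]), 0.9)
  expect_lte(mean(sh$significant[!tuned]), 0.15)
  stats <- classify_position_tuned(sh, dff = ses$dff$dff)
  expect_true(all(c("si_bits_per_event", "width_cm", "trial_corr",
                    "peak_amp_pct") %in% names(stats)))
  expect_true(all(stats$n_fields[stats$is_tuned] >= 1))
  w <- stats$width_cm[stats$is_tuned]
  expect_true(all(w >= 15 & w <= 120))
})

test_that("shuffle test errors on sessions shorter than twice the shift", {
  cfg <- sim_config(duration_s = 30, n_neurons = 2, seed = 1)
  ses <- make_place_session(cfg)
  expect_error(shuffle_test(ses$events, ses$behavior, ses$epochs,
                            min_shift_s = 20), "shorter")
})
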