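# Session orchestration and group statistics: end-to-end synthetic or
# file-based session runs, Mann-Whitney U and two-sample KS comparisons,
# and session-level summaries.

#' Mann-Whitney U test
#'
#' Two-sided Mann-Whitney U (rank-sum) test. `U` counts pairs where `x`
#' exceeds `y` plus half-ties (so complete separation with all `x` below
#' `y` gives `U = 0`). The exact null distribution is used for small
#' samples without ties (`min(n) <= 8`); otherwise the tie-corrected
#' normal approximation.
#'
#' @param x,y numeric samples.
#' @return list with `U`, `p`, `n_x`, `n_y`.
#' @export
mannwhitney_u <- function(x, y) {
  if (length(x) < 1 || length(y) < 1) stop_invalid("empty sample")
  exact <- min(length(x), length(y)) <= 8 && !any(duplicated(c(x, y)))
  wt <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE))
  list(U = unname(wt$statistic), p = min(1, wt$p.value),
       n_x = length(x), n_y = length(y))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D` is the supremum absolute difference between the two empirical CDFs;
#' the two-sided p-value uses the asymptotic distribution.
#'
#' @param x,y numeric samples (at least 2 each).
#' @return list with `D`, `p`, `n_x`, `n_y`.
#' @export
ks_two_sample <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) stop_invalid("need >= 2 values per sample")
  kt <- suppressWarnings(ks.test(x, y, exact = FALSE))
  list(D = unname(kt$statistic), p = kt$p.value,
       n_x = length(x), n_y = length(y))
}

#' Significance stars
#'
#' `p < 0.05` maps to `*`, `p < 0.01` to `**`, `p < 0.001` to `***`,
#' otherwise `ns`.
#'
#' @param p p-values.
#' @return character vector.
#' @export
significance_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns")))
}

#' Run one synthetic session end to end
#'
#' Generates behavior and place-cell traces from a [sim_config()], runs
#' the preprocessing chain (neuropil correction with coefficient 0.7,
#' min/max baseline, dF/F0, deconvolution with the configured kernel),
#' segments running epochs, applies the shuffle test and field criteria,
#' and (optionally) decodes position with odd/even cross-validation.
#' Every random stage draws a named substream of the config seed, so a
#' config fully determines the summary.
#'
#' @param config a [sim_config()].
#' @param session_id label recorded in the summary.
#' @param subregion group label (e.g. `"anterior"` / `"posterior"`).
#' @param n_shuffles shuffle count for the position test.
#' @param run_decoding fit and evaluate the Bayesian decoder?
#' @param decode_neurons neuron count for decoding (`NULL` = all).
#' @param np_coeff neuropil coefficient used in preprocessing.
#' @return list of class `session_summary` with the per-session metrics
#'   (`frac_position_tuned`, `median_decode_error_cm`, `mean_si`,
#'   `mean_width_cm`, `mean_trial_corr`, `mean_peak_amp_pct`,
#'   `field_count_fractions`), the per-neuron `stats` table and `truth`.
#' @export
run_session <- function(config, session_id = "session", subregion = NA,
                        n_shuffles = 200, run_decoding = TRUE,
                        decode_neurons = NULL, np_coeff = 0.7) {
  behavior <- simulate_behavior(config)
  sim <- simulate_place_cells(behavior, config)
  f_corr <- neuropil_correct(sim$traces, np_coeff)
  f0 <- estimate_baseline(f_corr, config$rate_hz)
  dff <- compute_dff(f_corr, f0)
  events <- deconvolve(dff, config$rate_hz, config$decay_s)
  epochs <- detect_running_epochs(behavior)
  shuffle <- shuffle_test(events, behavior, epochs, n_shuffles = n_shuffles,
                          seed = derive_seed(config$seed, 11L))
  stats <- classify_position_tuned(shuffle, dff = dff$dff)
  tuned <- stats[stats$is_tuned, , drop = FALSE]
  nf <- tabulate(tuned$n_fields, nbins = 3)
  decode_err <- NA_real_
  if (run_decoding) {
    cv <- cross_validate_decode(events, behavior, epochs,
                                scheme = "odd_even",
                                n_neurons = decode_neurons,
                                seed = derive_seed(config$seed, 12L))
    decode_err <- cv$median_error_cm
  }
  structure(list(
    session_id = session_id, subregion = subregion,
    n_neurons = config$n_neurons,
    frac_position_tuned = mean(stats$is_tuned),
    median_decode_error_cm = decode_err,
    mean_si = mean(tuned$si_bits_per_event, na.rm = TRUE),
    mean_width_cm = mean(tuned$width_cm, na.rm = TRUE),
    mean_trial_corr = mean(tuned$trial_corr, na.rm = TRUE),
    mean_peak_amp_pct = mean(tuned$peak_amp_pct, na.rm = TRUE),
    field_count_fractions = if (nrow(tuned) > 0) nf / nrow(tuned) else rep(NA_real_, 3),
    stats = stats, truth = sim$truth, seed = config$seed),
    class = "session_summary")
}

#' Summary-row data frame from session summaries
#'
#' @param sessions list of `session_summary` objects.
#' @return data frame with one row per session.
#' @export
session_table <- function(sessions) {
  do.call(rbind, lapply(sessions, function(s) data.frame(
    session_id = s$session_id, subregion = s$subregion,
    n_neurons = s$n_neurons,
    frac_position_tuned = s$frac_position_tuned,
    median_decode_error_cm = s$median_decode_error_cm,
    mean_si = s$mean_si, mean_width_cm = s$mean_width_cm,
    mean_trial_corr = s$mean_trial_corr,
    mean_peak_amp_pct = s$mean_peak_amp_pct)))
}

#' Compare a session-level metric between two groups
#'
#' Mann-Whitney U on per-session values (the paper-style per-session
#' statistic), optionally a KS test on pooled neuron-level values, group
#' means with SEM, and significance stars. Invariant to session ordering.
#'
#' @param summaries data frame from [session_table()].
#' @param metric column name to compare.
#' @param group_col grouping column (two levels).
#' @param pooled optional named list of two pooled neuron-level vectors
#'   for the KS comparison.
#' @return list of class `group_comparison`.
#' @export
compare_groups <- function(summaries, metric, group_col = "subregion",
                           pooled = NULL) {
  if (!metric %in% names(summaries)) stop_invalid("unknown metric '%s'", metric)
  groups <- sort(unique(summaries[[group_col]]))
  if (length(groups) != 2) stop_invalid("need exactly 2 groups")
  v <- split(summaries[[metric]], summaries[[group_col]])[as.character(groups)]
  u <- mannwhitney_u(v[[1]], v[[2]])
  ks <- if (!is.null(pooled)) ks_two_sample(pooled[[1]], pooled[[2]]) else NULL
  means <- vapply(v, mean, numeric(1), na.rm = TRUE)
  sems <- vapply(v, function(x) sd(x, na.rm = TRUE) / sqrt(sum(!is.na(x))),
                 numeric(1))
  structure(list(metric = metric, groups = as.character(groups),
                 values = v, mean = means, sem = sems,
                 U = u$U, p_u = u$p, stars = significance_stars(u$p),
                 ks = ks, n = vapply(v, length, 1L)),
            class = "group_comparison")
}
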