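# Drifting-grating analysis: trial de-randomization, visual reliability,
# SF/TF preference, orientation/direction selectivity.

# Internal: canonical condition table (direction fastest within each SF/TF
# combo, combos ordered by SF then TF).
canonical_conditions <- function(stim) {
  conds <- unique(stim[, c("direction_deg", "sf_cpd", "tf_hz")])
  conds <- conds[order(conds$sf_cpd, conds$tf_hz, conds$direction_deg), ]
  rownames(conds) <- NULL
  conds
}

#' De-randomize grating trials
#'
#' Groups pseudo-randomized trials by stimulus condition in canonical order
#' (directions within SF/TF combinations) and extracts, for each trial, the
#' dF/F0 snippet over the stimulus window, baseline-corrected by the median
#' of the five frames preceding stimulus onset. Trials whose onset leaves
#' fewer than `pre_frames` preceding samples are dropped with a warning.
#'
#' @param dff neurons x time dF/F0 matrix (or `dff_set`).
#' @param stim stimulus table with columns `onset_s`, `direction_deg`,
#'   `sf_cpd`, `tf_hz`, `repetition`.
#' @param rate_hz sampling rate.
#' @param pre_frames frames used for the pre-stimulus baseline.
#' @param stim_window_s stimulus window length (s).
#' @return list of class `visual_profile`: `resp` (4-D array
#'   neuron x condition x repetition x frame, baseline-corrected),
#'   `conditions` (canonical condition table), `n_rep`.
#' @export
derandomize <- function(dff, stim, rate_hz, pre_frames = 5,
                        stim_window_s = 3) {
  if (inherits(dff, "dff_set")) dff <- dff$dff
  if (is.null(dim(dff))) dff <- matrix(dff, nrow = 1)
  conds <- canonical_conditions(stim)
  n_cond <- nrow(conds)
  reps <- sort(unique(stim$repetition))
  n_rep <- length(reps)
  n_fr <- round(stim_window_s * rate_hz)
  n <- nrow(dff); nt <- ncol(dff)
  resp <- array(NA_real_, c(n, n_cond, n_rep, n_fr))
  dropped <- 0L
  ckey <- paste(conds$direction_deg, conds$sf_cpd, conds$tf_hz)
  for (k in seq_len(nrow(stim))) {
    i0 <- round(stim$onset_s[k] * rate_hz) + 1L
    if (i0 - pre_frames < 1 || i0 + n_fr - 1 > nt) { dropped <- dropped + 1L; next }
    ci <- match(paste(stim$direction_deg[k], stim$sf_cpd[k], stim$tf_hz[k]), ckey)
    ri <- match(stim$repetition[k], reps)
    base <- apply(dff[, (i0 - pre_frames):(i0 - 1), drop = FALSE], 1, median)
    resp[, ci, ri, ] <- dff[, i0:(i0 + n_fr - 1), drop = FALSE] - base
  }
  if (dropped > 0)
    warning(sprintf("%d trial(s) dropped (onset too close to trace edge)", dropped))
  structure(list(resp = resp, conditions = conds, n_rep = n_rep,
                 rate_hz = rate_hz), class = "visual_profile")
}

#' Visual reliability index
#'
#' Each repetition's de-randomized, condition-ordered response time courses
#' are concatenated into one long trace; the reliability index is the 75th
#' percentile of the Pearson correlations over all repetition pairs.
#' Constant repetitions are skipped; `NA` if no pair remains.
#'
#' @param profile a `visual_profile`, or a 3-D array
#'   condition x repetition x frame for a single neuron.
#' @return per-neuron reliability in `[-1, 1]`.
#' @export
reliability_index <- function(profile) {
  one <- function(a3) {                  # cond x rep x frame
    n_rep <- dim(a3)[2]
    if (n_rep < 2) stop_invalid("need at least 2 repetitions")
    tc <- sapply(seq_len(n_rep), function(r) as.vector(t(a3[, r, ])))
    rs <- c()
    for (i in seq_len(n_rep - 1)) for (j in (i + 1):n_rep) {
      ok <- is.finite(tc[, i]) & is.finite(tc[, j])
      if (sum(ok) < 2) next
      if (sd(tc[ok, i]) == 0 || sd(tc[ok, j]) == 0) next
      rs <- c(rs, cor(tc[ok, i], tc[ok, j]))
    }
    if (length(rs) == 0) NA_real_ else quantile(rs, 0.75, names = FALSE)
  }
  if (inherits(profile, "visual_profile")) {
    n <- dim(profile$resp)[1]
    sapply(seq_len(n), function(i) one(profile$resp[i, , , , drop = TRUE]))
  } else one(profile)
}

#' Classify visually responsive neurons
#'
#' Strictly `r > threshold` (default 0.3).
#'
#' @param r reliability indices.
#' @param threshold classification threshold.
#' @return logical vector (`NA` reliabilities give `FALSE`).
#' @export
classify_visual <- function(r, threshold = 0.3) {
  out <- r > threshold
  out[is.na(out)] <- FALSE
  out
}

#' Condition-mean response matrix
#'
#' Mean baseline-corrected dF/F0 over the stimulus window and repetitions,
#' arranged as a directions x combos matrix (combos ordered by SF then TF).
#'
#' @param profile a `visual_profile`.
#' @param neuron neuron index.
#' @return matrix with one row per direction and one column per SF/TF
#'   combo; `attr(, "combos")` holds the combo table,
#'   `attr(, "directions")` the direction values.
#' @export
condition_means <- function(profile, neuron = 1) {
  conds <- profile$conditions
  m <- apply(profile$resp[neuron, , , , drop = TRUE], 1, mean, na.rm = TRUE)
  dirs <- sort(unique(conds$direction_deg))
  combos <- unique(conds[, c("sf_cpd", "tf_hz")])
  combos <- combos[order(combos$sf_cpd, combos$tf_hz), ]
  out <- matrix(NA_real_, length(dirs), nrow(combos))
  for (k in seq_along(m)) {
    di <- match(conds$direction_deg[k], dirs)
    ci <- which(combos$sf_cpd == conds$sf_cpd[k] & combos$tf_hz == conds$tf_hz[k])
    out[di, ci] <- m[k]
  }
  attr(out, "combos") <- combos
  attr(out, "directions") <- dirs
  out
}

#' Preferred spatial/temporal frequency combination
#'
#' The preferred combo maximizes the mean response across all directions.
#' Ties resolve to the lowest (SF, TF) in canonical order and are flagged.
#'
#' @param cond_mean directions x combos matrix from [condition_means()].
#' @return list with `pref_sf_cpd`, `pref_tf_hz`, `combo_index`, `tie`.
#' @export
sf_tf_preference <- function(cond_mean) {
  combos <- attr(cond_mean, "combos")
  avg <- colMeans(cond_mean, na.rm = TRUE)
  best <- which(avg == max(avg))
  list(pref_sf_cpd = combos$sf_cpd[best[1]],
       pref_tf_hz = combos$tf_hz[best[1]],
       combo_index = best[1], tie = length(best) > 1)
}

#' Session-level SF/TF tuning fractions
#'
#' Fraction of visually responsive neurons preferring each SF/TF combo;
#' sums to 1 over responsive neurons.
#'
#' @param combo_index integer preferred-combo index per responsive neuron.
#' @param n_combos total number of combos (default 6).
#' @return numeric vector of fractions.
#' @export
sf_tf_fractions <- function(combo_index, n_combos = 6) {
  tabulate(combo_index, nbins = n_combos) / length(combo_index)
}

#' Orientation and direction selectivity indices
#'
#' From a 12-point direction tuning curve (negative condition means
#' rectified to 0): `R_p` is the response at the preferred (argmax)
#' direction, `R_null` the response 180 degrees away, `R_ortho` the mean of
#' the two orthogonal directions, and
#' \deqn{OSI = (R_p - R_ortho) / (R_p + R_ortho), \quad
#'       DSI = (R_p - R_null) / (R_p + R_null).}
#' Neurons with OSI > 0.33 or DSI > 0.33 count as orientation- or
#' direction-selective. Both indices are invariant to positive scaling of
#' the curve; a zero denominator yields `NA`.
#'
#' @param curve responses at the sampled directions (typically at the
#'   preferred SF/TF combo).
#' @param directions direction values (deg), same length as `curve`.
#' @param threshold selectivity threshold (strict).
#' @return list with `osi`, `dsi`, `pref_dir_deg`, `pref_ori_deg`,
#'   `orientation_selective`, `direction_selective`.
#' @export
osi_dsi <- function(curve, directions = seq(0, 330, by = 30),
                    threshold = 0.33) {
  stopifnot(length(curve) == length(directions))
  r <- pmax(curve, 0)
  n <- length(r)
  ip <- which.max(r)
  rp <- r[ip]
  shift <- function(k) ((ip - 1 + k) %% n) + 1
  q <- n %/% 4; h <- n %/% 2
  r_null <- r[shift(h)]
  r_ortho <- mean(r[c(shift(q), shift(-q))])
  osi <- if (rp + r_ortho > 0) (rp - r_ortho) / (rp + r_ortho) else NA_real_
  dsi <- if (rp + r_null > 0) (rp - r_null) / (rp + r_null) else NA_real_
  list(osi = osi, dsi = dsi,
       pref_dir_deg = directions[ip],
       pref_ori_deg = directions[ip] %% 180,
       orientation_selective = isTRUE(osi > threshold),
       direction_selective = isTRUE(dsi > threshold))
}

#' Peak response amplitude
#'
#' 95th percentile of per-trial maximal dF/F0, reported in percent.
#'
#' @param trial_max per-trial maximum dF/F0 values, or a trials x frames
#'   matrix of snippets (maxima taken per row).
#' @return amplitude in percent dF/F0.
#' @export
peak_amplitude <- function(trial_max) {
  if (!is.null(dim(trial_max))) trial_max <- apply(trial_max, 1, max)
  if (length(trial_max) == 0) stop_invalid("need at least one trial")
  100 * quantile(trial_max, 0.95, names = FALSE)
}

#' Per-neuron visual tuning summary
#'
#' Runs the full grating analysis for every neuron: reliability,
#' responsiveness, preferred SF/TF, OSI/DSI at the preferred combo, and
#' peak amplitude.
#'
#' @param profile a `visual_profile` from [derandomize()].
#' @param threshold responsiveness threshold.
#' @return data frame with one row per neuron.
#' @export
visual_tuning_stats <- function(profile, threshold = 0.3) {
  n <- dim(profile$resp)[1]
  r <- reliability_index(profile)
  responsive <- classify_visual(r, threshold)
  out <- data.frame(neuron_id = seq_len(n), r_index = r,
                    is_visual = responsive,
                    pref_sf_cpd = NA_real_, pref_tf_hz = NA_real_,
                    combo_index = NA_integer_,
                    osi = NA_real_, dsi = NA_real_,
                    pref_dir_deg = NA_real_, pref_ori_deg = NA_real_,
                    peak_amp_pct = NA_real_)
  for (i in seq_len(n)) {
    cm <- condition_means(profile, i)
    pref <- sf_tf_preference(cm)
    out$pref_sf_cpd[i] <- pref$pref_sf_cpd
    out$pref_tf_hz[i] <- pref$pref_tf_hz
    out$combo_index[i] <- pref$combo_index
    sel <- osi_dsi(cm[, pref$combo_index], attr(cm, "directions"))
    out$osi[i] <- sel$osi; out$dsi[i] <- sel$dsi
    out$pref_dir_deg[i] <- sel$pref_dir_deg
    out$pref_ori_deg[i] <- sel$pref_ori_deg
    tm <- apply(profile$resp[i, , , , drop = TRUE], c(1, 2),
                max, na.rm = TRUE)
    out$peak_amp_pct[i] <- peak_amplitude(as.vector(tm))
  }
  out
}
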