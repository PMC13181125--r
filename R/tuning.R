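# Position tuning: occupancy-normalized trial x bin maps with circular
# Gaussian smoothing, a circular-shift shuffle test, field detection,
# spatial information and trial-to-trial reliability.

# Internal: shared geometry for map computations. Restricts samples to
# running epochs and complete laps, assigns (trial, bin) groups, and
# precomputes per-group dwell times, the visited mask and the circular
# smoothing matrix.
map_context <- function(track, epochs, n_bins, smooth_sd_bins) {
  sel <- which(if (is.null(epochs)) rep(TRUE, nrow(track)) else epoch_mask(track, epochs))
  laps_ok <- complete_laps(track)
  sel <- sel[track$lap_id[sel] %in% laps_ok]
  trials <- sort(unique(track$lap_id[sel]))
  if (length(trials) < 2) stop_invalid("need at least 2 complete laps")
  dt <- 1 / attr(track, "rate_hz")
  L <- attr(track, "track_length_cm")
  bin <- position_bins(track$position_cm[sel], L, n_bins)
  trial_idx <- match(track$lap_id[sel], trials)
  g <- (trial_idx - 1L) * n_bins + bin
  obs <- sort(unique(g))
  time_obs <- tabulate(match(g, obs), nbins = length(obs)) * dt
  visited <- matrix(FALSE, length(trials), n_bins)
  visited[cbind((obs - 1L) %/% n_bins + 1L, (obs - 1L) %% n_bins + 1L)] <- TRUE
  list(sel = sel, g = g, obs = obs, gmap = match(g, obs),
       time_obs = time_obs, visited = visited, trials = trials,
       n_trials = length(trials), n_bins = n_bins, dt = dt, L = L,
       bin_width_cm = L / n_bins,
       S = circular_smoother(n_bins, smooth_sd_bins))
}

# Internal: linear operator A (n_bins x n_obs_groups) such that
# A %*% rates gives the across-trial mean of the per-trial circularly
# smoothed maps, for any per-(trial, bin) rate vector with the fixed
# visitation pattern of `ctx`. Smoothing weights are renormalized over each
# trial's visited bins; the mean at bin b runs over trials that visited b.
mean_map_operator <- function(ctx) {
  n_bins <- ctx$n_bins
  nvis <- colSums(ctx$visited)
  A <- matrix(0, n_bins, length(ctx$obs))
  for (t in seq_len(ctx$n_trials)) {
    vb <- which(ctx$visited[t, ])
    cols <- match((t - 1L) * n_bins + vb, ctx$obs)
    W <- ctx$S[, vb, drop = FALSE]
    W <- W / rowSums(W)
    rows <- vb                       # smoothed map defined at visited bins
    A[rows, cols] <- A[rows, cols] + W[rows, , drop = FALSE] / nvis[rows]
  }
  A
}

#' Occupancy-normalized tuning maps
#'
#' Divides the belt into `n_bins` equal position bins (1.5 cm on a 150 cm
#' belt with the default 100) and computes, per trial (complete lap) and
#' bin, summed deconvolved activity divided by the time spent in the bin,
#' restricted to running epochs. Each trial's map is smoothed with a
#' circular Gaussian (SD = 3 bins by default; weights renormalized over the
#' trial's visited bins); bins unvisited in a trial are missing for that
#' trial and excluded from the across-trial mean and SEM.
#'
#' @param events neurons x time matrix of deconvolved event amplitudes (or
#'   an `event_set`).
#' @param track a [behavior_track()] aligned to `events`.
#' @param epochs running epochs from [detect_running_epochs()]; `NULL`
#'   uses all samples.
#' @param n_bins number of position bins.
#' @param smooth_sd_bins circular Gaussian SD in bins.
#' @return list of class `tuning_profile`: `per_trial`
#'   (trials x bins x neurons, smoothed), `mean_map` and `sem_map`
#'   (neurons x bins), `p_occ`, `bin_centers_cm`, `visited`, `trials`.
#' @export
tuning_map <- function(events, track, epochs = NULL, n_bins = 100,
                       smooth_sd_bins = 3) {
  if (inherits(events, "event_set")) events <- events$events
  if (is.null(dim(events))) events <- matrix(events, nrow = 1)
  if (ncol(events) != nrow(track)) stop_invalid("events and track lengths differ")
  ctx <- map_context(track, epochs, n_bins, smooth_sd_bins)
  n <- nrow(events)

  counts <- rowsum(t(events[, ctx$sel, drop = FALSE]), ctx$g)  # obs x n
  rates <- counts / ctx$time_obs

  per_trial <- array(NA_real_, c(ctx$n_trials, n_bins, n))
  mean_map <- sem_map <- matrix(NA_real_, n, n_bins)
  ti <- (ctx$obs - 1L) %/% n_bins + 1L
  bi <- (ctx$obs - 1L) %% n_bins + 1L
  for (t in seq_len(ctx$n_trials)) {
    vb <- bi[ti == t]
    raw <- matrix(0, n_bins, n)
    raw[vb, ] <- rates[ti == t, , drop = FALSE]
    den <- rowSums(ctx$S[, vb, drop = FALSE])
    sm <- (ctx$S[, vb, drop = FALSE] %*% raw[vb, , drop = FALSE]) / den
    sm[!ctx$visited[t, ], ] <- NA_real_
    per_trial[t, , ] <- sm
  }
  nvis <- colSums(ctx$visited)
  for (b in seq_len(n_bins)) {
    if (nvis[b] == 0) next
    v <- per_trial[ctx$visited[, b], b, , drop = FALSE]
    v <- matrix(v, nrow = nvis[b])
    mean_map[, b] <- colMeans(v)
    if (nvis[b] > 1) sem_map[, b] <- apply(v, 2, sd) / sqrt(nvis[b])
  }
  p_occ <- numeric(n_bins)
  tt <- rowsum(ctx$time_obs, bi)
  p_occ[sort(unique(bi))] <- tt / sum(tt)
  structure(list(per_trial = per_trial, mean_map = mean_map,
                 sem_map = sem_map, p_occ = p_occ,
                 bin_centers_cm = (seq_len(n_bins) - 0.5) * ctx$bin_width_cm,
                 bin_width_cm = ctx$bin_width_cm, n_bins = n_bins,
                 smooth_sd_bins = smooth_sd_bins, visited = ctx$visited,
                 trials = ctx$trials, ctx = ctx),
            class = "tuning_profile")
}

#' Circular-shift shuffle test for position selectivity
#'
#' For each shuffle, every neuron's event train is circularly shifted in
#' time by a random offset drawn uniformly between `min_shift_s` and the
#' session duration minus `min_shift_s`, and the across-trial mean tuning
#' map is recomputed. This yields a per-bin null distribution of mean-map
#' values; a neuron is significant if the lower bound of its observed
#' activity (mean - SEM across trials) exceeds the per-bin 97.5th
#' percentile of the null in at least one position bin.
#'
#' @param events neurons x time event matrix (or `event_set`).
#' @param track,epochs,n_bins,smooth_sd_bins as in [tuning_map()].
#' @param n_shuffles number of circular shifts.
#' @param min_shift_s minimum shift (s); the session must be longer than
#'   twice this.
#' @param pct null percentile (in percent).
#' @param seed optional seed, recorded in the output.
#' @param profile optional precomputed [tuning_map()] with matching
#'   parameters, to avoid recomputation.
#' @return list of class `shuffle_result`: `significant` (logical per
#'   neuron), `lower_bound` and `null_threshold` (neurons x bins), plus the
#'   profile and parameters.
#' @export
shuffle_test <- function(events, track, epochs = NULL, n_shuffles = 200,
                         min_shift_s = 20, pct = 97.5, seed = NULL,
                         n_bins = 100, smooth_sd_bins = 3, profile = NULL) {
  if (inherits(events, "event_set")) events <- events$events
  if (is.null(dim(events))) events <- matrix(events, nrow = 1)
  nt <- ncol(events)
  dt <- 1 / attr(track, "rate_hz")
  if (nt * dt <= 2 * min_shift_s)
    stop_invalid("session shorter than twice min_shift_s")
  if (is.null(profile))
    profile <- tuning_map(events, track, epochs, n_bins, smooth_sd_bins)
  ctx <- profile$ctx
  A <- mean_map_operator(ctx)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(events)
  lo <- round(min_shift_s / dt)
  hi <- nt - lo
  lower <- profile$mean_map - profile$sem_map
  thresh <- matrix(NA_real_, n, n_bins)
  significant <- logical(n)
  gfac <- ctx$gmap
  for (i in seq_len(n)) {
    shifts <- sample(seq.int(lo, hi), n_shuffles, replace = TRUE)
    idx <- (outer(ctx$sel - 1L, shifts, "-") %% nt) + 1L
    evm <- matrix(events[i, ], nt)[idx]
    dim(evm) <- dim(idx)
    counts <- rowsum(evm, gfac)                    # obs x n_shuffles
    null_maps <- A %*% (counts / ctx$time_obs)     # n_bins x n_shuffles
    thresh[i, ] <- apply(null_maps, 1, quantile, probs = pct / 100,
                         names = FALSE)
    significant[i] <- any(lower[i, ] > thresh[i, ], na.rm = TRUE)
  }
  structure(list(significant = significant, lower_bound = lower,
                 null_threshold = thresh, profile = profile,
                 n_shuffles = n_shuffles, min_shift_s = min_shift_s,
                 pct = pct, seed = seed),
            class = "shuffle_result")
}

#' Detect position-tuning fields
#'
#' Thresholds the smoothed mean map at `baseline + frac * (peak -
#' baseline)`, with the baseline taken as the map minimum. Fields are
#' circularly contiguous supra-threshold runs (they may straddle the 0 cm
#' seam) with width within `[min_w_cm, max_w_cm]`; a field is retained only
#' if its trial-mean activity over the field span exceeds the same
#' threshold in more than `presence` of all trials.
#'
#' @param mean_map length-`n_bins` smoothed mean map for one neuron.
#' @param per_trial trials x bins matrix of smoothed per-trial maps.
#' @param bin_width_cm width of one position bin (cm).
#' @param frac threshold fraction of the peak-baseline range.
#' @param min_w_cm,max_w_cm admissible field widths (cm).
#' @param presence minimum fraction of trials showing the field.
#' @return data frame with one row per field: `start_bin`, `end_bin`
#'   (inclusive; `end_bin < start_bin` indicates seam wrap), `width_cm`,
#'   `peak_bin` (argmax bin) and `center_cm` (activity-weighted mean
#'   position along the field span, a lower-variance center estimate than
#'   the argmax).
#' @export
detect_fields <- function(mean_map, per_trial, bin_width_cm, frac = 0.3,
                          min_w_cm = 15, max_w_cm = 120, presence = 1 / 3) {
  n_bins <- length(mean_map)
  empty <- data.frame(start_bin = integer(), end_bin = integer(),
                      width_cm = numeric(), peak_bin = integer(),
                      center_cm = numeric())
  fin <- is.finite(mean_map)
  if (!any(fin)) return(empty)
  base <- min(mean_map[fin]); peak <- max(mean_map[fin])
  if (peak <= base) return(empty)
  thr <- base + frac * (peak - base)
  supra <- fin & mean_map > thr
  if (!any(supra)) return(empty)
  # circular runs of supra-threshold bins
  r <- rle(supra)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  if (nrow(runs) > 1 && supra[1] && supra[n_bins]) {
    runs$start[1] <- runs$start[nrow(runs)]       # wrap across the seam
    runs <- runs[-nrow(runs), , drop = FALSE]
  }
  out <- empty
  for (k in seq_len(nrow(runs))) {
    bins <- if (runs$start[k] <= runs$end[k]) runs$start[k]:runs$end[k]
            else c(runs$start[k]:n_bins, 1:runs$end[k])
    width <- length(bins) * bin_width_cm
    if (width < min_w_cm || width > max_w_cm) next
    tm <- rowMeans(per_trial[, bins, drop = FALSE], na.rm = TRUE)
    pres <- mean(tm > thr, na.rm = TRUE)
    if (is.na(pres) || pres <= presence) next
    pk <- bins[which.max(mean_map[bins])]
    # field center: activity-weighted mean along the (unwrapped) field span,
    # a lower-variance estimate than the raw argmax
    wts <- pmax(mean_map[bins] - base, 0)
    com <- sum(wts * seq_along(bins)) / sum(wts)
    center <- ((runs$start[k] - 1 + com - 1) %% n_bins) * bin_width_cm +
      bin_width_cm / 2
    out <- rbind(out, data.frame(start_bin = runs$start[k],
                                 end_bin = runs$end[k], width_cm = width,
                                 peak_bin = pk, center_cm = center))
  }
  out
}

#' Skaggs spatial information (bits/event)
#'
#' `SI = sum_i p_i (f_i / f) log2(f_i / f)` with occupancy probabilities
#' `p_i`, occupancy-normalized activity `f_i` and overall mean activity
#' `f = sum_i p_i f_i`. Terms with `f_i = 0` contribute 0. SI is the KL
#' divergence between the activity-weighted and occupancy distributions,
#' hence non-negative; it is 0 for a uniform map and `log2(N)` for
#' activity confined to one of `N` equal-occupancy bins.
#'
#' @param p_occ occupancy probabilities (summing to 1).
#' @param mean_map activity map: a vector, or a neurons x bins matrix for
#'   several neurons at once.
#' @return SI in bits/event (vector for matrix input); `NA` when the
#'   overall mean activity is 0.
#' @export
spatial_information <- function(p_occ, mean_map) {
  si_one <- function(f) {
    ok <- p_occ > 0 & is.finite(f)
    p <- p_occ[ok]; f <- f[ok]
    fbar <- sum(p * f)
    if (!is.finite(fbar) || fbar <= 0) return(NA_real_)
    pos <- f > 0
    sum(p[pos] * (f[pos] / fbar) * log2(f[pos] / fbar))
  }
  if (is.null(dim(mean_map))) si_one(mean_map)
  else apply(mean_map, 1, si_one)
}

#' Trial-to-trial correlation
#'
#' Median of the pairwise Pearson correlation coefficients across trials,
#' computed over bins visited in both trials of each pair. Pairs with
#' fewer than 2 mutually visited bins, or with a constant map, are
#' skipped; `NA` when all pairs are skipped.
#'
#' @param per_trial_map trials x bins matrix (missing = unvisited).
#' @return median pairwise correlation.
#' @export
trial_correlation <- function(per_trial_map) {
  nt <- nrow(per_trial_map)
  if (nt < 2) stop_invalid("need at least 2 trials")
  rs <- c()
  for (i in seq_len(nt - 1)) for (j in (i + 1):nt) {
    ok <- is.finite(per_trial_map[i, ]) & is.finite(per_trial_map[j, ])
    if (sum(ok) < 2) next
    a <- per_trial_map[i, ok]; b <- per_trial_map[j, ok]
    if (sd(a) == 0 || sd(b) == 0) next
    rs <- c(rs, cor(a, b))
  }
  if (length(rs) == 0) NA_real_ else median(rs)
}

#' Classify position-tuned neurons and assemble tuning statistics
#'
#' A neuron is position-tuned if it passes the circular-shift shuffle test
#' and has at least one valid tuning field. Reported width is the widest
#' field; the field count is capped at 3 for reporting.
#'
#' @param shuffle a `shuffle_result` from [shuffle_test()].
#' @param dff optional neurons x time dF/F0 matrix used for the
#'   95th-percentile peak-amplitude statistic (percent).
#' @param frac,min_w_cm,max_w_cm,presence field-detection parameters, see
#'   [detect_fields()].
#' @return data frame with one row per neuron: `neuron_id`, `significant`,
#'   `is_tuned`, `si_bits_per_event`, `width_cm`, `n_fields`,
#'   `peak_pos_cm`, `trial_corr`, `peak_amp_pct`.
#' @export
classify_position_tuned <- function(shuffle, dff = NULL, frac = 0.3,
                                    min_w_cm = 15, max_w_cm = 120,
                                    presence = 1 / 3) {
  profile <- shuffle$profile
  n <- nrow(profile$mean_map)
  si <- spatial_information(profile$p_occ, profile$mean_map)
  out <- data.frame(neuron_id = seq_len(n), significant = shuffle$significant,
                    is_tuned = FALSE, si_bits_per_event = si,
                    width_cm = NA_real_, n_fields = 0L,
                    peak_pos_cm = NA_real_, trial_corr = NA_real_,
                    peak_amp_pct = NA_real_)
  for (i in seq_len(n)) {
    fields <- detect_fields(profile$mean_map[i, ], profile$per_trial[, , i],
                            profile$bin_width_cm, frac, min_w_cm, max_w_cm,
                            presence)
    out$n_fields[i] <- min(nrow(fields), 3L)
    out$is_tuned[i] <- shuffle$significant[i] && nrow(fields) > 0
    if (nrow(fields) > 0) out$width_cm[i] <- max(fields$width_cm)
    if (any(is.finite(profile$mean_map[i, ])))
      out$peak_pos_cm[i] <- profile$bin_centers_cm[which.max(profile$mean_map[i, ])]
    out$trial_corr[i] <- trial_correlation(profile$per_trial[, , i])
  }
  if (!is.null(dff)) {
    sel <- profile$ctx$sel
    trial_of <- (profile$ctx$g - 1L) %/% profile$n_bins + 1L
    for (i in seq_len(n)) {
      tr_max <- tapply(dff[i, sel], trial_of, max)
      out$peak_amp_pct[i] <- 100 * quantile(tr_max, 0.95, names = FALSE,
                                            na.rm = TRUE)
    }
  }
  out
}
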