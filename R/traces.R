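# Fluorescence preprocessing: neuropil correction, min/max baseline,
# dF/F0, fixed-kernel non-negative deconvolution, transient detection and
# task-activity classification.

#' Two-channel fluorescence container
#'
#' Holds raw somatic (`F_cell`) and surrounding-neuropil (`F_np`)
#' fluorescence as neurons x time matrices, with the sampling rate and
#' neuron identifiers. The same schema accepts Suite2p-exported arrays.
#'
#' @param F_cell,F_np neurons x time numeric matrices of identical shape
#'   (arbitrary units).
#' @param rate_hz sampling rate (samples/s).
#' @param neuron_ids optional identifiers (default `1:n`).
#' @return a list of class `trace_set`.
#' @export
trace_set <- function(F_cell, F_np, rate_hz, neuron_ids = NULL) {
  F_cell <- as.matrix(F_cell); F_np <- as.matrix(F_np)
  if (!all(dim(F_cell) == dim(F_np)))
    stop_invalid("F_cell and F_np shapes differ")
  if (rate_hz <= 0) stop_invalid("rate_hz must be positive")
  if (is.null(neuron_ids)) neuron_ids <- seq_len(nrow(F_cell))
  structure(list(F_cell = F_cell, F_np = F_np, rate_hz = rate_hz,
                 neuron_ids = neuron_ids), class = "trace_set")
}

#' Neuropil correction
#'
#' Subtracts scaled neuropil fluorescence from the somatic channel:
#' `F_corr = F_cell - coeff * F_np`, elementwise, with the conventional
#' coefficient 0.7.
#'
#' @param traces a [trace_set()], or a matrix `F_cell` (then `F_np` must be
#'   supplied).
#' @param coeff neuropil contamination coefficient in `[0, 1]`.
#' @param F_np neuropil matrix when `traces` is a bare matrix.
#' @return corrected fluorescence matrix (neurons x time).
#' @export
neuropil_correct <- function(traces, coeff = 0.7, F_np = NULL) {
  if (coeff < 0 || coeff > 1) stop_invalid("coeff must be in [0, 1]")
  if (inherits(traces, "trace_set")) {
    traces$F_cell - coeff * traces$F_np
  } else {
    traces <- as.matrix(traces)
    if (is.null(F_np)) stop_invalid("F_np required when traces is a matrix")
    F_np <- as.matrix(F_np)
    if (!all(dim(traces) == dim(F_np)))
      stop_invalid("F_cell and F_np shapes differ")
    traces - coeff * F_np
  }
}

#' Baseline fluorescence via a min/max filter
#'
#' Rolling minimum followed by rolling maximum, both over a 60 s window,
#' then Gaussian smoothing (SD = 10 samples). The morphological opening
#' tracks slow drift while ignoring brief positive transients; window edges
#' use shrunken windows, so constants are preserved exactly and the
#' operator is translation-equivariant.
#'
#' @param F_corr neurons x time matrix (or vector) of corrected
#'   fluorescence.
#' @param rate_hz sampling rate (samples/s).
#' @param window_s filter kernel size (s).
#' @param smooth_sigma_samples Gaussian SD in samples.
#' @return baseline matrix `F0` of the same shape; rows that are entirely
#'   non-finite come back as all-`NA`.
#' @export
estimate_baseline <- function(F_corr, rate_hz, window_s = 60,
                              smooth_sigma_samples = 10) {
  vec <- is.null(dim(F_corr))
  m <- if (vec) matrix(F_corr, nrow = 1) else as.matrix(F_corr)
  w <- max(3L, as.integer(round(window_s * rate_hz)))
  f0 <- matrix(NA_real_, nrow(m), ncol(m))
  for (i in seq_len(nrow(m))) {
    x <- m[i, ]
    if (all(!is.finite(x))) next
    f0[i, ] <- run_max_c(run_min_c(x, w), w)
  }
  f0 <- smooth_rows_gaussian(f0, smooth_sigma_samples)
  if (vec) drop(f0) else f0
}

#' Compute dF/F0
#'
#' `dff = (F_corr - F0) / F0` wherever the baseline is usable. A neuron
#' whose baseline falls at or below `eps` anywhere is flagged invalid
#' (a flag, not an exception); `eps` defaults to `1e-6` of the median
#' baseline.
#'
#' @param F_corr,F0 matrices of identical shape.
#' @param eps positive floor for usable baselines; `NULL` uses
#'   `1e-6 * median(F0)`.
#' @return list of class `dff_set` with `dff`, `F0` and per-neuron `valid`.
#' @export
compute_dff <- function(F_corr, F0, eps = NULL) {
  F_corr <- as.matrix(F_corr); F0 <- as.matrix(F0)
  if (!all(dim(F_corr) == dim(F0))) stop_invalid("F_corr and F0 shapes differ")
  if (is.null(eps)) eps <- 1e-6 * median(F0[is.finite(F0) & F0 > 0])
  valid <- apply(F0, 1, function(r) all(is.finite(r)) && all(r > eps))
  dff <- (F_corr - F0) / F0
  dff[!valid, ] <- NA_real_
  structure(list(dff = dff, F0 = F0, valid = valid), class = "dff_set")
}

#' Non-negative deconvolution with a fixed exponential kernel
#'
#' Models the calcium trace as the convolution of events with an exponential
#' decay kernel: finds the non-negative event train `s` minimizing
#' `||c - dff||^2` subject to `c[t] = gamma * c[t-1] + s[t]`, with
#' `gamma = exp(-1 / (rate_hz * decay_s))` (pool-adjacent-violators, no
#' sparsity penalty). The default 1.5 s decay is appropriate for GCaMP6s.
#'
#' @param dff a `dff_set` from [compute_dff()] or a neurons x time matrix.
#' @param rate_hz sampling rate; taken from nothing, so must be supplied
#'   when `dff` is a bare matrix.
#' @param decay_s kernel decay constant (s).
#' @return list of class `event_set` with `events` (non-negative amplitudes
#'   in dF/F units per frame) and `gamma`.
#' @export
deconvolve <- function(dff, rate_hz, decay_s = 1.5) {
  if (decay_s <= 0) stop_invalid("decay_s must be positive")
  m <- if (inherits(dff, "dff_set")) dff$dff else as.matrix(dff)
  gamma <- exp(-1 / (rate_hz * decay_s))
  ev <- matrix(0, nrow(m), ncol(m))
  for (i in seq_len(nrow(m))) {
    x <- m[i, ]
    if (any(!is.finite(x))) { ev[i, ] <- NA_real_; next }
    ev[i, ] <- deconv_ar1_c(x, gamma)
  }
  dimnames(ev) <- dimnames(m)
  structure(list(events = ev, gamma = gamma), class = "event_set")
}

#' Significant calcium transients
#'
#' Flags samples where dF/F0 exceeds three times the per-neuron noise SD.
#' The noise scale is a median-absolute-deviation estimate
#' (`mad * 1.4826`, centered on the median) so that the transients
#' themselves do not inflate it. Zero-variance traces yield an empty mask.
#'
#' @param dff a `dff_set` or matrix.
#' @param n_sd threshold in noise SDs.
#' @return logical matrix of the same shape.
#' @export
significant_transients <- function(dff, n_sd = 3) {
  m <- if (inherits(dff, "dff_set")) dff$dff else as.matrix(dff)
  mask <- matrix(FALSE, nrow(m), ncol(m))
  for (i in seq_len(nrow(m))) {
    x <- m[i, ]
    if (any(!is.finite(x))) next
    s <- mad(x)
    if (s == 0) next
    mask[i, ] <- x > median(x) + n_sd * s
  }
  mask
}

#' Lap reliability
#'
#' Proportion of running laps in which a neuron exhibited at least one
#' significant calcium transient.
#'
#' @param transient_mask logical neurons x time matrix (or vector) from
#'   [significant_transients()].
#' @param lap_ids integer lap index per sample; samples with `NA` lap are
#'   ignored.
#' @return numeric vector of per-neuron fractions in `[0, 1]`.
#' @export
lap_reliability <- function(transient_mask, lap_ids) {
  if (is.null(dim(transient_mask)))
    transient_mask <- matrix(transient_mask, nrow = 1)
  keep <- !is.na(lap_ids)
  laps <- unique(lap_ids[keep])
  if (length(laps) == 0) stop_invalid("no laps available")
  hits <- rowsum(t(transient_mask[, keep, drop = FALSE]) + 0, lap_ids[keep])
  colMeans(hits > 0)
}

#' Task-activity classification
#'
#' A neuron counts as active during the task if either its lap reliability
#' or its visual reliability strictly exceeds the threshold (default 0.3).
#'
#' @param lap_rel,visual_rel per-neuron reliabilities; either may be `NULL`
#'   for sessions lacking that block, but not both.
#' @param threshold strict threshold.
#' @return logical vector.
#' @export
classify_active <- function(lap_rel = NULL, visual_rel = NULL,
                            threshold = 0.3) {
  if (is.null(lap_rel) && is.null(visual_rel))
    stop_invalid("at least one reliability metric is required")
  a <- if (is.null(lap_rel)) FALSE else lap_rel > threshold
  b <- if (is.null(visual_rel)) FALSE else visual_rel > threshold
  as.logical(a | b)
}
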