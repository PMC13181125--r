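# Bayesian population decoding of position from deconvolved activity:
# position-binned encoding models, the Poisson-form posterior, odd/even and
# 5-fold cross-validation over laps, error traces and confusion matrices.

#' Fit a position-binned encoding model
#'
#' For each neuron, the expected activity per decoding time bin at each
#' position: summed training activity in the bin divided by the time spent
#' there, scaled by `tau_s`. Rates are floored at `eps_frac` times the
#' grand-mean rate so the log-likelihood stays finite.
#'
#' @param events neurons x time event matrix (or `event_set`).
#' @param track a [behavior_track()].
#' @param epochs running epochs; decoding and fitting are restricted to
#'   them.
#' @param train_laps lap ids used for training.
#' @param n_bins number of position bins (default 100, 1.5 cm bins).
#' @param tau_s decoding time-bin size (s); default one imaging frame.
#' @param eps_frac regularization floor as a fraction of the grand mean.
#' @return list of class `encoding_model` with `f` (neurons x bins expected
#'   activity per time bin), `tau_s`, `bin_centers_cm`.
#' @export
fit_encoding <- function(events, track, epochs = NULL, train_laps,
                         n_bins = 100, tau_s = NULL, eps_frac = 1e-3) {
  if (inherits(events, "event_set")) events <- events$events
  if (is.null(dim(events))) events <- matrix(events, nrow = 1)
  dt <- 1 / attr(track, "rate_hz")
  if (is.null(tau_s)) tau_s <- dt
  sel <- which(if (is.null(epochs)) rep(TRUE, nrow(track)) else epoch_mask(track, epochs))
  sel <- sel[track$lap_id[sel] %in% train_laps]
  if (length(sel) == 0) stop_invalid("empty training set")
  L <- attr(track, "track_length_cm")
  b <- position_bins(track$position_cm[sel], L, n_bins)
  time_b <- tabulate(b, nbins = n_bins) * dt
  sums <- matrix(0, nrow(events), n_bins)
  obs <- sort(unique(b))
  sums[, obs] <- t(rowsum(t(events[, sel, drop = FALSE]), b))
  f <- sweep(sums, 2, pmax(time_b, dt), "/") * tau_s
  f[, time_b == 0] <- 0
  floor_val <- eps_frac * mean(f)
  if (floor_val <= 0) floor_val <- eps_frac
  f <- pmax(f, floor_val)
  structure(list(f = f, tau_s = tau_s, n_bins = n_bins,
                 bin_centers_cm = (seq_len(n_bins) - 0.5) * L / n_bins,
                 track_length_cm = L, floor_val = floor_val),
            class = "encoding_model")
}

#' Decode position from population activity
#'
#' Evaluates, in the log domain, the posterior
#' \deqn{P(pos | a) = C \prod_i f_i(pos)^{a_i} e^{-\tau \sum_i f_i(pos)}}
#' over position bins for each time bin, where `a_i` is the (non-negative)
#' activity of neuron `i` and `f_i` its encoding model. Negative activity
#' values are clipped to 0. The decoded position is the bin with maximal
#' posterior probability; ties resolve to the lowest bin index.
#'
#' @param model an `encoding_model`.
#' @param activity time x neurons matrix (a vector decodes a single time
#'   bin).
#' @return list with `posterior` (time x bins, rows summing to 1),
#'   `decoded_bin` and `decoded_cm`.
#' @export
decode <- function(model, activity) {
  if (is.null(dim(activity))) activity <- matrix(activity, nrow = 1)
  if (ncol(activity) != nrow(model$f))
    stop_invalid("activity has %d neurons, model has %d",
                 ncol(activity), nrow(model$f))
  if (any(!is.finite(activity))) stop_invalid("non-finite activity")
  a <- pmax(activity, 0)
  # note f is per-time-bin expected activity, so tau is already absorbed
  lp <- a %*% log(model$f)
  lp <- sweep(lp, 2, colSums(model$f), "-")
  lp <- lp - logsumexp_rows(lp)
  posterior <- exp(lp)
  decoded_bin <- max.col(posterior, ties.method = "first")
  list(posterior = posterior, decoded_bin = decoded_bin,
       decoded_cm = model$bin_centers_cm[decoded_bin])
}

#' Decoding error
#'
#' Absolute difference between decoded and actual position, per sample,
#' with the median across samples. Linear by default; `circular = TRUE`
#' folds the error on the belt (`min(d, L - d)`). A Gaussian-smoothed copy
#' (SD = 10 time bins) is returned for display only.
#'
#' @param decoded_cm,actual_cm aligned position sequences (cm).
#' @param circular fold errors on the circular belt?
#' @param track_length_cm belt length, required when `circular`.
#' @return list with `error_cm`, `median_error_cm`, `error_smooth_cm`.
#' @export
decoding_error <- function(decoded_cm, actual_cm, circular = FALSE,
                           track_length_cm = NULL) {
  if (length(decoded_cm) != length(actual_cm))
    stop_invalid("decoded and actual lengths differ")
  err <- abs(decoded_cm - actual_cm)
  if (circular) {
    if (is.null(track_length_cm)) stop_invalid("track_length_cm required")
    err <- pmin(err, track_length_cm - err)
  }
  list(error_cm = err, median_error_cm = median(err),
       error_smooth_cm = smooth_rows_gaussian(err, 10))
}

#' Confusion matrix of decoded versus actual position
#'
#' Rows are actual bins, columns predicted bins; rows are normalized to
#' sum to 1 over visited bins.
#'
#' @param decoded_bin,actual_bin integer bin indices in `1..n_bins`.
#' @param n_bins number of position bins.
#' @return `n_bins x n_bins` matrix; unvisited rows are all-`NA`.
#' @export
confusion_matrix <- function(decoded_bin, actual_bin, n_bins) {
  m <- matrix(0, n_bins, n_bins)
  for (k in seq_along(actual_bin))
    m[actual_bin[k], decoded_bin[k]] <- m[actual_bin[k], decoded_bin[k]] + 1
  tot <- rowSums(m)
  m <- m / tot
  m[tot == 0, ] <- NA_real_
  m
}

#' Cross-validated position decoding
#'
#' Splits complete laps into train/test sets ("odd_even": odd-numbered laps
#' train, even-numbered laps test; "kfold5": 5 contiguous folds, each lap
#' tested exactly once with the remaining 80 percent training), fits the
#' encoding model on training running-epoch samples, decodes test samples,
#' and reports the error trace, its median, and the confusion matrix.
#' Optionally decodes from a random subset of neurons, mirroring
#' fixed-population-size comparisons.
#'
#' @param events neurons x time event matrix (or `event_set`).
#' @param track a [behavior_track()].
#' @param epochs running epochs.
#' @param scheme `"odd_even"` or `"kfold5"`.
#' @param n_neurons optional number of randomly selected neurons.
#' @param seed seed for the neuron subsample.
#' @param n_bins position bins.
#' @param tau_s decoding time-bin size (s); default one frame.
#' @param circular use circular error?
#' @return list of class `decode_result`: `decoded_cm`, `actual_cm`,
#'   `error_cm`, `median_error_cm`, `confusion`, `test_laps`, `n_neurons`,
#'   `chance_cm` (the half-belt chance reference, 75 cm on a 150 cm belt).
#' @export
cross_validate_decode <- function(events, track, epochs = NULL,
                                  scheme = c("odd_even", "kfold5"),
                                  n_neurons = NULL, seed = NULL,
                                  n_bins = 100, tau_s = NULL,
                                  circular = FALSE) {
  scheme <- match.arg(scheme)
  if (inherits(events, "event_set")) events <- events$events
  if (is.null(dim(events))) events <- matrix(events, nrow = 1)
  laps <- complete_laps(track)
  need <- if (scheme == "kfold5") 5 else 4
  if (length(laps) < need)
    stop_invalid("need at least %d complete laps for scheme '%s'", need, scheme)
  if (!is.null(n_neurons) && n_neurons < nrow(events)) {
    if (!is.null(seed)) set.seed(seed)
    keep <- sample.int(nrow(events), n_neurons)
    events <- events[keep, , drop = FALSE]
  }
  folds <- if (scheme == "odd_even") {
    list(list(train = laps[seq_along(laps) %% 2 == 1],
              test = laps[seq_along(laps) %% 2 == 0]))
  } else {
    grp <- cut(seq_along(laps), 5, labels = FALSE)
    lapply(1:5, function(k) list(train = laps[grp != k], test = laps[grp == k]))
  }
  sel_all <- which(if (is.null(epochs)) rep(TRUE, nrow(track)) else epoch_mask(track, epochs))
  L <- attr(track, "track_length_cm")
  dec <- act <- numeric(0)
  dec_bin <- act_bin <- integer(0)
  for (fold in folds) {
    model <- fit_encoding(events, track, epochs, fold$train, n_bins, tau_s)
    sel <- sel_all[track$lap_id[sel_all] %in% fold$test]
    if (length(sel) == 0) next
    d <- decode(model, t(events[, sel, drop = FALSE]))
    dec <- c(dec, d$decoded_cm)
    act <- c(act, track$position_cm[sel])
    dec_bin <- c(dec_bin, d$decoded_bin)
    act_bin <- c(act_bin, position_bins(track$position_cm[sel], L, n_bins))
  }
  err <- decoding_error(dec, act, circular = circular, track_length_cm = L)
  structure(list(decoded_cm = dec, actual_cm = act,
                 error_cm = err$error_cm,
                 median_error_cm = err$median_error_cm,
                 confusion = confusion_matrix(dec_bin, act_bin, n_bins),
                 test_laps = sort(unlist(lapply(folds, `[[`, "test"))),
                 scheme = scheme, n_neurons = nrow(events),
                 chance_cm = L / 2),
            class = "decode_result")
}
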