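# Behavioral segmentation: track container, lap segmentation, running
# epochs, occupancy and speed scores.

#' Behavior track container
#'
#' Time-aligned treadmill behavior: time, circular position, speed and lap
#' index. Speed, when not supplied, is estimated from wrap-corrected
#' position differences smoothed with a 0.5 s boxcar; laps are segmented
#' with [segment_laps()].
#'
#' @param t_s sample times (s), strictly increasing.
#' @param position_cm circular position on `[0, track_length_cm)`.
#' @param track_length_cm belt length (cm).
#' @param speed_cm_s optional speed (cm/s).
#' @param lap_id optional integer lap index per sample.
#' @param rate_hz optional sampling rate; inferred from `t_s` if missing.
#' @param cue_positions_cm,reward_position_cm optional belt layout metadata.
#' @return data frame of class `behavior_track` with columns `t_s`,
#'   `position_cm`, `speed_cm_s`, `lap_id` and layout attributes.
#' @export
behavior_track <- function(t_s, position_cm, track_length_cm,
                           speed_cm_s = NULL, lap_id = NULL, rate_hz = NULL,
                           cue_positions_cm = NULL,
                           reward_position_cm = NULL) {
  if (any(diff(t_s) <= 0)) stop_invalid("t_s must be strictly increasing")
  if (any(position_cm < 0 | position_cm >= track_length_cm))
    stop_invalid("position_cm must lie in [0, track_length_cm)")
  if (is.null(rate_hz)) rate_hz <- 1 / median(diff(t_s))
  if (is.null(speed_cm_s)) {
    dp <- diff(position_cm)
    dp <- ifelse(dp < -track_length_cm / 2, dp + track_length_cm,
                 ifelse(dp > track_length_cm / 2, dp - track_length_cm, dp))
    v <- c(dp / diff(t_s), 0)
    w <- max(1L, round(0.5 * rate_hz))
    speed_cm_s <- as.numeric(stats::filter(v, rep(1 / w, w), sides = 2))
    speed_cm_s[is.na(speed_cm_s)] <- v[is.na(speed_cm_s)]
  }
  if (is.null(lap_id)) lap_id <- segment_laps(position_cm, track_length_cm)
  df <- data.frame(t_s = t_s, position_cm = position_cm,
                   speed_cm_s = speed_cm_s, lap_id = lap_id)
  attr(df, "track_length_cm") <- track_length_cm
  attr(df, "rate_hz") <- rate_hz
  attr(df, "cue_positions_cm") <- cue_positions_cm
  attr(df, "reward_position_cm") <- reward_position_cm
  class(df) <- c("behavior_track", "data.frame")
  df
}

#' Segment laps from circular position
#'
#' The lap index starts at 1 and increments wherever the position drops by
#' more than half the track length between consecutive samples. The
#' half-track hysteresis makes the detector robust to position jitter at
#' the 0 cm seam. The first and last laps are typically partial
#' traversals; [complete_laps()] identifies the interior ones.
#'
#' @param position_cm circular position, or a `behavior_track`.
#' @param track_length_cm belt length; taken from the track if omitted.
#' @return integer lap index per sample.
#' @export
segment_laps <- function(position_cm, track_length_cm = NULL) {
  if (inherits(position_cm, "behavior_track")) {
    track_length_cm <- attr(position_cm, "track_length_cm")
    position_cm <- position_cm$position_cm
  }
  wraps <- c(FALSE, diff(position_cm) < -track_length_cm / 2)
  cumsum(wraps) + 1L
}

#' Identify complete laps
#'
#' Lap ids whose traversal both starts and ends at a belt wrap (i.e.,
#' excludes the partial first and last laps).
#'
#' @param track a `behavior_track`.
#' @return integer vector of complete lap ids (possibly empty).
#' @export
complete_laps <- function(track) {
  ids <- unique(track$lap_id)
  if (length(ids) <= 2) return(integer(0))
  ids[-c(1, length(ids))]
}

#' Detect running epochs
#'
#' Maximal runs of samples with speed at or above `min_speed`; epochs
#' separated by less than `merge_gap_s` are merged first, then epochs
#' shorter than `min_dur_s` are dropped. Intervals are half-open
#' `[start_s, end_s)` on the sample grid.
#'
#' @param track a `behavior_track`.
#' @param min_dur_s minimum epoch duration (s).
#' @param min_speed speed threshold (cm/s).
#' @param merge_gap_s gaps shorter than this are bridged (s).
#' @return data frame of class `running_epochs` with `start_s`, `end_s`.
#' @export
detect_running_epochs <- function(track, min_dur_s = 1.0, min_speed = 5.0,
                                  merge_gap_s = 0.5) {
  if (nrow(track) == 0)
    return(structure(data.frame(start_s = numeric(), end_s = numeric()),
                     class = c("running_epochs", "data.frame")))
  dt <- 1 / attr(track, "rate_hz")
  fast <- track$speed_cm_s >= min_speed
  r <- rle(fast)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- data.frame(start_s = track$t_s[starts[r$values]],
                     end_s = track$t_s[ends[r$values]] + dt)
  if (nrow(runs) > 1) {
    merged <- runs[1, ]
    for (k in 2:nrow(runs)) {
      if (runs$start_s[k] - merged$end_s[nrow(merged)] < merge_gap_s) {
        merged$end_s[nrow(merged)] <- runs$end_s[k]
      } else {
        merged <- rbind(merged, runs[k, ])
      }
    }
    runs <- merged
  }
  runs <- runs[runs$end_s - runs$start_s >= min_dur_s, , drop = FALSE]
  rownames(runs) <- NULL
  structure(runs, class = c("running_epochs", "data.frame"))
}

#' Per-sample mask of running-epoch membership
#'
#' @param track a `behavior_track`.
#' @param epochs a `running_epochs` data frame.
#' @return logical vector, `TRUE` where `start_s <= t < end_s` for some
#'   epoch.
#' @export
epoch_mask <- function(track, epochs) {
  m <- rep(FALSE, nrow(track))
  for (k in seq_len(nrow(epochs)))
    m <- m | (track$t_s >= epochs$start_s[k] & track$t_s < epochs$end_s[k])
  m
}

# Internal: 1-based half-open position bin index; position L maps to bin 1.
position_bins <- function(position_cm, track_length_cm, n_bins) {
  (floor(position_cm / track_length_cm * n_bins) %% n_bins) + 1L
}

#' Occupancy distribution over position bins
#'
#' Fraction of running-epoch time spent in each of `n_bins` half-open,
#' equal-width position bins, normalized to sum to 1.
#'
#' @param track a `behavior_track`.
#' @param epochs running epochs; `NULL` uses the whole session.
#' @param n_bins number of position bins (default 100, i.e. 1.5 cm bins on
#'   a 150 cm belt).
#' @return numeric vector of length `n_bins` summing to 1.
#' @export
occupancy <- function(track, epochs = NULL, n_bins = 100) {
  if (n_bins < 2) stop_invalid("n_bins must be >= 2")
  sel <- if (is.null(epochs)) rep(TRUE, nrow(track)) else epoch_mask(track, epochs)
  if (!any(sel)) stop_invalid("no running time in the selected epochs")
  L <- attr(track, "track_length_cm")
  b <- position_bins(track$position_cm[sel], L, n_bins)
  counts <- tabulate(b, nbins = n_bins)
  counts / sum(counts)
}

#' Speed score
#'
#' Pearson product-moment correlation between each neuron's instantaneous
#' deconvolved activity and the running speed; ranges from -1 to 1.
#' Constant inputs yield `NA`.
#'
#' @param events neurons x time matrix (or vector) of event amplitudes.
#' @param speed speed trace (cm/s), one value per sample.
#' @return per-neuron correlation vector.
#' @export
speed_score <- function(events, speed) {
  if (is.null(dim(events))) events <- matrix(events, nrow = 1)
  if (ncol(events) != length(speed)) stop_invalid("events/speed lengths differ")
  if (length(speed) < 2) stop_invalid("need at least 2 samples")
  apply(events, 1, function(x) {
    if (sd(x) == 0 || sd(speed) == 0) return(NA_real_)
    cor(x, speed)
  })
}
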