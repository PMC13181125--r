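# Widefield Fourier retinotopy: min-max contrast enhancement, pixel-wise
# DFT at the stimulus frequency, HSV encoding of amplitude/phase maps.

# Internal: coerce a movie to a frames x pixels matrix plus dims.
movie_as_matrix <- function(movie) {
  d <- dim(movie)
  stopifnot(length(d) == 3)
  list(m = matrix(movie, d[1], d[2] * d[3]), h = d[2], w = d[3],
       n_frames = d[1])
}

#' Min-max contrast enhancement
#'
#' Per pixel, `(x - rollingmin) / (rollingmax - rollingmin + delta)` over a
#' sliding window, enhancing temporal contrast. Constant pixels map to 0
#' (the `delta` guard) and the output is invariant to per-pixel positive
#' scaling.
#'
#' @param movie array frames x height x width.
#' @param rate_hz frame rate; taken from the movie attribute if present.
#' @param window_s window length (s).
#' @param delta small positive guard.
#' @return enhanced movie of the same shape.
#' @export
minmax_contrast <- function(movie, rate_hz = attr(movie, "rate_hz"),
                            window_s = 10, delta = 1e-12) {
  mm <- movie_as_matrix(movie)
  w <- as.integer(round(window_s * rate_hz))
  if (w < 3) stop_invalid("window must cover at least 3 samples")
  out <- mm$m
  for (p in seq_len(ncol(out))) {
    lo <- run_min_c(out[, p], w)
    hi <- run_max_c(out[, p], w)
    out[, p] <- (out[, p] - lo) / (hi - lo + delta)
  }
  res <- array(out, c(mm$n_frames, mm$h, mm$w))
  attributes(res)[c("rate_hz", "stim_freq_hz")] <-
    attributes(movie)[c("rate_hz", "stim_freq_hz")]
  res
}

#' Pixel-wise Fourier retinotopic map
#'
#' Discrete Fourier transform along the temporal axis of a trial-averaged
#' movie, evaluated at the stimulus frequency. For a pixel
#' `baseline + A cos(2 pi f t - phi)`, the recovered amplitude is `A` and
#' the recovered phase is `phi` (positive phase = later response). When
#' the movie does not cover an integer number of stimulus cycles a Hann
#' window is applied with a warning.
#'
#' @param movie array frames x height x width (trial-averaged).
#' @param stim_freq_hz stimulus frequency (Hz).
#' @param rate_hz frame rate.
#' @return list of class `retinotopy_map` with `amplitude` (height x
#'   width, in movie units), `phase` (radians in `[-pi, pi)`),
#'   `amplitude_rel` (amplitude / per-pixel temporal mean) and
#'   `stim_freq_hz`.
#' @export
fourier_map <- function(movie, stim_freq_hz = attr(movie, "stim_freq_hz"),
                        rate_hz = attr(movie, "rate_hz")) {
  mm <- movie_as_matrix(movie)
  n <- mm$n_frames
  t <- (seq_len(n) - 1) / rate_hz
  cycles <- stim_freq_hz * n / rate_hz
  win <- rep(1, n)
  if (abs(cycles - round(cycles)) > 1e-8) {
    warning("movie does not cover an integer number of stimulus cycles; applying a Hann window")
    win <- 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
  }
  basis <- exp(-2i * pi * stim_freq_hz * t) * win
  coef <- as.vector(basis %*% mm$m) / sum(win)
  amp <- 2 * Mod(coef)
  phase <- -Arg(coef)
  phase <- ((phase + pi) %% (2 * pi)) - pi
  px_mean <- colMeans(mm$m)
  rel <- ifelse(px_mean > 0, amp / px_mean, NA_real_)
  structure(list(amplitude = matrix(amp, mm$h, mm$w),
                 phase = matrix(phase, mm$h, mm$w),
                 amplitude_rel = matrix(rel, mm$h, mm$w),
                 stim_freq_hz = stim_freq_hz),
            class = "retinotopy_map")
}

#' HSV encoding of a retinotopy map
#'
#' Hue encodes phase (circular: phase 0 and 2 pi give the same hue), value
#' encodes amplitude normalized to its maximum, saturation is 1. Zero
#' amplitude gives black.
#'
#' @param map a `retinotopy_map`.
#' @return matrix of hex color strings (height x width).
#' @export
hsv_encode <- function(map) {
  hue <- (map$phase / (2 * pi)) %% 1
  amax <- max(map$amplitude, na.rm = TRUE)
  val <- if (amax > 0) map$amplitude / amax else map$amplitude * 0
  cols <- hsv(h = as.vector(hue), s = 1, v = pmin(1, pmax(0, as.vector(val))))
  matrix(cols, nrow(map$phase), ncol(map$phase))
}
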