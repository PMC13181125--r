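# Plain-text I/O for the pipeline's tabular interfaces. Trace matrices use
# a wide CSV (one row per neuron per channel); behavior, stimulus, cell and
# stats tables are ordinary CSVs with documented columns (times in seconds,
# positions in cm).

#' Write / read a trace set as CSV
#'
#' The CSV stores one row per neuron and channel with columns
#' `neuron_id, channel` (`F_cell` or `F_np`) followed by the samples; the
#' sampling rate is kept in a `# rate_hz:` header comment.
#'
#' @param traces a [trace_set()].
#' @param path output file.
#' @export
write_trace_set <- function(traces, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# rate_hz: %.10g", traces$rate_hz), con)
  df <- rbind(
    data.frame(neuron_id = traces$neuron_ids, channel = "F_cell",
               traces$F_cell, check.names = FALSE),
    data.frame(neuron_id = traces$neuron_ids, channel = "F_np",
               traces$F_np, check.names = FALSE))
  write.csv(df, con, row.names = FALSE)
}

#' @rdname write_trace_set
#' @param path CSV file written by [write_trace_set()].
#' @return a [trace_set()].
#' @export
read_trace_set <- function(path) {
  hdr <- readLines(path, n = 1)
  rate <- as.numeric(sub("# rate_hz:", "", hdr))
  df <- read.csv(path, comment.char = "#", check.names = FALSE)
  cell <- df[df$channel == "F_cell", , drop = FALSE]
  np <- df[df$channel == "F_np", , drop = FALSE]
  ids <- cell$neuron_id
  trace_set(as.matrix(cell[, -(1:2)]), as.matrix(np[, -(1:2)]),
            rate_hz = rate, neuron_ids = ids)
}

#' Write / read a behavior track as CSV
#'
#' Columns `t_s, position_cm, speed_cm_s, lap_id`; the track length is
#' kept in a header comment.
#'
#' @param track a [behavior_track()].
#' @param path file path.
#' @export
write_behavior <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# track_length_cm: %.10g", attr(track, "track_length_cm")), con)
  write.csv(as.data.frame(track), con, row.names = FALSE)
}

#' @rdname write_behavior
#' @param track_length_cm override for files without the header comment.
#' @return a [behavior_track()].
#' @export
read_behavior <- function(path, track_length_cm = NULL) {
  hdr <- readLines(path, n = 1)
  if (grepl("track_length_cm", hdr))
    track_length_cm <- as.numeric(sub("# track_length_cm:", "", hdr))
  if (is.null(track_length_cm)) stop_invalid("track_length_cm unknown")
  df <- read.csv(path, comment.char = "#")
  behavior_track(df$t_s, df$position_cm, track_length_cm,
                 speed_cm_s = df$speed_cm_s, lap_id = df$lap_id)
}

#' Read a stimulus table CSV
#'
#' Expects columns `onset_s, direction_deg, sf_cpd, tf_hz, repetition`.
#'
#' @param path CSV file.
#' @return validated data frame.
#' @export
read_stimulus_table <- function(path) {
  df <- read.csv(path)
  need <- c("onset_s", "direction_deg", "sf_cpd", "tf_hz", "repetition")
  if (!all(need %in% names(df))) stop_invalid("stimulus table lacks required columns")
  if (any(diff(df$onset_s) <= 0)) stop_invalid("onsets must be strictly increasing")
  df
}

#' Read a labeled-cells table CSV
#'
#' Expects columns `cell_id, acronym, target` and optional stereotaxic
#' coordinates `ap_mm, dv_mm, ml_mm`.
#'
#' @param path CSV file.
#' @return validated data frame.
#' @export
read_cells_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("acronym", "target") %in% names(df)))
    stop_invalid("cells table lacks required columns")
  df
}
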