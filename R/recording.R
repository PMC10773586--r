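#' Annotated multichannel EEG recording
#'
#' Container for a scalp EEG recording: a channels-by-time sample matrix in
#' microvolts, its sampling rate, channel labels, and seizure annotations as
#' half-open intervals `[onset, offset)` in seconds from recording start.
#'
#' @param samples numeric matrix, channels x time, in microvolts.
#' @param rate sampling rate in Hz (> 0).
#' @param channel_labels character vector, one label per channel.
#' @param annotations two-column matrix or data frame of seizure intervals
#'   (onset_s, offset_s), sorted, non-overlapping, within the record duration.
#'   May have zero rows.
#' @param subject_id subject identifier string.
#'
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(samples, rate, channel_labels = NULL,
                          annotations = NULL, subject_id = "synthetic") {
  if (!is.matrix(samples) || !is.numeric(samples)) {
    stop("`samples` must be a numeric channels x time matrix", call. = FALSE)
  }
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0) {
    stop("`rate` must be a single positive number (Hz)", call. = FALSE)
  }
  n_ch <- nrow(samples)
  if (is.null(channel_labels)) {
    channel_labels <- sprintf("CH%02d", seq_len(n_ch))
  }
  if (length(channel_labels) != n_ch) {
    stop("`channel_labels` length must equal nrow(samples)", call. = FALSE)
  }
  ann <- normalize_annotations(annotations, duration = ncol(samples) / rate)
  structure(
    list(samples = samples, rate = rate,
         channel_labels = as.character(channel_labels),
         annotations = ann, subject_id = subject_id),
    class = "eeg_recording")
}

# validate/sort seizure intervals; returns a data.frame(onset, offset)
normalize_annotations <- function(annotations, duration) {
  if (is.null(annotations) || NROW(annotations) == 0L) {
    return(data.frame(onset = numeric(0), offset = numeric(0)))
  }
  ann <- as.data.frame(annotations)[, 1:2]
  names(ann) <- c("onset", "offset")
  if (any(!is.finite(ann$onset)) || any(!is.finite(ann$offset))) {
    stop("annotations must be finite numbers", call. = FALSE)
  }
  if (any(ann$offset <= ann$onset)) {
    stop("annotation offsets must exceed onsets", call. = FALSE)
  }
  if (any(ann$onset < 0) || any(ann$offset > duration + 1e-9)) {
    stop("annotations must lie within [0, duration]", call. = FALSE)
  }
  ann <- ann[order(ann$onset), , drop = FALSE]
  if (nrow(ann) > 1L && any(ann$onset[-1L] < ann$offset[-nrow(ann)])) {
    stop("annotations must be non-overlapping", call. = FALSE)
  }
  rownames(ann) <- NULL
  ann
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s: %d channels x %d samples @ %g Hz (%.1f s), %d seizure annotation(s)\n",
              x$subject_id, nrow(x$samples), ncol(x$samples), x$rate,
              ncol(x$samples) / x$rate, nrow(x$annotations)))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param recording an [eeg_recording()].
#' @return Length in seconds.
#' @export
recording_duration <- function(recording) {
  ncol(recording$samples) / recording$rate
}
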