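#' Preprocessing configuration
#'
#' Settings for the standard EEG cleaning and windowing chain: band-pass
#' noise reduction, resampling to a common rate, and cutting balanced 2-s
#' seizure/interictal segments.
#'
#' @param band numeric length-2, band-pass corner frequencies in Hz
#'   (default `c(0.5, 40)`, the range holding most seizure activity).
#' @param target_rate common sampling rate in Hz (default 256).
#' @param window_seconds analysis window length (default 2).
#' @param stride_seconds window stride (default 2, i.e. non-overlapping).
#' @param channel_whitelist optional character vector of channel labels to
#'   keep, in order.
#' @param interictal_buffer_s minimum distance (s) of an interictal window
#'   from any seizure interval (default 300, guarding against pre-ictal
#'   contamination).
#' @param seed integer seed for the interictal subsample.
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(band = c(0.5, 40), target_rate = 256,
                              window_seconds = 2, stride_seconds = 2,
                              channel_whitelist = NULL,
                              interictal_buffer_s = 300, seed = 1L) {
  if (length(band) != 2 || band[1] <= 0 || band[2] <= band[1] ||
      band[2] >= target_rate / 2) {
    stop("band must satisfy 0 < low < high < target_rate/2", call. = FALSE)
  }
  if (interictal_buffer_s < 0) stop("buffer must be >= 0", call. = FALSE)
  structure(
    list(band = band, target_rate = target_rate,
         window_seconds = window_seconds, stride_seconds = stride_seconds,
         channel_whitelist = channel_whitelist,
         interictal_buffer_s = interictal_buffer_s, seed = as.integer(seed)),
    class = "preprocess_config")
}

#' The 19-channel bipolar montage shared across CHB-MIT-style recordings
#'
#' Channel labels common to recordings that mix montages; selecting these
#' keeps channel identity consistent across files.
#' @return Character vector of 19 bipolar channel labels.
#' @export
chb_channel_whitelist <- function() {
  c("FP1-F7", "F7-T7", "T7-P7", "P7-O1", "FP1-F3", "F3-C3", "C3-P3",
    "P3-O1", "FP2-F4", "F4-C4", "C4-P4", "P4-O2", "FP2-F8", "F8-T8",
    "P8-O2", "P7-T7", "T7-FT9", "FT9-FT10", "FT10-T8")
}

#' Select and reorder channels
#'
#' @param recording an [eeg_recording()].
#' @param whitelist channel labels to keep, in the desired order; every label
#'   must be present in the recording.
#' @return The recording restricted to exactly the whitelist channels.
#' @export
select_channels <- function(recording, whitelist) {
  idx <- match(whitelist, recording$channel_labels)
  if (anyNA(idx)) {
    stop("channel(s) not present in recording: ",
         paste(whitelist[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  recording$samples <- recording$samples[idx, , drop = FALSE]
  recording$channel_labels <- recording$channel_labels[idx]
  recording
}

#' Zero-phase band-pass filter
#'
#' 4th-order Butterworth band-pass applied forward-backward
#' (`signal::filtfilt`), so the filter is zero-phase and event timing is
#' preserved for latency measurement.
#'
#' @param recording an [eeg_recording()].
#' @param low,high corner frequencies in Hz; must satisfy
#'   `0 < low < high < rate/2`.
#' @return The filtered recording (same shape and rate).
#' @export
bandpass <- function(recording, low = 0.5, high = 40) {
  nyq <- recording$rate / 2
  if (low <= 0 || high <= low || high >= nyq) {
    stop("invalid band: need 0 < low < high < Nyquist (", nyq, " Hz)",
         call. = FALSE)
  }
  bf <- signal::butter(4, c(low, high) / nyq, type = "pass")
  recording$samples <- t(apply(recording$samples, 1, function(x) {
    signal::filtfilt(bf, x)
  }))
  recording
}

#' Resample a recording to a target rate
#'
#' Fourier-domain resampling: the spectrum is truncated (down-sampling,
#' which is an ideal anti-alias filter) or zero-padded (up-sampling) and
#' inverse-transformed, so band-limited content is reproduced without phase
#' delay. Annotations are in seconds and carry over unchanged.
#'
#' @param recording an [eeg_recording()].
#' @param target_rate new sampling rate in Hz.
#' @return The resampled recording.
#' @export
resample_recording <- function(recording, target_rate = 256) {
  if (target_rate <= 0) stop("target_rate must be > 0", call. = FALSE)
  if (target_rate == recording$rate) return(recording)
  n_out <- round(ncol(recording$samples) * target_rate / recording$rate)
  recording$samples <- t(apply(recording$samples, 1, fft_resample,
                               n_out = n_out))
  recording$rate <- target_rate
  recording
}

# spectral truncation / zero-padding resampler
fft_resample <- function(x, n_out) {
  n <- length(x)
  if (n_out == n) return(x)
  X <- stats::fft(x)
  Y <- complex(n_out)
  half <- floor(min(n, n_out) / 2)
  Y[1:(half + 1)] <- X[1:(half + 1)]
  if (half >= 1) Y[n_out - seq_len(half) + 1] <- X[n - seq_len(half) + 1]
  Re(stats::fft(Y, inverse = TRUE)) / n
}

#' Cut balanced seizure/interictal segments
#'
#' Seizure windows tile each annotated interval with the configured stride;
#' a window counts as seizure only when fully inside an interval (windows
#' straddling a boundary are discarded). Interictal candidate windows tile
#' the whole recording and must lie at least `interictal_buffer_s` from every
#' seizure interval; a seeded uniform subsample (without replacement) brings
#' the interictal count down to the seizure count, so the two classes are
#' balanced.
#'
#' @param recording an [eeg_recording()] already at the target rate.
#' @param config a [preprocess_config()].
#' @return A list of segments; each segment is a list with `samples`
#'   (channels x window matrix), `start_time` (s), `label` ("seizure" or
#'   "interictal"), `subject_id`, and `event_index` (which seizure event a
#'   seizure segment belongs to; `NA` for interictal).
#' @export
cut_segments <- function(recording, config = preprocess_config()) {
  w_s <- config$window_seconds
  stride <- config$stride_seconds
  rate <- recording$rate
  w_n <- round(w_s * rate)
  dur <- recording_duration(recording)
  ann <- recording$annotations

  grab <- function(t0, label, event_index) {
    i0 <- round(t0 * rate)
    list(samples = recording$samples[, (i0 + 1):(i0 + w_n), drop = FALSE],
         start_time = t0, label = label,
         subject_id = recording$subject_id, event_index = event_index)
  }

  seizure <- list()
  for (ev in seq_len(nrow(ann))) {
    t0 <- ann$onset[ev]
    while (t0 + w_s <= ann$offset[ev] + 1e-9) {
      seizure[[length(seizure) + 1L]] <- grab(t0, "seizure", ev)
      t0 <- t0 + stride
    }
  }
  n_seiz <- length(seizure)
  if (nrow(ann) > 0 && n_seiz == 0L) {
    warning("all seizure intervals shorter than the window; 0 seizure segments")
  }

  starts <- seq(0, dur - w_s + 1e-9, by = stride)
  clear <- rep(TRUE, length(starts))
  buf <- config$interictal_buffer_s
  for (ev in seq_len(nrow(ann))) {
    clear <- clear & (starts + w_s <= ann$onset[ev] - buf |
                        starts >= ann$offset[ev] + buf)
  }
  pool <- starts[clear]
  if (length(pool) < n_seiz) {
    stop(sprintf(
      "interictal pool (%d windows) smaller than seizure count (%d)",
      length(pool), n_seiz), call. = FALSE)
  }
  keep <- if (n_seiz > 0) {
    sort(with_seed(config$seed, sample(length(pool), n_seiz)))
  } else integer(0)
  interictal <- lapply(pool[keep], grab, label = "interictal",
                       event_index = NA_integer_)

  c(seizure, interictal)
}

#' Labels of a segment list
#' @param segments list produced by [cut_segments()].
#' @return Character vector of per-segment labels.
#' @export
segment_labels <- function(segments) {
  vapply(segments, `[[`, "", "label")
}
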