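#' Configuration for the synthetic EEG generator
#'
#' Describes a synthetic multichannel scalp recording: pink-noise background
#' with an alpha-band (10 Hz) component, plus rhythmic high-amplitude
#' spike-wave discharge inside annotated seizure intervals. The generator is
#' deliberately simple -- it emulates the amplitude and rhythm contrast between
#' ictal and interictal EEG, not scalp physiology.
#'
#' @param n_channels number of channels (default 19, a standard 10-20 montage
#'   count).
#' @param rate sampling rate in Hz (default 256).
#' @param duration recording length in seconds.
#' @param seizure_intervals two-column matrix/data frame of (onset_s,
#'   offset_s) seizure intervals; sorted, non-overlapping, within
#'   `[0, duration]`. May be empty.
#' @param background list with `pink_exponent` (spectral slope of the 1/f
#'   background, default 1), `rms` (background RMS amplitude in microvolts,
#'   default 20) and `alpha_amp` (10 Hz component amplitude in microvolts,
#'   default 10).
#' @param seizure_model list with `freq` (discharge rhythm in Hz, default 4),
#'   `amplitude` (multiplier on the background RMS, default 5, must be > 1)
#'   and `phase_jitter_sd` (per-channel phase jitter, radians, default 0.3).
#' @param noise_sd broadband sensor noise SD in microvolts (default 2).
#' @param seed integer RNG seed.
#'
#' @return A list of class `synthesis_config`.
#' @seealso [generate_recording()]
#' @export
synthesis_config <- function(n_channels = 19, rate = 256, duration = 60,
                             seizure_intervals = NULL,
                             background = list(),
                             seizure_model = list(),
                             noise_sd = 2, seed = 1L) {
  bg <- utils::modifyList(
    list(pink_exponent = 1, rms = 20, alpha_amp = 10), background)
  sz <- utils::modifyList(
    list(freq = 4, amplitude = 5, phase_jitter_sd = 0.3), seizure_model)
  if (sz$amplitude <= 1) {
    stop("seizure amplitude multiplier must be > 1", call. = FALSE)
  }
  ann <- tryCatch(
    normalize_annotations(seizure_intervals, duration),
    error = function(e) stop("invalid seizure_intervals: ",
                             conditionMessage(e), call. = FALSE))
  structure(
    list(n_channels = n_channels, rate = rate, duration = duration,
         seizure_intervals = ann, background = bg, seizure_model = sz,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "synthesis_config")
}

# run expr under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# one channel of 1/f^exponent noise with unit RMS, via spectral shaping
pink_noise <- function(n, exponent) {
  white <- stats::rnorm(n)
  spec <- stats::fft(white)
  f <- c(1, seq_len(n - 1))                # DC handled separately
  f <- pmin(f, n - f + 1)                  # mirror for negative frequencies
  scale <- f^(-exponent / 2)
  scale[1] <- 0                            # remove DC
  x <- Re(stats::fft(spec * scale, inverse = TRUE)) / n
  x / sqrt(mean(x^2))
}

# spike-wave-like periodic discharge, unit RMS: fundamental plus two
# harmonics sharpen the waveform toward a spike-and-wave morphology
spike_wave <- function(t, freq, phase) {
  w <- sin(2 * pi * freq * t + phase) +
    0.5 * sin(2 * pi * 2 * freq * t + 2 * phase) +
    0.25 * sin(2 * pi * 3 * freq * t + 3 * phase)
  w / sqrt(mean(w^2))
}

#' Generate a synthetic annotated EEG recording
#'
#' Draws a pink-noise + alpha background on every channel and superimposes a
#' rhythmic spike-wave discharge, `amplitude` times the background RMS, inside
#' each annotated seizure interval (with a 0.25 s raised-cosine onset/offset
#' ramp and per-channel phase jitter). Identical seeds give identical samples.
#'
#' @param config a [synthesis_config()].
#' @return An [eeg_recording()] carrying the configured annotations.
#' @examples
#' cfg <- synthesis_config(n_channels = 4, rate = 64, duration = 20,
#'                         seizure_intervals = cbind(8, 12), seed = 42)
#' rec <- generate_recording(cfg)
#' rec
#' @export
generate_recording <- function(config) {
  stopifnot(inherits(config, "synthesis_config"))
  n <- round(config$duration * config$rate)
  t <- (seq_len(n) - 1) / config$rate
  bg <- config$background
  sz <- config$seizure_model

  # seizure envelope shared by all channels: 1 inside intervals, cosine ramps
  envelope <- numeric(n)
  ramp_s <- 0.25
  for (r in seq_len(nrow(config$seizure_intervals))) {
    onset <- config$seizure_intervals$onset[r]
    offset <- config$seizure_intervals$offset[r]
    inside <- t >= onset & t < offset
    e <- numeric(n)
    e[inside] <- 1
    rise <- inside & t < onset + ramp_s
    fall <- inside & t >= offset - ramp_s
    e[rise] <- 0.5 - 0.5 * cos(pi * (t[rise] - onset) / ramp_s)
    e[fall] <- 0.5 - 0.5 * cos(pi * (offset - t[fall]) / ramp_s)
    envelope <- pmax(envelope, e)
  }

  samples <- with_seed(config$seed, {
    out <- matrix(0, config$n_channels, n)
    for (ch in seq_len(config$n_channels)) {
      chan <- bg$rms * pink_noise(n, bg$pink_exponent) +
        bg$alpha_amp * sin(2 * pi * 10 * t + stats::runif(1, 0, 2 * pi))
      phase <- stats::rnorm(1, sd = sz$phase_jitter_sd)
      discharge <- sz$amplitude * bg$rms * spike_wave(t, sz$freq, phase)
      chan <- chan + envelope * discharge + stats::rnorm(n, sd = config$noise_sd)
      out[ch, ] <- chan
    }
    out
  })

  eeg_recording(samples, rate = config$rate,
                channel_labels = sprintf("CH%02d", seq_len(config$n_channels)),
                annotations = config$seizure_intervals,
                subject_id = sprintf("synthetic-seed%d", config$seed))
}

#' Reference synthetic seizure study
#'
#' The package's canonical desk-scale study: a 19-channel, 256 Hz, 2400 s
#' recording with four 50 s seizure events (at 300, 700, 1100 and 1500 s),
#' yielding 100 seizure and (after balancing) 100 interictal 2 s segments
#' under the default preprocessing configuration.
#'
#' @param seed integer RNG seed.
#' @return A [synthesis_config()].
#' @export
study_config <- function(seed = 1L) {
  onsets <- c(300, 700, 1100, 1500)
  synthesis_config(
    n_channels = 19, rate = 256, duration = 2400,
    seizure_intervals = cbind(onsets, onsets + 50),
    seed = seed)
}

#' The five-point planar example cloud
#'
#' A fixed five-point planar point cloud, a standard worked example for
#' Vietoris-Rips filtrations: as epsilon grows the five components merge
#' (the closest pair at distance 1, the next at sqrt(2), ...) and a single
#' 1-cycle is born at sqrt(5) and filled at 3.
#'
#' @return A [point_cloud] with points (2,2), (0,3), (-1,2), (0,0), (1,0),
#'   in that order.
#' @examples
#' pc <- five_point_cloud()
#' betti_numbers(vr_persistence(pc), eps = 1.44)
#' @export
five_point_cloud <- function() {
  pts <- rbind(c(2, 2), c(0, 3), c(-1, 2), c(0, 0), c(1, 0))
  new_point_cloud(pts, n_channels = 5L, n_folds = 0L, source = "fixture")
}
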