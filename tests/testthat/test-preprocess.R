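test_that("channel selection keeps whitelist channels in order", {
  rec <- small_recording()
  rec$channel_labels <- c("FP1-F7", "F7-T7", "T7-P7", "P7-O1")
  sel <- select_channels(rec, c("T7-P7", "FP1-F7"))
  expect_identical(sel$channel_labels, c("T7-P7", "FP1-F7"))
  expect_identical(sel$samples[1, ], rec$samples[3, ])

  # identity whitelist
  same <- select_channels(rec, rec$channel_labels)
  expect_identical(same$samples, rec$samples)

  expect_error(select_channels(rec, c("FP1-F7", "XX-YY")), "XX-YY")
})

test_that("the montage whitelist selects 19 channels from a 23-channel file", {
  labels23 <- c(chb_channel_whitelist(), "EXTRA1", "EXTRA2", "EXTRA3",
                "EXTRA4")
  set.seed(1)
  rec <- eeg_recording(matrix(rnorm(23 * 64), 23, 64), rate = 64,
                       channel_labels = sample(labels23))
  sel <- select_channels(rec, chb_channel_whitelist())
  expect_equal(nrow(sel$samples), 19)
  expect_identical(sel$channel_labels, chb_channel_whitelist())
})

test_that("band-pass keeps in-band and rejects out-of-band sinusoids", {
  # steady-state response oracle: long sinusoids, filter transients excluded
  t <- (0:8191) / 256
  core <- 1024:7168
  mk <- function(f) eeg_recording(matrix(sin(2 * pi * f * t), 1), rate = 256)
  rms <- function(r) sqrt(mean(r$samples[1, core]^2))
  expect_gt(rms(bandpass(mk(10), 0.5, 40)) / rms(mk(10)), 0.9)
  expect_lt(rms(bandpass(mk(50), 0.5, 40)) / rms(mk(50)), 0.1)
  zero <- bandpass(eeg_recording(matrix(0, 2, 512), 256), 0.5, 40)
  expect_equal(max(abs(zero$samples)), 0)
  expect_error(bandpass(mk(10), 0.5, 200), "Nyquist")
})

test_that("resampling scales counts and preserves sinusoids", {
  t <- (0:5119) / 512
  rec <- eeg_recording(matrix(sin(2 * pi * 5 * t), 1), rate = 512)
  down <- resample_recording(rec, 256)
  expect_equal(ncol(down$samples), 2560)
  expect_equal(down$rate, 256)
  # closed-form oracle: the same sinusoid sampled at the target rate
  oracle <- sin(2 * pi * 5 * (0:2559) / 256)
  core <- 100:2460  # ignore filter edge transients
  expect_gt(stats::cor(down$samples[1, core], oracle[core]), 0.99)

  same <- resample_recording(rec, 512)
  expect_identical(same$samples, rec$samples)
})

test_that("segment cutting tiles seizures and balances classes", {
  rec <- small_recording(duration = 200, intervals = cbind(60, 70))
  segs <- cut_segments(rec, small_preproc())
  lab <- segment_labels(segs)
  expect_equal(sum(lab == "seizure"), 5)       # 10 s interval, 2 s stride
  expect_equal(sum(lab == "interictal"), 5)    # balanced
  expect_true(all(vapply(segs, function(s) ncol(s$samples), 0) == 128))

  # stride 1 s on a 10 s interval: floor((L-W)/S)+1 = 9 windows
  segs1 <- cut_segments(rec, small_preproc(stride_seconds = 1))
  expect_equal(sum(segment_labels(segs1) == "seizure"), 9)

  # sub-window interval yields no seizure segments, with a warning
  tiny <- small_recording(duration = 60, intervals = cbind(30, 31))
  expect_warning(segs0 <- cut_segments(tiny, small_preproc()), "shorter")
  expect_equal(length(segs0), 0)
})

test_that("segment labels are consistent with the annotations", {
  rec <- small_recording(duration = 300,
                         intervals = cbind(c(50, 120), c(74, 150)))
  segs <- cut_segments(rec, small_preproc())
  for (s in segs) {
    inside <- any(s$start_time >= rec$annotations$onset - 1e-9 &
                    s$start_time + 2 <= rec$annotations$offset + 1e-9)
    expect_equal(s$label == "seizure", inside)
    if (s$label == "seizure") {
      ev <- s$event_index
      expect_true(s$start_time >= rec$annotations$onset[ev] &&
                    s$start_time + 2 <= rec$annotations$offset[ev])
    }
  }
})

test_that("an undersized interictal pool raises a balance error", {
  rec <- small_recording(duration = 60, intervals = cbind(10, 50))
  expect_error(cut_segments(rec, small_preproc()),
               "interictal pool \\(\\d+ windows\\) smaller than seizure count")
})

test_that("filtering commutes with segmentation on the same data path", {
  rec <- small_recording(duration = 100, intervals = cbind(40, 50))
  filt <- bandpass(rec, 0.5, 30)
  segs <- cut_segments(filt, small_preproc())
  seg1 <- segs[[1]]
  i0 <- round(seg1$start_time * rec$rate)
  expect_equal(seg1$samples,
               filt$samples[, (i0 + 1):(i0 + 128), drop = FALSE])
})
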