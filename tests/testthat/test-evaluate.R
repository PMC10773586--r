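test_that("metric formulas reproduce reference confusion counts", {
  perfect <- compute_metrics(c(TP = 50, FP = 0, TN = 50, FN = 0))
  expect_equal(unclass(perfect)[1:6],
               c(Acc = 100, Sens = 100, Spec = 100, Pre = 100, F1 = 100,
                 mAcc = 100))

  m <- compute_metrics(c(TP = 49, FP = 0, TN = 51, FN = 2))
  expect_equal(unclass(m)[1:6],
               c(Acc = 98.04, Sens = 96.08, Spec = 100, Pre = 100, F1 = 98,
                 mAcc = 98.04))

  degenerate <- compute_metrics(c(TP = 0, FP = 0, TN = 10, FN = 10))
  expect_equal(degenerate[["Sens"]], 0)
  expect_equal(degenerate[["Spec"]], 100)
  expect_equal(degenerate[["mAcc"]], 50)
  expect_true(is.na(degenerate[["Pre"]]))       # 0/0 flagged, not NaN

  expect_error(compute_metrics(c(TP = 0, FP = 0, TN = 0, FN = 0)), "zero")
})

test_that("metrics match an independent recomputation from label pairs", {
  set.seed(12)
  truth <- sample(c("seizure", "interictal"), 80, replace = TRUE)
  pred <- ifelse(runif(80) < 0.8, truth,
                 ifelse(truth == "seizure", "interictal", "seizure"))
  m <- compute_metrics(confusion_counts(truth, pred))
  expect_equal(m[["Acc"]], round(mean(truth == pred) * 100, 2))
  expect_equal(m[["Sens"]],
               round(mean(pred[truth == "seizure"] == "seizure") * 100, 2))
  expect_equal(m[["Spec"]],
               round(mean(pred[truth == "interictal"] == "interictal") * 100,
                     2))
})

test_that("balanced test sets give Acc equal to mAcc", {
  m <- compute_metrics(c(TP = 40, FN = 10, TN = 35, FP = 15))
  expect_equal(m[["Acc"]], m[["mAcc"]])
})

test_that("detection latency is the first positive segment minus onset", {
  ann <- data.frame(onset = 3527, offset = 3607)
  pred <- data.frame(start_time = seq(3527, 3605, by = 2),
                     label = "interictal")
  pred$label[pred$start_time >= 3575] <- "seizure"
  res <- event_detection(pred, ann)
  expect_true(res$detected)
  expect_equal(res$latency_s, 48)

  pred$label <- "seizure"                        # first segment positive
  expect_equal(event_detection(pred, ann)$latency_s, 0)

  pred$label <- "interictal"                     # never positive
  res0 <- event_detection(pred, ann)
  expect_false(res0$detected)
  expect_true(is.na(res0$latency_s))

  expect_error(event_detection(pred, data.frame(onset = 10, offset = 20)),
               "no test segments")
})

test_that("experiment 1 splits 70/30 per class, reproducibly", {
  rec <- small_recording(duration = 260, intervals = cbind(c(30, 90),
                                                           c(70, 130)))
  segs <- cut_segments(rec, small_preproc())
  cc <- classifier_config(input_size = 16, epochs = 60, seed = 2)
  fc <- filtration_config(n_folds = 2)
  rc <- render_config(size = 32)
  r1 <- run_experiment1(segs, cc, fc, rc, seed = 5)
  r2 <- run_experiment1(segs, cc, fc, rc, seed = 5)
  expect_identical(r1$train_idx, r2$train_idx)
  expect_identical(unclass(r1$metrics), unclass(r2$metrics))

  labels <- segment_labels(segs)
  for (cl in unique(labels)) {
    n_cl <- sum(labels == cl)
    n_test <- sum(labels[r1$test_idx] == cl)
    expect_lte(abs(n_test - round(0.3 * n_cl)), 1)
  }
  expect_length(intersect(r1$train_idx, r1$test_idx), 0)
})

test_that("experiment 2 trains one model per event without leakage", {
  rec <- small_recording(duration = 400,
                         intervals = cbind(c(40, 110, 180), c(60, 130, 200)))
  segs <- cut_segments(rec, small_preproc())
  res <- run_experiment2(segs, rec$annotations,
                         classifier_config(input_size = 16, epochs = 60,
                                           seed = 3),
                         filtration_config(n_folds = 2),
                         render_config(size = 32), seed = 3)
  expect_equal(nrow(res$events), 3)
  expect_length(res$folds, 3)                    # S trained models
  ev_idx <- vapply(segs, function(s) {
    if (is.na(s$event_index)) NA_integer_ else s$event_index
  }, 0L)
  for (s in seq_along(res$folds)) {
    fold <- res$folds[[s]]
    held_out <- which(!is.na(ev_idx) & ev_idx == fold$event)
    expect_length(intersect(fold$train_idx, held_out), 0)  # leakage guard
    expect_true(all(held_out %in% fold$test_idx))
  }
  expect_error(
    run_experiment2(segs[ev_idx %in% c(1, NA)], rec$annotations),
    "at least 2 events")
})
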