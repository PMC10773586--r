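#' Confusion counts from labels and predictions
#'
#' @param truth,predicted character vectors of class labels.
#' @param positive the positive class (default "seizure").
#' @return Named integer vector `c(TP, FP, TN, FN)`.
#' @export
confusion_counts <- function(truth, predicted, positive = "seizure") {
  stopifnot(length(truth) == length(predicted))
  c(TP = sum(truth == positive & predicted == positive),
    FP = sum(truth != positive & predicted == positive),
    TN = sum(truth != positive & predicted != positive),
    FN = sum(truth == positive & predicted != positive))
}

#' Segment-based detection metrics
#'
#' Computes the six standard per-segment indices from confusion counts, each
#' on a 0-100 scale and reported to 2 decimals:
#' \deqn{Acc = (TP+TN)/(TP+FP+TN+FN) \times 100}
#' \deqn{Sens = TP/(TP+FN) \times 100, \quad Spec = TN/(TN+FP) \times 100}
#' \deqn{Pre = TP/(TP+FP) \times 100, \quad F1 = TP/(TP+0.5(FP+FN)) \times 100}
#' \deqn{mAcc = (Sens+Spec)/2}
#' A metric whose denominator is zero is reported as `NA` (undefined) rather
#' than propagating NaN.
#'
#' @param counts named vector/list with TP, FP, TN, FN (all >= 0, not all 0).
#' @return Named numeric vector of class `seizure_metrics` with elements
#'   Acc, Sens, Spec, Pre, F1, mAcc; the counts ride along as an attribute.
#' @examples
#' compute_metrics(c(TP = 49, FP = 0, TN = 51, FN = 2))
#' @export
compute_metrics <- function(counts) {
  counts <- unlist(counts)[c("TP", "FP", "TN", "FN")]
  if (anyNA(counts) || any(counts < 0)) {
    stop("counts must provide non-negative TP, FP, TN, FN", call. = FALSE)
  }
  tp <- counts[["TP"]]; fp <- counts[["FP"]]
  tn <- counts[["TN"]]; fn <- counts[["FN"]]
  if (tp + fp + tn + fn == 0) {
    stop("all confusion counts are zero; metrics undefined", call. = FALSE)
  }
  frac <- function(num, den) if (den == 0) NA_real_ else round(num / den * 100, 2)
  m <- c(Acc = frac(tp + tn, tp + fp + tn + fn),
         Sens = frac(tp, tp + fn),
         Spec = frac(tn, tn + fp),
         Pre = frac(tp, tp + fp),
         F1 = frac(tp, tp + 0.5 * (fp + fn)))
  m["mAcc"] <- round((m[["Sens"]] + m[["Spec"]]) / 2, 2)
  structure(m, counts = counts, class = "seizure_metrics")
}

#' @export
print.seizure_metrics <- function(x, ...) {
  cat("<seizure_metrics>", paste(names(x), unclass(x), sep = "=",
                                 collapse = "  "), "\n")
  invisible(x)
}

#' Event-based detection and latency
#'
#' An annotated seizure event is detected when at least one of its test
#' segments is predicted seizure; its detection latency is the start time of
#' the earliest such segment minus the annotated onset (0 when the first
#' in-event segment is already positive). Segments before the onset never
#' count as detections. A segment belongs to an event when its window lies
#' fully inside the annotated interval.
#'
#' @param predictions data frame with columns `start_time` (s) and `label`
#'   (predicted class) for the test segments.
#' @param annotations data.frame(onset, offset) of the events to score.
#' @param window_seconds segment window length (default 2).
#' @param positive positive class label (default "seizure").
#' @return data.frame(event_index, detected, latency_s); `latency_s` is `NA`
#'   for undetected events.
#' @examples
#' pred <- data.frame(start_time = c(3527, 3551, 3575),
#'                    label = c("interictal", "interictal", "seizure"))
#' event_detection(pred, data.frame(onset = 3527, offset = 3607))
#' @export
event_detection <- function(predictions, annotations, window_seconds = 2,
                            positive = "seizure") {
  predictions <- predictions[order(predictions$start_time), , drop = FALSE]
  ann <- as.data.frame(annotations)
  out <- data.frame(event_index = seq_len(nrow(ann)), detected = FALSE,
                    latency_s = NA_real_)
  for (ev in seq_len(nrow(ann))) {
    inside <- predictions$start_time >= ann$onset[ev] - 1e-9 &
      predictions$start_time + window_seconds <= ann$offset[ev] + 1e-9
    if (!any(inside)) {
      stop("event ", ev, " has no test segments inside its interval",
           call. = FALSE)
    }
    hits <- predictions$start_time[inside][predictions$label[inside] == positive]
    if (length(hits)) {
      out$detected[ev] <- TRUE
      out$latency_s[ev] <- round(min(hits) - ann$onset[ev], 2)
    }
  }
  out
}

# shared segment -> image chain with a common x-range taken from a
# reference (training) set, so all images share one epsilon scale
pipeline_images <- function(segments, filtration, render, ref_idx = NULL) {
  barcodes <- lapply(segments, function(seg) {
    vr_persistence(fold_segment(seg, filtration$n_folds), filtration)
  })
  if (is.null(render$x_range)) {
    idx <- if (is.null(ref_idx)) seq_along(barcodes) else ref_idx
    render$x_range <- max(vapply(barcodes[idx], attr, 0, "eps_max"))
  }
  list(images = lapply(barcodes, render_barcode, config = render),
       x_range = render$x_range)
}

#' Segment-based experiment: stratified 70/30 split
#'
#' Splits the labeled segments per class into 70% training / 30% testing
#' (seeded), runs the fold -> persistence -> barcode-image -> classifier
#' chain, and scores the test split. Images share a fixed epsilon range
#' taken from the training barcodes, so amplitude differences between
#' classes survive rasterization.
#'
#' @param segments balanced labeled segments from [cut_segments()].
#' @param classifier a [classifier_config()].
#' @param filtration a [filtration_config()].
#' @param render a [render_config()].
#' @param train_frac training fraction (default 0.7).
#' @param seed split seed.
#' @return List with `metrics` ([compute_metrics()] output), `counts`,
#'   `train_idx`, `test_idx`, `predictions`, `model` and `x_range`.
#' @export
run_experiment1 <- function(segments, classifier = classifier_config(),
                            filtration = filtration_config(),
                            render = render_config(), train_frac = 0.7,
                            seed = 1L) {
  labels <- segment_labels(segments)
  classes <- sort(unique(labels))
  train_idx <- sort(unlist(with_seed(seed, lapply(classes, function(cl) {
    idx <- which(labels == cl)
    sample(idx, round(train_frac * length(idx)))
  }))))
  test_idx <- setdiff(seq_along(segments), train_idx)
  if (!all(classes %in% labels[train_idx]) ||
      !all(classes %in% labels[test_idx])) {
    stop("a class is missing from the training or test split", call. = FALSE)
  }

  pi <- pipeline_images(segments, filtration, render, ref_idx = train_idx)
  model <- train_classifier(pi$images[train_idx], labels[train_idx],
                            classifier)
  pred <- predict_classifier(model, pi$images[test_idx])
  counts <- confusion_counts(labels[test_idx], pred$label)
  list(metrics = compute_metrics(counts), counts = counts,
       train_idx = train_idx, test_idx = test_idx,
       predictions = cbind(
         data.frame(start_time = vapply(segments[test_idx], `[[`, 0,
                                        "start_time"),
                    truth = labels[test_idx]), pred),
       model = model, x_range = pi$x_range)
}

#' Event-based experiment: leave-one-seizure-event-out
#'
#' With S annotated seizure events, trains S models: fold s holds out event
#' s's segments (plus a matched, seeded share of the interictal segments,
#' reserved so the test fold has negatives) and trains on everything else.
#' Each held-out event is scored for detection and latency; interictal test
#' segments predicted seizure are tallied as false positives.
#'
#' @param segments labeled segments carrying `event_index` from
#'   [cut_segments()].
#' @param annotations data.frame(onset, offset), one row per seizure event,
#'   in event-index order.
#' @param classifier a [classifier_config()].
#' @param filtration a [filtration_config()].
#' @param render a [render_config()].
#' @param window_seconds segment window length (default 2).
#' @param seed seed for the interictal partition.
#' @return List with `events` (per-event data frame: detected, latency_s,
#'   false_positives), `event_sensitivity` (percent), `mean_latency_s`
#'   (over detected events), and `folds` (per-fold train/test index
#'   manifest).
#' @export
run_experiment2 <- function(segments, annotations,
                            classifier = classifier_config(),
                            filtration = filtration_config(),
                            render = render_config(), window_seconds = 2,
                            seed = 1L) {
  labels <- segment_labels(segments)
  event_of <- vapply(segments, function(s) {
    if (is.null(s$event_index)) NA_integer_ else as.integer(s$event_index)
  }, 0L)
  events <- sort(unique(event_of[!is.na(event_of)]))
  S <- length(events)
  if (S < 2) stop("leave-one-event-out needs at least 2 events", call. = FALSE)
  if (nrow(annotations) < S) {
    stop("annotations must cover every event index", call. = FALSE)
  }

  inter_idx <- which(labels != "seizure")
  groups <- with_seed(seed, split(sample(inter_idx),
                                  rep_len(seq_len(S), length(inter_idx))))

  pi <- pipeline_images(segments, filtration, render)
  res <- data.frame(event_index = events, detected = FALSE,
                    latency_s = NA_real_, n_test_segments = 0L,
                    false_positives = 0L)
  folds <- vector("list", S)
  for (s in seq_len(S)) {
    ev <- events[s]
    test_idx <- sort(c(which(!is.na(event_of) & event_of == ev),
                       groups[[s]]))
    train_idx <- setdiff(seq_along(segments), test_idx)
    stopifnot(length(intersect(train_idx, test_idx)) == 0)
    model <- train_classifier(pi$images[train_idx], labels[train_idx],
                              classifier)
    pred <- predict_classifier(model, pi$images[test_idx])
    pred_df <- data.frame(
      start_time = vapply(segments[test_idx], `[[`, 0, "start_time"),
      label = pred$label, truth = labels[test_idx])
    ev_res <- event_detection(pred_df, annotations[ev, , drop = FALSE],
                              window_seconds = window_seconds)
    res$detected[s] <- ev_res$detected[1]
    res$latency_s[s] <- ev_res$latency_s[1]
    res$n_test_segments[s] <- length(test_idx)
    res$false_positives[s] <- sum(pred_df$truth != "seizure" &
                                    pred_df$label == "seizure")
    folds[[s]] <- list(event = ev, train_idx = train_idx,
                       test_idx = test_idx,
                       model_manifest = model$manifest)
  }

  list(events = res,
       event_sensitivity = round(mean(res$detected) * 100, 2),
       mean_latency_s = if (any(res$detected)) {
         round(mean(res$latency_s[res$detected]), 2)
       } else NA_real_,
       folds = folds)
}
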