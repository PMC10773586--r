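test_that("the classifier separates a scale-separable image set", {
  set <- toy_image_set(n_per_class = 30, seed = 1)
  idx <- rep(c(TRUE, TRUE, FALSE), 20)          # 2/3 train, 1/3 test
  cfg <- classifier_config(input_size = 16, epochs = 100, seed = 1)
  model <- train_classifier(set$images[idx], set$labels[idx], cfg)
  pred <- predict_classifier(model, set$images[!idx])
  expect_gte(mean(pred$label == set$labels[!idx]), 0.95)

  # training accuracy of a converged model is at least held-out accuracy
  pred_tr <- predict_classifier(model, set$images[idx])
  expect_gte(mean(pred_tr$label == set$labels[idx]),
             mean(pred$label == set$labels[!idx]))
})

test_that("scores are softmax-normalized and predictions deterministic", {
  set <- toy_image_set(n_per_class = 10, seed = 2)
  cfg <- classifier_config(input_size = 16, epochs = 50, seed = 9)
  m1 <- train_classifier(set$images, set$labels, cfg)
  m2 <- train_classifier(set$images, set$labels, cfg)
  p1 <- predict_classifier(m1, set$images)
  p2 <- predict_classifier(m2, set$images)
  expect_identical(p1, p2)
  sums <- rowSums(p1[, grepl("^score_", names(p1))])
  expect_true(all(abs(sums - 1) < 1e-6))
})

test_that("an untrained network predicts near chance on balanced data", {
  # images drawn from one distribution, labels assigned alternately: no
  # signal, so a model left at initialization must sit near 50%
  set.seed(3)
  rc <- render_config(size = 64, x_range = 12)
  images <- lapply(1:100, function(i) {
    pc <- fold_segment(matrix(rnorm(16 * 4), 16, 4), 0)
    render_barcode(vr_persistence(pc), rc)
  })
  labels <- rep(c("interictal", "seizure"), 50)
  cfg <- classifier_config(input_size = 16, epochs = 0, seed = 4)
  model <- train_classifier(images, labels, cfg)
  acc <- mean(predict_classifier(model, images)$label == labels)
  # binomial 99.9% band around 0.5 for n = 100
  expect_gt(acc, 0.5 - 3.3 * sqrt(0.25 / 100))
  expect_lt(acc, 0.5 + 3.3 * sqrt(0.25 / 100))
})

test_that("single-class training data raises a label error", {
  set <- toy_image_set(n_per_class = 4, seed = 5)
  expect_error(train_classifier(set$images[1:4], rep("seizure", 4),
                                classifier_config(input_size = 16)),
               "single class")
})

test_that("three-class problems train and predict without code changes", {
  set.seed(6)
  rc <- render_config(size = 64, x_range = 20)
  mk <- function(scale) {
    pc <- fold_segment(matrix(rnorm(16 * 4, sd = scale), 16, 4), 0)
    render_barcode(vr_persistence(pc), rc)
  }
  images <- c(lapply(1:15, function(i) mk(0.5)),
              lapply(1:15, function(i) mk(2)),
              lapply(1:15, function(i) mk(6)))
  labels <- rep(c("background", "interictal", "seizure"), each = 15)
  cfg <- classifier_config(n_classes = 3, input_size = 16, epochs = 150,
                           seed = 7)
  model <- train_classifier(images, labels, cfg)
  pred <- predict_classifier(model, images)
  expect_equal(ncol(pred), 4)                   # label + 3 score columns
  expect_gte(mean(pred$label == labels), 0.9)
})

test_that("empty prediction input returns an empty frame", {
  set <- toy_image_set(n_per_class = 5, seed = 8)
  model <- train_classifier(set$images, set$labels,
                            classifier_config(input_size = 16, epochs = 20))
  out <- predict_classifier(model, list())
  expect_equal(nrow(out), 0)
  expect_named(out, c("label", "score_interictal", "score_seizure"))
})

test_that("image size mismatches are rejected", {
  set <- toy_image_set(n_per_class = 5, size = 64, seed = 10)
  model <- train_classifier(set$images, set$labels,
                            classifier_config(input_size = 16, epochs = 20))
  other <- toy_image_set(n_per_class = 1, size = 32, seed = 10)
  expect_error(predict_classifier(model, other$images), "does not match")
})
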