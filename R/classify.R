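#' Classifier configuration
#'
#' The package's classifier is deliberately compact so the whole pipeline
#' trains on one CPU in seconds: barcode images are converted to grayscale,
#' block-averaged down to `input_size` x `input_size`, and fed to either a
#' single-hidden-layer feed-forward network ("mlp", the default) or a
#' multinomial logistic model ("logistic"), both fit with `nnet` and a
#' softmax output so class scores sum to 1. Any number of classes >= 2 is
#' supported.
#'
#' @param architecture "mlp" or "logistic".
#' @param n_classes expected number of classes (>= 2, default 2).
#' @param epochs optimizer iteration budget (BFGS iterations; default 100).
#'   `epochs = 0` leaves the network at its random initialization.
#' @param hidden_units hidden-layer width for "mlp" (default 8).
#' @param decay L2 weight decay (default 5e-4).
#' @param input_size down-sampled image side fed to the network (default
#'   14). The quasi-Newton optimizer's cost grows with the square of the
#'   weight count, so the input stays small.
#' @param seed integer seed; fixed seed + data give identical fits
#'   (single-threaded deterministic optimization).
#' @return A list of class `classifier_config`.
#' @export
classifier_config <- function(architecture = c("mlp", "logistic"),
                              n_classes = 2, epochs = 100, hidden_units = 8,
                              decay = 5e-4, input_size = 14, seed = 1L) {
  architecture <- match.arg(architecture)
  if (n_classes < 2) stop("n_classes must be >= 2", call. = FALSE)
  structure(
    list(architecture = architecture, n_classes = n_classes, epochs = epochs,
         hidden_units = hidden_units, decay = decay, input_size = input_size,
         seed = as.integer(seed)),
    class = "classifier_config")
}

# barcode_image -> numeric feature vector: grayscale block means in [0, 1];
# rows/columns are binned as evenly as possible, so any image size works
image_features <- function(image, input_size) {
  px <- image$pixels
  s <- dim(px)[1]
  if (s < input_size) {
    stop("image size ", s, " is smaller than input_size ", input_size,
         call. = FALSE)
  }
  gray <- (px[, , 1] + px[, , 2] + px[, , 3]) / (3 * 255)
  bins <- ceiling(seq_len(s) * input_size / s)
  counts <- tabulate(bins, input_size)
  g <- rowsum(gray, bins) / counts
  g <- t(rowsum(t(g), bins)) / rep(counts, each = input_size)
  as.numeric(g)
}

feature_matrix <- function(images, input_size) {
  t(vapply(images, image_features, numeric(input_size^2),
           input_size = input_size))
}

#' Train the barcode-image classifier
#'
#' @param images list of `barcode_image`s.
#' @param labels character vector of class labels, one per image; at least
#'   two distinct classes must be present.
#' @param config a [classifier_config()].
#' @return A `trained_model`: list with the fitted network, class labels,
#'   input size, and a training manifest (config, seed, data hash, size)
#'   sufficient to reproduce the fit.
#' @export
train_classifier <- function(images, labels, config = classifier_config()) {
  stopifnot(length(images) == length(labels))
  classes <- sort(unique(as.character(labels)))
  if (length(classes) < 2) {
    stop("training data contains a single class: ", classes, call. = FALSE)
  }
  x <- feature_matrix(images, config$input_size)
  y <- nnet::class.ind(factor(labels, levels = classes))
  size <- if (config$architecture == "mlp") config$hidden_units else 0
  fit <- with_seed(config$seed, suppressWarnings(
    nnet::nnet(x, y, size = size, skip = (size == 0), softmax = TRUE,
               decay = config$decay, maxit = config$epochs,
               MaxNWts = 100000, trace = FALSE)))
  structure(
    list(fit = fit, classes = classes, input_size = config$input_size,
         image_size = dim(images[[1]]$pixels)[1],
         manifest = list(
           architecture = config$architecture, seed = config$seed,
           epochs = config$epochs, hidden_units = size,
           decay = config$decay, n_train = length(images),
           data_hash = object_md5(x), label_hash = object_md5(labels))),
    class = "trained_model")
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf("<trained_model> %s, classes: %s, %d training images (hash %s)\n",
              x$manifest$architecture, paste(x$classes, collapse = "/"),
              x$manifest$n_train, substr(x$manifest$data_hash, 1, 8)))
  invisible(x)
}

# md5 of an R object's serialized bytes (connection-free, via a temp file)
object_md5 <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

#' Predict classes for barcode images
#'
#' @param model a `trained_model` from [train_classifier()].
#' @param images list of `barcode_image`s with the same pixel size the model
#'   was trained on.
#' @return Data frame with one row per image: `label` plus one `score_*`
#'   column per class (softmax scores summing to 1).
#' @export
predict_classifier <- function(model, images) {
  score_cols <- paste0("score_", model$classes)
  if (length(images) == 0) {
    out <- as.data.frame(matrix(numeric(0), 0, 1 + length(score_cols)))
    names(out) <- c("label", score_cols)
    return(out)
  }
  sz <- dim(images[[1]]$pixels)[1]
  if (sz != model$image_size) {
    stop("image size ", sz, " does not match model input ", model$image_size,
         call. = FALSE)
  }
  x <- feature_matrix(images, model$input_size)
  scores <- predict(model$fit, x)
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1)
  colnames(scores) <- score_cols
  out <- data.frame(label = model$classes[max.col(scores, ties.method = "first")],
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(scores))
}
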