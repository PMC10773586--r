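#' Point cloud in Euclidean space
#'
#' A P x D coordinate matrix (one point per row) plus provenance metadata.
#' For EEG-derived clouds, `P = n_channels * 2^n_folds` and
#' `D = window_samples / 2^n_folds`, so `P * D` always equals the number of
#' raw samples in the source window (sample conservation).
#'
#' @param points numeric P x D matrix.
#' @param n_channels number of source channels.
#' @param n_folds how many folds produced this cloud.
#' @param source free-form provenance tag ("segment" or "fixture").
#' @return Object of class `point_cloud`.
#' @name point_cloud
NULL

new_point_cloud <- function(points, n_channels, n_folds, source = "segment") {
  stopifnot(is.matrix(points), is.numeric(points))
  dup <- duplicated(points)
  if (any(dup)) {
    warning(sum(dup), " duplicate point(s) merged in point cloud")
    points <- points[!dup, , drop = FALSE]
  }
  structure(
    list(points = points, n_channels = as.integer(n_channels),
         n_folds = as.integer(n_folds), source = source),
    class = "point_cloud")
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("<point_cloud> %d points in R^%d (%d channels, %d fold(s), %s)\n",
              nrow(x$points), ncol(x$points), x$n_channels, x$n_folds,
              x$source))
  invisible(x)
}

#' @export
as.matrix.point_cloud <- function(x, ...) x$points

#' Fold a segment into a point cloud
#'
#' Each fold halves every existing point (row) in time and stacks the two
#' halves as separate rows: first all first halves in the original row order,
#' then all second halves, applied recursively. An n-channel window thus
#' yields `n * 2^k` points of dimension `window_samples / 2^k` after k folds;
#' the multiset of raw samples is conserved. Row order is fixed for
#' reproducibility, but persistence is invariant to point order, so the
#' barcode does not depend on it.
#'
#' @param segment a segment from [cut_segments()], or a bare channels x time
#'   numeric matrix.
#' @param n_folds number of folds (>= 0); the window sample count must be
#'   divisible by `2^n_folds`.
#' @return A [point_cloud].
#' @examples
#' seg <- matrix(1:16, nrow = 2, byrow = TRUE)
#' as.matrix(fold_segment(seg, 1))
#' @export
fold_segment <- function(segment, n_folds = 3) {
  m <- if (is.list(segment)) segment$samples else segment
  stopifnot(is.matrix(m), is.numeric(m))
  if (n_folds < 0 || n_folds != round(n_folds)) {
    stop("n_folds must be a non-negative integer", call. = FALSE)
  }
  k <- 2^n_folds
  if (ncol(m) %% k != 0) {
    stop(sprintf("window of %d samples is not divisible by 2^n_folds = %d",
                 ncol(m), k), call. = FALSE)
  }
  pts <- m
  for (f in seq_len(n_folds)) {
    half <- ncol(pts) / 2
    pts <- rbind(pts[, seq_len(half), drop = FALSE],
                 pts[, half + seq_len(half), drop = FALSE])
  }
  new_point_cloud(pts, n_channels = nrow(m), n_folds = n_folds,
                  source = if (is.list(segment)) "segment" else "matrix")
}

#' Filtration configuration
#'
#' Controls the point-cloud construction and the Vietoris-Rips filtration.
#'
#' @param n_folds folds applied to each window (default 3: 152 points for 19
#'   channels, the best-performing construction among 19/38/76/152).
#' @param max_homology_dim 0 or 1 (default 1).
#' @param eps_max filtration ceiling; `NULL` (default) means the maximum
#'   pairwise distance of each cloud, which guarantees a single component at
#'   the top of the filtration.
#' @param normalize "none" (default; distances keep their microvolt scale,
#'   which carries the ictal amplitude signal) or "zscore" for per-channel
#'   standardization before folding.
#' @param eps_grid optional strictly increasing thresholds for Betti-curve
#'   reporting.
#' @return A list of class `filtration_config`.
#' @export
filtration_config <- function(n_folds = 3, max_homology_dim = 1,
                              eps_max = NULL, normalize = c("none", "zscore"),
                              eps_grid = NULL) {
  normalize <- match.arg(normalize)
  if (!max_homology_dim %in% c(0, 1)) {
    stop("max_homology_dim must be 0 or 1", call. = FALSE)
  }
  if (!is.null(eps_grid) && any(diff(eps_grid) <= 0)) {
    stop("eps_grid must be strictly increasing", call. = FALSE)
  }
  structure(
    list(n_folds = n_folds, max_homology_dim = max_homology_dim,
         eps_max = eps_max, normalize = normalize, eps_grid = eps_grid),
    class = "filtration_config")
}

#' Write / read a point cloud as plain numeric text
#'
#' One point per row, whitespace-separated coordinates.
#' @param cloud a [point_cloud].
#' @param path file path.
#' @return `read_point_cloud()` returns a [point_cloud];
#'   `write_point_cloud()` returns `path` invisibly.
#' @export
write_point_cloud <- function(cloud, path) {
  utils::write.table(as.matrix(cloud), path, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_point_cloud
#' @export
read_point_cloud <- function(path) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  dimnames(m) <- NULL
  new_point_cloud(m, n_channels = nrow(m), n_folds = 0L, source = "file")
}
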