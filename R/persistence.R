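#' Euclidean distance matrix of a point cloud
#'
#' @param cloud a [point_cloud] (or bare point matrix).
#' @return Symmetric P x P matrix of pairwise Euclidean distances with zero
#'   diagonal.
#' @export
distance_matrix <- function(cloud) {
  pts <- if (inherits(cloud, "point_cloud")) cloud$points else cloud
  if (NROW(pts) < 1) stop("empty point cloud", call. = FALSE)
  as.matrix(stats::dist(pts))
}

#' Vietoris-Rips persistent homology (dimensions 0 and 1)
#'
#' Computes the barcode of the Vietoris-Rips filtration of a point cloud over
#' Z/2. Dimension 0 is the single-linkage merge structure: every point is
#' born at 0, finite deaths are the minimum-spanning-tree edge weights, and
#' each connected component at `eps_max` contributes one infinite bar.
#' Dimension 1 comes from column reduction of the boundary matrix of all
#' edges and triangles of diameter at most `eps_max`, with simplices ordered
#' by (filtration value, dimension, lexicographic vertex tuple); 1-cycles
#' still open at `eps_max` are reported with infinite death.
#'
#' Two points are connected at scale `eps` when their distance is at most
#' `eps` (equivalently, balls of radius `eps/2` touch).
#'
#' @param cloud a [point_cloud] or point matrix.
#' @param config a [filtration_config()]; only `max_homology_dim` and
#'   `eps_max` are used here (`eps_max = NULL` means the cloud's maximum
#'   pairwise distance).
#' @return A `barcode`: data frame with columns `dim`, `birth`, `death`
#'   (`Inf` for never-dying classes) and attributes `eps_max`, `n_points`.
#' @examples
#' bc <- vr_persistence(five_point_cloud())
#' bc
#' betti_numbers(bc, 2.35)
#' @export
vr_persistence <- function(cloud, config = filtration_config()) {
  D <- distance_matrix(cloud)
  n <- nrow(D)
  eps_max <- config$eps_max
  if (is.null(eps_max)) eps_max <- if (n > 1) max(D) else 0
  if (eps_max <= 0 && n > 1) stop("eps_max must be > 0", call. = FALSE)

  res <- .rips_pairs_cpp(D, eps_max)
  h0 <- data.frame(
    dim = 0L,
    birth = 0,
    death = c(res$h0_deaths, rep(Inf, res$n_components)))
  h1 <- if (config$max_homology_dim >= 1 && length(res$h1_birth)) {
    data.frame(dim = 1L, birth = res$h1_birth, death = res$h1_death)
  } else {
    data.frame(dim = integer(0), birth = numeric(0), death = numeric(0))
  }
  bc <- rbind(h0, h1)
  rownames(bc) <- NULL
  structure(bc, eps_max = eps_max, n_points = n,
            class = c("barcode", "data.frame"))
}

#' @export
print.barcode <- function(x, ...) {
  cat(sprintf("<barcode> %d interval(s) on %d points, eps_max = %g\n",
              nrow(x), attr(x, "n_points"), attr(x, "eps_max")))
  print.data.frame(x, ...)
  invisible(x)
}

#' Betti numbers from a barcode
#'
#' Counts the intervals alive at scale `eps` per dimension: an interval
#' `[birth, death)` is alive when `birth <= eps < death`.
#'
#' @param barcode a barcode from [vr_persistence()].
#' @param eps scale (>= 0).
#' @return Named integer vector `c(b0 = ..., b1 = ...)`.
#' @export
betti_numbers <- function(barcode, eps) {
  stopifnot(eps >= 0)
  alive <- barcode$birth <= eps & eps < barcode$death
  c(b0 = sum(alive & barcode$dim == 0L),
    b1 = sum(alive & barcode$dim == 1L))
}

#' Betti curves over a threshold grid
#'
#' Evaluates [betti_numbers()] along an ascending grid of scales, the
#' discretized filtration view of a barcode.
#'
#' @param barcode a barcode from [vr_persistence()].
#' @param eps_grid strictly increasing scales (defaults to 64 values from 0
#'   to the barcode's `eps_max`).
#' @return data.frame(eps, b0, b1).
#' @export
betti_curve <- function(barcode, eps_grid = NULL) {
  if (is.null(eps_grid)) {
    eps_grid <- seq(0, attr(barcode, "eps_max"), length.out = 64)
  }
  if (any(diff(eps_grid) <= 0)) {
    stop("eps_grid must be strictly increasing", call. = FALSE)
  }
  counts <- vapply(eps_grid, function(e) betti_numbers(barcode, e),
                   c(b0 = 0L, b1 = 0L))
  data.frame(eps = eps_grid, b0 = counts["b0", ], b1 = counts["b1", ])
}

#' Brute-force Betti numbers of a Vietoris-Rips complex (verification oracle)
#'
#' Builds the full complex at a single scale explicitly (vertices, edges,
#' triangles) and computes Betti numbers as ranks of the Z/2 boundary
#' operators by Gaussian elimination: `b0 = n - rank(d1)`,
#' `b1 = dim ker(d1) - rank(d2)`. Exponential-cost reference implementation,
#' limited to small clouds; kept independent of the filtration engine it
#' cross-checks.
#'
#' @param cloud a [point_cloud] or point matrix with at most `max_points`
#'   points.
#' @param eps scale at which to build the complex.
#' @param max_points safety bound (default 12).
#' @return Named integer vector `c(b0 = ..., b1 = ...)`.
#' @export
oracle_betti <- function(cloud, eps, max_points = 12L) {
  D <- distance_matrix(cloud)
  n <- nrow(D)
  if (n > max_points) {
    stop("oracle limited to ", max_points, " points (got ", n, ")",
         call. = FALSE)
  }
  edges <- which(upper.tri(D) & D <= eps, arr.ind = TRUE)
  edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  m <- nrow(edges)
  eidx <- matrix(0L, n, n)
  for (e in seq_len(m)) {
    eidx[edges[e, 1], edges[e, 2]] <- e
  }

  # d1: vertices x edges
  d1 <- matrix(0L, n, m)
  for (e in seq_len(m)) d1[edges[e, ], e] <- 1L
  r1 <- z2_rank(d1)
  b0 <- n - r1

  # d2: edges x triangles
  tri <- list()
  if (n >= 3) {
    combs <- utils::combn(n, 3)
    for (c_i in seq_len(ncol(combs))) {
      v <- combs[, c_i]
      if (D[v[1], v[2]] <= eps && D[v[1], v[3]] <= eps &&
          D[v[2], v[3]] <= eps) {
        tri[[length(tri) + 1L]] <- c(eidx[v[1], v[2]], eidx[v[1], v[3]],
                                     eidx[v[2], v[3]])
      }
    }
  }
  r2 <- if (length(tri) && m > 0) {
    d2 <- matrix(0L, m, length(tri))
    for (t_i in seq_along(tri)) d2[tri[[t_i]], t_i] <- 1L
    z2_rank(d2)
  } else 0L
  b1 <- (m - r1) - r2
  c(b0 = b0, b1 = b1)
}

# rank of a 0/1 matrix over Z/2 by Gaussian elimination
z2_rank <- function(M) {
  if (length(M) == 0) return(0L)
  M <- M %% 2L
  rank <- 0L
  row <- 1L
  for (col in seq_len(ncol(M))) {
    piv <- which(M[row:nrow(M), col] == 1L)
    if (!length(piv)) next
    piv <- piv[1] + row - 1L
    if (piv != row) M[c(row, piv), ] <- M[c(piv, row), ]
    hits <- which(M[, col] == 1L)
    hits <- hits[hits != row]
    if (length(hits)) {
      M[hits, ] <- (M[hits, , drop = FALSE] +
                      rep(M[row, ], each = length(hits))) %% 2L
    }
    rank <- rank + 1L
    if (row == nrow(M)) break
    row <- row + 1L
  }
  rank
}

#' Serialize / deserialize a barcode
#'
#' One interval per line: `dim<TAB>birth<TAB>death`, with `inf` for infinite
#' deaths.
#' @param barcode a barcode from [vr_persistence()].
#' @param path file path.
#' @return `read_barcode()` returns a barcode; `write_barcode()` returns
#'   `path` invisibly.
#' @export
write_barcode <- function(barcode, path) {
  df <- as.data.frame(barcode)
  df$death <- ifelse(is.infinite(df$death), "inf",
                     format(df$death, digits = 17))
  df$birth <- format(df$birth, digits = 17)
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_barcode
#' @export
read_barcode <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("dim", "birth", "death"),
                          colClasses = c("integer", "numeric", "character"))
  df$death <- ifelse(df$death == "inf", Inf, as.numeric(df$death))
  structure(df, eps_max = max(c(df$birth, df$death[is.finite(df$death)], 0)),
            n_points = sum(df$dim == 0L),
            class = c("barcode", "data.frame"))
}
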