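test_that("distance matrix reproduces hand-computed values", {
  D <- distance_matrix(five_point_cloud())
  expect_equal(D[4, 5], 1)
  expect_equal(D[2, 3], sqrt(2))
  expect_equal(D[1, 2], sqrt(5))
  expect_true(isSymmetric(D))
  expect_equal(diag(D), rep(0, 5), ignore_attr = TRUE)

  expect_equal(distance_matrix(matrix(c(3, 4), 1)), matrix(0, 1, 1),
               ignore_attr = TRUE)
  expect_error(distance_matrix(matrix(numeric(0), 0, 2)), "empty")
})

test_that("the five-point filtration walk-through is reproduced", {
  bc <- vr_persistence(five_point_cloud())
  expect_equal(unname(betti_numbers(bc, 0.6)), c(5, 0))
  expect_equal(unname(betti_numbers(bc, 1.0)), c(4, 0))
  expect_equal(unname(betti_numbers(bc, 1.44)), c(3, 0))
  expect_equal(unname(betti_numbers(bc, 2.35)), c(1, 1))

  # the loop is born when the last sqrt(5) edge closes the 5-cycle; its
  # death matches the brute-force rank oracle at every critical value
  h1 <- bc[bc$dim == 1, ]
  expect_equal(nrow(h1), 1)
  expect_equal(h1$birth, sqrt(5))
  eps_vals <- critical_eps(five_point_cloud())
  oracle_death <- min(eps_vals[vapply(eps_vals, function(e) {
    oracle_betti(five_point_cloud(), e)[["b1"]] == 0 && e > sqrt(5)
  }, TRUE)])
  expect_equal(h1$death, oracle_death)
  expect_equal(h1$death, 3)
})

test_that("two points at distance 3 give bars [0,Inf) and [0,3)", {
  bc <- vr_persistence(rbind(c(0, 0), c(3, 0)))
  expect_equal(bc$dim, c(0L, 0L))
  expect_equal(sort(bc$death), c(3, Inf))
  expect_equal(bc$birth, c(0, 0))
})

test_that("betti numbers at 0 count all points, with no loops", {
  for (n in c(2, 5, 9)) {
    bc <- vr_persistence(random_cloud(n, seed = n))
    expect_equal(unname(betti_numbers(bc, 0)), c(n, 0))
  }
})

test_that("oracle handles the filled triangle and the hollow square", {
  tri <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
  expect_equal(oracle_betti(tri, 1), c(b0 = 1L, b1 = 0L))
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(oracle_betti(sq, 1), c(b0 = 1L, b1 = 1L))
  expect_equal(oracle_betti(sq, sqrt(2)), c(b0 = 1L, b1 = 0L))
  expect_equal(oracle_betti(five_point_cloud(), 0.6), c(b0 = 5L, b1 = 0L))
  expect_error(oracle_betti(random_cloud(20, seed = 1), 1), "12")
})

test_that("barcode matches the exhaustive Z/2 rank oracle on random clouds", {
  for (trial in 1:50) {
    n <- sample(4:10, 1)
    pc <- random_cloud(n, d = sample(2:3, 1), seed = 1000 + trial)
    bc <- vr_persistence(pc)
    for (eps in critical_eps(pc)) {
      expect_equal(betti_numbers(bc, eps), oracle_betti(pc, eps),
                   info = sprintf("trial %d, eps %.4f", trial, eps))
    }
  }
})

test_that("dim-0 deaths equal single-linkage merge heights", {
  for (seed in 1:5) {
    pc <- random_cloud(12, seed = seed)
    bc <- vr_persistence(pc)
    deaths <- sort(bc$death[bc$dim == 0 & is.finite(bc$death)])
    merge_heights <- sort(stats::hclust(stats::dist(as.matrix(pc)),
                                        method = "single")$height)
    expect_equal(deaths, merge_heights)
    expect_equal(sum(bc$dim == 0), 12)          # one bar per point
    expect_equal(sum(bc$dim == 0 & is.infinite(bc$death)), 1)
  }
})

test_that("b0 is non-increasing in eps and reaches 1 at eps_max", {
  for (seed in 6:10) {
    pc <- random_cloud(10, seed = seed)
    bc <- vr_persistence(pc)
    eps_vals <- c(0, critical_eps(pc))
    b0 <- vapply(eps_vals, function(e) betti_numbers(bc, e)[["b0"]], 0L)
    expect_true(all(diff(b0) <= 0))
    expect_equal(b0[1], 10)
    D <- distance_matrix(pc)
    expect_equal(betti_numbers(bc, max(D))[["b0"]], 1L)
  }
})

test_that("barcodes are invariant under point permutation", {
  pc <- random_cloud(9, seed = 33)
  m <- as.matrix(pc)
  bc1 <- vr_persistence(pc)
  set.seed(34)
  bc2 <- vr_persistence(m[sample(9), ])
  srt <- function(b) b[order(b$dim, b$birth, b$death), c("dim", "birth", "death")]
  expect_equal(srt(as.data.frame(bc1)), srt(as.data.frame(bc2)),
               ignore_attr = TRUE)
})

test_that("scaling coordinates by c scales all finite endpoints by c", {
  pc <- random_cloud(8, seed = 55)
  m <- as.matrix(pc)
  bc1 <- vr_persistence(pc)
  bc2 <- vr_persistence(m * 2.5)
  expect_equal(bc2$birth, bc1$birth * 2.5)
  finite <- is.finite(bc1$death)
  expect_equal(bc2$death[finite], bc1$death[finite] * 2.5)
})

test_that("betti curves report the discretized filtration", {
  bc <- vr_persistence(five_point_cloud())
  curve <- betti_curve(bc, c(0.6, 1.0, 1.44, 2.35))
  expect_equal(curve$b0, c(5, 4, 3, 1))
  expect_equal(curve$b1, c(0, 0, 0, 1))
  expect_error(betti_curve(bc, c(1, 1)), "increasing")
})

test_that("barcodes serialize to TSV and back", {
  bc <- vr_persistence(five_point_cloud())
  path <- withr::local_tempfile(fileext = ".tsv")
  write_barcode(bc, path)
  expect_true(any(grepl("inf", readLines(path))))
  back <- read_barcode(path)
  expect_equal(as.data.frame(back), as.data.frame(bc), ignore_attr = TRUE)
})
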