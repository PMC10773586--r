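#' Barcode rendering configuration
#'
#' @param size image side in pixels (square, default 224 -- the native input
#'   size of standard image-classification CNNs; minimum 32).
#' @param x_range `NULL` (default) maps each barcode's own `eps_max` to the
#'   right edge; a fixed positive value gives all images a common scale,
#'   which preserves amplitude differences between segments.
#' @param dim0_color,dim1_color RGB triplets in 0..255 for the two homology
#'   dimensions (defaults: red for components, blue for loops, on white).
#' @param bar_thickness bar height in pixels (default 2).
#' @return A list of class `render_config`.
#' @export
render_config <- function(size = 224, x_range = NULL,
                          dim0_color = c(255, 0, 0),
                          dim1_color = c(0, 0, 255),
                          bar_thickness = 2) {
  if (size < 32) stop("image size must be >= 32 pixels", call. = FALSE)
  if (!is.null(x_range) && x_range <= 0) {
    stop("x_range must be positive", call. = FALSE)
  }
  structure(
    list(size = size, x_range = x_range, dim0_color = dim0_color,
         dim1_color = dim1_color, bar_thickness = bar_thickness),
    class = "render_config")
}

#' Rasterize a barcode into a fixed-size image
#'
#' Each interval becomes a horizontal bar from its birth to
#' `min(death, x_range)` on white background; infinite bars run to the right
#' edge. The upper half of the image is the dimension-0 band, the lower half
#' the dimension-1 band; within a band, bars are sorted by (birth, death) and
#' spread evenly over the band's rows. Rendering is pure arithmetic, so the
#' same barcode and configuration always give byte-identical pixels.
#'
#' @param barcode a barcode from [vr_persistence()].
#' @param config a [render_config()].
#' @return A `barcode_image`: list with `pixels` (size x size x 3 integer
#'   array in 0..255), `scale` (epsilon per pixel) and `meta`
#'   (n_points, eps_max, x_range).
#' @export
render_barcode <- function(barcode, config = render_config()) {
  s <- config$size
  px <- array(255L, dim = c(s, s, 3))
  x_range <- config$x_range
  if (is.null(x_range)) x_range <- attr(barcode, "eps_max")
  if (is.null(x_range) || !is.finite(x_range) || x_range <= 0) x_range <- 1

  to_px <- function(eps) pmin(s, pmax(1, 1 + round(eps / x_range * (s - 1))))
  half <- floor(s / 2)
  bands <- list(`0` = c(1, half), `1` = c(half + 1, s))
  cols <- list(`0` = config$dim0_color, `1` = config$dim1_color)

  for (d in c(0L, 1L)) {
    bars <- barcode[barcode$dim == d, , drop = FALSE]
    if (nrow(bars) == 0) next
    bars <- bars[order(bars$birth, bars$death), , drop = FALSE]
    band <- bands[[as.character(d)]]
    band_h <- band[2] - band[1] + 1
    centers <- band[1] + round(band_h * seq_len(nrow(bars)) /
                                 (nrow(bars) + 1))
    for (b in seq_len(nrow(bars))) {
      x0 <- to_px(bars$birth[b])
      x1 <- if (is.infinite(bars$death[b])) s else to_px(bars$death[b])
      rows <- centers[b] + seq_len(config$bar_thickness) -
        ceiling(config$bar_thickness / 2)
      rows <- rows[rows >= band[1] & rows <= band[2]]
      for (ch in 1:3) px[rows, x0:x1, ch] <- cols[[as.character(d)]][ch]
    }
  }

  structure(
    list(pixels = px, scale = x_range / (s - 1),
         meta = list(n_points = attr(barcode, "n_points"),
                     eps_max = attr(barcode, "eps_max"),
                     x_range = x_range)),
    class = "barcode_image")
}

#' @export
print.barcode_image <- function(x, ...) {
  cat(sprintf("<barcode_image> %d x %d px, %g eps/px, %s points\n",
              dim(x$pixels)[1], dim(x$pixels)[2], x$scale,
              x$meta$n_points %||% "?"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a barcode image as PNG
#'
#' @param image a `barcode_image`.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_barcode_png <- function(image, path) {
  png::writePNG(image$pixels / 255, path)
  invisible(path)
}

#' Turn segments into barcode images
#'
#' Convenience chain fold -> Vietoris-Rips persistence -> raster, applied to
#' a list of segments.
#'
#' @param segments list from [cut_segments()].
#' @param filtration a [filtration_config()].
#' @param render a [render_config()].
#' @return List of `barcode_image`s (same order as `segments`).
#' @export
segments_to_images <- function(segments, filtration = filtration_config(),
                               render = render_config()) {
  barcodes <- lapply(segments, function(seg) {
    vr_persistence(fold_segment(seg, filtration$n_folds), filtration)
  })
  lapply(barcodes, render_barcode, config = render)
}

#' Save barcode images in a class-per-directory layout
#'
#' Writes `<dir>/<subject>/<label>/<start_time>.png` for each image, the
#' layout an image classifier consumes.
#'
#' @param images list of `barcode_image`s.
#' @param segments matching list of segments (for subject, label, time).
#' @param dir output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
save_barcode_images <- function(images, segments, dir) {
  stopifnot(length(images) == length(segments))
  paths <- vapply(seq_along(images), function(i) {
    seg <- segments[[i]]
    d <- file.path(dir, seg$subject_id, seg$label)
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    p <- file.path(d, sprintf("%08.2f.png", seg$start_time))
    write_barcode_png(images[[i]], p)
    p
  }, "")
  invisible(paths)
}
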