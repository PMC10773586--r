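# shared fixtures: small, fast synthetic recordings and clouds built in code

# 4-channel, 64 Hz recording with two seizure events; cheap enough for most
# I/O and preprocessing tests
small_recording <- function(seed = 7, duration = 120,
                            intervals = cbind(c(30, 70), c(40, 80))) {
  generate_recording(synthesis_config(
    n_channels = 4, rate = 64, duration = duration,
    seizure_intervals = intervals, seed = seed))
}

small_preproc <- function(...) {
  preprocess_config(band = c(0.5, 30), target_rate = 64,
                    interictal_buffer_s = 5, seed = 11, ...)
}

# random point cloud for property tests
random_cloud <- function(n, d = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  new_cloud(matrix(stats::rnorm(n * d), n, d))
}

new_cloud <- function(m) {
  fold_segment(m, 0)  # wraps a bare matrix as a point_cloud
}

# critical scales of a cloud (edge lengths) plus midpoints between them
critical_eps <- function(cloud) {
  D <- distance_matrix(cloud)
  vals <- sort(unique(D[upper.tri(D)]))
  mids <- (head(vals, -1) + tail(vals, -1)) / 2
  sort(c(vals, mids, max(vals) * 1.05))
}

# separable barcode-image set for classifier tests: renders small images
# from clouds whose scale differs by class
toy_image_set <- function(n_per_class = 30, size = 64, seed = 1) {
  set.seed(seed)
  rc <- render_config(size = size, x_range = 12)
  make <- function(scale) {
    pc <- new_cloud(matrix(stats::rnorm(16 * 4, sd = scale), 16, 4))
    render_barcode(vr_persistence(pc), rc)
  }
  images <- c(lapply(seq_len(n_per_class), function(i) make(1)),
              lapply(seq_len(n_per_class), function(i) make(3)))
  list(images = images,
       labels = rep(c("interictal", "seizure"), each = n_per_class))
}
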