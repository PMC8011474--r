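# shared fixtures: planted-spot images, smooth test images, tiny cohorts

# sample n points in [lo, hi]^2 with pairwise separation >= sep
plant_min_sep <- function(n, lo, hi, sep) {
  pts <- matrix(numeric(0), 0, 2)
  while (nrow(pts) < n) {
    p <- stats::runif(2, lo, hi)
    if (nrow(pts) == 0 ||
        min((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2) >= sep^2)
      pts <- rbind(pts, p)
  }
  colnames(pts) <- c("x", "y")
  pts
}

# smooth random image: sum of gaussian blobs (for registration tests)
smooth_image <- function(n = 64, blobs = 25) {
  img <- matrix(0, n, n)
  for (k in seq_len(blobs)) {
    cx <- stats::runif(1, 8, n - 8); cy <- stats::runif(1, 8, n - 8)
    a <- stats::runif(1, 40, 100); s <- stats::runif(1, 3, 6)
    img <- img + a * exp(-(outer((0:(n - 1) - cy)^2, (0:(n - 1) - cx)^2, "+")) /
                           (2 * s^2))
  }
  img
}

# small fast cohort configuration for pipeline-level tests
small_cohort <- function(seed, n_eyes = 12, ...) {
  cohort_config(n_eyes = n_eyes, image_size = 128, slices_per_volume = 25,
                seed = seed, ...)
}
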