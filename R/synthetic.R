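# Synthetic two-class ultrasound-like texture generator.
#
# Class 0 ("benign-like"): a smooth random base field under multiplicative
# speckle — the granular pattern characteristic of ultrasound. Class 1
# ("malignant-like"): the same construction plus sparse bright spots and
# thin linear edge segments, which raises the high-frequency (edge/spot)
# texture energy the downstream LBP and Laws descriptors measure.
#
# Reproducibility: image (class, index) is drawn under the substream seed
# `seed + index`, so an image does not depend on how many others are
# generated. Class 1 consumes the class-0 draws first and only then draws
# its spots/edges, so with spot density 0 and edge count 0 the two classes
# coincide exactly.

#' Configuration for the synthetic texture generator
#'
#' Defaults define the package's reference study conditions: 100 images per
#' class at 128x128.
#'
#' @param n_per_class Images per class (>= 1).
#' @param image_size `c(rows, cols)`, each >= 16 so that the largest LBP
#'   radius (3) and the 7x7 texture-energy window fit.
#' @param benign_smoothness Gaussian blur scale of the base field, pixels.
#' @param malignant_spot_density Fraction of pixels seeded with bright
#'   spots in class 1, in `[0, 1]`.
#' @param malignant_edge_count Number of thin linear segments added in
#'   class 1.
#' @param speckle_scale Multiplicative speckle strength (> 0).
#' @param seed Nonnegative integer base seed.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_per_class = 100L,
                             image_size = c(128L, 128L),
                             benign_smoothness = 2.5,
                             malignant_spot_density = 0.02,
                             malignant_edge_count = 4L,
                             speckle_scale = 0.3,
                             seed = 7L) {
  n_per_class <- as.integer(n_per_class)
  image_size <- as.integer(image_size)
  stopifnot(
    length(n_per_class) == 1, n_per_class >= 1L,
    length(image_size) == 2, all(image_size >= 16L),
    is.numeric(benign_smoothness), benign_smoothness > 0,
    is.numeric(malignant_spot_density),
    malignant_spot_density >= 0, malignant_spot_density <= 1,
    malignant_edge_count >= 0,
    is.numeric(speckle_scale), speckle_scale > 0,
    is.numeric(seed), seed >= 0
  )
  structure(list(n_per_class = n_per_class, image_size = image_size,
                 benign_smoothness = benign_smoothness,
                 malignant_spot_density = malignant_spot_density,
                 malignant_edge_count = as.integer(malignant_edge_count),
                 speckle_scale = speckle_scale, seed = as.integer(seed)),
            class = "synthetic_config")
}

# separable Gaussian blur with symmetric padding
.gaussian_blur <- function(x, sigma) {
  rad <- max(1L, ceiling(3 * sigma))
  rad <- min(rad, nrow(x) - 1L, ncol(x) - 1L)
  g <- exp(-((-rad):rad)^2 / (2 * sigma^2))
  g <- g / sum(g)
  correlate2d(correlate2d(x, matrix(g, ncol = 1)), matrix(g, nrow = 1))
}

#' Generate one synthetic texture image
#'
#' @param class_label 0 (benign-like) or 1 (malignant-like).
#' @param config A [synthetic_config()].
#' @param index Image index within the class, `0 <= index < n_per_class`.
#' @return Numeric matrix with values in `[0, 1]`.
#' @export
generate_texture_image <- function(class_label, config, index = 0L) {
  if (!inherits(config, "synthetic_config")) {
    stop("`config` must be a synthetic_config", call. = FALSE)
  }
  if (length(class_label) != 1 || !class_label %in% c(0, 1)) {
    stop("`class_label` must be 0 or 1", call. = FALSE)
  }
  index <- as.integer(index)
  if (index < 0L || index >= config$n_per_class) {
    stop("`index` must satisfy 0 <= index < n_per_class", call. = FALSE)
  }
  nr <- config$image_size[1]; nc <- config$image_size[2]
  with_seed(config$seed + index, {
    base <- matrix(stats::runif(nr * nc), nr, nc)
    base <- .gaussian_blur(base, config$benign_smoothness)
    rng <- range(base)
    base <- 0.25 + 0.5 * (base - rng[1]) / (rng[2] - rng[1])
    if (class_label == 1) {
      n_spots <- round(config$malignant_spot_density * nr * nc)
      if (n_spots > 0) {
        impulse <- matrix(0, nr, nc)
        impulse[sample.int(nr * nc, n_spots)] <- 1
        dot <- matrix(c(0, 0.25, 0, 0.25, 0.6, 0.25, 0, 0.25, 0), 3, 3)
        base <- base + correlate2d(impulse, dot)
      }
      if (config$malignant_edge_count > 0) {
        for (e in seq_len(config$malignant_edge_count)) {
          len <- stats::runif(1, 0.25, 0.5) * min(nr, nc)
          ang <- stats::runif(1, 0, pi)
          p0 <- c(stats::runif(1, 1, nr), stats::runif(1, 1, nc))
          t <- seq(0, len, by = 0.5)
          rr <- round(p0[1] + t * sin(ang))
          cc <- round(p0[2] + t * cos(ang))
          keep <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
          base[cbind(rr[keep], cc[keep])] <- base[cbind(rr[keep], cc[keep])] + 0.4
        }
      }
    }
    img <- base * (1 + config$speckle_scale * matrix(stats::rnorm(nr * nc), nr, nc))
    clip01(img)
  })
}

#' Generate a labeled two-class image set
#'
#' @param config A [synthetic_config()].
#' @return A list of class `labeled_image_set` with `images` (list of
#'   matrices, class 0 first) and `labels` (integer 0/1 vector).
#' @export
generate_dataset <- function(config) {
  if (!inherits(config, "synthetic_config")) {
    stop("`config` must be a synthetic_config", call. = FALSE)
  }
  n <- config$n_per_class
  images <- vector("list", 2L * n)
  labels <- integer(2L * n)
  for (i in seq_len(n)) {
    images[[i]] <- generate_texture_image(0, config, i - 1L)
  }
  for (i in seq_len(n)) {
    images[[n + i]] <- generate_texture_image(1, config, i - 1L)
    labels[n + i] <- 1L
  }
  structure(list(images = images, labels = labels), class = "labeled_image_set")
}

#' Inject noise into an image
#'
#' The three corruption models commonly used to stress ultrasound
#' denoising: additive Gaussian noise, salt-and-pepper impulses, and
#' multiplicative speckle.
#'
#' @param image Numeric matrix with finite values.
#' @param kind `"gaussian"` (adds `N(0, level^2)` per pixel),
#'   `"salt_pepper"` (each pixel independently replaced by 0 or 1 with
#'   probability `level`), or `"speckle"` (multiplies by
#'   `1 + level * N(0, 1)`).
#' @param level Nonnegative noise level; 0 returns the input unchanged.
#' @param seed Integer seed; the corruption is deterministic given it.
#' @param clip Clip the result to `[0, 1]` (default `TRUE`).
#' @return Corrupted image matrix.
#' @export
inject_noise <- function(image, kind = c("gaussian", "salt_pepper", "speckle"),
                         level, seed = 0L, clip = TRUE) {
  kind <- match.arg(kind)
  assert_image(image)
  if (!is.numeric(level) || length(level) != 1 || level < 0) {
    stop("`level` must be a single nonnegative number", call. = FALSE)
  }
  if (level == 0) return(image)
  n <- length(image)
  out <- with_seed(seed, {
    switch(kind,
      gaussian = image + matrix(stats::rnorm(n, 0, level), nrow(image)),
      salt_pepper = {
        hit <- stats::runif(n) < level
        val <- ifelse(stats::runif(n) < 0.5, 0, 1)
        x <- image
        x[hit] <- val[hit]
        x
      },
      speckle = image * (1 + level * matrix(stats::rnorm(n), nrow(image)))
    )
  })
  if (clip) clip01(out) else out
}
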