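# Local binary patterns over circular neighborhoods: original codes,
# rotation-invariant uniform (riu2) codes, per-image code maps, histograms,
# and multiscale energy/entropy descriptors.
#
# Conventions (fixed and documented): neighbor p of D sits at angle
# theta_p = 2*pi*p/D measured counterclockwise from the +column axis, so its
# offset from the center is (drow, dcol) = (-r*sin(theta_p), r*cos(theta_p)).
# Off-grid samples are bilinearly interpolated; samples that land on a grid
# node (within 1e-9) are read directly. Ties threshold as >= (T(0) = 1).

#' LBP configuration
#'
#' @param D Number of sampling points on the circle (4 to 24).
#' @param r Circle radius in pixels (>= 1, need not be integer).
#' @param mode `"riu2"` (rotation-invariant uniform, default) or `"orig"`.
#' @return A list of class `lbp_config`.
#' @export
lbp_config <- function(D = 8L, r = 1, mode = c("riu2", "orig")) {
  mode <- match.arg(mode)
  D <- as.integer(D)
  if (is.na(D) || D < 4L || D > 24L) stop("`D` must be an integer in [4, 24]", call. = FALSE)
  if (!is.numeric(r) || length(r) != 1 || r < 1) stop("`r` must be >= 1", call. = FALSE)
  structure(list(D = D, r = r, mode = mode), class = "lbp_config")
}

# angular offsets for neighbor p = 0..D-1; snapped to the grid when exact
.lbp_offsets <- function(D, r) {
  p <- seq_len(D) - 1
  theta <- 2 * pi * p / D
  dr <- -r * sin(theta)
  dc <- r * cos(theta)
  snap <- function(x) ifelse(abs(x - round(x)) < 1e-9, round(x), x)
  cbind(drow = snap(dr), dcol = snap(dc))
}

#' Sample a circular neighborhood
#'
#' Returns the gray levels \eqn{g_0, \dots, g_{D-1}} of `D` points evenly
#' spaced on a circle of radius `r` around `center`, bilinearly interpolating
#' off-grid positions.
#'
#' @param image Numeric matrix.
#' @param center Integer vector `c(row, col)`, at least `ceiling(r)` pixels
#'   away from every border.
#' @param D,r Circle geometry, see [lbp_config()].
#' @return Numeric vector of length `D`.
#' @export
sample_neighbors <- function(image, center, D, r) {
  assert_image(image, min_dim = 2L)
  m <- ceiling(r)
  if (center[1] <= m || center[1] > nrow(image) - m ||
      center[2] <= m || center[2] > ncol(image) - m) {
    stop("`center` is closer than ceiling(r) to an image border", call. = FALSE)
  }
  off <- .lbp_offsets(D, r)
  rr <- center[1] + off[, "drow"]
  cc <- center[2] + off[, "dcol"]
  r0 <- floor(rr); c0 <- floor(cc)
  fr <- rr - r0;   fc <- cc - c0
  r1 <- pmin(r0 + 1, nrow(image)); c1 <- pmin(c0 + 1, ncol(image))
  (1 - fr) * (1 - fc) * image[cbind(r0, c0)] +
    (1 - fr) * fc * image[cbind(r0, c1)] +
    fr * (1 - fc) * image[cbind(r1, c0)] +
    fr * fc * image[cbind(r1, c1)]
}

#' Original LBP code
#'
#' Thresholds each neighbor against the center (`>=` maps to bit 1) and
#' packs the bits with binomial weights: code \eqn{= \sum_p b_p 2^p}.
#'
#' @param neighbors Numeric vector `g_0..g_{D-1}`.
#' @param g_c Center gray level.
#' @param D Number of neighbors; must equal `length(neighbors)`.
#' @return Integer code in `[0, 2^D - 1]`.
#' @export
lbp_code_orig <- function(neighbors, g_c, D) {
  if (length(neighbors) != D) stop("`neighbors` must have length D", call. = FALSE)
  bits <- as.numeric(neighbors >= g_c)
  sum(bits * 2^(seq_len(D) - 1))
}

#' Circular uniformity of a bit pattern
#'
#' Counts the 0/1 transitions when the bit string is traversed circularly;
#' patterns with at most two transitions are called uniform.
#'
#' @param bits Vector of 0/1 values, length >= 2.
#' @return Integer transition count `U`.
#' @export
lbp_uniformity <- function(bits) {
  D <- length(bits)
  if (D < 2) stop("`bits` must have length >= 2", call. = FALSE)
  sum(bits != bits[c(2:D, 1)])
}

#' Rotation-invariant uniform (riu2) LBP code
#'
#' Uniform patterns (`U <= 2`) are coded by their number of 1-bits
#' (0..D); all non-uniform patterns share the single code `D + 1`.
#'
#' @inheritParams lbp_code_orig
#' @return Integer code in `[0, D + 1]`.
#' @export
lbp_code_riu2 <- function(neighbors, g_c, D) {
  if (length(neighbors) != D) stop("`neighbors` must have length D", call. = FALSE)
  bits <- as.numeric(neighbors >= g_c)
  if (lbp_uniformity(bits) <= 2) sum(bits) else D + 1
}

#' LBP code image
#'
#' Computes the LBP code of every pixel whose full circular neighborhood
#' fits inside the image; the returned code grid is smaller than the input
#' by `ceiling(r)` on each side.
#'
#' @param image Numeric matrix, larger than `2*ceiling(r) + 1` in both
#'   dimensions.
#' @param config An [lbp_config()].
#' @return Object of class `lbp_image`: list with the integer `codes`
#'   matrix, the `config` and the `valid_margin`.
#' @export
lbp_image <- function(image, config) {
  if (!inherits(config, "lbp_config")) stop("`config` must be an lbp_config", call. = FALSE)
  assert_image(image)
  m <- as.integer(ceiling(config$r))
  nr <- nrow(image) - 2L * m
  nc <- ncol(image) - 2L * m
  if (nrow(image) <= 2L * m + 1L || ncol(image) <= 2L * m + 1L) {
    stop(sprintf("image too small for radius %s (needs > %d in each dimension)",
                 format(config$r), 2L * m + 1L), call. = FALSE)
  }
  D <- config$D
  off <- .lbp_offsets(D, config$r)
  center <- image[m + seq_len(nr), m + seq_len(nc), drop = FALSE]
  # bilinear sample of neighbor p for every valid center at once
  neighbor_plane <- function(p) {
    rr <- off[p, "drow"]; cc <- off[p, "dcol"]
    r0 <- floor(rr); c0 <- floor(cc)
    fr <- rr - r0;   fc <- cc - c0
    # when an offset is exact the +1 block has zero weight; skip it so the
    # index stays inside the padded range
    r1 <- if (fr == 0) r0 else r0 + 1
    c1 <- if (fc == 0) c0 else c0 + 1
    blk <- function(dr, dc) {
      image[m + dr + seq_len(nr), m + dc + seq_len(nc), drop = FALSE]
    }
    (1 - fr) * (1 - fc) * blk(r0, c0) +
      (1 - fr) * fc * blk(r0, c1) +
      fr * (1 - fc) * blk(r1, c0) +
      fr * fc * blk(r1, c1)
  }
  bits <- vector("list", D)
  for (p in seq_len(D)) {
    bits[[p]] <- (neighbor_plane(p) >= center) * 1
  }
  if (config$mode == "orig") {
    codes <- matrix(0, nr, nc)
    for (p in seq_len(D)) codes <- codes + bits[[p]] * 2^(p - 1)
  } else {
    ones <- Reduce(`+`, bits)
    trans <- matrix(0, nr, nc)
    for (p in seq_len(D)) {
      q <- if (p == D) 1L else p + 1L
      trans <- trans + (bits[[p]] != bits[[q]])
    }
    codes <- ifelse(trans <= 2, ones, D + 1)
  }
  structure(list(codes = codes, config = config, valid_margin = m),
            class = "lbp_image")
}

#' Normalized LBP histogram
#'
#' @param lbp An [lbp_image()] result.
#' @return Object of class `lbp_histogram`: normalized bin frequencies over
#'   `2^D` bins (`orig`) or `D + 2` bins (`riu2`, codes `0..D+1`).
#' @export
lbp_histogram <- function(lbp) {
  if (!inherits(lbp, "lbp_image")) stop("`lbp` must be an lbp_image", call. = FALSE)
  codes <- lbp$codes
  if (length(codes) == 0) stop("empty code grid", call. = FALSE)
  nbins <- if (lbp$config$mode == "orig") 2^lbp$config$D else lbp$config$D + 2L
  counts <- tabulate(as.integer(codes) + 1L, nbins = nbins)
  structure(list(bins = counts / sum(counts), mode = lbp$config$mode,
                 D = lbp$config$D),
            class = "lbp_histogram")
}

#' Multiscale LBP energy/entropy descriptors
#'
#' For each scale `(D, r)` the riu2 histogram `h` is summarized by its
#' energy \eqn{\sum_i h_i^2} and Shannon entropy \eqn{-\sum_i h_i \log_2
#' h_i} (with \eqn{0 \log 0 = 0}), yielding two named features per scale.
#'
#' @param image Numeric matrix, large enough for the largest radius.
#' @param scales List of `c(D, r)` pairs; default
#'   `list(c(8, 1), c(16, 2), c(24, 3))`.
#' @return Named numeric vector, `lbp_energy_D{D}_r{r}` and
#'   `lbp_entropy_D{D}_r{r}` per scale.
#' @export
lbp_features <- function(image, scales = list(c(8, 1), c(16, 2), c(24, 3))) {
  out <- numeric(0)
  for (s in scales) {
    cfg <- lbp_config(D = s[1], r = s[2], mode = "riu2")
    h <- lbp_histogram(lbp_image(image, cfg))$bins
    nz <- h[h > 0]
    tag <- sprintf("D%d_r%s", cfg$D, format(cfg$r, trim = TRUE))
    v <- c(sum(h^2), -sum(nz * log2(nz)))
    names(v) <- paste0(c("lbp_energy_", "lbp_entropy_"), tag)
    out <- c(out, v)
  }
  out
}
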