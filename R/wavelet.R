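# 2-D discrete wavelet transform with symmetric half-sample boundary
# extension, multi-level decomposition, and soft-threshold denoising.
#
# The separable DWT is implemented directly (orthonormal haar/db2/db4
# filter banks): coefficients follow the usual boundary-extended layout in
# which a length-n signal yields floor((n + L - 1)/2) coefficients per band
# for a length-L filter (= ceiling(n/2) for Haar). Reconstruction is exact
# for all supported sizes and wavelets.

# Orthonormal reconstruction low-pass filters; decomposition filters and the
# high-pass pair follow from the quadrature-mirror relations.
.wavelet_filters <- function(wavelet) {
  rec_lo <- switch(wavelet,
    haar = c(0.7071067811865476, 0.7071067811865476),
    db2  = c(0.4829629131445341, 0.8365163037378079,
             0.2241438680420134, -0.1294095225512604),
    db4  = c(0.2303778133088965, 0.7148465705529157, 0.6308807679298589,
             -0.0279837694168599, -0.1870348117190931, 0.0308413818355607,
             0.0328830116668852, -0.0105974017850690),
    stop(sprintf("unsupported wavelet '%s' (use haar, db2 or db4)", wavelet),
         call. = FALSE)
  )
  L <- length(rec_lo)
  dec_lo <- rev(rec_lo)
  dec_hi <- rev(dec_lo) * (-1)^(seq_len(L) - 1)
  list(dec_lo = dec_lo, dec_hi = dec_hi,
       rec_lo = rec_lo, rec_hi = rev(dec_hi), L = L)
}

# One analysis step along the columns of X. Returns approximation and detail
# halves, each with floor((n + L - 1)/2) rows.
.dwt_cols <- function(X, f) {
  n <- nrow(X); L <- f$L
  if (n < L - 1) stop("signal too short for this wavelet", call. = FALSE)
  XE <- if (L > 2) {
    rbind(X[rev(seq_len(L - 1)), , drop = FALSE], X, X[n:(n - L + 2), , drop = FALSE])
  } else {
    rbind(X[1, , drop = FALSE], X, X[n, , drop = FALSE])
  }
  nv <- nrow(XE) - L + 1
  a <- matrix(0, nv, ncol(X)); d <- matrix(0, nv, ncol(X))
  for (j in seq_len(L)) {
    seg <- XE[j:(j + nv - 1), , drop = FALSE]
    a <- a + f$dec_lo[L - j + 1] * seg
    d <- d + f$dec_hi[L - j + 1] * seg
  }
  keep <- seq(2, nv, by = 2)
  list(a = a[keep, , drop = FALSE], d = d[keep, , drop = FALSE])
}

# One synthesis step along columns; `n` is the original row count.
.idwt_cols <- function(A, D, f, n) {
  up <- function(C) {
    U <- matrix(0, 2 * nrow(C), ncol(C))
    U[seq(1, 2 * nrow(C), by = 2), ] <- C
    U
  }
  conv_full <- function(U, g) {
    L <- length(g); m <- nrow(U)
    R <- matrix(0, m + L - 1, ncol(U))
    for (j in seq_len(L)) {
      R[j:(j + m - 1), ] <- R[j:(j + m - 1), ] + g[j] * U
    }
    R
  }
  R <- conv_full(up(A), f$rec_lo) + conv_full(up(D), f$rec_hi)
  i0 <- f$L - 1
  R[i0:(i0 + n - 1), , drop = FALSE]
}

#' One-level 2-D discrete wavelet transform
#'
#' Splits an image into an approximation band `B` (low-low) and three detail
#' bands: `J` (low-high, horizontal detail), `U` (high-low, vertical detail)
#' and `F` (high-high, diagonal detail), using a separable orthonormal
#' filter bank with symmetric half-sample boundary extension.
#'
#' @param image Numeric matrix of finite values, at least 2x2.
#' @param wavelet One of `"haar"` (default), `"db2"`, `"db4"`.
#' @return A list with matrices `B`, `J`, `U`, `F`.
#' @examples
#' b <- dwt2_level(matrix(1, 2, 2))
#' b$B          # [[2]] for the orthonormal Haar transform
#' @export
dwt2_level <- function(image, wavelet = "haar") {
  assert_image(image)
  f <- .wavelet_filters(wavelet)
  rows <- .dwt_cols(t(image), f)            # filter along the original columns
  lo <- .dwt_cols(t(rows$a), f)             # then along the rows
  hi <- .dwt_cols(t(rows$d), f)
  list(B = lo$a, J = hi$a, U = lo$d, F = hi$d)
}

.idwt2_level <- function(B, J, U, F, wavelet, shape) {
  f <- .wavelet_filters(wavelet)
  lo <- .idwt_cols(B, U, f, shape[1])
  hi <- .idwt_cols(J, F, f, shape[1])
  t(.idwt_cols(t(lo), t(hi), f, shape[2]))
}

#' Multi-level 2-D wavelet decomposition
#'
#' Recursively applies [dwt2_level()] to the approximation band, producing
#' the familiar pyramid: at three levels the image is represented by one
#' approximation band plus nine detail bands (J/U/F at each level).
#'
#' @inheritParams dwt2_level
#' @param levels Number of decomposition levels, 1 to 3.
#' @return An object of class `wavelet_decomposition`: a list with `approx`
#'   (the final approximation band), `details` (per level, a list with `J`,
#'   `U`, `F`), `levels`, `wavelet` and the per-level input shapes needed for
#'   exact reconstruction.
#' @seealso [wavelet_reconstruct()], [wavelet_denoise()]
#' @export
wavelet_decompose <- function(image, wavelet = "haar", levels = 3L) {
  assert_image(image)
  levels <- as.integer(levels)
  if (!levels %in% 1:3) stop("`levels` must be 1, 2 or 3", call. = FALSE)
  f <- .wavelet_filters(wavelet)
  # a level is feasible while the current band supports the filter extension
  feasible <- 0L
  d <- dim(image)
  while (feasible < levels && all(d >= max(2L, f$L - 1L))) {
    feasible <- feasible + 1L
    d <- floor((d + f$L - 1) / 2)
  }
  if (feasible < levels) {
    stop(sprintf("image too small for %d levels (maximum feasible: %d)",
                 levels, feasible), call. = FALSE)
  }
  approx <- image
  details <- vector("list", levels)
  shapes <- vector("list", levels)
  for (l in seq_len(levels)) {
    shapes[[l]] <- dim(approx)
    bands <- dwt2_level(approx, wavelet)
    details[[l]] <- bands[c("J", "U", "F")]
    approx <- bands$B
  }
  structure(
    list(approx = approx, details = details, levels = levels,
         wavelet = wavelet, shapes = shapes),
    class = "wavelet_decomposition"
  )
}

#' Inverse multi-level 2-D wavelet transform
#'
#' @param decomp A `wavelet_decomposition` from [wavelet_decompose()].
#' @return The reconstructed image matrix, equal to the decomposed input up
#'   to floating-point round-off.
#' @export
wavelet_reconstruct <- function(decomp) {
  if (!inherits(decomp, "wavelet_decomposition")) {
    stop("`decomp` must be a wavelet_decomposition", call. = FALSE)
  }
  approx <- decomp$approx
  for (l in rev(seq_len(decomp$levels))) {
    det <- decomp$details[[l]]
    if (!identical(dim(det$J), dim(approx)) ||
        !identical(dim(det$U), dim(approx)) ||
        !identical(dim(det$F), dim(approx))) {
      stop(sprintf("band shape mismatch at level %d", l), call. = FALSE)
    }
    approx <- .idwt2_level(approx, det$J, det$U, det$F,
                           decomp$wavelet, decomp$shapes[[l]])
  }
  approx
}

#' Wavelet shrinkage denoising
#'
#' Soft-thresholds every detail coefficient of a multi-level decomposition
#' and reconstructs. The `"universal"` rule (VisuShrink) uses
#' \eqn{t = \hat\sigma \sqrt{2 \log N}} with the noise scale
#' \eqn{\hat\sigma = \mathrm{median}(|F_1|)/0.6745} estimated from the
#' finest diagonal band and N the pixel count; the approximation band is
#' never touched.
#'
#' @inheritParams wavelet_decompose
#' @param threshold_rule `"universal"` (default) or `"manual"`.
#' @param manual_t Nonnegative threshold used when `threshold_rule =
#'   "manual"`; `manual_t = 0` returns the input unchanged (up to round-off).
#' @return The denoised image matrix.
#' @export
wavelet_denoise <- function(image, wavelet = "haar", levels = 1L,
                            threshold_rule = c("universal", "manual"),
                            manual_t = 0) {
  threshold_rule <- match.arg(threshold_rule)
  dec <- wavelet_decompose(image, wavelet, levels)
  if (threshold_rule == "manual") {
    if (!is.numeric(manual_t) || length(manual_t) != 1 || manual_t < 0) {
      stop("`manual_t` must be a single nonnegative number", call. = FALSE)
    }
    t <- manual_t
  } else {
    sigma <- stats::median(abs(dec$details[[1]]$F)) / 0.6745
    t <- sigma * sqrt(2 * log(length(image)))
  }
  soft <- function(x) sign(x) * pmax(abs(x) - t, 0)
  dec$details <- lapply(dec$details, function(d) lapply(d, soft))
  wavelet_reconstruct(dec)
}
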