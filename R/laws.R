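# Laws' texture-energy features from the 3x3 mask family built on the
# level [1,2,1], border/edge [-1,0,1] and dot/spot [-1,2,-1] vectors.
# Pipeline per mask: filter -> contrast-balance by the L3L3 response ->
# 7x7 texture-energy window over absolute values -> mean.

.laws_vectors <- list(
  L3 = c(1, 2, 1),
  B3 = c(-1, 0, 1),
  D3 = c(-1, 2, -1)
)

#' The nine 3x3 Laws masks
#'
#' Each mask `XY` is the outer product of column vector `X` and row vector
#' `Y` with `L3 = (1,2,1)`, `B3 = (-1,0,1)`, `D3 = (-1,2,-1)`. Every mask
#' except `L3L3` has zero sum; `L3L3` sums to 16 and acts as the local
#' luminance estimate used for contrast balancing.
#'
#' @return Named list of nine 3x3 integer matrices (`L3L3`, `L3B3`, ...).
#' @export
laws_masks <- function() {
  out <- list()
  for (x in names(.laws_vectors)) {
    for (y in names(.laws_vectors)) {
      out[[paste0(x, y)]] <- outer(.laws_vectors[[x]], .laws_vectors[[y]])
    }
  }
  out
}

# the eight zero-sum masks, in a fixed feature order
.laws_feature_masks <- c("L3B3", "L3D3", "B3L3", "B3B3", "B3D3",
                         "D3L3", "D3B3", "D3D3")

#' Filter an image with a Laws mask
#'
#' 2-D cross-correlation with symmetric boundary padding; the output has
#' the same shape as the input.
#'
#' @param image Numeric matrix, at least 3x3.
#' @param mask A 3x3 numeric matrix (typically from [laws_masks()]).
#' @return Numeric matrix of filter responses.
#' @export
laws_filter <- function(image, mask) {
  assert_image(image, min_dim = 3L)
  if (!is.matrix(mask) || any(dim(mask) != c(3L, 3L))) {
    stop("`mask` must be a 3x3 matrix", call. = FALSE)
  }
  correlate2d(image, mask)
}

#' Contrast-balance a texture image
#'
#' Divides a filter response elementwise by the `L3L3` response, removing
#' the local luminance/contrast so that texture energy is scale-free. The
#' divisor magnitude is floored at `epsilon` (sign preserved) so zeros in
#' the `L3L3` map cannot produce non-finite output.
#'
#' @param tp Filter response matrix.
#' @param tp_l3l3 `L3L3` response matrix of the same shape.
#' @param epsilon Positive magnitude floor for the divisor; default `1e-8`.
#' @return Balanced matrix, `tp / sign-preserving max(|tp_l3l3|, epsilon)`.
#' @export
laws_balance <- function(tp, tp_l3l3, epsilon = 1e-8) {
  if (!identical(dim(tp), dim(tp_l3l3))) stop("shape mismatch", call. = FALSE)
  if (!is.numeric(epsilon) || epsilon <= 0) stop("`epsilon` must be > 0", call. = FALSE)
  mag <- pmax(abs(tp_l3l3), epsilon)
  denom <- ifelse(tp_l3l3 < 0, -mag, mag)
  tp / denom
}

#' Texture energy map (7x7 window)
#'
#' Moving-window sum of absolute balanced responses over a 7x7 frame with
#' symmetric boundary padding. The absolute value makes the statistic an
#' energy: zero-mean filter responses would otherwise cancel to ~0 under a
#' plain window sum.
#'
#' @param balanced Numeric matrix, at least 7x7.
#' @return Nonnegative matrix of the same shape.
#' @export
laws_tem <- function(balanced) {
  assert_image(balanced, min_dim = 7L)
  correlate2d(abs(balanced), matrix(1, 7, 7))
}

#' Laws' texture-energy feature vector
#'
#' For each of the eight zero-sum masks: filter, balance by the `L3L3`
#' response, apply the 7x7 texture-energy window, and summarize by the mean
#' of the energy map. The features are invariant to a positive rescaling
#' of the input image (up to the `epsilon` divisor floor).
#'
#' @inheritParams laws_filter
#' @param epsilon Divisor floor passed to [laws_balance()].
#' @return Named nonnegative numeric vector of length 8
#'   (`laws_L3B3`, ..., `laws_D3D3`).
#' @export
laws_features <- function(image, epsilon = 1e-8) {
  assert_image(image, min_dim = 7L)
  masks <- laws_masks()
  tp_l3l3 <- laws_filter(image, masks$L3L3)
  out <- vapply(.laws_feature_masks, function(nm) {
    tp <- laws_filter(image, masks[[nm]])
    mean(laws_tem(laws_balance(tp, tp_l3l3, epsilon)))
  }, numeric(1))
  names(out) <- paste0("laws_", .laws_feature_masks)
  out
}
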