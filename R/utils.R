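# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

assert_image <- function(image, min_dim = 2L, arg = "image") {
  if (!is.matrix(image) || !is.numeric(image)) {
    stop(sprintf("`%s` must be a numeric matrix", arg), call. = FALSE)
  }
  if (any(!is.finite(image))) {
    stop(sprintf("`%s` contains non-finite values", arg), call. = FALSE)
  }
  if (nrow(image) < min_dim || ncol(image) < min_dim) {
    stop(sprintf("`%s` must be at least %dx%d (got %dx%d)",
                 arg, min_dim, min_dim, nrow(image), ncol(image)), call. = FALSE)
  }
  invisible(image)
}

# Half-sample symmetric padding: ... x2 x1 | x1 x2 ... xn | xn x(n-1) ...
pad_symmetric <- function(x, k) {
  n <- nrow(x); m <- ncol(x)
  if (k >= n || k >= m) stop("image too small for requested padding", call. = FALSE)
  ri <- c(rev(seq_len(k)), seq_len(n), n:(n - k + 1))
  ci <- c(rev(seq_len(k)), seq_len(m), m:(m - k + 1))
  x[ri, ci, drop = FALSE]
}

# 2-D cross-correlation with an odd-sized kernel, symmetric boundary padding,
# output the same shape as the input.
correlate2d <- function(image, kernel) {
  kr <- nrow(kernel); kc <- ncol(kernel)
  if (kr %% 2 == 0 || kc %% 2 == 0) stop("kernel dimensions must be odd", call. = FALSE)
  a <- (kr - 1) %/% 2; b <- (kc - 1) %/% 2
  k <- max(a, b)
  xp <- pad_symmetric(image, k)
  n <- nrow(image); m <- ncol(image)
  out <- matrix(0, n, m)
  for (u in seq_len(kr)) {
    for (v in seq_len(kc)) {
      w <- kernel[u, v]
      if (w == 0) next
      out <- out + w * xp[(k - a + u - 1) + seq_len(n), (k - b + v - 1) + seq_len(m), drop = FALSE]
    }
  }
  out
}

clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}
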