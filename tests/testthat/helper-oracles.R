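# Independent brute-force oracles used to cross-check the vectorized
# implementations. These deliberately share no code with the package: plain
# double loops and direct index arithmetic.

# bilinear read at fractional (row, col)
oracle_bilinear <- function(image, r, c) {
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  r1 <- min(r0 + 1, nrow(image)); c1 <- min(c0 + 1, ncol(image))
  (1 - fr) * (1 - fc) * image[r0, c0] + (1 - fr) * fc * image[r0, c1] +
    fr * (1 - fc) * image[r1, c0] + fr * fc * image[r1, c1]
}

# per-pixel LBP code map by explicit loops
oracle_lbp_image <- function(image, D, r, mode = "riu2") {
  m <- ceiling(r)
  nr <- nrow(image) - 2 * m
  nc <- ncol(image) - 2 * m
  codes <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      ci <- m + i; cj <- m + j
      gc <- image[ci, cj]
      bits <- numeric(D)
      for (p in 0:(D - 1)) {
        th <- 2 * pi * p / D
        rr <- ci - r * sin(th)
        cc <- cj + r * cos(th)
        if (abs(rr - round(rr)) < 1e-9) rr <- round(rr)
        if (abs(cc - round(cc)) < 1e-9) cc <- round(cc)
        bits[p + 1] <- as.numeric(oracle_bilinear(image, rr, cc) >= gc)
      }
      if (mode == "orig") {
        codes[i, j] <- sum(bits * 2^(0:(D - 1)))
      } else {
        u <- sum(bits != c(bits[-1], bits[1]))
        codes[i, j] <- if (u <= 2) sum(bits) else D + 1
      }
    }
  }
  codes
}

# mirror (half-sample symmetric) index into 1..n
oracle_mirror <- function(i, n) {
  while (i < 1 || i > n) {
    if (i < 1) i <- 1 - i
    if (i > n) i <- 2 * n + 1 - i
  }
  i
}

# 7x7 moving window sum of absolute values, symmetric padding, by loops
oracle_tem <- function(x) {
  n <- nrow(x); m <- ncol(x)
  out <- matrix(0, n, m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- 0
      for (u in -3:3) {
        for (v in -3:3) {
          s <- s + abs(x[oracle_mirror(i + u, n), oracle_mirror(j + v, m)])
        }
      }
      out[i, j] <- s
    }
  }
  out
}

# 3x3 cross-correlation with symmetric padding, by loops
oracle_correlate3 <- function(x, k) {
  n <- nrow(x); m <- ncol(x)
  out <- matrix(0, n, m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- 0
      for (u in -1:1) {
        for (v in -1:1) {
          s <- s + k[u + 2, v + 2] * x[oracle_mirror(i + u, n), oracle_mirror(j + v, m)]
        }
      }
      out[i, j] <- s
    }
  }
  out
}

# one-level Haar DWT for even-sized images by direct filter-and-downsample
oracle_haar_dwt2 <- function(x) {
  stopifnot(nrow(x) %% 2 == 0, ncol(x) %% 2 == 0)
  lo <- function(a, b) (a + b) / sqrt(2)
  hi <- function(a, b) (a - b) / sqrt(2)
  n2 <- nrow(x) / 2; m2 <- ncol(x) / 2
  B <- J <- U <- F_ <- matrix(0, n2, m2)
  for (i in seq_len(n2)) {
    for (j in seq_len(m2)) {
      a <- x[2 * i - 1, 2 * j - 1]; b <- x[2 * i - 1, 2 * j]
      c <- x[2 * i, 2 * j - 1];     d <- x[2 * i, 2 * j]
      B[i, j] <- lo(lo(a, b), lo(c, d))
      U[i, j] <- hi(lo(a, b), lo(c, d))   # high along rows (vertical variation)
      J[i, j] <- lo(hi(a, b), hi(c, d))   # high along columns
      F_[i, j] <- hi(hi(a, b), hi(c, d))
    }
  }
  list(B = B, J = J, U = U, F = F_)
}

# two-sided Fisher p for a 2x2 table by hypergeometric enumeration
oracle_fisher_p <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  support <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- dhyper(support, c1, n - c1, r1)
  p_obs <- dhyper(a, c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

rand_image <- function(nr, nc, seed) {
  set.seed(seed)
  matrix(runif(nr * nc), nr, nc)
}
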