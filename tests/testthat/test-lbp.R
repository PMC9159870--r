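test_that("circular sampling reads exact grid points and interpolates off-grid ones", {
  img <- matrix(as.numeric(1:25), 5, 5)
  g <- sample_neighbors(img, c(3, 3), D = 8, r = 1)
  # p = 0 -> (row, col+1); p = 2 -> (row-1, col); p = 4 -> (row, col-1)
  expect_equal(g[1], img[3, 4])
  expect_equal(g[3], img[2, 3])
  expect_equal(g[5], img[3, 2])
  expect_equal(g[7], img[4, 3])

  # p = 1 at D=8, r=1: offset (-sqrt(2)/2, +sqrt(2)/2); hand-computed
  # bilinear blend of the four surrounding pixels
  patch <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8, 9), 3, 3, byrow = TRUE)
  g1 <- sample_neighbors(patch, c(2, 2), D = 8, r = 1)[2]
  fr <- 1 - sqrt(2) / 2; fc <- sqrt(2) / 2
  hand <- (1 - fr) * (1 - fc) * patch[1, 2] + (1 - fr) * fc * patch[1, 3] +
    fr * (1 - fc) * patch[2, 2] + fr * fc * patch[2, 3]
  expect_equal(g1, hand, tolerance = 1e-12)

  # constant image: every sample equals the constant at any scale
  const <- matrix(0.4, 11, 11)
  for (s in list(c(8, 1), c(16, 2), c(24, 3))) {
    expect_equal(sample_neighbors(const, c(6, 6), s[1], s[2]),
                 rep(0.4, s[1]), tolerance = 1e-12)
  }

  expect_error(sample_neighbors(img, c(1, 3), 8, 1), "border")
})

test_that("LBP codes follow the thresholding and coding rules", {
  # T(0) = 1: equality counts as 1, so a flat neighborhood is all ones
  expect_equal(lbp_code_orig(rep(5, 8), 5, 8), 255)
  expect_equal(lbp_code_orig(rep(4, 8), 5, 8), 0)
  expect_equal(lbp_code_orig(c(6, 4, 6, 4, 6, 4, 6, 4), 5, 8), 85)

  expect_equal(lbp_uniformity(rep(0, 8)), 0)
  expect_equal(lbp_uniformity(c(1, 1, 1, 1, 0, 0, 0, 0)), 2)
  expect_equal(lbp_uniformity(c(0, 1, 0, 1, 0, 1, 0, 1)), 8)

  expect_equal(lbp_code_riu2(rep(5, 8), 5, 8), 8)           # uniform, all ones
  expect_equal(lbp_code_riu2(c(4, 4, 4, 4, 6, 6, 6, 6), 5, 8), 4)
  expect_equal(lbp_code_riu2(c(4, 6, 4, 6, 4, 6, 4, 6), 5, 8), 9)  # non-uniform
})

test_that("exhaustive 8-bit enumeration: 58 uniform patterns, 10 riu2 codes, rotation invariance", {
  to_bits <- function(n) as.numeric(intToBits(n))[1:8]
  riu2_of <- function(bits) lbp_code_riu2(ifelse(bits == 1, 1, -1), 0, 8)
  codes <- vapply(0:255, function(n) riu2_of(to_bits(n)), numeric(1))
  uniform <- vapply(0:255, function(n) lbp_uniformity(to_bits(n)) <= 2, logical(1))
  expect_equal(sum(uniform), 58)
  expect_equal(sort(unique(codes)), 0:9)
  # every cyclic rotation of the neighbor bits yields the same riu2 code
  for (n in 0:255) {
    bits <- to_bits(n)
    base <- riu2_of(bits)
    for (k in 1:7) {
      expect_identical(riu2_of(bits[c((k + 1):8, 1:k)]), base)
    }
  }
})

test_that("vectorized code image equals the naive per-pixel oracle", {
  for (seed in 1:20) {
    img <- rand_image(16, 16, seed)
    for (s in list(c(8, 1), c(16, 2), c(24, 3))) {
      for (mode in if (s[1] == 8) c("riu2", "orig") else "riu2") {
        got <- lbp_image(img, lbp_config(s[1], s[2], mode))
        ref <- oracle_lbp_image(img, s[1], s[2], mode)
        expect_equal(got$codes, ref,
                     info = sprintf("seed %d D=%d r=%d %s", seed, s[1], s[2], mode))
        expect_equal(dim(got$codes), dim(img) - 2 * ceiling(s[2]))
      }
    }
  }
})

test_that("LBP codes are invariant to gray-level shifts and bounded by mode", {
  img <- rand_image(14, 14, 42)
  cfg <- lbp_config(8, 1, "riu2")
  expect_identical(lbp_image(img, cfg)$codes, lbp_image(img + 0.37, cfg)$codes)
  expect_true(all(lbp_image(img, cfg)$codes <= 9))
  cfg_o <- lbp_config(8, 1, "orig")
  expect_true(all(lbp_image(img, cfg_o)$codes <= 255))
  expect_error(lbp_image(matrix(1, 3, 3), lbp_config(8, 1)), "too small")
})

test_that("histograms are normalized with mode-dependent bin counts", {
  const <- matrix(0.5, 10, 10)
  h <- lbp_histogram(lbp_image(const, lbp_config(8, 1, "riu2")))
  expect_length(h$bins, 10)        # codes 0..9
  expect_equal(h$bins[9], 1)       # code 8 = all-ones uniform pattern
  expect_equal(sum(h$bins), 1, tolerance = 1e-12)

  ho <- lbp_histogram(lbp_image(rand_image(12, 12, 3), lbp_config(8, 1, "orig")))
  expect_length(ho$bins, 256)
  expect_equal(sum(ho$bins), 1, tolerance = 1e-12)
  expect_true(all(ho$bins >= 0))
})

test_that("multiscale energy/entropy descriptors match their closed forms", {
  # degenerate histogram: all mass in one bin
  const <- matrix(0.5, 20, 20)
  f <- lbp_features(const)
  expect_length(f, 6)
  expect_named(f, c("lbp_energy_D8_r1", "lbp_entropy_D8_r1",
                    "lbp_energy_D16_r2", "lbp_entropy_D16_r2",
                    "lbp_energy_D24_r3", "lbp_entropy_D24_r3"))
  expect_equal(unname(f[c(1, 3, 5)]), rep(1, 3), tolerance = 1e-12)
  expect_equal(unname(f[c(2, 4, 6)]), rep(0, 3), tolerance = 1e-12)

  # uniform histogram closed form: energy 1/k, entropy log2(k)
  h <- rep(1 / 10, 10)
  expect_equal(sum(h^2), 0.1)
  expect_equal(-sum(h * log2(h)), log2(10))

  # generic image: energy in (0, 1], entropy within [0, log2(bins)]
  f2 <- lbp_features(rand_image(24, 24, 8))
  expect_true(all(f2[c(1, 3, 5)] > 0 & f2[c(1, 3, 5)] <= 1))
  expect_true(all(f2[c(2, 4, 6)] >= 0))
  expect_lte(f2[["lbp_entropy_D8_r1"]], log2(10))
})
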