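fit_toy_model <- function() {
  # hand-built model: alpha 1, one slope 2, identity standardization
  structure(list(alpha = 1, betas = c(f = 2), feature_names = "f",
                 standardize_means = c(f = 0), standardize_sds = c(f = 1),
                 ridge_lambda = 0, converged = TRUE, n_iter = 0, loglik = 0),
            class = "ulr_model")
}

test_that("the two closed forms of the inverse logit agree and probabilities pair to 1", {
  a <- seq(-30, 30, by = 0.25)
  expect_equal(exp(a) / (1 + exp(a)), 1 / (1 + exp(-a)), tolerance = 1e-12)

  m <- fit_toy_model()
  expect_equal(predict_prob(m, c(f = -0.5)), 0.5)           # a = 0
  expect_equal(predict_prob(m, c(f = 0)), exp(1) / (1 + exp(1)), tolerance = 1e-12)
  # P(R=1) + P(R=0) = 1 for random models and inputs
  set.seed(3)
  for (i in 1:50) {
    x <- c(f = rnorm(1, 0, 5))
    p1 <- predict_prob(m, x)
    p0 <- 1 / (1 + exp(log_odds(m, x)))
    expect_lt(abs(p1 + p0 - 1), 1e-15)
    expect_true(p1 > 0 && p1 < 1)
  }
  # numerically stable far into the tails
  expect_equal(predict_prob(m, c(f = 400)), 1)
  expect_equal(predict_prob(m, c(f = -400)), 0)
})

test_that("the linear predictor is linear with slope beta_j", {
  m <- fit_toy_model()
  expect_equal(log_odds(m, c(f = 0.5)), 2.0)
  zero <- structure(modifyList(m, list(alpha = 0, betas = c(f = 0))),
                    class = "ulr_model")
  expect_equal(log_odds(zero, c(f = 123)), 0)
  # finite-difference slope equals the coefficient
  h <- 1e-6
  slope <- (log_odds(m, c(f = 1 + h)) - log_odds(m, c(f = 1))) / h
  expect_equal(slope, 2, tolerance = 1e-4)
  expect_error(log_odds(m, c(g = 1)), "missing feature")
})

test_that("maximum-likelihood fitting recovers simulated parameters", {
  set.seed(42)
  n <- 5000
  X <- matrix(rnorm(2 * n), n, 2, dimnames = list(NULL, c("a", "b")))
  y <- rbinom(n, 1, 1 / (1 + exp(-(-1 + 2 * X[, 1] - X[, 2]))))
  fit <- ulr_fit(X, y, ridge_lambda = 0)
  expect_true(fit$converged)
  # features are ~N(0,1) so standardized coefficients estimate the truth
  expect_lt(abs(fit$alpha - (-1)), 0.15)
  expect_lt(abs(fit$betas[["a"]] - 2), 0.15)
  expect_lt(abs(fit$betas[["b"]] - (-1)), 0.15)

  # independent oracle: glm's IRLS on the same standardized design
  Z <- scale(X)
  ref <- glm(y ~ Z, family = binomial)
  expect_equal(unname(fit$alpha), unname(coef(ref)[1]), tolerance = 1e-6)
  expect_equal(unname(fit$betas), unname(coef(ref)[-1]), tolerance = 1e-6)
})

test_that("null data give bounded coefficients and base-rate intercepts", {
  set.seed(11)
  X <- matrix(rnorm(4000), 2000, 2, dimnames = list(NULL, c("a", "b")))
  y <- rep(0:1, 1000)
  fit <- ulr_fit(X, y, ridge_lambda = 0)
  expect_lt(abs(fit$alpha), 0.1)
  expect_true(all(abs(fit$betas) < 0.15))

  # 3:1 class ratio with zero-signal features: intercept ~ log(3)
  set.seed(12)
  y2 <- rbinom(2000, 1, 0.75)
  fit2 <- ulr_fit(X, y2, ridge_lambda = 0)
  expect_lt(abs(fit2$alpha - log(3)), 0.15)
})

test_that("fitting validates its inputs and flags degenerate designs", {
  X <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(ulr_fit(X, rep(1, 20)), "both classes")
  expect_error(ulr_fit(X, c(rep(0, 10), rep(2, 10))), "binary")
  Xc <- cbind(a = rnorm(20), b = rep(1, 20))
  expect_error(ulr_fit(Xc, rep(0:1, 10)), "constant")
  expect_error(ulr_fit(X[1:3, ], c(0, 1, 0)), "n > k")
  # perfectly separable data without a ridge penalty are flagged
  Xs <- matrix(c(rep(-1, 10) + rnorm(10, 0, 0.01),
                 rep(1, 10) + rnorm(10, 0, 0.01)), ncol = 1,
               dimnames = list(NULL, "a"))
  ys <- c(rep(0, 10), rep(1, 10))
  expect_warning(fit <- ulr_fit(Xs, ys, ridge_lambda = 0, max_iter = 50),
                 "separation")
  expect_false(fit$converged)
  # and converge with one
  expect_silent(fitr <- ulr_fit(Xs, ys, ridge_lambda = 1e-2))
  expect_true(fitr$converged)
})

test_that("classification applies the >= threshold rule", {
  m <- fit_toy_model()  # pi = 0.5 exactly at f = -0.5
  expect_equal(ulr_classify(m, c(f = -0.5), 0.5), 1L)      # tie -> malignant
  expect_equal(ulr_classify(m, c(f = -0.6), 0.5), 0L)
  expect_equal(ulr_classify(m, c(f = -50), 0), 1L)         # threshold 0: always 1
  expect_error(ulr_classify(m, c(f = 0), 1.5), "threshold")
})

test_that("confusion counts partition the sample", {
  cc <- confusion_counts(c(1, 0, 1), c(1, 0, 1))
  expect_equal(unlist(cc[c("tp", "tn", "fp", "fn")]), c(tp = 2, tn = 1, fp = 0, fn = 0))
  inv <- confusion_counts(1 - c(1, 0, 1), c(1, 0, 1))
  expect_equal(inv$tp + inv$tn, 0)
  set.seed(5)
  p <- rbinom(40, 1, 0.5); t <- rbinom(40, 1, 0.5)
  cc2 <- confusion_counts(p, t)
  expect_equal(cc2$tp + cc2$tn + cc2$fp + cc2$fn, 40)
  expect_error(confusion_counts(c(1, 0), c(1, 0, 1)), "equal")
})

test_that("metrics match their formulas, including undefined-ratio reporting", {
  cc <- structure(list(tp = 90, tn = 42, fp = 3, fn = 2), class = "confusion_counts")
  m <- classification_metrics(cc)
  expect_equal(m$accuracy, 132 / 137)
  expect_equal(m$precision, 90 / 93)
  expect_equal(m$recall, 90 / 92)
  expect_equal(m$f1, 2 * m$precision * m$recall / (m$precision + m$recall))
  expect_equal(m$accuracy, 1 - (cc$fp + cc$fn) / 137)

  perfect <- confusion_counts(c(1, 1, 0), c(1, 1, 0))
  mp <- classification_metrics(perfect)
  expect_equal(unlist(mp[c("accuracy", "precision", "recall", "f1")]),
               c(accuracy = 1, precision = 1, recall = 1, f1 = 1))

  none <- structure(list(tp = 0, tn = 10, fp = 0, fn = 5), class = "confusion_counts")
  # precision is 0/0 and, in consequence, so is f1: both are flagged
  expect_warning(expect_warning(mn <- classification_metrics(none),
                                "precision undefined"), "f1 undefined")
  expect_equal(mn$precision, 0)
  expect_true(all(c("precision", "f1") %in% mn$undefined))
})

test_that("stratified cross-validation is deterministic with balanced folds", {
  set.seed(21)
  X <- matrix(rnorm(200), 100, 2, dimnames = list(NULL, c("a", "b")))
  y <- rep(0:1, each = 50)
  X[y == 1, 1] <- X[y == 1, 1] + 2
  r1 <- cross_validate(X, y, k_folds = 5, seed = 9)
  r2 <- cross_validate(X, y, k_folds = 5, seed = 9)
  expect_identical(r1$folds, r2$folds)
  expect_identical(r1$metrics, r2$metrics)
  # fold sizes differ by at most 1 within each class
  for (cl in 0:1) {
    sizes <- table(r1$folds[y == cl])
    expect_lte(max(sizes) - min(sizes), 1)
  }
  expect_gt(r1$metrics$accuracy, 0.8)
  expect_error(cross_validate(X, y, k_folds = 60, seed = 1), "at least")
})
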