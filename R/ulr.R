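# Logistic classification of texture feature vectors.
#
# The model is the standard binary logistic regression: the log-odds of a
# malignant (label 1) outcome are linear in the (standardized) features,
# log(pi / (1 - pi)) = alpha + sum_j beta_j z_j, and probabilities follow
# from the inverse logit 1 / (1 + exp(-a)). Fitting maximizes the Bernoulli
# log-likelihood (optionally ridge-penalized) by Newton-Raphson with
# step-halving; features are z-scored on the training data so coefficients
# are scale-free.

.inv_logit <- function(a) {
  # numerically stable on both tails
  ifelse(a >= 0, 1 / (1 + exp(-a)), exp(a) / (1 + exp(a)))
}

#' Fit a logistic classifier by penalized maximum likelihood
#'
#' @param X Numeric matrix or data frame, n rows (cases) by k feature
#'   columns; columns must be named and non-constant.
#' @param y Binary response vector (0 = benign, 1 = malignant); both
#'   classes must be present and `n > k + 1`.
#' @param ridge_lambda Nonnegative ridge penalty `lambda * ||beta||^2 / 2`
#'   on the (standardized) slopes; the intercept is never penalized. The
#'   small default keeps the Newton iteration well-posed when classes are
#'   linearly separable.
#' @param max_iter,tol Newton-Raphson iteration cap and convergence
#'   tolerance on the maximum absolute parameter change.
#' @return An object of class `ulr_model`: `alpha`, `betas` (named),
#'   `feature_names`, `standardize_means`, `standardize_sds`,
#'   `ridge_lambda`, `converged`, `n_iter`, `loglik`.
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(400), 200, 2, dimnames = list(NULL, c("f1", "f2")))
#' y <- rbinom(200, 1, plogis(-1 + X[, 1]))
#' fit <- ulr_fit(X, y)
#' predict(fit, X[1:3, ], type = "prob")
#' @export
ulr_fit <- function(X, y, ridge_lambda = 1e-6, max_iter = 100L, tol = 1e-8) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("`y` must be binary 0/1", call. = FALSE)
  if (length(unique(y)) < 2) stop("both classes must be present in `y`", call. = FALSE)
  n <- nrow(X); k <- ncol(X)
  if (length(y) != n) stop("`X` and `y` lengths differ", call. = FALSE)
  if (n <= k + 1) stop("need n > k + 1 cases", call. = FALSE)
  if (any(!is.finite(X))) stop("`X` contains non-finite values", call. = FALSE)
  if (ridge_lambda < 0) stop("`ridge_lambda` must be >= 0", call. = FALSE)

  mu <- colMeans(X)
  sds <- apply(X, 2, stats::sd)
  if (any(sds <= 0)) {
    stop(sprintf("constant feature column(s): %s",
                 paste(colnames(X)[sds <= 0], collapse = ", ")), call. = FALSE)
  }
  Z <- cbind(`(Intercept)` = 1, sweep(sweep(X, 2, mu), 2, sds, "/"))
  pen <- c(0, rep(ridge_lambda, k))

  theta <- numeric(k + 1)
  pll <- function(th) {
    eta <- drop(Z %*% th)
    sum(y * eta - log1p(exp(-abs(eta))) - pmax(eta, 0)) - sum(pen * th^2) / 2
  }
  ll_old <- pll(theta)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    p <- .inv_logit(drop(Z %*% theta))
    w <- pmax(p * (1 - p), 1e-12)
    grad <- drop(crossprod(Z, y - p)) - pen * theta
    H <- crossprod(Z * w, Z) + diag(pen, k + 1)
    step <- tryCatch(solve(H, grad), error = function(e) {
      solve(H + diag(1e-8, k + 1), grad)
    })
    # step-halving keeps the penalized log-likelihood non-decreasing
    s <- 1
    repeat {
      cand <- theta + s * step
      if (pll(cand) >= ll_old - 1e-12 || s < 1e-8) break
      s <- s / 2
    }
    delta <- max(abs(s * step))
    theta <- theta + s * step
    ll_old <- pll(theta)
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged && ridge_lambda == 0 && max(abs(theta)) > 15) {
    warning("possible perfect separation; refit with ridge_lambda > 0",
            call. = FALSE)
  }
  structure(list(alpha = theta[1],
                 betas = stats::setNames(theta[-1], colnames(X)),
                 feature_names = colnames(X),
                 standardize_means = stats::setNames(mu, colnames(X)),
                 standardize_sds = stats::setNames(sds, colnames(X)),
                 ridge_lambda = ridge_lambda,
                 converged = converged, n_iter = iter, loglik = ll_old),
            class = "ulr_model")
}

.ulr_design <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1, dimnames = list(NULL, names(x)))
  x <- as.matrix(x)
  nms <- model$feature_names
  if (is.null(colnames(x))) {
    if (ncol(x) != length(nms)) stop("feature count mismatch", call. = FALSE)
    colnames(x) <- nms
  }
  if (!all(nms %in% colnames(x))) {
    stop(sprintf("missing feature(s): %s",
                 paste(setdiff(nms, colnames(x)), collapse = ", ")), call. = FALSE)
  }
  x <- x[, nms, drop = FALSE]
  if (any(!is.finite(x))) stop("non-finite feature values", call. = FALSE)
  sweep(sweep(x, 2, model$standardize_means), 2, model$standardize_sds, "/")
}

#' Linear predictor (log-odds) of a fitted model
#'
#' @param model A fitted [ulr_fit()] model.
#' @param x Named feature vector, or a matrix/data frame with one row per
#'   case and the model's feature columns.
#' @return Numeric vector `alpha + sum_j beta_j z_j`.
#' @export
log_odds <- function(model, x) {
  if (!inherits(model, "ulr_model")) stop("`model` must be a ulr_model", call. = FALSE)
  Z <- .ulr_design(model, x)
  drop(model$alpha + Z %*% model$betas)
}

#' Predicted probability of a malignant (label 1) outcome
#'
#' The inverse-logit transform of [log_odds()]; the complementary benign
#' probability is exactly `1 - predict_prob(...)`.
#'
#' @inheritParams log_odds
#' @return Probabilities in (0, 1).
#' @export
predict_prob <- function(model, x) {
  .inv_logit(log_odds(model, x))
}

#' Classify feature vectors
#'
#' @inheritParams log_odds
#' @param threshold Decision threshold in `[0, 1)`; probability `>=
#'   threshold` classifies as 1 (malignant) — ties go to the positive
#'   class.
#' @return Integer labels 0/1.
#' @export
ulr_classify <- function(model, x, threshold = 0.5) {
  if (!is.numeric(threshold) || threshold < 0 || threshold >= 1) {
    stop("`threshold` must be in [0, 1)", call. = FALSE)
  }
  as.integer(predict_prob(model, x) >= threshold)
}

#' @export
predict.ulr_model <- function(object, newdata,
                              type = c("prob", "link", "class"),
                              threshold = 0.5, ...) {
  type <- match.arg(type)
  switch(type,
         link = log_odds(object, newdata),
         prob = predict_prob(object, newdata),
         class = ulr_classify(object, newdata, threshold))
}

#' @export
print.ulr_model <- function(x, ...) {
  cat(sprintf("Logistic texture classifier (%d features, %s)\n",
              length(x$betas),
              if (x$converged) sprintf("converged in %d iterations", x$n_iter)
              else "NOT converged"))
  cat(sprintf("  alpha: %.4f\n", x$alpha))
  print(round(x$betas, 4))
  invisible(x)
}

#' Confusion counts
#'
#' Tallies predictions against truth with 1 (malignant) as the positive
#' class.
#'
#' @param pred,truth Equal-length binary 0/1 vectors.
#' @return Object of class `confusion_counts` with `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(pred, truth) {
  if (length(pred) != length(truth) || length(pred) == 0) {
    stop("`pred` and `truth` must have equal positive length", call. = FALSE)
  }
  if (!all(pred %in% c(0, 1)) || !all(truth %in% c(0, 1))) {
    stop("labels must be binary 0/1", call. = FALSE)
  }
  structure(list(tp = sum(pred == 1 & truth == 1),
                 tn = sum(pred == 0 & truth == 0),
                 fp = sum(pred == 1 & truth == 0),
                 fn = sum(pred == 0 & truth == 1)),
            class = "confusion_counts")
}

#' Classification metrics from confusion counts
#'
#' Accuracy `(tp + tn) / n`, precision `tp / (tp + fp)`, recall
#' `tp / (tp + fn)` and their harmonic mean F1. A ratio with zero
#' denominator is reported as 0 and listed in `undefined` rather than
#' raising an error, so pooled cross-validation never aborts.
#'
#' @param counts A [confusion_counts()] object.
#' @return List with `accuracy`, `precision`, `recall`, `f1`, and
#'   `undefined` (character vector of metrics with zero denominators).
#' @export
classification_metrics <- function(counts) {
  if (!inherits(counts, "confusion_counts")) {
    stop("`counts` must be confusion_counts", call. = FALSE)
  }
  total <- counts$tp + counts$tn + counts$fp + counts$fn
  if (total == 0) stop("all counts are zero", call. = FALSE)
  undefined <- character(0)
  ratio <- function(num, den, what) {
    if (den == 0) {
      undefined <<- c(undefined, what)
      warning(sprintf("%s undefined (zero denominator); reported as 0", what),
              call. = FALSE)
      0
    } else num / den
  }
  accuracy <- (counts$tp + counts$tn) / total
  precision <- ratio(counts$tp, counts$tp + counts$fp, "precision")
  recall <- ratio(counts$tp, counts$tp + counts$fn, "recall")
  f1 <- ratio(2 * precision * recall, precision + recall, "f1")
  list(accuracy = accuracy, precision = precision, recall = recall,
       f1 = f1, undefined = undefined)
}

#' Stratified k-fold cross-validation
#'
#' Splits each class into `k_folds` near-equal folds (sizes differ by at
#' most 1 within a class), fits on the k-1 training folds — including the
#' feature standardization, which uses training rows only — and evaluates
#' on the held-out fold. Confusion counts are pooled over folds.
#'
#' @param features Numeric matrix or data frame of features.
#' @param labels Binary 0/1 labels, each class at least `k_folds` cases.
#' @param k_folds Number of folds (>= 2), default 5.
#' @param seed Seed controlling the fold shuffle.
#' @param ridge_lambda,threshold Passed to [ulr_fit()] / [ulr_classify()].
#' @return List with `pooled` (a [confusion_counts()]), `metrics` (pooled
#'   [classification_metrics()]), `fold_metrics` (per-fold accuracy), and
#'   `folds` (the fold assignment vector).
#' @export
cross_validate <- function(features, labels, k_folds = 5L, seed = 7L,
                           ridge_lambda = 1e-6, threshold = 0.5) {
  features <- as.matrix(features)
  labels <- as.integer(labels)
  k_folds <- as.integer(k_folds)
  if (k_folds < 2) stop("`k_folds` must be >= 2", call. = FALSE)
  if (!all(labels %in% 0:1)) stop("labels must be binary 0/1", call. = FALSE)
  if (min(table(labels)) < k_folds) {
    stop("each class must have at least `k_folds` cases", call. = FALSE)
  }
  folds <- integer(length(labels))
  with_seed(seed, {
    for (cl in 0:1) {
      idx <- which(labels == cl)
      folds[idx] <- sample(rep_len(seq_len(k_folds), length(idx)))
    }
  })
  pred <- integer(length(labels))
  fold_metrics <- numeric(k_folds)
  for (f in seq_len(k_folds)) {
    test <- folds == f
    fit <- ulr_fit(features[!test, , drop = FALSE], labels[!test],
                   ridge_lambda = ridge_lambda)
    pred[test] <- ulr_classify(fit, features[test, , drop = FALSE], threshold)
    fold_metrics[f] <- mean(pred[test] == labels[test])
  }
  pooled <- confusion_counts(pred, labels)
  list(pooled = pooled, metrics = classification_metrics(pooled),
       fold_metrics = fold_metrics, folds = folds)
}
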