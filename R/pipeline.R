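# End-to-end pipeline: wavelet denoising -> multiscale LBP + Laws texture
# features -> logistic classification under stratified cross-validation.

#' Pipeline configuration
#'
#' Collects every tunable of the classification pipeline with the package
#' defaults; serializes round-trip stably via JSON.
#'
#' @param wavelet,denoise_levels Denoising wavelet and decomposition depth
#'   (see [wavelet_denoise()]).
#' @param lbp_scales List of `c(D, r)` LBP scales (see [lbp_features()]).
#' @param laws_epsilon Divisor floor for [laws_balance()].
#' @param ridge_lambda Ridge penalty for [ulr_fit()].
#' @param cv_folds,seed,threshold Cross-validation folds, RNG seed, and
#'   decision threshold.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(wavelet = "haar", denoise_levels = 1L,
                            lbp_scales = list(c(8, 1), c(16, 2), c(24, 3)),
                            laws_epsilon = 1e-8, ridge_lambda = 1e-6,
                            cv_folds = 5L, seed = 7L, threshold = 0.5) {
  .wavelet_filters(wavelet)                      # validates the name
  stopifnot(denoise_levels %in% 1:3,
            length(lbp_scales) >= 1,
            laws_epsilon > 0, ridge_lambda >= 0,
            cv_folds >= 2, threshold > 0, threshold < 1)
  structure(list(wavelet = wavelet, denoise_levels = as.integer(denoise_levels),
                 lbp_scales = lbp_scales, laws_epsilon = laws_epsilon,
                 ridge_lambda = ridge_lambda, cv_folds = as.integer(cv_folds),
                 seed = as.integer(seed), threshold = threshold),
            class = "pipeline_config")
}

#' Extract the combined texture feature vector of one image
#'
#' Denoises the image by wavelet shrinkage, then computes the multiscale
#' riu2 LBP energy/entropy descriptors and the eight Laws texture
#' energies: 14 features at the default scales.
#'
#' @param image Numeric matrix in `[0, 1]`.
#' @param config A [pipeline_config()].
#' @return Named numeric feature vector.
#' @export
extract_features <- function(image, config = pipeline_config()) {
  if (!inherits(config, "pipeline_config")) {
    stop("`config` must be a pipeline_config", call. = FALSE)
  }
  dn <- wavelet_denoise(image, wavelet = config$wavelet,
                        levels = config$denoise_levels,
                        threshold_rule = "universal")
  c(lbp_features(dn, scales = config$lbp_scales),
    laws_features(dn, epsilon = config$laws_epsilon))
}

#' Build a feature table from a labeled image set
#'
#' @param set A `labeled_image_set` (e.g. from [generate_dataset()]).
#' @param config A [pipeline_config()].
#' @return Data frame: one row per image, feature columns plus `label`.
#' @export
build_feature_table <- function(set, config = pipeline_config()) {
  if (!inherits(set, "labeled_image_set")) {
    stop("`set` must be a labeled_image_set", call. = FALSE)
  }
  rows <- lapply(set$images, extract_features, config = config)
  df <- as.data.frame(do.call(rbind, rows))
  df$label <- as.integer(set$labels)
  df
}

#' Run the full benchmark pipeline
#'
#' Generates the synthetic two-class dataset, denoises, extracts the
#' combined LBP + Laws feature table, and evaluates the logistic
#' classifier by stratified cross-validation.
#'
#' @param synth A [synthetic_config()]; its `seed` also drives the fold
#'   shuffle unless `config$seed` differs.
#' @param config A [pipeline_config()].
#' @return List with `features` (the feature table), `cv` (the
#'   [cross_validate()] result), `counts` (pooled confusion counts) and
#'   `metrics` (pooled accuracy/precision/recall/F1).
#' @export
run_pipeline <- function(synth = synthetic_config(), config = pipeline_config()) {
  set <- generate_dataset(synth)
  features <- build_feature_table(set, config)
  cv <- cross_validate(features[, setdiff(names(features), "label")],
                       features$label, k_folds = config$cv_folds,
                       seed = config$seed, ridge_lambda = config$ridge_lambda,
                       threshold = config$threshold)
  list(features = features, cv = cv, counts = cv$pooled, metrics = cv$metrics)
}
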