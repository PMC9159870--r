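# Image, feature-table and model file I/O.

#' Read a grayscale image
#'
#' Reads an 8- or 16-bit PNG or TIFF into a numeric matrix scaled to
#' `[0, 1]`. RGB(A) inputs are converted by the unweighted mean of the
#' color channels (ultrasound captures are gray; any tint is incidental).
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return Numeric matrix in `[0, 1]`.
#' @export
read_gray_image <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  img <- tryCatch(
    switch(ext,
           png = png::readPNG(path),
           tif = ,
           tiff = tiff::readTIFF(path),
           stop(sprintf("unsupported image format '.%s': %s", ext, path),
                call. = FALSE)),
    error = function(e) stop(sprintf("cannot read %s: %s", path, conditionMessage(e)),
                             call. = FALSE))
  if (is.list(img)) stop(sprintf("multi-frame image not supported: %s", path),
                         call. = FALSE)
  if (length(dim(img)) == 3) {
    nch <- min(dim(img)[3], 3L)          # drop alpha
    img <- apply(img[, , seq_len(nch), drop = FALSE], c(1, 2), mean)
  }
  img
}

#' Write a grayscale image as PNG
#'
#' @param image Numeric matrix; values are clipped to `[0, 1]`.
#' @param path Output path (`.png`).
#' @export
write_gray_image <- function(image, path) {
  assert_image(image)
  png::writePNG(clip01(image), path)
  invisible(path)
}

.check_feature_table <- function(df, path = NULL) {
  where <- if (is.null(path)) "" else sprintf(" in %s", path)
  if (!"label" %in% names(df)) {
    stop(sprintf("missing 'label' column%s", where), call. = FALSE)
  }
  if (anyDuplicated(names(df))) {
    stop(sprintf("duplicate column names%s", where), call. = FALSE)
  }
  num_cols <- if (nrow(df) == 0) character(0) else setdiff(names(df), "filename")
  for (cn in num_cols) {
    v <- df[[cn]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1]
      stop(sprintf("non-numeric value in column '%s'%s (row %s)", cn, where,
                   ifelse(is.na(bad), "?", bad)), call. = FALSE)
    }
    if (anyNA(v)) {
      stop(sprintf("missing value in column '%s'%s (row %d)", cn, where,
                   which(is.na(v))[1]), call. = FALSE)
    }
  }
  if (nrow(df) > 0 && !all(df$label %in% c(0, 1))) {
    stop(sprintf("'label' must be 0/1%s", where), call. = FALSE)
  }
  df
}

#' Write / read a feature table
#'
#' Plain CSV with a header; one row per image, numeric feature columns, a
#' binary `label` column and (optionally) a `filename` column. Both
#' directions validate the schema and report the offending row/column on
#' failure.
#'
#' @param table Data frame of features (validated before writing).
#' @param path CSV path.
#' @return `read_feature_table()` returns the validated data frame.
#' @export
write_feature_table <- function(table, path) {
  table <- .check_feature_table(as.data.frame(table))
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  .check_feature_table(df, path)
}

.MODEL_FORMAT <- "ovatex-ulr-1"

#' Save / load a fitted classifier
#'
#' Models are stored as JSON (coefficients, standardization parameters,
#' penalty and convergence metadata) under a format-version tag; loading a
#' file with a different tag fails rather than guessing. A loaded model
#' predicts identically to the saved one.
#'
#' @param model A fitted [ulr_fit()] model with at least one feature.
#' @param path JSON path.
#' @return `load_ulr_model()` returns the `ulr_model`.
#' @export
save_ulr_model <- function(model, path) {
  if (!inherits(model, "ulr_model")) stop("`model` must be a ulr_model", call. = FALSE)
  if (length(model$betas) == 0) stop("model has no features", call. = FALSE)
  payload <- list(format = .MODEL_FORMAT,
                  alpha = model$alpha,
                  betas = as.list(model$betas),
                  feature_names = model$feature_names,
                  standardize_means = as.list(model$standardize_means),
                  standardize_sds = as.list(model$standardize_sds),
                  ridge_lambda = model$ridge_lambda,
                  converged = model$converged,
                  n_iter = model$n_iter,
                  loglik = model$loglik)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_ulr_model
#' @export
load_ulr_model <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  payload <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                      error = function(e) stop(sprintf("cannot parse model file %s: %s",
                                                       path, conditionMessage(e)),
                                               call. = FALSE))
  if (!identical(payload$format, .MODEL_FORMAT)) {
    stop(sprintf("unsupported model format '%s' (expected '%s') in %s",
                 paste(payload$format, collapse = "/"), .MODEL_FORMAT, path),
         call. = FALSE)
  }
  nms <- payload$feature_names
  structure(list(alpha = payload$alpha,
                 betas = stats::setNames(unlist(payload$betas)[nms], nms),
                 feature_names = nms,
                 standardize_means = stats::setNames(unlist(payload$standardize_means)[nms], nms),
                 standardize_sds = stats::setNames(unlist(payload$standardize_sds)[nms], nms),
                 ridge_lambda = payload$ridge_lambda,
                 converged = payload$converged,
                 n_iter = payload$n_iter,
                 loglik = payload$loglik),
            class = "ulr_model")
}
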