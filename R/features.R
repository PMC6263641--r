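# Per-batch feature extraction: the 23-element vector of 9 colour-channel
# means (RGB, HSV, CIELAB) and 14 Haralick texture descriptors, and the
# assembly of the features-by-batches matrix joined to the chemistry table.

#' Names of the 23 batch features, in fixed order
#'
#' Nine colour means (`mean_R`, `mean_G`, `mean_B`, `mean_H`, `mean_S`,
#' `mean_V`, `mean_L`, `mean_a`, `mean_b`; note `mean_B` = blue and
#' `mean_b` = CIELAB b*), then the 14 Haralick descriptors prefixed
#' `glcm_`.
#'
#' @return character vector of length 23.
#' @export
feature_names <- function() {
  c("mean_R", "mean_G", "mean_B", "mean_H", "mean_S", "mean_V",
    "mean_L", "mean_a", "mean_b",
    "glcm_asm", "glcm_contrast", "glcm_correlation", "glcm_variance",
    "glcm_idm", "glcm_sum_average", "glcm_sum_variance", "glcm_sum_entropy",
    "glcm_entropy", "glcm_diff_variance", "glcm_diff_entropy",
    "glcm_imc1", "glcm_imc2", "glcm_mcc")
}

#' Feature-extraction settings
#'
#' @param threshold global binarisation threshold in `[0, 255]`, or
#'   `"auto"` for Otsu's criterion.
#' @param mean_mode `"all_pixels"`: channel sums divided by the full pixel
#'   count, background zeros included (the conventional whole-image mean);
#'   `"fruit_only"`: average over fruit pixels only.
#' @param hue_circular use the circular mean for the hue channel (only
#'   meaningful with `mean_mode = "fruit_only"`); default `FALSE`, plain
#'   arithmetic mean like every other channel.
#' @param levels,offsets,symmetric GLCM parameters, see [compute_glcm()].
#' @return a `feature_settings` list.
#' @export
feature_settings <- function(threshold = "auto",
                             mean_mode = c("all_pixels", "fruit_only"),
                             hue_circular = FALSE,
                             levels = 64L, offsets = glcm_offsets(),
                             symmetric = TRUE) {
  mean_mode <- match.arg(mean_mode)
  structure(list(threshold = threshold, mean_mode = mean_mode,
                 hue_circular = hue_circular, levels = as.integer(levels),
                 offsets = offsets, symmetric = symmetric),
            class = "feature_settings")
}

#' Extract the 23-feature vector of one batch image
#'
#' Runs the imaging pipeline (grayscale, global threshold, mask) and then
#' computes the 9 colour-channel means of the masked image and the 14
#' Haralick descriptors of its grey-level co-occurrence matrix (pairs
#' restricted to fruit pixels).
#'
#' @param image a [batch_image()].
#' @param settings a [feature_settings()].
#' @return named numeric vector of length 23 (order of [feature_names()]),
#'   with attribute `threshold` recording the binarisation level used.
#' @export
extract_features <- function(image, settings = feature_settings()) {
  stopifnot(inherits(image, "batch_image"))
  grey <- to_grayscale(image)
  mask <- binarize(grey, settings$threshold)
  if (mask$coverage == 0) {
    stop_olivescan("empty mask: no fruit pixels in the image",
                   "olivescan_empty_mask_error")
  }
  masked <- apply_mask(image, mask)
  hsv <- rgb_to_hsv_img(masked)
  lab <- rgb_to_lab_img(masked)

  chans <- list(
    mean_R = masked$pixels[, , 1], mean_G = masked$pixels[, , 2],
    mean_B = masked$pixels[, , 3],
    mean_H = hsv[, , 1], mean_S = hsv[, , 2], mean_V = hsv[, , 3],
    mean_L = lab[, , 1], mean_a = lab[, , 2], mean_b = lab[, , 3])
  means <- vapply(names(chans), function(nm) {
    if (nm == "mean_H" && isTRUE(settings$hue_circular)) {
      circular_hue_mean(chans[[nm]], mask)
    } else {
      channel_mean(chans[[nm]], mask, mode = settings$mean_mode)
    }
  }, numeric(1))

  grey_masked <- to_grayscale(masked$pixels)
  glcm <- compute_glcm(grey_masked, mask, levels = settings$levels,
                       offsets = settings$offsets,
                       symmetric = settings$symmetric)
  texture <- haralick_features(glcm)

  out <- c(means, texture)
  names(out) <- feature_names()
  attr(out, "threshold") <- mask$threshold
  out
}

#' Build the features-by-batches matrix joined to the chemistry table
#'
#' Extracts (or accepts precomputed) feature vectors for every image and
#' joins them to the chemistry rows by `batch_id`.  The join is order-free:
#' rows are sorted by batch id, and any id present on one side only is an
#' error that names the offenders.
#'
#' @param images list of [batch_image()] objects, or a data frame of
#'   precomputed features with a `batch_id` column.
#' @param chemistry data frame with a `batch_id` column and one column per
#'   chemical parameter.
#' @param settings a [feature_settings()] (ignored for precomputed
#'   features).
#' @return list with `X` (numeric matrix, rownames = batch ids), `Y`
#'   (numeric matrix of chemistry values, same row order), `batch_ids`.
#' @export
build_feature_matrix <- function(images, chemistry,
                                 settings = feature_settings()) {
  if (is.data.frame(images)) {
    feats <- images
    if (!"batch_id" %in% names(feats)) {
      stop_olivescan("precomputed features need a batch_id column",
                     "olivescan_join_error")
    }
  } else {
    rows <- lapply(images, function(img) {
      c(list(batch_id = img$batch_id),
        as.list(extract_features(img, settings)))
    })
    feats <- do.call(rbind, lapply(rows, as.data.frame))
  }
  if (!"batch_id" %in% names(chemistry)) {
    stop_olivescan("chemistry needs a batch_id column", "olivescan_join_error")
  }
  miss_chem <- setdiff(feats$batch_id, chemistry$batch_id)
  miss_img <- setdiff(chemistry$batch_id, feats$batch_id)
  if (length(miss_chem) || length(miss_img)) {
    stop_olivescan(paste0(
      "batch ids do not match; ",
      if (length(miss_chem)) paste0("no chemistry for: ",
                                    paste(miss_chem, collapse = ", "), ". "),
      if (length(miss_img)) paste0("no image for: ",
                                   paste(miss_img, collapse = ", "))),
      "olivescan_join_error")
  }
  ord <- order(feats$batch_id)
  feats <- feats[ord, , drop = FALSE]
  chem <- chemistry[match(feats$batch_id, chemistry$batch_id), , drop = FALSE]
  X <- as.matrix(feats[, setdiff(names(feats), "batch_id"), drop = FALSE])
  Y <- as.matrix(chem[, setdiff(names(chem), "batch_id"), drop = FALSE])
  rownames(X) <- rownames(Y) <- feats$batch_id
  if (anyNA(X) || anyNA(Y)) {
    stop_olivescan("missing values in the joined matrices", "olivescan_join_error")
  }
  list(X = X, Y = Y, batch_ids = feats$batch_id)
}
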