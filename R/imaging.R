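# Background removal: grayscale conversion, global threshold binarisation,
# and channelwise masking.  Fruits are dark objects on a near-white tray, so
# fruit pixels are those *below* the threshold; the fruit mask is the inverse
# of the background mask and is applied to each RGB channel.

#' Construct a batch image
#'
#' A thin S3 container for one 8-bit RGB tray image: an `H x W x 3` numeric
#' array of intensities in `[0, 255]` plus a batch identifier.
#'
#' @param pixels `H x W x 3` array, values in `[0, 255]`.
#' @param batch_id character identifier.
#' @return an object of class `batch_image` with fields `pixels`,
#'   `batch_id`, `height`, `width`.
#' @export
batch_image <- function(pixels, batch_id = "batch") {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L) {
    stop_olivescan("pixels must be an H x W x 3 array", "olivescan_image_error")
  }
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255) {
    stop_olivescan("pixel values must be finite and in [0, 255]", "olivescan_image_error")
  }
  structure(
    list(pixels = pixels, batch_id = as.character(batch_id),
         height = dim(pixels)[1], width = dim(pixels)[2]),
    class = "batch_image"
  )
}

#' @export
print.batch_image <- function(x, ...) {
  cat(sprintf("<batch_image> %s: %d x %d px\n", x$batch_id, x$width, x$height))
  invisible(x)
}

#' Convert an RGB image to 8-bit luminance
#'
#' Uses the Rec. 601 luma weights 0.299 R + 0.587 G + 0.114 B, rounded to
#' the nearest integer grey level.
#'
#' @param image a [batch_image()] or an `H x W x 3` array.
#' @return an `H x W` matrix of grey levels in `[0, 255]`.
#' @export
to_grayscale <- function(image) {
  px <- if (inherits(image, "batch_image")) image$pixels else image
  if (inherits(image, "masked_image")) px <- image$pixels
  if (!is.array(px) || length(dim(px)) != 3L) {
    stop_olivescan("expected an H x W x 3 image", "olivescan_image_error")
  }
  round(0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3])
}

#' Otsu's global threshold
#'
#' Maximises the between-class variance of the 256-bin grey-level histogram.
#' The returned value `t` is used as: fruit (foreground) pixels are those
#' with `grey < t`.
#'
#' @param grey `H x W` matrix of grey levels in `[0, 255]`.
#' @return a single integer threshold in `[1, 255]`.
#' @export
otsu_threshold <- function(grey) {
  g <- as.integer(round(grey))
  if (min(g) == max(g)) {
    stop_olivescan("degenerate histogram: image is constant, cannot auto-threshold",
                   "olivescan_threshold_error")
  }
  counts <- tabulate(g + 1L, nbins = 256L)
  p <- counts / sum(counts)
  levels <- 0:255
  omega <- cumsum(p)              # class-0 probability for threshold k
  mu <- cumsum(p * levels)        # class-0 first moment
  mu_t <- mu[256]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  # with a well-separated bimodal histogram the criterion plateaus between
  # the modes; take the plateau midpoint rather than its first point
  plateau <- which(sigma_b >= max(sigma_b) - 1e-12)
  k <- plateau[ceiling(length(plateau) / 2)]
  as.integer(k)                   # fruit pixels: grey < k  (i.e. grey <= k - 1)
}

#' Binarise a grey image into a fruit mask
#'
#' Fruit pixels are those strictly below the threshold (dark fruit on a
#' white tray).  `threshold = "auto"` selects the threshold by Otsu's
#' between-class-variance criterion and records the chosen value.
#'
#' @param grey `H x W` grey-level matrix.
#' @param threshold a level in `[0, 255]`, or `"auto"`.
#' @return a `fruit_mask`: list with `mask` (logical `H x W`, `TRUE` =
#'   fruit), `coverage` (fraction of fruit pixels) and `threshold` used.
#' @export
binarize <- function(grey, threshold = "auto") {
  if (!is.matrix(grey)) {
    stop_olivescan("grey must be an H x W matrix", "olivescan_image_error")
  }
  if (identical(threshold, "auto")) {
    threshold <- otsu_threshold(grey)
  } else {
    if (!is.numeric(threshold) || length(threshold) != 1L ||
        threshold < 0 || threshold > 255) {
      stop_olivescan("threshold must be in [0, 255] or \"auto\"",
                     "olivescan_image_error")
    }
  }
  mask <- grey < threshold
  structure(
    list(mask = mask, coverage = mean(mask), threshold = as.numeric(threshold)),
    class = "fruit_mask"
  )
}

#' Apply a fruit mask to an RGB image
#'
#' Channelwise product with the logical mask: background pixels become
#' exactly `(0, 0, 0)`, fruit pixels are unchanged.  Idempotent: masking a
#' masked image with its own mask is a no-op.
#'
#' @param image a [batch_image()] (or `masked_image`).
#' @param mask a `fruit_mask` from [binarize()] of the same shape.
#' @return a `masked_image`: list with `pixels`, `mask`, `batch_id`.
#' @export
apply_mask <- function(image, mask) {
  stopifnot(inherits(mask, "fruit_mask"))
  px <- if (is.list(image)) image$pixels else image
  if (!identical(dim(px)[1:2], dim(mask$mask))) {
    stop_olivescan("image and mask shapes differ", "olivescan_image_error")
  }
  m <- mask$mask
  storage.mode(m) <- "double"
  out <- px * as.vector(m) # recycles the H x W mask across the 3 channels
  structure(
    list(pixels = out, mask = mask,
         batch_id = if (is.list(image)) image$batch_id else "image"),
    class = "masked_image"
  )
}
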