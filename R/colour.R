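# Colour-space conversions and channel means.  The 9 colour features of a
# batch are the mean intensities of the R, G, B, H, S, V, L*, a*, b*
# channels of the masked image.

#' Convert a masked RGB image to HSV
#'
#' Standard hexcone HSV via [grDevices::rgb2hsv()]; all three channels are
#' scaled to `[0, 1]` (hue 0 = red, 1/3 = green, 2/3 = blue).  Background
#' pixels, being exactly black, map to `(0, 0, 0)`.
#'
#' @param image a `masked_image`, [batch_image()] or `H x W x 3` array with
#'   values in `[0, 255]`.
#' @return an `H x W x 3` array with channels H, S, V in `[0, 1]`.
#' @export
rgb_to_hsv_img <- function(image) {
  px <- if (is.list(image)) image$pixels else image
  d <- dim(px)
  rgb <- rbind(as.vector(px[, , 1]), as.vector(px[, , 2]), as.vector(px[, , 3]))
  hsv <- grDevices::rgb2hsv(rgb, maxColorValue = 255)
  array(c(hsv[1, ], hsv[2, ], hsv[3, ]), dim = d,
        dimnames = list(NULL, NULL, c("H", "S", "V")))
}

#' Convert a masked RGB image to CIELAB
#'
#' Assumes sRGB primaries and the D65 white point (the common default for
#' consumer colour cameras).  `L*` lies in `[0, 100]`; `a*`/`b*` are signed.
#' Background pixels map to `L* = 0`.
#'
#' @inheritParams rgb_to_hsv_img
#' @return an `H x W x 3` array with channels L, a, b.
#' @export
rgb_to_lab_img <- function(image) {
  px <- if (is.list(image)) image$pixels else image
  d <- dim(px)
  srgb <- cbind(as.vector(px[, , 1]), as.vector(px[, , 2]), as.vector(px[, , 3])) / 255
  lab <- grDevices::convertColor(srgb, from = "sRGB", to = "Lab")
  array(c(lab[, 1], lab[, 2], lab[, 3]), dim = d,
        dimnames = list(NULL, NULL, c("L", "a", "b")))
}

#' Mean intensity of one channel
#'
#' `mode = "all_pixels"` divides the channel sum by the full pixel count
#' `N x M` — on a masked image the zeroed background is included in the
#' denominator, so fruit coverage leaks into the mean.  `mode =
#' "fruit_only"` averages over mask pixels only.  Both modes are provided
#' because the literal all-pixel mean is the conventional definition for
#' whole-tray features while the fruit-only mean is coverage-invariant.
#'
#' @param channel `H x W` numeric matrix.
#' @param mask a `fruit_mask` (required for `fruit_only`).
#' @param mode `"all_pixels"` (default) or `"fruit_only"`.
#' @return a single numeric mean.
#' @export
channel_mean <- function(channel, mask = NULL, mode = c("all_pixels", "fruit_only")) {
  mode <- match.arg(mode)
  if (!is.matrix(channel)) {
    stop_olivescan("channel must be an H x W matrix", "olivescan_image_error")
  }
  if (mode == "all_pixels") {
    return(sum(channel) / length(channel))
  }
  if (is.null(mask) || !inherits(mask, "fruit_mask")) {
    stop_olivescan("fruit_only mode needs a fruit_mask", "olivescan_image_error")
  }
  if (!identical(dim(channel), dim(mask$mask))) {
    stop_olivescan("channel and mask shapes differ", "olivescan_image_error")
  }
  n <- sum(mask$mask)
  if (n == 0L) {
    stop_olivescan("empty mask: no fruit pixels to average", "olivescan_empty_mask_error")
  }
  sum(channel[mask$mask]) / n
}

#' Circular mean of a hue channel
#'
#' Optional alternative to the plain arithmetic hue mean: hue is an angle,
#' so values near 0 and 1 are neighbours.  Returns the direction of the
#' mean resultant vector, scaled back to `[0, 1)`.
#'
#' @param hue matrix or vector of hues in `[0, 1]`.
#' @param mask optional `fruit_mask` restricting the average.
#' @return circular mean hue in `[0, 1)`.
#' @export
circular_hue_mean <- function(hue, mask = NULL) {
  h <- if (!is.null(mask)) hue[mask$mask] else as.vector(hue)
  if (length(h) == 0L) {
    stop_olivescan("empty mask: no fruit pixels to average", "olivescan_empty_mask_error")
  }
  ang <- 2 * pi * h
  m <- atan2(mean(sin(ang)), mean(cos(ang))) / (2 * pi)
  if (m < 0) m <- m + 1
  if (1 - m < 1e-9) m <- 0 # wrap the seam: hue 1 is hue 0
  m
}
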