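# Latent -> chemistry link for the synthetic generator.
#
# Each oil quality parameter responds linearly to the batch latents
# (ripeness r, spoilage s) plus Gaussian noise; polyphenols additionally
# carry a concave quadratic in ripeness (they accumulate up to full
# ripeness and decline past it, and drop in spoiled fruit).  The link is
# calibrated so that the implied noise-free values at the centroids of the
# four visual categories match published category-level means for Picual
# olive batches: degradation parameters (acidity, peroxides, UV
# absorbances, ethyl esters) rise with ripeness and spoilage, pigments
# (chlorophyll, carotenoids) fall, and polyphenols peak in healthy ripe
# batches (Cat-2).

# Latent centroids of the four visual categories (ripeness, spoilage).
category_centroids <- function() {
  m <- rbind(`Cat-1` = c(0.25, 0.10), `Cat-2` = c(0.675, 0.10),
             `Cat-3` = c(0.675, 0.55), `Cat-4` = c(0.925, 0.55))
  colnames(m) <- c("ripeness", "spoilage")
  m
}

#' Chemistry parameter names
#'
#' The ten oil quality parameters predicted by the pipeline, in report
#' order.
#'
#' @return character vector of length 10.
#' @export
chem_parameter_names <- function() {
  c("acidity", "peroxide", "k270", "k232", "ethyl_ester", "ethyl_palmitate",
    "ethyl_oleate", "polyphenols", "chlorophyll", "carotenoids")
}

# Calibration targets: category-level mean values of each parameter
# (rows Cat-1..Cat-4) and the min-max envelope the implied means must stay
# inside.  Units: acidity % oleic acid, peroxide meq O2/kg, K270/K232
# absorbance, ethyl esters mg/kg, polyphenols mg/kg, pigments mg/kg.
chem_reference <- function() {
  params <- chem_parameter_names()
  mean_tab <- rbind(
    `Cat-1` = c(0.20, 3.87, 0.13, 1.38,  5.77, 2.92,  2.85, 538.31, 21.26, 13.20),
    `Cat-2` = c(0.22, 3.75, 0.17, 1.53,  5.77, 2.62,  3.15, 765.92, 17.42, 12.20),
    `Cat-3` = c(0.35, 6.76, 0.15, 1.52, 17.00, 4.92, 12.00, 585.54, 12.89, 10.50),
    `Cat-4` = c(0.41, 8.98, 0.15, 1.50, 31.00, 7.38, 23.31, 457.62, 10.42,  9.39))
  min_tab <- rbind(
    `Cat-1` = c(0.17, 2.70, 0.09, 1.26,  3.00, 2.00,  1.00, 241.00,  9.80,  8.83),
    `Cat-2` = c(0.12, 2.10, 0.12, 1.34,  4.00, 2.00,  1.00, 452.00,  6.24,  7.49),
    `Cat-3` = c(0.17, 2.60, 0.11, 1.39,  5.00, 2.00,  3.00, 182.00,  6.30,  4.96),
    `Cat-4` = c(0.15, 2.70, 0.10, 1.31,  5.00, 2.00,  2.00, 171.00,  2.42,  3.04))
  max_tab <- rbind(
    `Cat-1` = c(0.25,  4.80, 0.17, 1.51,  10.00,  4.00,  6.00,  841.00, 34.73, 16.53),
    `Cat-2` = c(0.31,  5.80, 0.28, 1.92,   9.00,  4.00,  5.00, 1275.00, 31.88, 20.46),
    `Cat-3` = c(0.59, 15.40, 0.21, 1.70,  64.00, 15.00, 50.00,  864.00, 20.30, 16.91),
    `Cat-4` = c(0.79, 22.50, 0.20, 1.77, 104.00, 21.00, 83.00,  846.00, 22.90, 14.78))
  colnames(mean_tab) <- colnames(min_tab) <- colnames(max_tab) <- params
  list(mean = mean_tab, min = min_tab, max = max_tab)
}

#' Default latent -> chemistry link model
#'
#' Per-parameter response `intercept + b_r * r + b_s * s + b_q * (r -
#' r_peak)^2` plus Gaussian noise.  The four coefficients (with `r_peak =
#' 0`, so the quadratic term is simply `b_q * r^2`) are solved exactly so
#' that the noise-free response at the four category centroids reproduces
#' the category-mean calibration targets: the 4 x 4 design `(1, r, s, r^2)`
#' at the centroids is invertible because ripeness takes three distinct
#' values and spoilage separates the tied pair.  The quadratic term lets
#' the strongly convex degradation parameters (ethyl esters, peroxides)
#' accelerate in overripe batches, and gives polyphenols their concave
#' rise-then-fall in ripeness (vertex near the healthy-ripe Cat-2 centroid)
#' with a negative spoilage coefficient.
#'
#' @param noise_sd optional named vector overriding the per-parameter noise
#'   standard deviations (same units as the parameter).
#' @param include_control add an eleventh pure-noise parameter `control`
#'   (no latent link); useful as a negative control in end-to-end checks.
#' @return a `chem_link` data frame with columns `parameter`, `intercept`,
#'   `b_r`, `b_s`, `b_q`, `r_peak`, `noise_sd`.
#' @export
default_chem_link <- function(noise_sd = NULL, include_control = FALSE) {
  ref <- chem_reference()
  cent <- category_centroids()
  params <- chem_parameter_names()
  # noise scaled to roughly a third of the between-category mean spread
  default_sd <- c(acidity = 0.04, peroxide = 1.2, k270 = 0.015, k232 = 0.05,
                  ethyl_ester = 6, ethyl_palmitate = 1.3, ethyl_oleate = 5,
                  polyphenols = 110, chlorophyll = 2.5, carotenoids = 1.6)
  if (!is.null(noise_sd)) default_sd[names(noise_sd)] <- noise_sd
  design <- cbind(1, cent[, "ripeness"], cent[, "spoilage"],
                  cent[, "ripeness"]^2)

  rows <- lapply(params, function(pname) {
    beta <- solve(design, ref$mean[, pname])
    data.frame(parameter = pname, intercept = unname(beta[1]),
               b_r = unname(beta[2]), b_s = unname(beta[3]),
               b_q = unname(beta[4]), r_peak = 0,
               noise_sd = unname(default_sd[pname]))
  })
  link <- do.call(rbind, rows)
  if (include_control) {
    link <- rbind(link, data.frame(parameter = "control", intercept = 0,
                                   b_r = 0, b_s = 0, b_q = 0, r_peak = 0,
                                   noise_sd = 1))
  }
  class(link) <- c("chem_link", "data.frame")
  validate_chem_link(link)
  link
}

#' Validate a chemistry link model
#'
#' Checks that noise standard deviations are non-negative and that the
#' implied noise-free category-centroid means of the ten standard
#' parameters stay inside the calibration min-max envelope of their
#' category.
#'
#' @param link a `chem_link`.
#' @return `link`, invisibly; errors on violation.
#' @export
validate_chem_link <- function(link) {
  if (!all(c("parameter", "intercept", "b_r", "b_s", "b_q", "r_peak",
             "noise_sd") %in% names(link))) {
    stop_olivescan("malformed chem_link", "olivescan_link_error")
  }
  if (any(link$noise_sd < 0)) {
    stop_olivescan("noise_sd must be >= 0", "olivescan_link_error")
  }
  ref <- chem_reference()
  cent <- category_centroids()
  for (pname in intersect(link$parameter, chem_parameter_names())) {
    mu <- chem_mean(link, cent[, "ripeness"], cent[, "spoilage"])[, pname]
    bad <- mu < ref$min[, pname] | mu > ref$max[, pname]
    if (any(bad)) {
      stop_olivescan(sprintf(
        "implied %s mean outside the calibration envelope for %s",
        pname, paste(rownames(cent)[bad], collapse = ", ")),
        "olivescan_link_error")
    }
  }
  invisible(link)
}

#' Noise-free chemistry means implied by a link model
#'
#' @param link a `chem_link`.
#' @param ripeness,spoilage latent vectors (same length).
#' @return matrix with one row per latent pair and one column per parameter.
#' @export
chem_mean <- function(link, ripeness, spoilage) {
  out <- sapply(seq_len(nrow(link)), function(i) {
    link$intercept[i] + link$b_r[i] * ripeness + link$b_s[i] * spoilage +
      link$b_q[i] * (ripeness - link$r_peak[i])^2
  })
  out <- matrix(out, nrow = length(ripeness),
                dimnames = list(NULL, link$parameter))
  out
}

#' Draw one chemistry record
#'
#' Adds Gaussian noise (per-parameter `noise_sd`) to the noise-free means
#' implied by the latents.
#'
#' @param latents a [batch_latents()].
#' @param link a `chem_link` (default [default_chem_link()]).
#' @param seed optional integer seed; fixed seed and inputs give an
#'   identical record.
#' @return named numeric vector, one entry per link parameter.
#' @export
generate_chemistry <- function(latents, link = default_chem_link(), seed = NULL) {
  stopifnot(inherits(latents, "batch_latents"))
  validate_chem_link(link)
  mu <- drop(chem_mean(link, latents$ripeness, latents$spoilage))
  with_seed(seed, {
    noise <- stats::rnorm(nrow(link), 0, link$noise_sd)
    out <- mu + noise
    names(out) <- link$parameter
    out
  })
}
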