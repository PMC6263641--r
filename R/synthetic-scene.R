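# Synthetic tray-scene generator.
#
# Emulates the acquisition geometry used for olive batch inspection: a
# near-white methacrylate tray photographed from above, carrying a few dozen
# roughly elliptical fruits whose skin colour runs green -> purple -> black
# with ripening, and whose skin texture grows heterogeneous (dark/brown
# blotches) with spoilage.  Images are plain 8-bit RGB arrays; a ground-truth
# fruit mask is attached so segmentation accuracy can be scored exactly.

# Skin palette anchors (8-bit RGB): unripe green, mid-ripe purple, overripe
# black.  Chosen so that at low ripeness the green channel clearly dominates
# (margin > 2x the pixel-noise amplitude) and so that fruit grey levels stay
# far below the tray background.
.palette_green  <- c(60, 130, 50)
.palette_purple <- c(90, 30, 85)
.palette_black  <- c(15, 10, 12)

#' Scene configuration for the synthetic tray generator
#'
#' Defaults describe a quarter-resolution version of the acquisition camera
#' frame (512 x 272 instead of 2048 x 1088) to keep simulated datasets fast;
#' the full frame is available by overriding `image_width`/`image_height`.
#'
#' @param image_width,image_height image size in pixels.
#' @param fruits_per_batch integer count, or a length-2 range from which the
#'   per-batch count is drawn uniformly.  May be 0 (empty tray).
#' @param fruit_axis_px length-2 range for the ellipse semi-major axis in
#'   pixels; the semi-minor axis is drawn as 0.6-0.9 of the major one.
#' @param background_grey 8-bit tray background level; must be >= 200 so
#'   that fruits (always darker) are separable by a global threshold.
#' @param overlap_allowed may fruits overlap?  Trays of real fruit batches
#'   touch, so the default is `TRUE`; `FALSE` uses rejection sampling.
#' @param noise_amplitude per-pixel uniform noise bound (grey levels); noise
#'   is drawn in `[-noise_amplitude, noise_amplitude]` per channel.
#' @return an object of class `scene_config`.
#' @export
#' @examples
#' cfg <- scene_config(image_width = 160, image_height = 120,
#'                     fruits_per_batch = c(4, 6), fruit_axis_px = c(8, 12))
scene_config <- function(image_width = 512L,
                         image_height = 272L,
                         fruits_per_batch = c(25L, 40L),
                         fruit_axis_px = c(10, 18),
                         background_grey = 235L,
                         overlap_allowed = TRUE,
                         noise_amplitude = 4L) {
  image_width <- as.integer(image_width)
  image_height <- as.integer(image_height)
  if (image_width < 1L || image_height < 1L) {
    stop_olivescan("image dimensions must be positive", "olivescan_config_error")
  }
  if (length(fruits_per_batch) == 1L) fruits_per_batch <- rep(fruits_per_batch, 2L)
  fruits_per_batch <- as.integer(fruits_per_batch)
  if (any(fruits_per_batch < 0L) || fruits_per_batch[2] < fruits_per_batch[1]) {
    stop_olivescan("fruits_per_batch must be a non-negative count or range",
                   "olivescan_config_error")
  }
  if (length(fruit_axis_px) == 1L) fruit_axis_px <- rep(fruit_axis_px, 2L)
  if (any(fruit_axis_px <= 0) || fruit_axis_px[2] < fruit_axis_px[1]) {
    stop_olivescan("fruit_axis_px must be a positive range", "olivescan_config_error")
  }
  if (fruit_axis_px[2] >= min(image_width, image_height)) {
    stop_olivescan("fruit axes must be strictly smaller than the image",
                   "olivescan_config_error")
  }
  background_grey <- as.integer(background_grey)
  if (background_grey < 200L || background_grey > 255L) {
    stop_olivescan("background_grey must be in [200, 255] for threshold separability",
                   "olivescan_config_error")
  }
  noise_amplitude <- as.integer(noise_amplitude)
  if (noise_amplitude < 0L || noise_amplitude > 10L) {
    stop_olivescan("noise_amplitude must be in [0, 10]", "olivescan_config_error")
  }
  structure(
    list(image_width = image_width, image_height = image_height,
         fruits_per_batch = fruits_per_batch, fruit_axis_px = fruit_axis_px,
         background_grey = background_grey, overlap_allowed = overlap_allowed,
         noise_amplitude = noise_amplitude),
    class = "scene_config"
  )
}

#' Latent state of one olive batch
#'
#' The generator drives everything downstream from two latent variables:
#' `ripeness` (0 = fully green skin, 1 = fully black) and `spoilage` (the
#' fraction of fruits carrying visible damage blotches).  The visual
#' category is a deterministic function of the two: batches under 50%
#' ripeness are Cat-1 (green), ripe batches split into healthy Cat-2 and
#' spoiled Cat-3 at 30% spoilage, and batches at 85% ripeness or above are
#' overripe Cat-4.
#'
#' @param ripeness real in `[0, 1]`.
#' @param spoilage real in `[0, 1]`.
#' @return an object of class `batch_latents` with fields `ripeness`,
#'   `spoilage` and `category`.
#' @export
batch_latents <- function(ripeness, spoilage) {
  if (!is.numeric(ripeness) || length(ripeness) != 1L || is.na(ripeness) ||
      ripeness < 0 || ripeness > 1) {
    stop_olivescan("ripeness must be a single value in [0, 1]", "olivescan_latents_error")
  }
  if (!is.numeric(spoilage) || length(spoilage) != 1L || is.na(spoilage) ||
      spoilage < 0 || spoilage > 1) {
    stop_olivescan("spoilage must be a single value in [0, 1]", "olivescan_latents_error")
  }
  structure(
    list(ripeness = ripeness, spoilage = spoilage,
         category = categorize_latents(ripeness, spoilage)),
    class = "batch_latents"
  )
}

#' Visual category implied by latent ripeness and spoilage
#'
#' @param ripeness,spoilage vectors in `[0, 1]` (recycled).
#' @return character vector of `"Cat-1"` ... `"Cat-4"`.
#' @export
categorize_latents <- function(ripeness, spoilage) {
  out <- ifelse(ripeness < 0.5, "Cat-1",
         ifelse(ripeness >= 0.85, "Cat-4",
         ifelse(spoilage >= 0.3, "Cat-3", "Cat-2")))
  as.character(out)
}

#' Skin colour for a given per-fruit ripeness
#'
#' Piecewise-linear interpolation through the green / purple / black palette
#' anchors: green -> purple over ripeness 0-0.5, purple -> black over 0.5-1.
#'
#' @param t ripeness values in `[0, 1]`.
#' @return a `length(t)` x 3 matrix of 8-bit RGB values.
#' @export
olive_palette <- function(t) {
  t <- clamp(t, 0, 1)
  out <- matrix(0, length(t), 3L, dimnames = list(NULL, c("R", "G", "B")))
  lo <- t < 0.5
  u <- ifelse(lo, t / 0.5, (t - 0.5) / 0.5)
  for (k in 1:3) {
    out[, k] <- ifelse(lo,
      .palette_green[k] + u * (.palette_purple[k] - .palette_green[k]),
      .palette_purple[k] + u * (.palette_black[k] - .palette_purple[k]))
  }
  out
}

#' Generate one synthetic tray image
#'
#' Renders `fruits_per_batch` filled ellipses on a near-white background.
#' Each fruit's base colour follows [olive_palette()] at a per-fruit
#' ripeness jittered around the batch latent (truncated at +/- 0.2 so a
#' fully green batch stays green); a `spoilage` fraction of fruits receives
#' 2-5 dark/brown disk blotches that raise local grey-level contrast.  A
#' mild radial shading and uniform per-pixel noise complete the scene.
#'
#' Rendering draws all fruit geometry and colours first and blotches last,
#' so two calls with the same seed but different `spoilage` produce
#' identical scenes except for the blotches.
#'
#' @param config a [scene_config()].
#' @param latents a [batch_latents()].
#' @param seed optional integer; when supplied the scene is a pure function
#'   of `(config, latents, seed)`.
#' @param batch_id identifier stored with the image.
#' @return a `batch_image` (see [batch_image()]) with attribute
#'   `ground_truth`: a logical fruit-pixel mask.
#' @export
generate_batch_scene <- function(config, latents, seed = NULL,
                                 batch_id = "batch_001") {
  stopifnot(inherits(config, "scene_config"), inherits(latents, "batch_latents"))
  with_seed(seed, {
    W <- config$image_width
    H <- config$image_height
    n_range <- config$fruits_per_batch
    n_fruits <- if (n_range[1] == n_range[2]) n_range[1] else
      sample(n_range[1]:n_range[2], 1L)

    px <- array(as.numeric(config$background_grey), dim = c(H, W, 3L))
    truth <- matrix(FALSE, H, W)

    fruits <- vector("list", n_fruits)
    if (n_fruits > 0L) {
      a_max <- config$fruit_axis_px[2]
      if (2 * a_max + 2 > min(W, H)) {
        stop_olivescan("cannot place fruits: axes too large for the image",
                       "olivescan_placement_error")
      }
      for (i in seq_len(n_fruits)) {
        a <- stats::runif(1, config$fruit_axis_px[1], config$fruit_axis_px[2])
        b <- a * stats::runif(1, 0.6, 0.9)
        theta <- stats::runif(1, 0, pi)
        placed <- FALSE
        for (attempt in seq_len(200L)) {
          cx <- stats::runif(1, a + 1, W - a)
          cy <- stats::runif(1, a + 1, H - a)
          if (config$overlap_allowed) {
            placed <- TRUE
            break
          }
          ok <- TRUE
          for (f in fruits[seq_len(i - 1L)]) {
            if (sqrt((cx - f$cx)^2 + (cy - f$cy)^2) < (a + f$a)) {
              ok <- FALSE
              break
            }
          }
          if (ok) {
            placed <- TRUE
            break
          }
        }
        if (!placed) {
          stop_olivescan("cannot place fruits without overlap; reduce count or axes",
                         "olivescan_placement_error")
        }
        jitter <- clamp(stats::rnorm(1, 0, 0.07), -0.2, 0.2)
        fruits[[i]] <- list(cx = cx, cy = cy, a = a, b = b, theta = theta,
                            ripeness = clamp(latents$ripeness + jitter, 0, 1))
      }

      # rasterise fruits (later fruits overdraw earlier ones where allowed)
      for (f in fruits) {
        cols <- round(max(1, floor(f$cx - f$a)):min(W, ceiling(f$cx + f$a)))
        rows <- round(max(1, floor(f$cy - f$a)):min(H, ceiling(f$cy + f$a)))
        dx <- outer(rep(1, length(rows)), cols - f$cx)
        dy <- outer(rows - f$cy, rep(1, length(cols)))
        xr <- (dx * cos(f$theta) + dy * sin(f$theta)) / f$a
        yr <- (-dx * sin(f$theta) + dy * cos(f$theta)) / f$b
        rho2 <- xr^2 + yr^2
        inside <- rho2 <= 1
        if (!any(inside)) next
        base <- olive_palette(f$ripeness)[1, ]
        shade <- 1 - 0.15 * rho2 # mild radial darkening toward the rim
        for (k in 1:3) {
          plane <- px[rows, cols, k]
          plane[inside] <- base[k] * shade[inside]
          px[rows, cols, k] <- plane
        }
        tr <- truth[rows, cols]
        tr[inside] <- TRUE
        truth[rows, cols] <- tr
      }

      # draw the pixel noise before any spoilage randomness so that two
      # scenes sharing a seed differ only in the blotch pixels
      noise <- NULL
      if (config$noise_amplitude > 0L) {
        amp <- config$noise_amplitude
        noise <- array(sample(-amp:amp, H * W * 3L, replace = TRUE),
                       dim = c(H, W, 3L))
      }

      # blotches last: spoiled fruits get dark/brown disks on their skin
      n_spoiled <- round(latents$spoilage * n_fruits)
      if (n_spoiled > 0L) {
        spoiled <- sample(seq_len(n_fruits), n_spoiled)
        blotch_cols <- rbind(brown = c(96, 60, 28), dark = c(45, 28, 16))
        for (i in spoiled) {
          f <- fruits[[i]]
          k_blotch <- sample(2:5, 1L)
          for (j in seq_len(k_blotch)) {
            # blotch centre inside the ellipse (polar in canonical frame)
            rr <- sqrt(stats::runif(1)) * 0.7
            ang <- stats::runif(1, 0, 2 * pi)
            ex <- rr * cos(ang) * f$a
            ey <- rr * sin(ang) * f$b
            bx <- f$cx + ex * cos(f$theta) - ey * sin(f$theta)
            by <- f$cy + ex * sin(f$theta) + ey * cos(f$theta)
            rad <- stats::runif(1, 0.15, 0.35) * f$b
            colr <- blotch_cols[sample(1:2, 1L), ]
            cols <- round(max(1, floor(bx - rad)):min(W, ceiling(bx + rad)))
            rows <- round(max(1, floor(by - rad)):min(H, ceiling(by + rad)))
            dx <- outer(rep(1, length(rows)), cols - bx)
            dy <- outer(rows - by, rep(1, length(cols)))
            disk <- (dx^2 + dy^2) <= rad^2
            disk <- disk & truth[rows, cols] # paint on fruit skin only
            if (!any(disk)) next
            for (k in 1:3) {
              plane <- px[rows, cols, k]
              plane[disk] <- colr[k]
              px[rows, cols, k] <- plane
            }
          }
        }
      }
    }

    if (n_fruits == 0L && config$noise_amplitude > 0L) {
      amp <- config$noise_amplitude
      noise <- array(sample(-amp:amp, H * W * 3L, replace = TRUE), dim = c(H, W, 3L))
    }
    if (config$noise_amplitude > 0L) px <- px + noise
    px <- round(clamp(px, 0, 255))
    img <- batch_image(px, batch_id = batch_id)
    attr(img, "ground_truth") <- truth
    img
  })
}
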