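test_that("category thresholds partition the latent plane", {
  expect_equal(categorize_latents(0.2, 0.9), "Cat-1")
  expect_equal(categorize_latents(0.49, 0), "Cat-1")
  expect_equal(categorize_latents(0.5, 0.29), "Cat-2")
  expect_equal(categorize_latents(0.5, 0.3), "Cat-3")
  expect_equal(categorize_latents(0.84, 0.9), "Cat-3")
  expect_equal(categorize_latents(0.85, 0), "Cat-4")
  expect_error(batch_latents(1.2, 0), class = "olivescan_latents_error")
  expect_error(batch_latents(0.5, -0.1), class = "olivescan_latents_error")
})

test_that("fully green batches have green-dominant fruit pixels", {
  img <- generate_batch_scene(tiny_config(), batch_latents(0, 0), seed = 11)
  truth <- attr(img, "ground_truth")
  r <- img$pixels[, , 1][truth]
  g <- img$pixels[, , 2][truth]
  b <- img$pixels[, , 3][truth]
  expect_gt(length(g), 0)
  expect_true(all(g > r))
  expect_true(all(g > b))
})

test_that("an empty tray is pure background up to the noise bound", {
  cfg <- tiny_config(fruits_per_batch = 0L)
  img <- generate_batch_scene(cfg, batch_latents(0.5, 0.5), seed = 3)
  expect_true(all(img$pixels >= cfg$background_grey - cfg$noise_amplitude))
  expect_false(any(attr(img, "ground_truth")))
})

test_that("scenes are pure functions of (config, latents, seed)", {
  cfg <- tiny_config()
  lat <- batch_latents(0.6, 0.4)
  a <- generate_batch_scene(cfg, lat, seed = 99)
  b <- generate_batch_scene(cfg, lat, seed = 99)
  expect_identical(a$pixels, b$pixels)
  c <- generate_batch_scene(cfg, lat, seed = 100)
  expect_false(identical(a$pixels, c$pixels))
})

test_that("impossible fruit placement raises a placement error", {
  expect_error(scene_config(image_width = 40, image_height = 40,
                            fruit_axis_px = c(45, 50)),
               class = "olivescan_config_error")
  cfg <- scene_config(image_width = 64, image_height = 64,
                      fruits_per_batch = 3L, fruit_axis_px = c(31, 31.4))
  expect_error(generate_batch_scene(cfg, batch_latents(0.5, 0), seed = 1),
               class = "olivescan_placement_error")
  dense <- scene_config(image_width = 80, image_height = 80,
                        fruits_per_batch = 60L, fruit_axis_px = c(14, 16),
                        overlap_allowed = FALSE)
  expect_error(generate_batch_scene(dense, batch_latents(0.5, 0), seed = 1),
               class = "olivescan_placement_error")
})

test_that("spoilage blotches raise GLCM contrast (paired scenes)", {
  higher <- vapply(1:20, function(s) {
    cfg <- tiny_config()
    clean <- generate_batch_scene(cfg, batch_latents(0.5, 0), seed = 1000 + s)
    spoilt <- generate_batch_scene(cfg, batch_latents(0.5, 1), seed = 1000 + s)
    contrast_of <- function(img) {
      grey <- to_grayscale(img)
      mask <- binarize(grey, threshold = 180)
      haralick_features(compute_glcm(grey, mask))[["glcm_contrast"]]
    }
    contrast_of(spoilt) > contrast_of(clean)
  }, logical(1))
  expect_true(all(higher))
})

test_that("fruit and background grey levels separate at the default threshold", {
  for (s in 1:5) {
    img <- generate_batch_scene(scene_config(), batch_latents(s / 6, 0.3),
                                seed = 200 + s)
    truth <- attr(img, "ground_truth")
    mask <- binarize(to_grayscale(img))
    recovered <- sum(mask$mask & truth) / sum(truth)
    expect_gte(recovered, 0.99)
    expect_equal(mask$coverage, mean(truth), tolerance = 0.01)
  }
})
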