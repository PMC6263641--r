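test_that("grayscale conversion follows the Rec. 601 weights", {
  expect_true(all(to_grayscale(flat_image(255, 255, 255)) == 255))
  expect_true(all(to_grayscale(flat_image(0, 0, 0)) == 0))
  # pure red: 0.299 * 255 = 76.245 -> 76
  expect_true(all(to_grayscale(flat_image(255, 0, 0)) == 76))
  expect_true(all(to_grayscale(flat_image(0, 255, 0)) == round(0.587 * 255)))
})

test_that("binarisation polarity and trivial coverages are correct", {
  white <- matrix(255, 10, 10)
  black <- matrix(0, 10, 10)
  expect_equal(binarize(white, 200)$coverage, 0)
  expect_equal(binarize(black, 200)$coverage, 1)
  expect_error(otsu_threshold(white), class = "olivescan_threshold_error")
  expect_error(binarize(white, "auto"), class = "olivescan_threshold_error")
  expect_error(binarize(white, 300), class = "olivescan_image_error")
})

test_that("coverage is monotone non-decreasing in the threshold", {
  set.seed(31)
  grey <- matrix(sample(0:255, 400, replace = TRUE), 20, 20)
  covs <- vapply(seq(0, 255, by = 15),
                 function(t) binarize(grey, t)$coverage, numeric(1))
  expect_true(all(diff(covs) >= 0))
})

test_that("auto threshold separates a synthetic tray and reports its value", {
  img <- generate_batch_scene(tiny_config(), batch_latents(0.4, 0.2), seed = 7)
  mask <- binarize(to_grayscale(img))
  expect_gt(mask$threshold, 110)  # above every fruit grey level
  expect_lt(mask$threshold, 231)  # below the noisy background
  truth <- attr(img, "ground_truth")
  expect_equal(mask$coverage, mean(truth), tolerance = 0.01)
})

test_that("masking zeroes the background, keeps fruit, and is idempotent", {
  img <- generate_batch_scene(tiny_config(), batch_latents(0.5, 0.5), seed = 13)
  mask <- binarize(to_grayscale(img))
  masked <- apply_mask(img, mask)
  expect_true(all(masked$pixels[!mask$mask] == 0))
  keep <- array(mask$mask, dim(img$pixels))
  expect_identical(masked$pixels[keep], img$pixels[keep])
  twice <- apply_mask(masked, mask)
  expect_identical(twice$pixels, masked$pixels)

  all_true <- binarize(matrix(0, img$height, img$width), 1)
  expect_identical(apply_mask(img, all_true)$pixels, img$pixels)
  all_false <- binarize(matrix(255, img$height, img$width), 1)
  expect_true(all(apply_mask(img, all_false)$pixels == 0))
  small <- binarize(matrix(0, 3, 3), 1)
  expect_error(apply_mask(img, small), class = "olivescan_image_error")
})

test_that("the mask can be recomputed from the masked image's nonzero pixels", {
  img <- generate_batch_scene(tiny_config(), batch_latents(0.6, 0.3), seed = 17)
  mask <- binarize(to_grayscale(img))
  masked <- apply_mask(img, mask)
  nonzero <- apply(masked$pixels, c(1, 2), function(v) any(v > 0))
  # wherever the input image was nonzero, the recomputed mask agrees
  input_nonzero <- apply(img$pixels, c(1, 2), function(v) any(v > 0))
  expect_identical(nonzero[input_nonzero], mask$mask[input_nonzero])
})

test_that("images survive a PNG round trip", {
  img <- generate_batch_scene(tiny_config(), batch_latents(0.3, 0.6), seed = 23)
  path <- withr::local_tempfile(fileext = ".png")
  write_batch_image(img, path)
  back <- read_batch_image(path)
  expect_equal(back$pixels, img$pixels, ignore_attr = TRUE)
  expect_error(read_batch_image("missing_file.png"), class = "olivescan_io_error")
})
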