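test_that("a constant region yields a single diagonal GLCM entry", {
  grey <- matrix(100, 8, 8)
  glcm <- compute_glcm(grey, levels = 16)
  expect_equal(sum(glcm), 1, tolerance = 1e-12)
  q <- floor(100 * 16 / 256) + 1
  expect_equal(unclass(glcm)[q, q], 1)
  expect_equal(sum(unclass(glcm) != 0), 1L)
})

test_that("a two-level checkerboard puts all mass off the diagonal", {
  grey <- matrix(c(0, 128, 128, 0), 2, 2)
  glcm <- compute_glcm(grey, levels = 2, offsets = list(c(0L, 1L)),
                       symmetric = TRUE)
  P <- unclass(glcm)
  # two horizontal pairs, both between the two levels; symmetric closure
  expect_equal(P[1, 1], 0)
  expect_equal(P[2, 2], 0)
  expect_equal(P[1, 2] + P[2, 1], 1)
  expect_equal(P[1, 2], P[2, 1])
})

test_that("GLCMs are normalised, symmetric in symmetric mode, and mask-aware", {
  set.seed(53)
  grey <- matrix(sample(0:255, 15 * 15, replace = TRUE), 15, 15)
  glcm <- compute_glcm(grey, levels = 8)
  expect_equal(sum(glcm), 1, tolerance = 1e-12)
  expect_equal(unclass(glcm), t(unclass(glcm)), tolerance = 1e-15)

  # restrict to a mask: pairs crossing the mask edge must not count
  m <- matrix(FALSE, 15, 15)
  m[4:9, 4:9] <- TRUE
  mask <- structure(list(mask = m, coverage = mean(m), threshold = NA),
                    class = "fruit_mask")
  inner <- compute_glcm(grey, mask, levels = 8, offsets = list(c(0L, 1L)),
                        symmetric = FALSE)
  sub <- compute_glcm(grey[4:9, 4:9], levels = 8, offsets = list(c(0L, 1L)),
                      symmetric = FALSE)
  expect_equal(unclass(inner), unclass(sub), tolerance = 1e-12)

  none <- structure(list(mask = matrix(FALSE, 15, 15), coverage = 0,
                         threshold = NA), class = "fruit_mask")
  expect_error(compute_glcm(grey, none), class = "olivescan_glcm_error")
})

test_that("degenerate and maximum-entropy GLCMs give the textbook feature values", {
  single <- matrix(0, 4, 4)
  single[2, 2] <- 1
  f <- haralick_features(single)
  expect_equal(f[["glcm_asm"]], 1)
  expect_equal(f[["glcm_entropy"]], 0)
  expect_equal(f[["glcm_contrast"]], 0)
  expect_equal(f[["glcm_mcc"]], 0)
  expect_true(isTRUE(attr(f, "mcc_degenerate")))

  G <- 5
  uniform <- matrix(1 / G^2, G, G)
  fu <- haralick_features(uniform)
  expect_equal(fu[["glcm_asm"]], 1 / G^2, tolerance = 1e-12)
  expect_equal(fu[["glcm_entropy"]], log(G^2), tolerance = 1e-12)
})

test_that("all 14 descriptors match the brute-force oracle on random GLCMs", {
  set.seed(61)
  for (rep in 1:120) {
    G <- sample(3:8, 1)
    P <- random_glcm(G)
    if (rep %% 4 == 0) {
      P[sample(G * G, G)] <- 0 # exercise zero-probability guards
      P <- P / sum(P)
    }
    fast <- haralick_features(P)
    slow <- haralick_oracle(P)
    expect_equal(unname(fast), unname(slow), tolerance = 1e-10)
  }
})
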