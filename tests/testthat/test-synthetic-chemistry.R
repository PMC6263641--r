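centroid_latents <- function(cat) {
  cent <- list(`Cat-1` = c(0.25, 0.10), `Cat-2` = c(0.675, 0.10),
               `Cat-3` = c(0.675, 0.55), `Cat-4` = c(0.925, 0.55))[[cat]]
  batch_latents(cent[1], cent[2])
}

test_that("noise-free chemistry at category centroids hits the calibration means", {
  link <- default_chem_link()
  link$noise_sd[] <- 0
  cat1 <- generate_chemistry(centroid_latents("Cat-1"), link, seed = 1)
  expect_equal(unname(cat1[["acidity"]]), 0.20, tolerance = 1e-9)
  cat4 <- generate_chemistry(centroid_latents("Cat-4"), link, seed = 1)
  expect_equal(unname(cat4[["chlorophyll"]]), 10.42, tolerance = 1e-9)
})

test_that("category ordering of the implied means matches ripening chemistry", {
  link <- default_chem_link()
  link$noise_sd[] <- 0
  mus <- t(vapply(paste0("Cat-", 1:4), function(cat) {
    generate_chemistry(centroid_latents(cat), link, seed = 1)
  }, numeric(10)))
  expect_true(all(diff(mus[, "acidity"]) >= 0))
  expect_true(all(diff(mus[, "chlorophyll"]) <= 0))
  expect_true(all(diff(mus[, "carotenoids"]) <= 0))
  expect_equal(unname(which.max(mus[, "polyphenols"])), 2L)
})

test_that("the polyphenol response is concave in ripeness with a negative spoilage term", {
  link <- default_chem_link()
  pp <- link[link$parameter == "polyphenols", ]
  expect_lt(pp$b_q, 0)
  expect_lt(pp$b_s, 0)
  vertex <- -pp$b_r / (2 * pp$b_q)
  expect_gt(vertex, 0.5)
  expect_lt(vertex, 0.85)
})

test_that("chemistry records are deterministic under a fixed seed", {
  lat <- batch_latents(0.7, 0.2)
  a <- generate_chemistry(lat, seed = 42)
  b <- generate_chemistry(lat, seed = 42)
  expect_identical(a, b)
  c <- generate_chemistry(lat, seed = 43)
  expect_false(identical(a, c))
})

test_that("link validation enforces noise and envelope invariants", {
  link <- default_chem_link()
  expect_invisible(validate_chem_link(link))
  bad <- link
  bad$noise_sd[1] <- -1
  expect_error(validate_chem_link(bad), class = "olivescan_link_error")
  skew <- link
  skew$intercept[skew$parameter == "acidity"] <- 5 # way outside every envelope
  expect_error(validate_chem_link(skew), class = "olivescan_link_error")
  expect_error(generate_chemistry(batch_latents(0.5, 0.5), skew, seed = 1),
               class = "olivescan_link_error")
})

test_that("the optional control parameter is pure noise", {
  link <- default_chem_link(include_control = TRUE)
  ctl <- link[link$parameter == "control", ]
  expect_equal(ctl$b_r, 0)
  expect_equal(ctl$b_s, 0)
  expect_equal(ctl$b_q, 0)
  expect_equal(nrow(link), 11L)
})
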