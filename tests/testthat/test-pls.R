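test_that("full-rank PLS1 equals ordinary least squares", {
  set.seed(91)
  for (rep in 1:20) {
    n <- sample(20:40, 1)
    p <- sample(2:6, 1)
    X <- matrix(rnorm(n * p), n, p)
    y <- rnorm(n)
    fit <- fit_pls(X, y, lv = p)
    ols <- stats::lm.fit(cbind(1, X), y)$coefficients
    expect_equal(unname(fit$coefficients), unname(ols[-1]), tolerance = 1e-6)
    expect_equal(unname(fit$intercept), unname(ols[1]), tolerance = 1e-6)
  }
})

test_that("noiseless linear responses are reproduced exactly at full rank", {
  set.seed(93)
  X <- matrix(rnorm(50 * 6), 50, 6)
  beta <- rnorm(6)
  y <- drop(X %*% beta) + 2
  fit <- fit_pls(X, y, lv = 6)
  expect_equal(predict(fit, X), y, tolerance = 1e-8)
})

test_that("a single-column fit reduces to simple linear regression", {
  set.seed(95)
  x <- rnorm(30)
  y <- 3 + 2 * x + rnorm(30, 0, 0.1)
  fit <- fit_pls(matrix(x), y, lv = 1)
  slope <- stats::cov(x, y) / stats::var(x)
  expect_equal(unname(fit$coefficients), slope, tolerance = 1e-10)
  expect_equal(fit$intercept, mean(y) - slope * mean(x), tolerance = 1e-10)
})

test_that("scores are orthogonal and the X decomposition reconstructs exactly", {
  set.seed(97)
  X <- matrix(rnorm(40 * 8), 40, 8)
  y <- rnorm(40)
  fit <- fit_pls(X, y, lv = 5)
  G <- crossprod(fit$T)
  expect_lt(max(abs(G - diag(diag(G)))), 1e-10)
  Xs <- scale(X)
  expect_equal(fit$T %*% t(fit$P) + fit$E, unclass(Xs)[, ], tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("predictions are shift-equivariant and autoscale-invariant", {
  set.seed(99)
  X <- matrix(rnorm(30 * 5), 30, 5)
  y <- rnorm(30)
  Xnew <- matrix(rnorm(10 * 5), 10, 5)
  fit <- fit_pls(X, y, lv = 3)
  expect_equal(predict(fit, X), drop(X %*% fit$coefficients) + fit$intercept)

  shifted <- fit_pls(X, y + 7, lv = 3)
  expect_equal(predict(shifted, Xnew), predict(fit, Xnew) + 7, tolerance = 1e-10)

  Xs <- X
  Xs[, 2] <- Xs[, 2] * 10
  rescaled <- fit_pls(Xs, y, lv = 3)
  Xnew_s <- Xnew
  Xnew_s[, 2] <- Xnew_s[, 2] * 10
  expect_equal(predict(rescaled, Xnew_s), predict(fit, Xnew), tolerance = 1e-10)
})

test_that("contract violations raise informative errors", {
  X <- matrix(rnorm(20 * 4), 20, 4)
  expect_error(fit_pls(X, rep(1, 20), lv = 2), class = "olivescan_pls_error")
  expect_error(fit_pls(X, rnorm(20), lv = 5), class = "olivescan_pls_error")
  expect_error(fit_pls(X, rnorm(19), lv = 2), class = "olivescan_pls_error")
  Xc <- matrix(1, 20, 3)
  expect_error(fit_pls(Xc, rnorm(20), lv = 1), class = "olivescan_pls_error")

  # rank-deficient X: error by default, truncation on request
  tab <- generate_feature_table(40, p = 10, lv_true = 2, noise_sd = 0, seed = 3)
  expect_error(fit_pls(tab$X, tab$y, lv = 5), class = "olivescan_rank_error")
  fit <- fit_pls(tab$X, tab$y, lv = 5, on_rank_deficit = "truncate")
  expect_lte(fit$lv, 3L)
  fit2 <- fit_pls(tab$X, tab$y, lv = 2)
  expect_error(predict(fit2, tab$X[, 1:4]), class = "olivescan_pls_error")
})
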