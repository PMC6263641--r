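test_that("holdout validation is reproducible from the plan seed", {
  tab <- generate_feature_table(40, p = 6, lv_true = 2, noise_sd = 0.2, seed = 4)
  a <- holdout_validate(tab$X, tab$y, 2, holdout_plan(1, seed = 7))
  b <- holdout_validate(tab$X, tab$y, 2, holdout_plan(1, seed = 7))
  expect_identical(a$reps, b$reps)
  c <- holdout_validate(tab$X, tab$y, 2, holdout_plan(1, seed = 8))
  expect_false(identical(a$reps, c$reps))
})

test_that("noiseless linear data validates at Rv2 = 1 for any split", {
  tab <- generate_feature_table(60, p = 5, lv_true = 3, noise_sd = 0, seed = 6)
  hv <- holdout_validate(tab$X, tab$y, 3, holdout_plan(25, seed = 9))
  expect_equal(hv$summary$mean[["rv2"]], 1, tolerance = 1e-6)
  expect_lt(hv$summary$mean[["rmsev"]], 1e-6)
})

test_that("calibration RMSE is non-increasing in the latent-variable count", {
  set.seed(111)
  X <- matrix(rnorm(60 * 8), 60, 8)
  y <- drop(X %*% rnorm(8)) + rnorm(60, 0, 0.5)
  plan <- holdout_plan(30, seed = 13)
  sm <- select_model(X, y, plan, lv_max = 8)
  expect_true(all(diff(sm$sweep$rmsec) <= 1e-10))
})

test_that("reported RPD times RMSEv recovers the validation-half sd exactly", {
  tab <- generate_feature_table(50, p = 6, lv_true = 2, noise_sd = 0.3, seed = 14)
  hv <- holdout_validate(tab$X, tab$y, 2, holdout_plan(50, seed = 15))
  expect_true(all(abs(hv$reps$rpd * hv$reps$rmsev - hv$reps$sd_val) < 1e-9))
})

test_that("holdout summaries are exchangeable under sample permutation", {
  tab <- generate_feature_table(80, p = 6, lv_true = 2, noise_sd = 0.3, seed = 16)
  plan <- holdout_plan(200, seed = 17)
  a <- holdout_validate(tab$X, tab$y, 2, plan)
  perm <- sample(80)
  b <- holdout_validate(tab$X[perm, ], tab$y[perm], 2, plan)
  # means agree within a few Monte-Carlo standard errors
  se <- a$summary$sd[["rmsev"]] / sqrt(plan$repetitions)
  expect_lt(abs(a$summary$mean[["rmsev"]] - b$summary$mean[["rmsev"]]), 5 * se)
})

test_that("infeasible splits and sweeps are rejected", {
  tab <- generate_feature_table(10, p = 6, lv_true = 2, noise_sd = 0.1, seed = 18)
  expect_error(holdout_validate(tab$X, tab$y, 5, holdout_plan(5, seed = 1)),
               class = "olivescan_plan_error")
  expect_error(holdout_validate(tab$X[1:3, ], tab$y[1:3], 1,
                                holdout_plan(5, seed = 1)),
               class = "olivescan_plan_error")
  expect_error(holdout_plan(0), class = "olivescan_plan_error")
  expect_error(holdout_plan(10, train_fraction = 1), class = "olivescan_plan_error")
})

test_that("the sweep upper bound honours the feature count", {
  tab <- generate_feature_table(60, p = 23, lv_true = 23, noise_sd = 0.5, seed = 19)
  plan <- holdout_plan(3, seed = 20)
  sm <- select_model(tab$X, tab$y, plan, lv_max = 23)
  expect_equal(max(sm$sweep$lv), 23L)
  sm5 <- select_model(tab$X[, 1:5], tab$y, plan, lv_max = 23)
  expect_equal(max(sm5$sweep$lv), 5L)
})
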