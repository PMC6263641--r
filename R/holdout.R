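# Repeated 50/50 holdout validation and latent-variable selection.  Each
# chemical parameter gets its own PLS1 model: the latent-variable count is
# swept from 1 upwards, each candidate is trained and validated on many
# random half-splits, and the sweep's best model (smallest mean validation
# RMSE, ties to the simpler model) is reported with its calibration and
# validation metrics.

#' Repeated-holdout plan
#'
#' @param repetitions number of random splits (default 1000).
#' @param train_fraction fraction of samples in the calibration half
#'   (default 0.5).
#' @param seed integer seed for the split stream; `NULL` uses the current
#'   RNG state.
#' @return a `holdout_plan`.
#' @export
holdout_plan <- function(repetitions = 1000L, train_fraction = 0.5, seed = NULL) {
  repetitions <- as.integer(repetitions)
  if (repetitions < 1L) stop_olivescan("repetitions must be >= 1", "olivescan_plan_error")
  if (!is.numeric(train_fraction) || train_fraction <= 0 || train_fraction >= 1) {
    stop_olivescan("train_fraction must be in (0, 1)", "olivescan_plan_error")
  }
  structure(list(repetitions = repetitions, train_fraction = train_fraction,
                 seed = seed),
            class = "holdout_plan")
}

# Draw the calibration indices for every repetition up front so that a
# latent-variable sweep can reuse identical splits (common random numbers).
draw_splits <- function(n, plan) {
  n_train <- round(n * plan$train_fraction)
  if (n_train < 2L || n - n_train < 2L) {
    stop_olivescan("infeasible split: both halves need at least 2 samples",
                   "olivescan_plan_error")
  }
  with_seed(plan$seed,
            lapply(seq_len(plan$repetitions), function(i) sample.int(n, n_train)))
}

#' Repeated 50/50 holdout validation of a PLS1 model
#'
#' For each repetition the samples are split at random into a calibration
#' and a validation half, a PLS1 model with `lv` latent variables is fitted
#' on the calibration half, and both halves are scored.  Returns the
#' per-repetition metrics and their summaries.
#'
#' @param X feature matrix.
#' @param y response vector.
#' @param lv latent-variable count.
#' @param plan a [holdout_plan()].
#' @param scale passed to [fit_pls()].
#' @param splits optional precomputed list of calibration-index vectors
#'   (used internally by [select_model()] to share splits across the sweep).
#' @return a `holdout_result`: list with `reps` (data frame with columns
#'   `rmsec`, `rmsev`, `rc2`, `rv2`, `sd_val`, `rpd`) and `summary` (means
#'   and standard deviations over repetitions).
#' @export
holdout_validate <- function(X, y, lv, plan = holdout_plan(), scale = "autoscale",
                             splits = NULL) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  if (is.null(splits)) splits <- draw_splits(n, plan)
  n_train <- length(splits[[1]])
  if (n_train <= lv) {
    stop_olivescan(sprintf(
      "infeasible split: %d training samples cannot support lv = %d", n_train, lv),
      "olivescan_plan_error")
  }
  reps <- lapply(splits, function(cal) {
    val <- setdiff(seq_len(n), cal)
    fit <- fit_pls(X[cal, , drop = FALSE], y[cal], lv = lv, scale = scale,
                   on_rank_deficit = "truncate")
    yc_hat <- predict(fit, X[cal, , drop = FALSE])
    yv_hat <- predict(fit, X[val, , drop = FALSE])
    rmsec <- rmse(y[cal], yc_hat)
    rmsev <- rmse(y[val], yv_hat)
    sd_val <- stats::sd(y[val])
    c(rmsec = rmsec, rmsev = rmsev,
      rc2 = r_squared(y[cal], yc_hat), rv2 = r_squared(y[val], yv_hat),
      sd_val = sd_val, rpd = if (rmsev > 0) sd_val / rmsev else Inf)
  })
  reps <- as.data.frame(do.call(rbind, reps))
  summary <- list(mean = colMeans(reps), sd = vapply(reps, stats::sd, numeric(1)))
  structure(list(reps = reps, summary = summary, lv = lv, plan = plan),
            class = "holdout_result")
}

#' Sweep latent variables and select a PLS1 model
#'
#' Runs repeated holdout validation for every latent-variable count from 1
#' to `lv_max` (capped by the feature count, the effective rank of the
#' scaled feature matrix, and the calibration-half size), reusing the same
#' random splits across the sweep so candidates are compared on identical
#' partitions.  The model minimising the mean validation RMSE is selected;
#' ties go to the smaller latent-variable count.
#'
#' @param X feature matrix (typically 23 columns).
#' @param y response vector for one chemical parameter.
#' @param plan a [holdout_plan()].
#' @param lv_max upper bound of the sweep (default 23).
#' @param scale passed to [fit_pls()].
#' @param parameter optional parameter name carried into the result.
#' @return a `validation_result`: list with the selected `lv`, mean `rc2`,
#'   `rv2`, `rmsec`, `rmsev`, `rpd`, their dispersions, the full `sweep`
#'   table, and the per-repetition metrics at the selected `lv`.
#' @export
select_model <- function(X, y, plan = holdout_plan(), lv_max = 23L,
                         scale = "autoscale", parameter = NA_character_) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  splits <- draw_splits(n, plan)
  n_train <- length(splits[[1]])
  Xs <- scale(X)
  Xs[, apply(X, 2, stats::sd) == 0] <- 0
  rank_x <- qr(Xs)$rank
  max_lv <- min(lv_max, ncol(X), rank_x, n_train - 1L)
  if (max_lv < 1L) stop_olivescan("no feasible latent variable count", "olivescan_plan_error")

  sweep_rows <- vector("list", max_lv)
  results <- vector("list", max_lv)
  for (lv in seq_len(max_lv)) {
    hv <- holdout_validate(X, y, lv, plan, scale = scale, splits = splits)
    results[[lv]] <- hv
    m <- hv$summary$mean
    sweep_rows[[lv]] <- c(lv = lv, m)
  }
  sweep <- as.data.frame(do.call(rbind, sweep_rows))
  best <- which.min(sweep$rmsev) # which.min takes the first (smallest lv) on ties
  hv <- results[[best]]
  m <- hv$summary$mean
  s <- hv$summary$sd
  structure(
    list(parameter = parameter, lv = best,
         rc2 = m[["rc2"]], rv2 = m[["rv2"]],
         rmsec = m[["rmsec"]], rmsev = m[["rmsev"]], rpd = m[["rpd"]],
         rc2_sd = s[["rc2"]], rv2_sd = s[["rv2"]],
         rmsec_sd = s[["rmsec"]], rmsev_sd = s[["rmsev"]], rpd_sd = s[["rpd"]],
         sweep = sweep, reps = hv$reps, plan = plan),
    class = "validation_result"
  )
}

#' @export
print.validation_result <- function(x, ...) {
  cat(sprintf(
    "<validation_result> %s: lv = %d  Rc2 = %.3f  Rv2 = %.3f  RMSEc = %.4g  RMSEv = %.4g  RPD = %.3f\n",
    ifelse(is.na(x$parameter), "(unnamed)", x$parameter),
    x$lv, x$rc2, x$rv2, x$rmsec, x$rmsev, x$rpd))
  invisible(x)
}
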