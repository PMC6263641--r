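# PLS1 regression by NIPALS.  The model decomposes the (autoscaled)
# feature matrix as X = T P' + E and the centred response as y = T q' + f,
# extracting one latent component at a time: the weight vector w maximises
# the covariance between the X-score t = X w and y, then X and y are
# deflated and the next component is extracted.  Regression coefficients
# are folded back to the original units.

#' Fit a PLS1 regression by NIPALS
#'
#' @param X numeric matrix (samples x features), no missing values.
#' @param y numeric response vector.
#' @param lv number of latent variables, `1 <= lv <= min(nrow(X) - 1, ncol(X))`.
#' @param scale `"autoscale"` (centre + unit variance, the chemometric
#'   default) or `"center"` (centre only).
#' @param on_rank_deficit what to do when the residual X (or its covariance
#'   with y) vanishes before `lv` components are extracted: `"error"`
#'   (default) or `"truncate"` (stop early and keep the components found;
#'   the fitted `lv` is then smaller than requested).
#' @param tol convergence tolerance on the weight-vector change; PLS1
#'   converges in a single pass but the guard is kept.
#' @param max_iter inner-iteration cap per component.
#' @return a `pls_model`: scores `T`, loadings `P`, weights `W`,
#'   y-loadings `q`, y-scores `U`, X residual `E`, y residual `f`,
#'   `coefficients` and `intercept` in original units, the
#'   centring/scaling vectors, and `lv`.
#' @export
fit_pls <- function(X, y, lv, scale = c("autoscale", "center"),
                    on_rank_deficit = c("error", "truncate"),
                    tol = 1e-10, max_iter = 500L) {
  scale <- match.arg(scale)
  on_rank_deficit <- match.arg(on_rank_deficit)
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  p <- ncol(X)
  if (anyNA(X) || anyNA(y)) {
    stop_olivescan("X and y must not contain missing values", "olivescan_pls_error")
  }
  if (length(y) != n) stop_olivescan("length(y) must equal nrow(X)", "olivescan_pls_error")
  lv <- as.integer(lv)
  if (lv < 1L || lv > min(n - 1L, p)) {
    stop_olivescan(sprintf("lv must be in [1, %d]", min(n - 1L, p)),
                   "olivescan_pls_error")
  }
  if (stats::sd(y) == 0) {
    stop_olivescan("constant response: nothing to regress on", "olivescan_pls_error")
  }
  x_center <- colMeans(X)
  x_scale <- if (scale == "autoscale") apply(X, 2, stats::sd) else rep(1, p)
  if (all(x_scale == 0)) {
    stop_olivescan("all X columns are constant", "olivescan_pls_error")
  }
  x_scale[x_scale == 0] <- 1 # constant columns stay centred at zero
  Xs <- sweep(sweep(X, 2, x_center), 2, x_scale, "/")
  y_center <- mean(y)
  ys <- y - y_center

  Tm <- matrix(0, n, lv)
  U <- matrix(0, n, lv)
  Pm <- matrix(0, p, lv)
  W <- matrix(0, p, lv)
  q <- numeric(lv)
  Xd <- Xs
  yd <- ys
  a_done <- 0L
  for (a in seq_len(lv)) {
    w <- drop(crossprod(Xd, yd))
    wn <- sqrt(sum(w^2))
    if (wn < 1e-12 || sum(Xd^2) < 1e-24) {
      if (on_rank_deficit == "error") {
        stop_olivescan(sprintf(
          "rank deficit: only %d latent variables are extractable", a - 1L),
          "olivescan_rank_error")
      }
      break
    }
    w <- w / wn
    w_old <- w
    for (it in seq_len(max_iter)) {
      t_sc <- drop(Xd %*% w)
      qa <- sum(yd * t_sc) / sum(t_sc^2)
      u_sc <- yd * qa # PLS1 y-score direction
      w_new <- drop(crossprod(Xd, yd))
      w_new <- w_new / sqrt(sum(w_new^2))
      if (sqrt(sum((w_new - w_old)^2)) < tol) {
        w <- w_new
        break
      }
      w_old <- w_new
      w <- w_new
    }
    t_sc <- drop(Xd %*% w)
    tt <- sum(t_sc^2)
    p_load <- drop(crossprod(Xd, t_sc)) / tt
    qa <- sum(yd * t_sc) / tt
    Tm[, a] <- t_sc
    W[, a] <- w
    Pm[, a] <- p_load
    q[a] <- qa
    U[, a] <- yd * qa
    Xd <- Xd - tcrossprod(t_sc, p_load)
    yd <- yd - qa * t_sc
    a_done <- a
  }
  if (a_done == 0L) {
    stop_olivescan("no latent variable could be extracted", "olivescan_rank_error")
  }
  keep <- seq_len(a_done)
  Tm <- Tm[, keep, drop = FALSE]
  U <- U[, keep, drop = FALSE]
  Pm <- Pm[, keep, drop = FALSE]
  W <- W[, keep, drop = FALSE]
  q <- q[keep]

  # coefficients on the processed scale, then in original units
  b_proc <- drop(W %*% solve(crossprod(Pm, W), q))
  coefficients <- b_proc / x_scale
  intercept <- y_center - sum(x_center * coefficients)

  structure(
    list(T = Tm, U = U, P = Pm, W = W, q = q, E = Xd, f = yd,
         lv = a_done, lv_requested = lv,
         coefficients = coefficients, intercept = intercept,
         x_center = x_center, x_scale = x_scale, y_center = y_center,
         scale = scale),
    class = "pls_model"
  )
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model> %d latent variable(s), %d features, %d samples\n",
              x$lv, nrow(x$P), nrow(x$T)))
  invisible(x)
}

#' Predict from a fitted PLS1 model
#'
#' @param object a `pls_model`.
#' @param newdata matrix with the same columns as the training features.
#' @param ... unused.
#' @return numeric predictions in original response units.
#' @export
predict.pls_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$coefficients)) {
    stop_olivescan(sprintf("newdata has %d columns, model expects %d",
                           ncol(newdata), length(object$coefficients)),
                   "olivescan_pls_error")
  }
  drop(newdata %*% object$coefficients) + object$intercept
}
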