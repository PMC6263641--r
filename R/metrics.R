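# Calibration-quality metrics: root mean square error, coefficient of
# determination, and the ratio of performance to deviation.

#' Root mean square error
#'
#' `sqrt(mean((y - y_hat)^2))`.
#'
#' @param y reference values.
#' @param y_hat predicted values, same length.
#' @return non-negative numeric.
#' @export
rmse <- function(y, y_hat) {
  if (length(y) != length(y_hat)) {
    stop_olivescan("y and y_hat lengths differ", "olivescan_metric_error")
  }
  if (length(y) < 1L) stop_olivescan("need at least one value", "olivescan_metric_error")
  sqrt(mean((y - y_hat)^2))
}

#' Coefficient of determination
#'
#' `1 - SS_res / SS_tot` about the mean of the reference values; can be
#' negative when predictions are worse than the mean predictor.
#'
#' @inheritParams rmse
#' @return numeric (at most 1, unbounded below).
#' @export
r_squared <- function(y, y_hat) {
  if (length(y) != length(y_hat)) {
    stop_olivescan("y and y_hat lengths differ", "olivescan_metric_error")
  }
  if (length(y) < 2L) stop_olivescan("need at least two values", "olivescan_metric_error")
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) {
    stop_olivescan("constant reference values: R^2 undefined", "olivescan_metric_error")
  }
  1 - sum((y - y_hat)^2) / ss_tot
}

#' Ratio of performance to deviation
#'
#' Sample standard deviation of the reference values (divisor `n - 1`)
#' divided by the prediction RMSE.  Dimensionless; values above ~2 indicate
#' a model usable for screening.
#'
#' @param y reference values (`n >= 2`).
#' @param rmse_value positive RMSE of the predictions on `y`.
#' @return positive numeric.
#' @export
rpd <- function(y, rmse_value) {
  if (length(y) < 2L) stop_olivescan("need at least two values", "olivescan_metric_error")
  if (!is.numeric(rmse_value) || length(rmse_value) != 1L || rmse_value <= 0) {
    stop_olivescan("rmse_value must be a single positive number (RPD is infinite at 0)",
                   "olivescan_metric_error")
  }
  stats::sd(y) / rmse_value
}
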