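# Error-metric suite for VA prediction: MSE, RMSE, MAE, R^2, maximum and
# minimum absolute error, mode (on the 0.02 logMAR letter grid) and median,
# with an optional one-pass 3-sigma outlier drop.

#' Mode of absolute errors on the letter-scoring grid
#'
#' Errors are rounded to the nearest multiple of `grid` (0.02 logMAR, the
#' letter quantum of the chart) and the most frequent value is returned;
#' ties are broken toward the smallest error.
#'
#' @param e Absolute errors.
#' @param grid Quantization step (default 0.02).
#' @return Modal error value.
#' @export
error_mode <- function(e, grid = 0.02) {
  g <- round(e / grid) * grid
  tab <- table(g)
  vals <- as.numeric(names(tab))
  vals[tab == max(tab)][1]  # names(table) sorted ascending -> smallest wins ties
}

#' One-pass 3-sigma outlier rule
#'
#' Retains errors `e <= 3 * sd(e)` (standard deviation of the error sample
#' itself, computed once). A zero-spread sample removes nothing.
#'
#' @param errors Absolute errors (length >= 2).
#' @return List with logical `mask` (TRUE = retained), `n_removed` and
#'   `pct_removed` (percent of the sample).
#' @export
remove_outliers_3sigma <- function(errors) {
  if (length(errors) < 2) stop("need at least 2 errors")
  s <- stats::sd(errors)
  mask <- if (s == 0) rep(TRUE, length(errors)) else errors <= 3 * s
  list(mask = mask, n_removed = sum(!mask),
       pct_removed = 100 * sum(!mask) / length(errors))
}

#' Evaluate VA predictions
#'
#' Computes the metric suite on absolute errors `|y - yhat|`. With
#' `outlier_policy = "drop3sigma"`, rows whose error exceeds three standard
#' deviations of the error sample are removed first (one pass) and both
#' sample sizes are reported.
#'
#' @param y Observed values (logMAR).
#' @param yhat Predicted values.
#' @param outlier_policy `"none"` (default) or `"drop3sigma"`.
#' @return Object of class `metrics_report`: list with `mse`, `rmse`,
#'   `mae`, `r2`, `max_e`, `min_e`, `mode_e`, `median_e`, `n`, `n_used`,
#'   `pct_removed`, `outlier_policy`.
#' @export
evaluate <- function(y, yhat, outlier_policy = c("none", "drop3sigma")) {
  outlier_policy <- match.arg(outlier_policy)
  if (length(y) != length(yhat) || length(y) < 1)
    stop("y and yhat must have equal length >= 1")
  e <- abs(y - yhat)
  n <- length(e)
  pct_removed <- 0
  if (outlier_policy == "drop3sigma" && n >= 2) {
    o <- remove_outliers_3sigma(e)
    pct_removed <- o$pct_removed
    y <- y[o$mask]; yhat <- yhat[o$mask]; e <- e[o$mask]
  }
  mse <- mean((y - yhat)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) {
    warning("zero-variance response; R^2 undefined")
    NaN
  } else 1 - sum((y - yhat)^2) / ss_tot
  structure(list(mse = mse, rmse = sqrt(mse), mae = mean(e), r2 = r2,
                 max_e = max(e), min_e = min(e), mode_e = error_mode(e),
                 median_e = stats::median(e), n = n, n_used = length(e),
                 pct_removed = pct_removed, outlier_policy = outlier_policy),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(paste0("<metrics_report> n = %d (used %d, policy %s)\n",
                     "  MSE %.4f  RMSE %.4f  MAE %.4f  R2 %.4f\n",
                     "  MaxE %.4f  MinE %.4f  Mode %.4f  Median %.4f\n"),
              x$n, x$n_used, x$outlier_policy, x$mse, x$rmse, x$mae, x$r2,
              x$max_e, x$min_e, x$mode_e, x$median_e))
  invisible(x)
}

#' @export
as.data.frame.metrics_report <- function(x, ...) {
  data.frame(mse = x$mse, rmse = x$rmse, mae = x$mae, r2 = x$r2,
             max_e = x$max_e, min_e = x$min_e, mode_e = x$mode_e,
             median_e = x$median_e, n = x$n, n_used = x$n_used,
             pct_removed = x$pct_removed, outlier_policy = x$outlier_policy)
}

#' Percent change between two metric values
#'
#' Convenience for reporting, e.g., the MSE increase when a predictor is
#' removed from a model.
#'
#' @param from Reference value.
#' @param to New value.
#' @return Percent change `100 * (to - from) / from`.
#' @export
percent_change <- function(from, to) 100 * (to - from) / from
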