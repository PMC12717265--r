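# Thin adapter around the xgboost booster exposing the same
# predict / feature-importance contract as the from-scratch LSBoost.

#' Fit an XGBoost regression model (adapter)
#'
#' Wraps `xgboost` with squared-error loss and hyperparameters mirroring
#' the LSBoost defaults (`eta = 0.1`, `max_depth = 4`, 300 rounds,
#' exact splits, single thread for determinism). Requires the `xgboost`
#' package; a clear error is raised when it is unavailable.
#'
#' @param X Numeric feature matrix.
#' @param y Numeric response.
#' @param nrounds Boosting rounds.
#' @param eta Shrinkage.
#' @param max_depth Tree depth.
#' @param params Extra parameters passed through to the booster.
#' @param seed Integer seed.
#' @return Object of class `xgb_va_model`.
#' @export
fit_xgboost <- function(X, y, nrounds = 300, eta = 0.1, max_depth = 4,
                        params = list(), seed = 1) {
  if (!requireNamespace("xgboost", quietly = TRUE))
    stop("the external booster is unavailable: install the 'xgboost' package ",
         "or use fit_lsboost()")
  X <- as.matrix(X)
  set.seed(seed)
  p <- utils::modifyList(list(objective = "reg:squarederror", eta = eta,
                              max_depth = max_depth, nthread = 1,
                              tree_method = "exact", seed = seed), params)
  booster <- xgboost::xgb.train(params = p,
                                data = xgboost::xgb.DMatrix(X, label = y),
                                nrounds = nrounds, verbose = 0)
  structure(list(booster = booster, p = ncol(X),
                 features = colnames(X) %||% paste0("x", seq_len(ncol(X))),
                 hyper = list(nrounds = nrounds, eta = eta,
                              max_depth = max_depth, seed = seed)),
            class = "xgb_va_model")
}

#' @export
predict.xgb_va_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (ncol(X) != object$p) stop("feature count differs from training")
  as.numeric(stats::predict(object$booster, xgboost::xgb.DMatrix(X)))
}

#' @export
feature_importance.xgb_va_model <- function(model) {
  imp <- xgboost::xgb.importance(model = model$booster)
  out <- stats::setNames(numeric(model$p), model$features)
  out[imp$Feature] <- imp$Gain
  if (sum(out) > 0) out / sum(out) else out
}

#' @export
print.xgb_va_model <- function(x, ...) {
  cat(sprintf("<xgb_va_model> %d rounds, eta = %g, depth <= %d\n",
              x$hyper$nrounds, x$hyper$eta, x$hyper$max_depth))
  invisible(x)
}
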