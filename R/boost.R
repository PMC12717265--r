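# CART-style regression trees (greedy variance-reduction splitting) and
# least-squares gradient boosting (LSBoost): stagewise fitting of trees to
# residuals under squared loss with shrinkage. Implemented from scratch;
# an external booster adapter with the same contract lives in xgb.R.

# Best axis-aligned split of rows `idx`: exhaustive over features and
# thresholds via cumulative sums on the sorted responses. Ties broken to
# the lowest feature index, then the smallest threshold.
best_split <- function(X, y, idx, min_leaf) {
  n <- length(idx)
  if (n < 2 * min_leaf) return(NULL)
  ysub <- y[idx]
  sse_parent <- sum(ysub^2) - sum(ysub)^2 / n
  best <- NULL
  for (j in seq_len(ncol(X))) {
    x <- X[idx, j]
    o <- order(x)
    xo <- x[o]; yo <- ysub[o]
    csy <- cumsum(yo); csy2 <- cumsum(yo^2)
    i <- seq_len(n - 1)
    ok <- i >= min_leaf & (n - i) >= min_leaf & xo[i] < xo[i + 1]
    if (!any(ok)) next
    sse_l <- csy2[i] - csy[i]^2 / i
    sse_r <- (csy2[n] - csy2[i]) - (csy[n] - csy[i])^2 / (n - i)
    gain <- sse_parent - sse_l - sse_r
    gain[!ok] <- -Inf
    b <- which.max(gain)
    if (gain[b] > 1e-12 && (is.null(best) || gain[b] > best$gain + 1e-12)) {
      best <- list(feature = j, threshold = (xo[b] + xo[b + 1]) / 2,
                   gain = gain[b], left = idx[o[1:b]], right = idx[o[(b + 1):n]])
    }
  }
  best
}

grow_node <- function(X, y, idx, depth, max_depth, min_leaf) {
  leaf <- list(leaf = TRUE, value = mean(y[idx]), n = length(idx))
  if (depth >= max_depth || length(idx) < 2 * min_leaf ||
      stats::var(y[idx]) == 0) return(leaf)
  s <- best_split(X, y, idx, min_leaf)
  if (is.null(s)) return(leaf)
  list(leaf = FALSE, feature = s$feature, threshold = s$threshold,
       gain = s$gain, n = length(idx),
       left = grow_node(X, y, s$left, depth + 1, max_depth, min_leaf),
       right = grow_node(X, y, s$right, depth + 1, max_depth, min_leaf))
}

#' Fit a CART regression tree
#'
#' Greedy binary splitting minimizing within-node squared error; leaves
#' predict the mean of their training responses. Splitting stops at
#' `max_depth`, when a child would fall below `min_leaf` rows, or when no
#' split reduces the squared error.
#'
#' @param X Numeric feature matrix (rows = observations).
#' @param y Numeric response.
#' @param max_depth Maximum tree depth (root = depth 0).
#' @param min_leaf Minimum rows per leaf.
#' @return Object of class `regression_tree`.
#' @export
fit_tree <- function(X, y, max_depth = 4, min_leaf = 5) {
  X <- as.matrix(X)
  if (nrow(X) != length(y) || length(y) < 1) stop("X rows must match length(y) >= 1")
  root <- grow_node(X, y, seq_along(y), 0, max_depth, min_leaf)
  structure(list(root = root, p = ncol(X),
                 features = colnames(X)), class = "regression_tree")
}

predict_node <- function(node, X, idx, out) {
  if (node$leaf) { out[idx] <- node$value; return(out) }
  go_left <- X[idx, node$feature] <= node$threshold
  out <- predict_node(node$left, X, idx[go_left], out)
  predict_node(node$right, X, idx[!go_left], out)
}

#' @export
predict.regression_tree <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (ncol(X) != object$p) stop("feature count differs from training")
  predict_node(object$root, X, seq_len(nrow(X)), numeric(nrow(X)))
}

#' Fit a least-squares boosting ensemble (LSBoost)
#'
#' Stagewise gradient boosting under squared loss: the model starts at the
#' response mean and each stage fits a regression tree to the current
#' residuals, added with shrinkage `nu`. Training MSE is non-increasing in
#' the stage count.
#'
#' @param X Numeric feature matrix.
#' @param y Numeric response (logMAR VA in this package's use).
#' @param n_stages Number of boosting stages (default 300).
#' @param nu Shrinkage (learning rate) in (0, 1] (default 0.1).
#' @param max_depth,min_leaf Tree controls, see [fit_tree()].
#' @param seed Recorded in the fit metadata (the fit itself is
#'   deterministic: greedy splitting, no subsampling).
#' @return Object of class `lsboost` with fields `f0`, `trees`, `nu`,
#'   `train_mse` (per-stage trajectory) and metadata.
#' @export
fit_lsboost <- function(X, y, n_stages = 300, nu = 0.1, max_depth = 4,
                        min_leaf = 5, seed = NULL) {
  X <- as.matrix(X)
  if (n_stages < 0) stop("n_stages must be >= 0")
  if (nu <= 0 || nu > 1) stop("nu must lie in (0, 1]")
  f0 <- mean(y)
  fit <- rep(f0, length(y))
  trees <- vector("list", n_stages)
  train_mse <- numeric(n_stages)
  for (m in seq_len(n_stages)) {
    tr <- fit_tree(X, y - fit, max_depth, min_leaf)
    fit <- fit + nu * predict(tr, X)
    trees[[m]] <- tr
    train_mse[m] <- mean((y - fit)^2)
  }
  structure(list(f0 = f0, trees = trees, nu = nu, train_mse = train_mse,
                 p = ncol(X), features = colnames(X),
                 hyper = list(n_stages = n_stages, nu = nu,
                              max_depth = max_depth, min_leaf = min_leaf,
                              seed = seed)),
            class = "lsboost")
}

#' @export
predict.lsboost <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (ncol(X) != object$p) stop("feature count differs from training")
  out <- rep(object$f0, nrow(X))
  for (tr in object$trees) out <- out + object$nu * predict(tr, X)
  out
}

#' @export
print.lsboost <- function(x, ...) {
  cat(sprintf("<lsboost> %d stages, nu = %g, depth <= %d, F0 = %.4f\n",
              length(x$trees), x$nu, x$hyper$max_depth, x$f0))
  if (length(x$train_mse)) cat(sprintf("  final training MSE: %.6f\n",
                                       utils::tail(x$train_mse, 1)))
  invisible(x)
}

collect_gains <- function(node, acc) {
  if (node$leaf) return(acc)
  acc[node$feature] <- acc[node$feature] + node$gain
  acc <- collect_gains(node$left, acc)
  collect_gains(node$right, acc)
}

#' Split-gain feature importance
#'
#' Total squared-error reduction attributed to each feature across all
#' splits of all stages, normalized to sum to 1 (all zeros when no split
#' exists).
#'
#' @param model A fitted [fit_lsboost()], [fit_tree()] or [fit_xgboost()]
#'   model.
#' @return Named numeric vector of importances.
#' @export
feature_importance <- function(model) UseMethod("feature_importance")

#' @export
feature_importance.regression_tree <- function(model) {
  g <- collect_gains(model$root, numeric(model$p))
  names(g) <- model$features %||% paste0("x", seq_len(model$p))
  if (sum(g) > 0) g / sum(g) else g
}

#' @export
feature_importance.lsboost <- function(model) {
  g <- numeric(model$p)
  for (tr in model$trees) g <- g + collect_gains(tr$root, numeric(model$p))
  names(g) <- model$features %||% paste0("x", seq_len(model$p))
  if (sum(g) > 0) g / sum(g) else g
}

`%||%` <- function(a, b) if (is.null(a)) b else a
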