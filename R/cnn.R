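# Small convolutional recognizer, implemented directly on matrix algebra:
# input (side x side, grayscale) -> 3x3 convolution with 8 filters (valid
# padding) -> batch normalization -> ReLU -> 2x2 max pooling (stride 2) ->
# fully connected layer with 2 outputs -> softmax, trained with Adam on
# categorical cross-entropy.

#' Recognizer configuration
#'
#' Defaults follow the stated training recipe: Adam, batches of 32, 10
#' epochs, 70/15/15 train/validation/test split. Learning rate and
#' initialization are not pinned by that recipe; the defaults (Adam 1e-3,
#' seeded He-style initialization) are recorded in the training report.
#'
#' @param input_side Input image side in pixels (default 224).
#' @param filters Convolution filters (default 8, kernel 3x3).
#' @param lr Adam learning rate.
#' @param batch_size Mini-batch size.
#' @param epochs Training epochs.
#' @param split Train/validation/test fractions (used when no split is
#'   supplied to [train_recognizer()]).
#' @param seed Integer seed for initialization and shuffling.
#' @return Configuration list of class `recognizer_config`.
#' @export
recognizer_config <- function(input_side = 224, filters = 8, lr = 1e-3,
                              batch_size = 32, epochs = 10,
                              split = c(train = 0.70, validation = 0.15, test = 0.15),
                              seed = 1) {
  structure(list(input_side = input_side, filters = filters, lr = lr,
                 batch_size = batch_size, epochs = epochs, split = split,
                 seed = seed), class = "recognizer_config")
}

# im2col gather indices for valid 3x3 patches of a side x side image
conv_index <- function(side) {
  out_side <- side - 2L
  base <- outer(seq_len(out_side), (seq_len(out_side) - 1L) * side, "+")
  offs <- as.integer(outer(0:2, (0:2) * side, "+"))
  idx <- matrix(0L, out_side^2, 9L)
  for (k in 1:9) idx[, k] <- as.integer(base) + offs[k]
  idx
}

adam_new <- function(dim) list(m = array(0, dim), v = array(0, dim))
adam_step <- function(par, grad, st, lr, t, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  st$m <- b1 * st$m + (1 - b1) * grad
  st$v <- b2 * st$v + (1 - b2) * grad^2
  mhat <- st$m / (1 - b1^t); vhat <- st$v / (1 - b2^t)
  list(par = par - lr * mhat / (sqrt(vhat) + eps), st = st)
}

pool_pairs <- function(out_side) seq(1L, 2L * out_side - 1L, by = 2L)

as_pixel_matrix <- function(x, side) {
  m <- if (inherits(x, "optotype_image")) x$pixels else x
  if (!is.matrix(m) || nrow(m) != side || ncol(m) != side)
    stop(sprintf("image must be a %d x %d matrix", side, side))
  m
}

# forward pass for one image; returns pooled feature vector and, when
# train = TRUE, the intermediates needed for backpropagation
cnn_forward_one <- function(px, net, mu, va, train = FALSE) {
  idx <- net$idx
  xcol <- matrix(px[idx], ncol = 9L)
  conv <- xcol %*% net$W1 + rep(net$b1, each = nrow(xcol))
  xhat <- sweep(sweep(conv, 2, mu), 2, sqrt(va + 1e-5), "/")
  act <- sweep(sweep(xhat, 2, net$gamma, "*"), 2, net$beta, "+")
  act[act < 0] <- 0
  cs <- net$conv_side; ps <- cs %/% 2L; s1 <- pool_pairs(ps)
  A <- array(act, c(cs, cs, net$filters))
  a1 <- A[s1, s1, , drop = FALSE];     a2 <- A[s1 + 1L, s1, , drop = FALSE]
  a3 <- A[s1, s1 + 1L, , drop = FALSE]; a4 <- A[s1 + 1L, s1 + 1L, , drop = FALSE]
  pooled <- pmax(a1, a2, a3, a4)
  if (!train) return(list(p = as.numeric(pooled)))
  list(p = as.numeric(pooled), xcol = xcol, conv = conv, xhat = xhat,
       act = act, pooled = pooled, a = list(a1, a2, a3, a4))
}

cnn_logits <- function(P, net) {
  sweep(P %*% net$W2, 2, net$b2, "+")
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# inference-mode forward for a stack of images; returns class probabilities
cnn_predict_prob <- function(net, images) {
  P <- t(vapply(images,
                function(px) cnn_forward_one(px, net, net$run_mu, net$run_va)$p,
                numeric(net$fc_in)))
  softmax_rows(cnn_logits(P, net))
}

#' Train the convolutional recognizer
#'
#' @param images List of square grayscale matrices (or
#'   [optotype_image()]s) on `[0, 1]`, all of side `config$input_side`.
#' @param labels 0/1 vector (1 = recognized).
#' @param config A [recognizer_config()].
#' @param split Optional character vector (`"train"`, `"validation"`,
#'   `"test"`) per image; when `NULL` a seeded random split with the
#'   configured fractions is drawn.
#' @return Object of class `cnn_recognizer` with the learned parameters,
#'   batch-norm running statistics and a `report` (per-epoch training loss
#'   and validation accuracy, plus the recorded hyperparameters).
#' @export
train_recognizer <- function(images, labels, config = recognizer_config(),
                             split = NULL) {
  side <- config$input_side
  images <- lapply(images, as_pixel_matrix, side = side)
  y <- as.integer(as.logical(labels))
  if (length(images) != length(y)) stop("images and labels differ in length")
  set.seed(config$seed)
  if (is.null(split)) {
    n <- length(images)
    counts <- floor(config$split * n)
    counts[1] <- n - sum(counts[-1])
    split <- sample(rep(names(config$split), counts))
  }
  tr <- which(split == "train"); va_ix <- which(split == "validation")
  if (length(tr) == 0) stop("empty training split")
  if (length(unique(y[tr])) < 2)
    warning("single-class training set: the classifier degenerates to the majority class")

  nf <- config$filters
  cs <- side - 2L
  ps <- cs %/% 2L
  fc_in <- ps^2 * nf
  net <- list(W1 = matrix(stats::rnorm(9 * nf, 0, sqrt(2 / 9)), 9, nf),
              b1 = numeric(nf), gamma = rep(1, nf), beta = numeric(nf),
              W2 = matrix(stats::rnorm(fc_in * 2, 0, sqrt(2 / fc_in)), fc_in, 2),
              b2 = numeric(2),
              run_mu = numeric(nf), run_va = rep(1, nf),
              idx = conv_index(side), conv_side = cs, filters = nf,
              fc_in = fc_in, input_side = side)
  opt <- list(W1 = adam_new(dim(net$W1)), b1 = adam_new(nf),
              gamma = adam_new(nf), beta = adam_new(nf),
              W2 = adam_new(dim(net$W2)), b2 = adam_new(2))
  t_step <- 0
  momentum <- 0.9
  bn_seen <- FALSE
  epoch_loss <- numeric(config$epochs)
  val_acc <- rep(NA_real_, config$epochs)

  for (ep in seq_len(config$epochs)) {
    ord <- sample(tr)
    losses <- c()
    for (b0 in seq(1, length(ord), by = config$batch_size)) {
      bi <- ord[b0:min(b0 + config$batch_size - 1, length(ord))]
      B <- length(bi)
      # first conv pass to get batch statistics
      convs <- lapply(images[bi], function(px) {
        xcol <- matrix(px[net$idx], ncol = 9L)
        list(xcol = xcol, conv = xcol %*% net$W1 + rep(net$b1, each = nrow(xcol)))
      })
      allc <- do.call(rbind, lapply(convs, `[[`, "conv"))
      mu <- colMeans(allc)
      va <- colMeans(sweep(allc, 2, mu)^2)
      if (!bn_seen) {  # seed running stats from the first batch
        net$run_mu <- mu; net$run_va <- va; bn_seen <- TRUE
      } else {
        net$run_mu <- momentum * net$run_mu + (1 - momentum) * mu
        net$run_va <- momentum * net$run_va + (1 - momentum) * va
      }
      fwd <- lapply(seq_len(B), function(k) {
        f <- cnn_forward_one(images[[bi[k]]], net, mu, va, train = TRUE)
        f$xcol <- convs[[k]]$xcol; f$conv <- convs[[k]]$conv
        f
      })
      P <- t(vapply(fwd, `[[`, numeric(fc_in), "p"))
      probs <- softmax_rows(cnn_logits(P, net))
      Y <- cbind(1 - y[bi], y[bi])
      losses <- c(losses, -mean(log(pmax(probs[cbind(seq_len(B), y[bi] + 1L)], 1e-12))))

      # backward
      dZ <- (probs - Y) / B
      gW2 <- crossprod(P, dZ)
      gb2 <- colSums(dZ)
      dP <- dZ %*% t(net$W2)
      sd_b <- sqrt(va + 1e-5)
      M <- B * cs^2
      gW1 <- matrix(0, 9, nf); gb1 <- numeric(nf)
      ggamma <- numeric(nf); gbeta <- numeric(nf)
      # accumulate batch-norm sufficient statistics across images
      dxhat_list <- vector("list", B)
      s1 <- pool_pairs(ps)
      for (k in seq_len(B)) {
        f <- fwd[[k]]
        dpool <- array(dP[k, ], c(ps, ps, nf))
        dact <- array(0, c(cs, cs, nf))
        m <- f$pooled
        taken <- array(FALSE, dim(m))
        offs <- list(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L))
        for (q in 1:4) {
          sel <- (f$a[[q]] == m) & !taken
          taken <- taken | sel
          tmp <- array(0, dim(m)); tmp[sel] <- dpool[sel]
          dact[s1 + offs[[q]][1], s1 + offs[[q]][2], ] <-
            dact[s1 + offs[[q]][1], s1 + offs[[q]][2], ] + tmp
        }
        dact <- matrix(dact, ncol = nf)
        dact[f$act <= 0] <- 0            # ReLU gate (act stored post-ReLU)
        ggamma <- ggamma + colSums(dact * f$xhat)
        gbeta <- gbeta + colSums(dact)
        dxhat_list[[k]] <- sweep(dact, 2, net$gamma, "*")
      }
      sum_dxhat <- Reduce(`+`, lapply(dxhat_list, colSums))
      sum_dxhat_xhat <- Reduce(`+`, lapply(seq_len(B), function(k)
        colSums(dxhat_list[[k]] * fwd[[k]]$xhat)))
      for (k in seq_len(B)) {
        f <- fwd[[k]]
        dconv <- sweep(dxhat_list[[k]], 2, sd_b, "/") -
          matrix(sum_dxhat / (M * sd_b), cs^2, nf, byrow = TRUE) -
          sweep(f$xhat, 2, sum_dxhat_xhat / (M * sd_b), "*")
        gW1 <- gW1 + crossprod(f$xcol, dconv)
        gb1 <- gb1 + colSums(dconv)
      }

      t_step <- t_step + 1
      for (nm in c("W1", "b1", "gamma", "beta", "W2", "b2")) {
        g <- switch(nm, W1 = gW1, b1 = gb1, gamma = ggamma, beta = gbeta,
                    W2 = gW2, b2 = gb2)
        upd <- adam_step(net[[nm]], g, opt[[nm]], config$lr, t_step)
        net[[nm]] <- upd$par; opt[[nm]] <- upd$st
      }
    }
    epoch_loss[ep] <- mean(losses)
    if (length(va_ix)) {
      pr <- cnn_predict_prob(net, images[va_ix])
      val_acc[ep] <- mean((pr[, 2] > 0.5) == (y[va_ix] == 1))
    }
  }
  structure(list(net = net,
                 report = list(epoch_loss = epoch_loss,
                               val_accuracy = val_acc,
                               hyper = list(lr = config$lr,
                                            batch_size = config$batch_size,
                                            epochs = config$epochs,
                                            filters = config$filters,
                                            init = "He, seeded",
                                            seed = config$seed),
                               split_sizes = table(split)),
                 config = config),
            class = "cnn_recognizer")
}

#' Classify an optotype image
#'
#' Softmax probabilities over (unrecognized, recognized); the label is the
#' argmax with ties (probability exactly 0.5) resolved to unrecognized,
#' the protocol-safe choice.
#'
#' @param model A trained [train_recognizer()] model.
#' @param img An [optotype_image()] or matrix of the trained input size.
#' @return List with `label` (`"recognized"`/`"unrecognized"`),
#'   `recognized` (logical) and the `probabilities` vector.
#' @export
classify <- function(model, img) {
  stopifnot(inherits(model, "cnn_recognizer"))
  px <- as_pixel_matrix(img, model$net$input_side)
  pr <- cnn_predict_prob(model$net, list(px))[1, ]
  rec <- pr[2] > 0.5
  list(label = if (rec) "recognized" else "unrecognized",
       recognized = rec,
       probabilities = stats::setNames(pr, c("unrecognized", "recognized")))
}

#' @export
print.cnn_recognizer <- function(x, ...) {
  r <- x$report
  cat(sprintf("<cnn_recognizer> %dx%d input, %d filters; %d epochs\n",
              x$net$input_side, x$net$input_side, x$net$filters,
              length(r$epoch_loss)))
  cat(sprintf("  final training loss %.4f; validation accuracy %s\n",
              utils::tail(r$epoch_loss, 1),
              ifelse(is.na(utils::tail(r$val_accuracy, 1)), "n/a",
                     sprintf("%.1f%%", 100 * utils::tail(r$val_accuracy, 1)))))
  invisible(x)
}
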