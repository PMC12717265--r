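# Shared fixtures: a small, fast simulation configuration, the separable
# recognizer fixture, and a brute-force greedy split oracle for trees.

# Small canvas/pupil geometry for pipeline tests (letters at <= 0.6 logMAR
# fit a 64 px canvas at 64 px/degree).
small_config <- function(...) {
  defaults <- list(canvas_px = 64, ppd = 64, pupil_n = 64, pad_factor = 4,
                   noise_variance = 0, retina_spd = NULL)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# Linearly separable recognition fixture: sharp letters are recognizable,
# heavily low-pass-blurred ones are not.
separable_fixture <- function(n = 200, seed = 42, side = 224) {
  set.seed(seed)
  ppd <- side
  imgs <- vector("list", n)
  labs <- integer(n)
  for (i in seq_len(n)) {
    im <- render_sloan(sample(sloan_letters, 1), stats::runif(1, 0.3, 0.8),
                       ppd = ppd, canvas_px = side)
    if (i %% 2 == 0) {
      im <- suppressWarnings(retinal_sampling(im, samples_per_degree = 6))
      labs[i] <- 0L
    } else labs[i] <- 1L
    imgs[[i]] <- add_gaussian_noise(im, 0.01)$pixels
  }
  list(images = imgs, labels = labs)
}

# Greedy recursive split search evaluating every (feature, threshold)
# candidate by direct SSE computation; returns the total training SSE.
greedy_oracle_sse <- function(X, y, max_depth, min_leaf) {
  sse <- function(v) if (length(v) == 0) 0 else sum((v - mean(v))^2)
  rec <- function(idx, depth) {
    base <- sse(y[idx])
    if (depth >= max_depth || length(idx) < 2 * min_leaf) return(base)
    best <- NULL
    best_sse <- base
    for (j in seq_len(ncol(X))) for (th in sort(unique(X[idx, j]))) {
      l <- idx[X[idx, j] <= th]
      r <- idx[X[idx, j] > th]
      if (length(l) < min_leaf || length(r) < min_leaf) next
      s <- sse(y[l]) + sse(y[r])
      if (s < best_sse - 1e-12) { best_sse <- s; best <- list(l = l, r = r) }
    }
    if (is.null(best)) return(base)
    rec(best$l, depth + 1) + rec(best$r, depth + 1)
  }
  rec(seq_along(y), 0)
}

# bounding-box extent of ink (intensity < 0.5) in an optotype image
ink_bbox <- function(img) {
  m <- img$pixels < 0.5
  rows <- which(apply(m, 1, any))
  cols <- which(apply(m, 2, any))
  c(height = diff(range(rows)) + 1L, width = diff(range(cols)) + 1L)
}
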