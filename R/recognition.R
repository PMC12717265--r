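# Recognized/unrecognized classification of aberrated optotypes: a
# training-free template-correlation observer, plus confusion-matrix
# bookkeeping with axis-explicit metric names (the small convolutional
# recognizer lives in cnn.R).

#' Construct a 2x2 recognition confusion matrix
#'
#' Rows are the classifier's output class, columns the target class, in the
#' order unrecognized, recognized.
#'
#' @param pred_unrec_tgt_unrec,pred_unrec_tgt_rec,pred_rec_tgt_unrec,pred_rec_tgt_rec
#'   Cell counts.
#' @return Integer matrix of class `confusion_matrix`.
#' @export
confusion_matrix <- function(pred_unrec_tgt_unrec, pred_unrec_tgt_rec,
                             pred_rec_tgt_unrec, pred_rec_tgt_rec) {
  counts <- c(pred_unrec_tgt_unrec, pred_unrec_tgt_rec,
              pred_rec_tgt_unrec, pred_rec_tgt_rec)
  if (any(counts < 0) || sum(counts) == 0) stop("counts must be >= 0 with a positive total")
  m <- matrix(counts, 2, 2, byrow = TRUE,
              dimnames = list(predicted = c("unrecognized", "recognized"),
                              target = c("unrecognized", "recognized")))
  structure(m, class = c("confusion_matrix", "matrix"))
}

#' Tabulate a confusion matrix from labels
#'
#' @param predicted,target Vectors coercible to 0/1 (1 = recognized).
#' @return A [confusion_matrix()].
#' @export
tabulate_confusion <- function(predicted, target) {
  p <- as.integer(as.logical(predicted)); t <- as.integer(as.logical(target))
  confusion_matrix(sum(p == 0 & t == 0), sum(p == 0 & t == 1),
                   sum(p == 1 & t == 0), sum(p == 1 & t == 1))
}

#' Confusion-matrix performance metrics
#'
#' Axis-explicit fractions: `row_fraction[k]` is the share of outputs of
#' class k that are correct (diagonal over row total; the positive-class
#' row fraction is often reported as sensitivity/recall of a recognizer and
#' the negative-class one as specificity), `column_fraction[k]` the share
#' of targets of class k retrieved (diagonal over column total, often
#' labelled precision per class), and `accuracy` the trace over the total.
#' Empty rows or columns yield `NaN` with a warning.
#'
#' @param cm A [confusion_matrix()].
#' @return List of class `confusion_metrics` with `row_fraction` (length
#'   2, named), `column_fraction` (length 2, named) and `accuracy`.
#' @export
confusion_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  rs <- rowSums(cm); cs <- colSums(cm)
  if (any(rs == 0) || any(cs == 0)) warning("empty row/column: some metrics are NaN")
  structure(list(row_fraction = diag(cm) / rs,
                 column_fraction = diag(cm) / cs,
                 accuracy = sum(diag(cm)) / sum(cm)),
            class = "confusion_metrics")
}

#' @export
print.confusion_metrics <- function(x, ...) {
  cat("<confusion_metrics>\n")
  cat(sprintf("  output-row fractions:   unrecognized %.1f%%, recognized %.1f%%\n",
              100 * x$row_fraction[1], 100 * x$row_fraction[2]))
  cat(sprintf("  target-column fractions: unrecognized %.1f%%, recognized %.1f%%\n",
              100 * x$column_fraction[1], 100 * x$column_fraction[2]))
  cat(sprintf("  overall accuracy: %.1f%%\n", 100 * x$accuracy))
  invisible(x)
}

#' Template-correlation recognizer
#'
#' Computes the Pearson correlation of the image with the noise-free neural
#' image of every letter in the alphabet; the image counts as recognized
#' when the best-correlated template is the presented letter. A constant
#' (zero-variance) image is unrecognized by convention.
#'
#' @param img An [optotype_image()] or numeric matrix.
#' @param true_letter The presented letter.
#' @param templates Named list (by letter) of [optotype_image()]s or
#'   matrices rendered at the same logMAR and pixel scale.
#' @return List with `recognized` (logical), `best_letter` and the named
#'   `correlations` vector.
#' @export
correlation_recognizer <- function(img, true_letter, templates) {
  v <- as.numeric(if (inherits(img, "optotype_image")) img$pixels else img)
  if (stats::sd(v) == 0)
    return(list(recognized = FALSE, best_letter = NA_character_,
                correlations = stats::setNames(rep(NA_real_, length(templates)),
                                               names(templates))))
  cors <- vapply(templates, function(t) {
    tv <- as.numeric(if (inherits(t, "optotype_image")) t$pixels else t)
    if (stats::sd(tv) == 0) -Inf else stats::cor(v, tv)
  }, numeric(1))
  best <- names(cors)[which.max(cors)]
  list(recognized = identical(best, toupper(true_letter)),
       best_letter = best, correlations = cors)
}

#' Noise-free template set for the correlation recognizer
#'
#' Renders every Sloan letter at the given level and, when an eye is
#' supplied, runs it through the deterministic stages of the pipeline
#' (PSF blur, retinal sampling, NTF) with the noise stage off.
#'
#' @param logmar Presented level.
#' @param config A [sim_config()].
#' @param zset Optional [zernike_set()]; `NULL` keeps the templates sharp.
#' @param age Age in years (needed with `zset`).
#' @return Named list of [optotype_image()]s.
#' @export
letter_templates <- function(logmar, config = sim_config(), zset = NULL,
                             age = NULL) {
  cfg <- config
  cfg$noise_variance <- 0
  psf <- NULL
  if (!is.null(zset)) {
    grid <- pupil_grid(cfg$pupil_n, cfg$pad_factor, cfg$ppd)
    psf <- psf_from_pupil(pupil_function(zset, grid, cfg$rho_sc))
  }
  out <- lapply(sloan_letters, function(L) {
    if (is.null(zset)) render_sloan(L, logmar, cfg$ppd, cfg$canvas_px)
    else simulate_optotype(zset, age, L, logmar, cfg, psf = psf)
  })
  stats::setNames(out, sloan_letters)
}
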