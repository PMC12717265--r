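# Sloan optotype rendering and the end-to-end simulation pipeline:
# sharp letter -> PSF blur -> retinal sampling -> NTF filter -> neural noise.

#' The ten Sloan letters
#' @export
sloan_letters <- c("C", "D", "H", "K", "N", "O", "R", "S", "V", "Z")

#' Optotype image container
#'
#' @param pixels Square numeric matrix of intensities on `[0, 1]`
#'   (1 = background, 0 = ink).
#' @param ppd Angular pixel scale, pixels per degree.
#' @param meta Named list of provenance fields (letter, logmar, ...).
#' @return Object of class `optotype_image`.
#' @export
optotype_image <- function(pixels, ppd, meta = list()) {
  if (!is.matrix(pixels) || nrow(pixels) != ncol(pixels))
    stop("pixels must be a square matrix")
  if (any(pixels < 0) || any(pixels > 1)) stop("intensities must lie in [0, 1]")
  if (ppd <= 0) stop("ppd must be positive")
  structure(c(list(pixels = pixels, ppd = ppd, stage = "raw"), meta),
            class = "optotype_image")
}

#' @export
print.optotype_image <- function(x, ...) {
  cat(sprintf("<optotype_image> %dx%d px, %.0f px/degree, stage '%s'%s\n",
              nrow(x$pixels), ncol(x$pixels), x$ppd, x$stage,
              if (!is.null(x$letter)) sprintf(", letter %s @ %.1f logMAR",
                                              x$letter, x$logmar) else ""))
  invisible(x)
}

#' Letter height in pixels for a logMAR level
#'
#' A 0.0 logMAR letter subtends 5 arcmin (strokes of 1 arcmin, the minimum
#' angle of resolution); each 0.1 logMAR step scales the size by `10^0.1`.
#'
#' @param logmar Acuity level in logMAR units.
#' @param ppd Canvas scale, pixels per degree.
#' @param canvas_px Canvas side; heights exceeding it raise an error.
#' @return Integer pixel height.
#' @export
letter_height_pixels <- function(logmar, ppd, canvas_px = Inf) {
  if (ppd <= 0) stop("ppd must be positive")
  h <- round(5 * 10^logmar / 60 * ppd)
  if (any(h > canvas_px)) stop("letter does not fit the canvas at this logMAR/ppd")
  h
}

# Distance from points (u, v) to the segment (x1,y1)-(x2,y2); vectorized.
seg_dist <- function(u, v, x1, y1, x2, y2) {
  dx <- x2 - x1; dy <- y2 - y1
  t <- pmin(pmax(((u - x1) * dx + (v - y1) * dy) / (dx^2 + dy^2), 0), 1)
  sqrt((u - (x1 + t * dx))^2 + (v - (y1 + t * dy))^2)
}

# Glyph predicates on the Sloan 5x5 grid: coordinates (u, v) in [0, 5]^2,
# v upward, stroke width 1 grid unit. Vector approximations of the ten
# letters honouring the 5x5 geometry (outer size 5, stroke = height / 5).
sloan_glyph_ink <- function(letter, u, v) {
  r <- sqrt((u - 2.5)^2 + (v - 2.5)^2)
  ring <- r >= 1.5 & r <= 2.5
  bar <- function(u0, u1, v0, v1) u >= u0 & u <= u1 & v >= v0 & v <= v1
  stroke <- function(x1, y1, x2, y2) seg_dist(u, v, x1, y1, x2, y2) <= 0.5
  switch(letter,
    C = ring & !(u > 2.5 & abs(v - 2.5) <= 0.5),
    O = ring,
    D = bar(0, 1, 0, 5) | (ring & u >= 2.5) |
        bar(0, 2.5, 4, 5) | bar(0, 2.5, 0, 1),
    H = bar(0, 1, 0, 5) | bar(4, 5, 0, 5) | bar(1, 4, 2, 3),
    K = bar(0, 1, 0, 5) | stroke(1, 2.5, 4.5, 5) | stroke(1, 2.5, 4.5, 0),
    N = bar(0, 1, 0, 5) | bar(4, 5, 0, 5) | stroke(0.5, 4.5, 4.5, 0.5),
    R = bar(0, 1, 0, 5) | bar(0, 5, 4, 5) | bar(4, 5, 2, 4.5) |
        bar(0, 5, 2, 3) | stroke(3, 2.5, 4.5, 0),
    S = bar(0, 5, 4, 5) | bar(0, 5, 2, 3) | bar(0, 5, 0, 1) |
        bar(0, 1, 2.5, 4.5) | bar(4, 5, 0.5, 2.5),
    V = stroke(0.5, 4.5, 2.5, 0.5) | stroke(4.5, 4.5, 2.5, 0.5) |
        bar(0, 1, 4, 5) | bar(4, 5, 4, 5),
    Z = bar(0, 5, 4, 5) | bar(0, 5, 0, 1) | stroke(4.5, 4, 0.5, 1),
    stop(sprintf("unknown Sloan letter '%s'", letter))
  )
}

#' Render a sharp Sloan optotype
#'
#' Centers the letter on a square canvas, dark-on-light (ink 0, background
#' 1), with outer height given by [letter_height_pixels()] and stroke width
#' one fifth of the height (the Sloan 5x5 grid).
#'
#' @param letter One of [sloan_letters].
#' @param logmar Acuity level in logMAR.
#' @param ppd Canvas scale, pixels per degree (default 224).
#' @param canvas_px Canvas side in pixels (default 224).
#' @return An [optotype_image()].
#' @export
render_sloan <- function(letter, logmar, ppd = 224, canvas_px = 224) {
  letter <- toupper(letter)
  if (!letter %in% sloan_letters)
    stop(sprintf("'%s' is not a Sloan letter (%s)", letter,
                 paste(sloan_letters, collapse = " ")))
  h <- letter_height_pixels(logmar, ppd, canvas_px)
  px <- matrix(1, canvas_px, canvas_px)
  # pixel centers in grid units; rows are y (downward), map to v upward
  ctr <- (canvas_px + 1) / 2
  scale <- h / 5
  rows <- seq_len(canvas_px)
  uu <- outer(rep(1, canvas_px), (rows - ctr) / scale + 2.5)  # columns -> u
  vv <- outer((ctr - rows) / scale + 2.5, rep(1, canvas_px))  # rows -> v
  inkable <- uu >= -0.01 & uu <= 5.01 & vv >= -0.01 & vv <= 5.01
  idx <- which(inkable)
  ink <- sloan_glyph_ink(letter, uu[idx], vv[idx])
  px[idx[ink]] <- 0
  optotype_image(px, ppd, meta = list(letter = letter, logmar = logmar))
}

#' Simulate the aberrated "neural image" of an optotype
#'
#' Runs the full pipeline: sharp render, convolution with the eye's PSF,
#' retinal sampling, NTF filtering, additive Gaussian noise. Stages can be
#' disabled and intermediates kept for inspection.
#'
#' @param zset A [zernike_set()].
#' @param age Subject age, years (drives the MOTF age factor).
#' @param letter Sloan letter.
#' @param logmar Presented acuity level.
#' @param config Pipeline configuration, see [sim_config()].
#' @param psf Optional precomputed [psf_from_pupil()] result for this eye
#'   (reuse across letters to avoid recomputing the pupil transform).
#' @param keep_stages Keep intermediate images in `$stages`.
#' @return An [optotype_image()]; when `keep_stages` is TRUE the returned
#'   object has a `stages` list of intermediates.
#' @export
simulate_optotype <- function(zset, age, letter, logmar, config = sim_config(),
                              psf = NULL, keep_stages = FALSE) {
  img <- render_sloan(letter, logmar, config$ppd, config$canvas_px)
  stages <- list(sharp = img)
  if (is.null(psf)) {
    grid <- pupil_grid(config$pupil_n, config$pad_factor, config$ppd)
    psf <- psf_from_pupil(pupil_function(zset, grid, config$rho_sc))
  }
  k <- psf_kernel(psf, min(config$canvas_px, nrow(psf$image)))
  img$pixels <- pmin(pmax(conv2_background(img$pixels, k, pad_value = 1), 0), 1)
  img$stage <- "psf"
  stages$blurred <- img
  if (!is.null(config$retina_spd)) {
    img <- suppressWarnings(retinal_sampling(img, config$retina_spd))
    stages$retina <- img
  }
  img <- apply_ntf_filter(img, age, config$scsf, config$motf_form)
  stages$ntf <- img
  if (config$noise_variance > 0) {
    img <- add_gaussian_noise(img, config$noise_variance, config$noise_seed)
    stages$noisy <- img
  }
  if (keep_stages) img$stages <- stages
  img
}

#' Simulation pipeline configuration
#'
#' @param canvas_px Canvas side in pixels (default 224, the recognizer's
#'   input size).
#' @param ppd Canvas angular scale, pixels per degree; the default 224 makes
#'   the canvas subtend 1 degree so the largest protocol letter (1.0 logMAR,
#'   50 arcmin) fits.
#' @param pupil_n,pad_factor Pupil grid geometry, see [pupil_grid()].
#' @param rho_sc Stiles-Crawford coefficient, mm^-2.
#' @param retina_spd Retinal sampling rate, samples/degree (`NULL` disables).
#' @param scsf An [scsf_params()].
#' @param motf_form `"sum"` or `"product"`, see [motf()].
#' @param noise_variance Neural noise variance on `[0, 1]` intensities
#'   (0 disables).
#' @param noise_seed Optional seed for the noise stage.
#' @return Configuration list.
#' @export
sim_config <- function(canvas_px = 224, ppd = 224, pupil_n = 256,
                       pad_factor = 4, rho_sc = 0.05, retina_spd = 120,
                       scsf = scsf_params(), motf_form = "sum",
                       noise_variance = 0.01, noise_seed = NULL) {
  list(canvas_px = canvas_px, ppd = ppd, pupil_n = pupil_n,
       pad_factor = pad_factor, rho_sc = rho_sc, retina_spd = retina_spd,
       scsf = scsf, motf_form = motf_form, noise_variance = noise_variance,
       noise_seed = noise_seed)
}

#' Build a labeled optotype-image manifest for a cohort
#'
#' One manifest row per (eye, acuity level, letter slot). Letters are drawn
#' uniformly without replacement within a line (seeded). When the cohort
#' carries a ground-truth uncorrected VA (column `va_uncorrected_logmar`),
#' rows are labeled recognized/unrecognized by the psychometric
#' [simulated_observer()]; otherwise labels are `NA` and flagged.
#'
#' @param cohort Cohort table (one row per eye), e.g. from
#'   [generate_cohort()].
#' @param va_levels Presented acuity levels (default 1.0 down to -0.3 by
#'   0.1: 14 levels).
#' @param letters_per_level Letters per line (default 5).
#' @param seed Integer seed for letter draws, labels and split assignment.
#' @param split Named fractions for train/validation/test (default
#'   70/15/15).
#' @return `data.frame` manifest with columns `subject_id`, `eye`, `age`,
#'   `letter`, `logmar`, `label` (1 recognized / 0 not), `split`.
#' @export
generate_image_set <- function(cohort, va_levels = round(seq(1.0, -0.3, by = -0.1), 2),
                               letters_per_level = 5, seed = 1,
                               split = c(train = 0.70, validation = 0.15, test = 0.15)) {
  if (nrow(cohort) == 0) stop("empty cohort")
  if (abs(sum(split) - 1) > 1e-9) stop("split fractions must sum to 1")
  set.seed(seed)
  n_eyes <- nrow(cohort)
  rows <- vector("list", n_eyes)
  has_va <- "va_uncorrected_logmar" %in% names(cohort)
  for (i in seq_len(n_eyes)) {
    letters <- unlist(lapply(va_levels, function(lv)
      sample(sloan_letters, letters_per_level,
             replace = letters_per_level > length(sloan_letters))))
    lm <- rep(va_levels, each = letters_per_level)
    lab <- NA
    if (has_va && is.finite(cohort$va_uncorrected_logmar[i])) {
      p <- observer_probability(lm, cohort$va_uncorrected_logmar[i])
      lab <- as.integer(stats::runif(length(lm)) < p)
    }
    rows[[i]] <- data.frame(subject_id = cohort$subject_id[i],
                            eye = cohort$eye[i], age = cohort$age[i],
                            letter = letters, logmar = lm, label = lab,
                            stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  n <- nrow(manifest)
  counts <- floor(split * n)
  counts[1] <- n - sum(counts[-1])
  manifest$split <- sample(rep(names(split), counts))
  rownames(manifest) <- NULL
  manifest
}

#' Write an optotype image as 8-bit grayscale PNG with a JSON sidecar
#'
#' @param img An [optotype_image()].
#' @param path Output PNG path; the sidecar is written as `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_optotype_png <- function(img, path) {
  stopifnot(inherits(img, "optotype_image"))
  if (!requireNamespace("png", quietly = TRUE))
    stop("writing PNG requires the 'png' package")
  png::writePNG(img$pixels, path)
  side <- list(pixels_per_degree = img$ppd, stage = img$stage,
               letter = img$letter, logmar = img$logmar)
  jsonlite::write_json(side[!vapply(side, is.null, logical(1))],
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
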