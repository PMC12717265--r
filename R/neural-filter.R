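# Neural stage of the functional pipeline: standard contrast sensitivity
# function (SCSF), mean optical transfer function (MOTF) with an age factor,
# their quotient (the neural transfer function, NTF), retinal sampling, and
# additive Gaussian neural noise.

#' Standard contrast sensitivity function parameters
#'
#' Defaults are the published fit of the average photopic CSF:
#' gain `psi = 373.08`, lobe scale frequencies `f0 = 4.1726` and
#' `f1 = 1.3625` cycles/degree, low-frequency weight `a = 0.8493`,
#' exponent `p = 0.7786` and frequency scale `phi = 1`.
#'
#' @param psi,f0,f1,a,p,phi See details.
#' @return List of class `scsf_params`.
#' @export
scsf_params <- function(psi = 373.08, f0 = 4.1726, f1 = 1.3625,
                        a = 0.8493, p = 0.7786, phi = 1) {
  if (psi <= 0 || f1 <= 0 || f0 <= f1 || a < 0 || p <= 0 || phi <= 0)
    stop("invalid SCSF parameters: need psi > 0, f0 > f1 > 0, a >= 0, p > 0, phi > 0")
  structure(list(psi = psi, f0 = f0, f1 = f1, a = a, p = p, phi = phi),
            class = "scsf_params")
}

#' Standard contrast sensitivity function
#'
#' `SCSF(f) = psi * sech((f / (phi * f0))^p) - a * sech(f / (phi * f1))`.
#'
#' @param f Spatial frequency, cycles/degree (vectorized, `f >= 0`).
#' @param params An [scsf_params()].
#' @return Dimensionless sensitivity.
#' @export
scsf <- function(f, params = scsf_params()) {
  if (any(f < 0)) stop("frequency must be >= 0")
  sech <- function(x) 1 / cosh(x)
  params$psi * sech((f / (params$phi * params$f0))^params$p) -
    params$a * sech(f / (params$phi * params$f1))
}

#' Age factor of the mean optical transfer function
#'
#' `AF = 1 + (age / d_norm)^4`, with the normalization age `d_norm = 70`
#' years.
#'
#' @param age Age in years (>= 0).
#' @param d_norm Normalization parameter, years.
#' @return Dimensionless factor >= 1.
#' @export
age_factor <- function(age, d_norm = 70) {
  if (any(age < 0)) stop("age must be >= 0")
  if (d_norm <= 0) stop("d_norm must be > 0")
  1 + (age / d_norm)^4
}

#' Mean optical transfer function with age dependence
#'
#' Two functional forms are provided. `"sum"` is the four-term expression
#' \deqn{0.426 e^{-0.028f}/(1+AF/7) + 0.574 e^{-0.37f} +
#'       0.123 e^{-37f}/(1+AF/7) + 0.877 e^{-360f},}
#' `"product"` multiplies the two bracketed pairs (whose weights each sum
#' to 1, so the product form has unit gain at `f = 0` for `AF = 0`):
#' \deqn{[0.426 e^{-0.028f}/(1+AF/7) + 0.574 e^{-0.37f}] \times
#'       [0.123 e^{-37f}/(1+AF/7) + 0.877 e^{-360f}].}
#'
#' @param f Spatial frequency, cycles/degree (vectorized).
#' @param age Age in years.
#' @param form `"sum"` (default) or `"product"`.
#' @param d_norm Age-factor normalization, years.
#' @return Dimensionless modulation.
#' @export
motf <- function(f, age, form = c("sum", "product"), d_norm = 70) {
  if (any(f < 0)) stop("frequency must be >= 0")
  form <- match.arg(form)
  af <- age_factor(age, d_norm)
  g <- 1 + af / 7
  t1 <- 0.426 * exp(-0.028 * f) / g
  t2 <- 0.574 * exp(-0.37 * f)
  t3 <- 0.123 * exp(-37 * f) / g
  t4 <- 0.877 * exp(-360 * f)
  if (form == "sum") t1 + t2 + t3 + t4 else (t1 + t2) * (t3 + t4)
}

#' Neural transfer function
#'
#' `NTF(f) = SCSF(f) / MOTF(f)`. Values of the MOTF below `1e-12` are
#' clamped (with a warning) to avoid division blow-up at extreme
#' frequencies.
#'
#' @inheritParams motf
#' @param params An [scsf_params()].
#' @return Dimensionless transfer value(s).
#' @export
ntf <- function(f, age, params = scsf_params(), form = c("sum", "product"),
                d_norm = 70) {
  form <- match.arg(form)
  m <- motf(f, age, form, d_norm)
  if (any(m < 1e-12)) {
    warning("MOTF below 1e-12 at some frequencies; clamping")
    m <- pmax(m, 1e-12)
  }
  scsf(f, params) / m
}

#' Export an NTF (or SCSF/MOTF) curve
#'
#' @param f Frequency axis, cycles/degree.
#' @param age Age in years.
#' @param what One of `"ntf"`, `"scsf"`, `"motf"`.
#' @param ... Passed to the underlying function.
#' @return `data.frame` with columns `frequency_cpd` and `value`.
#' @export
filter_curve <- function(f = seq(0, 60, by = 0.25), age = 45,
                         what = c("ntf", "scsf", "motf"), ...) {
  what <- match.arg(what)
  v <- switch(what,
              ntf = ntf(f, age, ...),
              scsf = scsf(f, ...),
              motf = motf(f, age, ...))
  data.frame(frequency_cpd = f, value = v)
}

# Radial frequency map (cycles/degree) of an N x N image sampled at `ppd`
# pixels per degree, in unshifted FFT order.
freq_grid_cpd <- function(N, ppd) {
  k <- c(0:(N / 2), -((N / 2 - 1):1))
  if (N %% 2 == 1) k <- c(0:((N - 1) / 2), -(((N - 1) / 2):1))
  fx <- k / N * ppd
  sqrt(outer(fx^2, fx^2, "+"))
}

#' Filter an image by the neural transfer function
#'
#' Multiplies the image spectrum by the radially symmetric NTF, normalized
#' to unit gain at zero frequency (so the spatial mean is preserved before
#' clipping), inverse-transforms and clips to `[0, 1]`.
#'
#' @param img An [optotype_image()].
#' @param age Age in years.
#' @param params An [scsf_params()].
#' @param form MOTF form, see [motf()].
#' @param clip Clip the output to `[0, 1]` (default TRUE).
#' @return Filtered [optotype_image()].
#' @export
apply_ntf_filter <- function(img, age, params = scsf_params(),
                             form = c("sum", "product"), clip = TRUE) {
  stopifnot(inherits(img, "optotype_image"))
  form <- match.arg(form)
  if (is.null(img$ppd) || img$ppd <= 0) stop("image has no pixels-per-degree scale")
  N <- nrow(img$pixels)
  fr <- freq_grid_cpd(N, img$ppd)
  gain <- ntf(fr, age, params, form) / ntf(0, age, params, form)
  out <- Re(stats::fft(stats::fft(img$pixels) * gain, inverse = TRUE)) / N^2
  if (clip) out <- pmin(pmax(out, 0), 1)
  img$pixels <- out
  img$stage <- "ntf"
  img
}

#' Retinal sampling of an image
#'
#' Band-limits the image to the Nyquist frequency of the retinal sampling
#' mosaic (default 120 samples/degree, foveal cone density) with a
#' raised-cosine roll-off, emulating resampling onto the receptor grid and
#' reconstruction back onto the canvas. If the retinal rate is at or above
#' the canvas sampling rate the image is returned unchanged with a warning.
#'
#' @param img An [optotype_image()].
#' @param samples_per_degree Retinal sampling rate, 1/degree.
#' @param taper Fractional width of the raised-cosine transition band
#'   (default 0.1 of the cutoff; the response is zero above the cutoff).
#' @return Band-limited [optotype_image()].
#' @export
retinal_sampling <- function(img, samples_per_degree = 120, taper = 0.1) {
  stopifnot(inherits(img, "optotype_image"))
  if (samples_per_degree <= 0) stop("samples_per_degree must be > 0")
  if (samples_per_degree >= img$ppd) {
    warning("retinal sampling rate at or above the canvas rate; image unchanged")
    return(img)
  }
  fc <- samples_per_degree / 2
  N <- nrow(img$pixels)
  fr <- freq_grid_cpd(N, img$ppd)
  f0 <- fc * (1 - taper)
  gain <- ifelse(fr <= f0, 1,
                 ifelse(fr >= fc, 0, 0.5 * (1 + cos(pi * (fr - f0) / (fc - f0)))))
  out <- Re(stats::fft(stats::fft(img$pixels) * gain, inverse = TRUE)) / N^2
  img$pixels <- pmin(pmax(out, 0), 1)
  img$stage <- "retina"
  img
}

#' Add zero-mean Gaussian neural noise
#'
#' @param img An [optotype_image()] with intensities on `[0, 1]`.
#' @param variance Noise variance on the `[0, 1]` intensity scale
#'   (default 0.01).
#' @param seed Optional integer seed for reproducibility.
#' @return Noisy image, clipped to `[0, 1]`.
#' @export
add_gaussian_noise <- function(img, variance = 0.01, seed = NULL) {
  stopifnot(inherits(img, "optotype_image"))
  if (variance < 0) stop("variance must be >= 0")
  if (variance == 0) return(img)
  if (!is.null(seed)) set.seed(seed)
  n <- length(img$pixels)
  img$pixels <- pmin(pmax(img$pixels + stats::rnorm(n, 0, sqrt(variance)), 0), 1)
  img$stage <- "noise"
  img
}
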