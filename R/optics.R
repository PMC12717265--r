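# Pupil function and point-spread-function computation by Fourier optics.
#
# The pupil plane is sampled so that the PSF plane lands exactly on the
# requested angular pixel scale (pixels per degree), which lets the PSF be
# convolved with optotype rasters without resampling: with N = n * pad_factor
# samples per side and pupil-plane pitch dx, the PSF pixel subtends
# lambda / (N * dx) radians, so dx is solved from the target scale.

#' Pupil/PSF sampling geometry
#'
#' @param n Nominal minimum number of samples across the pupil diameter
#'   (>= 64).
#' @param pad_factor Zero-padding factor (integer >= 1); `n * pad_factor`
#'   samples per side in the transform.
#' @param ppd Target angular sampling of the PSF plane, pixels per degree
#'   (default 224, matching the default optotype canvas).
#' @return An object of class `pupil_grid`.
#' @export
pupil_grid <- function(n = 256, pad_factor = 4, ppd = 224) {
  if (n < 64 || n %% 2 != 0) stop("n must be an even integer >= 64")
  if (pad_factor < 1 || pad_factor != floor(pad_factor)) stop("pad_factor must be an integer >= 1")
  if (ppd <= 0) stop("ppd must be positive")
  structure(list(n = as.integer(n), pad_factor = as.integer(pad_factor),
                 N = as.integer(n * pad_factor), ppd = ppd),
            class = "pupil_grid")
}

# Quadrant swap putting the DC sample at (N/2 + 1, N/2 + 1) for even N.
fftshift2 <- function(m) {
  N1 <- nrow(m); N2 <- ncol(m)
  s1 <- c((N1 / 2 + 1):N1, 1:(N1 / 2))
  s2 <- c((N2 / 2 + 1):N2, 1:(N2 / 2))
  m[s1, s2]
}

#' Complex pupil function from a Zernike set
#'
#' Amplitude is the unit disc apodized by the Stiles-Crawford effect,
#' `A(r) = 10^(-rho_sc * r_mm^2 / 2)`; phase is `2 * pi * W / lambda` with
#' `W` the Zernike wavefront.
#'
#' @param zset A [zernike_set()].
#' @param grid A [pupil_grid()].
#' @param rho_sc Stiles-Crawford apodization coefficient, mm^-2 (default
#'   0.05; 0 disables apodization).
#' @return An object of class `pupil_function`: complex `N x N` field plus
#'   sampling metadata.
#' @export
pupil_function <- function(zset, grid = pupil_grid(), rho_sc = 0.05) {
  stopifnot(inherits(zset, "zernike_set"), inherits(grid, "pupil_grid"))
  if (rho_sc < 0) stop("rho_sc must be >= 0")
  lambda_um <- zset$wavelength_nm / 1000
  N <- grid$N
  dx_um <- grid$ppd * 180 * lambda_um / (pi * N)
  span <- 2 * zset$pupil_radius_mm * 1000 / dx_um
  if (span < grid$n) {
    warning(sprintf(paste0("pupil spans %.0f samples (< nominal n = %d); ",
                           "increase pad_factor or lower ppd for finer pupil sampling"),
                    span, grid$n))
  }
  x <- ((0:(N - 1)) - N / 2) * dx_um / 1000  # mm
  r_mm <- sqrt(outer(x^2, x^2, "+"))
  rho <- r_mm / zset$pupil_radius_mm
  inside <- rho <= 1
  theta <- atan2(matrix(x, N, N, byrow = TRUE), matrix(x, N, N))
  amp <- matrix(0, N, N)
  amp[inside] <- 10^(-rho_sc * r_mm[inside]^2 / 2)
  ph <- matrix(0, N, N)
  if (any(zset$coeffs != 0)) {
    w <- matrix(0, N, N)
    w[inside] <- wavefront(zset, rho[inside], theta[inside])
    ph <- 2 * pi * w / lambda_um
  }
  structure(list(field = amp * exp(1i * ph), mask = inside, dx_um = dx_um,
                 ppd = grid$ppd, wavelength_nm = zset$wavelength_nm,
                 pupil_radius_mm = zset$pupil_radius_mm, grid = grid),
            class = "pupil_function")
}

#' Point spread function of a pupil
#'
#' Squared modulus of the centered discrete Fourier transform of the pupil
#' field, normalized to unit sum. The angular pixel scale equals the grid's
#' `ppd` by construction.
#'
#' @param p A [pupil_function()].
#' @param normalize Normalize to unit sum (default TRUE).
#' @return An object of class `psf`: non-negative `N x N` matrix (`$image`)
#'   with `$ppd` and the unnormalized total (`$raw_sum`).
#' @export
psf_from_pupil <- function(p, normalize = TRUE) {
  stopifnot(inherits(p, "pupil_function"))
  img <- Mod(fftshift2(stats::fft(p$field)))^2
  raw_sum <- sum(img)
  if (normalize) img <- img / raw_sum
  structure(list(image = img, ppd = p$ppd, normalized = normalize,
                 raw_sum = raw_sum), class = "psf")
}

#' Strehl ratio of an aberrated eye
#'
#' Peak of the aberrated PSF divided by the peak of the PSF of the same
#' apodized aperture with a flat wavefront.
#'
#' @inheritParams pupil_function
#' @return Strehl ratio in `(0, 1]`.
#' @export
strehl_ratio <- function(zset, grid = pupil_grid(), rho_sc = 0.05) {
  ab <- psf_from_pupil(pupil_function(zset, grid, rho_sc), normalize = FALSE)
  z0 <- zset; z0$coeffs[] <- 0
  ref <- psf_from_pupil(pupil_function(z0, grid, rho_sc), normalize = FALSE)
  max(ab$image) / max(ref$image)
}

# Central crop of a PSF to a square kernel of side `size`, renormalized to
# unit sum so convolution conserves mean intensity.
psf_kernel <- function(psf, size) {
  stopifnot(inherits(psf, "psf"))
  N <- nrow(psf$image)
  if (size > N) stop("requested kernel larger than the PSF support")
  c0 <- N / 2 + 1
  half <- floor((size - 1) / 2)
  idx <- (c0 - half):(c0 - half + size - 1)
  k <- psf$image[idx, idx]
  k / sum(k)
}

# Linear 2-D convolution with constant background padding, via FFT.
conv2_background <- function(img, kernel, pad_value = 1) {
  ni <- nrow(img); nk <- nrow(kernel)
  N <- ni + nk
  big <- matrix(pad_value, N, N)
  off <- floor(nk / 2)
  big[(off + 1):(off + ni), (off + 1):(off + ni)] <- img
  kb <- matrix(0, N, N)
  kb[1:nk, 1:nk] <- kernel
  out <- Re(stats::fft(stats::fft(big) * stats::fft(kb), inverse = TRUE)) / N^2
  half <- floor((nk - 1) / 2)  # kernel origin (DC) index - 1
  out[(off + half + 1):(off + half + ni), (off + half + 1):(off + half + ni)]
}
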