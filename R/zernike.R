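# Zernike polynomials in the OSA/ANSI single-index convention with
# unit-variance normalization, plus the coefficient manipulations used to
# emulate refractive correction and defocus-curve conditions.

#' OSA single index to (n, m) radial order / angular frequency
#'
#' @param j OSA single index (0-based).
#' @return List with integer components `n` and `m`.
#' @export
osa_to_nm <- function(j) {
  if (any(j < 0) || any(j != floor(j))) stop("OSA index must be a non-negative integer")
  n <- ceiling((-3 + sqrt(9 + 8 * j)) / 2)
  m <- 2 * j - n * (n + 2)
  list(n = as.integer(n), m = as.integer(m))
}

# Radial polynomial R_n^{|m|}(rho), explicit factorial sum.
zernike_radial <- function(n, m, rho) {
  m <- abs(m)
  if ((n - m) %% 2 != 0) return(rho * 0)
  k <- 0:((n - m) / 2)
  coef <- (-1)^k * factorial(n - k) /
    (factorial(k) * factorial((n + m) / 2 - k) * factorial((n - m) / 2 - k))
  out <- rho * 0
  for (i in seq_along(k)) out <- out + coef[i] * rho^(n - 2 * k[i])
  out
}

#' Evaluate a normalized Zernike polynomial
#'
#' Unit-variance (ANSI Z80.28) normalization: the polynomials are orthonormal
#' over the unit disc, so a coefficient in micrometres is the RMS wavefront
#' contribution of that mode in micrometres.
#'
#' @param j OSA single index, 0 to 35.
#' @param rho Normalized pupil radius in `[0, 1]` (vectorized).
#' @param theta Azimuthal angle in radians (vectorized, recycled with `rho`).
#' @return Dimensionless polynomial value(s).
#' @examples
#' zernike_polynomial(4, 1, 0)       # sqrt(3): defocus at the pupil margin
#' zernike_polynomial(3, 1, pi / 4)  # sqrt(6): oblique astigmatism peak
#' @export
zernike_polynomial <- function(j, rho, theta) {
  if (length(j) != 1 || j < 0 || j > 35) stop("OSA index j must be a single integer in 0..35")
  if (any(rho < 0) || any(rho > 1)) stop("rho must lie in [0, 1]")
  nm <- osa_to_nm(j)
  n <- nm$n; m <- nm$m
  norm <- if (m == 0) sqrt(n + 1) else sqrt(2 * (n + 1))
  ang <- if (m > 0) cos(m * theta) else if (m < 0) sin(-m * theta) else 1
  norm * zernike_radial(n, m, rho) * ang
}

#' Construct a Zernike coefficient set
#'
#' @param coeffs Numeric vector of 36 OSA-indexed coefficients (j = 0..35),
#'   micrometres, for the stated pupil. Shorter vectors are zero-padded.
#' @param pupil_radius_mm Pupil radius in mm (default 1.5, the standardized
#'   3 mm analysis pupil of clinical aberrometry).
#' @param wavelength_nm Design wavelength in nm (default 555, photopic peak).
#' @return An object of class `zernike_set`.
#' @export
zernike_set <- function(coeffs = numeric(36), pupil_radius_mm = 1.5,
                        wavelength_nm = 555) {
  coeffs <- as.numeric(coeffs)
  if (length(coeffs) > 36) stop("at most 36 coefficients (OSA j = 0..35)")
  coeffs <- c(coeffs, numeric(36 - length(coeffs)))
  if (any(!is.finite(coeffs))) stop("all coefficients must be finite")
  if (!is.finite(pupil_radius_mm) || pupil_radius_mm <= 0) stop("pupil_radius_mm must be > 0")
  if (!is.finite(wavelength_nm) || wavelength_nm <= 0) stop("wavelength_nm must be > 0")
  structure(list(coeffs = coeffs, pupil_radius_mm = pupil_radius_mm,
                 wavelength_nm = wavelength_nm),
            class = "zernike_set")
}

#' @export
print.zernike_set <- function(x, ...) {
  nz <- which(x$coeffs != 0) - 1L
  cat(sprintf("<zernike_set> pupil radius %.2f mm, wavelength %.0f nm\n",
              x$pupil_radius_mm, x$wavelength_nm))
  if (length(nz) == 0) cat("  all 36 coefficients zero\n")
  else cat(sprintf("  non-zero modes (OSA j): %s\n", paste(nz, collapse = ", ")))
  invisible(x)
}

#' Wavefront height map from a Zernike set
#'
#' Sums `c_j * Z_j(rho, theta)` over the unit disc; zero outside.
#'
#' @param zset A [zernike_set()].
#' @param rho,theta Polar coordinates (rho normalized to the pupil radius).
#'   Points with `rho > 1` evaluate to 0.
#' @return Wavefront height in micrometres, same shape as `rho`.
#' @export
wavefront <- function(zset, rho, theta) {
  stopifnot(inherits(zset, "zernike_set"))
  w <- rho * 0
  inside <- rho <= 1
  active <- which(zset$coeffs != 0)
  for (j in active) {
    w[inside] <- w[inside] +
      zset$coeffs[j] * zernike_polynomial(j - 1L, rho[inside], theta[inside])
  }
  w
}

#' Convert a defocus power to a Zernike defocus coefficient
#'
#' For a pupil of radius `r` (mm) a defocus of `d` diopters corresponds to a
#' wavefront coefficient `c_2^0 = d * r^2 / (4 * sqrt(3))` micrometres.
#' Positive diopters give a positive coefficient (myopic wavefront defocus);
#' flip `sign` to adopt the opposite convention.
#'
#' @param d Defocus in diopters.
#' @param pupil_radius_mm Pupil radius in mm.
#' @param sign Either `+1` (default) or `-1`.
#' @return Defocus coefficient increment in micrometres.
#' @export
diopter_to_z20 <- function(d, pupil_radius_mm = 1.5, sign = 1) {
  if (any(pupil_radius_mm <= 0)) stop("pupil_radius_mm must be > 0")
  if (!sign %in% c(-1, 1)) stop("sign must be +1 or -1")
  sign * d * pupil_radius_mm^2 / (4 * sqrt(3))
}

#' Zero the second-order terms (best sphero-cylindrical correction)
#'
#' Emulates best refractive correction by setting defocus (j = 4) and both
#' second-order astigmatism terms (j = 3, 5) to zero.
#'
#' @param zset A [zernike_set()].
#' @return A corrected copy.
#' @export
apply_correction <- function(zset) {
  stopifnot(inherits(zset, "zernike_set"))
  zset$coeffs[c(4, 5, 6)] <- 0  # OSA j = 3, 4, 5
  zset
}

#' Apply a defocus-curve condition
#'
#' Starting from the corrected state (second-order terms zeroed, as clinical
#' defocus curves start from best correction), adds the defocus coefficient
#' corresponding to a trial lens of `delta_d` diopters.
#'
#' @param zset A [zernike_set()].
#' @param delta_d Trial-lens power in diopters (clinically -3.00 to +1.00).
#' @param sign Diopter-to-coefficient sign convention, see [diopter_to_z20()].
#' @return The modified set.
#' @export
apply_defocus_condition <- function(zset, delta_d, sign = 1) {
  out <- apply_correction(zset)
  out$coeffs[5] <- diopter_to_z20(delta_d, zset$pupil_radius_mm, sign = sign)
  out
}

#' Spherical equivalent of a sphero-cylindrical refraction
#'
#' @param s Sphere, diopters.
#' @param c Cylinder, diopters.
#' @return `s + c / 2`, diopters.
#' @export
spherical_equivalent <- function(s, c) {
  if (any(!is.finite(s)) || any(!is.finite(c))) stop("sphere and cylinder must be finite")
  s + c / 2
}

#' Vergence correction for a finite test distance
#'
#' A chart at distance `d` metres is not at optical infinity; the sphere is
#' adjusted by `-1/d` diopters (-0.25 D at the standard 4 m lane).
#'
#' @param d_m Test distance in metres.
#' @return Correction in diopters.
#' @export
vergence_correction <- function(d_m) {
  if (any(d_m <= 0)) stop("distance must be positive")
  -1 / d_m
}
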