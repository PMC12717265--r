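# Synthetic cohort generator: per-eye Zernike sets, age, amplitude of
# accommodation, dominant-eye flags and per-condition ground-truth VA with
# the statistical structure the prediction methods assume, plus a
# psychometric simulated observer for per-letter recognition labels.
# All generative constants are fixture parameters (declared here and in the
# methods vignette), not population estimates.

defocus_levels <- function() round(seq(-3, 1, by = 0.5), 2)

defocus_colnames <- function() {
  paste0("va_defocus_", sprintf("%+.2f", defocus_levels()))
}

#' Deterministic ground-truth VA rule of the synthetic cohort
#'
#' Residual dioptric blur is the total defocus of the condition, reduced by
#' accommodation when negative (trial-lens convention: negative total
#' defocus is compensable by accommodative effort up to the amplitude of
#' accommodation). VA rises linearly with residual blur, with an extra
#' penalty above age 50:
#' `va = clip(-0.1 + 0.18 * (|residual| + 0.5 * |cyl_res|) +
#'            0.004 * max(0, age - 50), -0.3, 1.1)`.
#'
#' @param delta_total Total defocus of the condition, diopters (spherical
#'   equivalent for uncorrected vision, 0 for corrected, the trial-lens
#'   power for defocus-curve conditions).
#' @param cyl_residual Uncompensated cylinder, diopters (0 except for
#'   uncorrected vision).
#' @param aa Amplitude of accommodation, diopters.
#' @param age Age in years.
#' @return Noise-free VA in logMAR.
#' @export
blur_rule_va <- function(delta_total, cyl_residual, aa, age) {
  residual <- ifelse(delta_total < 0,
                     delta_total + pmin(aa, -delta_total),
                     delta_total)
  pmin(pmax(-0.1 + 0.18 * (abs(residual) + 0.5 * abs(cyl_residual)) +
              0.004 * pmax(0, age - 50), -0.3), 1.1)
}

#' Generate a synthetic cohort
#'
#' One row per eye (two eyes per subject, one dominant eye per subject).
#' Ages are uniform on 30-65 years; amplitude of accommodation declines
#' with age (`max(0, 18.5 - 0.3 * age)` D plus N(0, 1) jitter, floored at
#' 0); spherical equivalent is N(-1, 2^2) D clipped to [-7, +4]; cylinder
#' is `-|N(0, 0.75^2)|` D. Defocus (j = 4) and astigmatism (j = 3, 5)
#' coefficients for the standardized 3 mm pupil follow from the refraction;
#' higher-order coefficients are N(0, 0.03^2) micrometres. Ground-truth VA
#' per condition comes from [blur_rule_va()] plus N(0, `va_noise_sd`)
#' measurement noise, clipped reporting range [-0.3, 1.1]. `missing_va`
#' VA cells (chosen uniformly among the cells that become observations)
#' are set to `NA` to emulate missing clinical entries.
#'
#' @param n_subjects Number of subjects (default 135; two eyes each).
#' @param seed Integer seed (mandatory for reproducibility).
#' @param missing_va Number of VA cells to blank (default 11).
#' @param va_noise_sd Measurement noise of the VA ground truth, logMAR.
#' @param hoa_sd Higher-order coefficient scale, micrometres.
#' @param pupil_radius_mm Standardized analysis pupil radius.
#' @return `data.frame`, one row per eye, in the cohort CSV schema (see
#'   [read_cohort()]).
#' @export
generate_cohort <- function(n_subjects = 135, seed = 1, missing_va = 11,
                            va_noise_sd = 0.02, hoa_sd = 0.03,
                            pupil_radius_mm = 1.5) {
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  set.seed(seed)
  n_eyes <- 2L * n_subjects
  subj <- rep(seq_len(n_subjects), each = 2)
  age <- rep(stats::runif(n_subjects, 30, 65), each = 2)
  aa <- rep(pmax(0, pmax(0, 18.5 - 0.3 * unique_by_subject(age)) +
                   stats::rnorm(n_subjects, 0, 1)), each = 2)
  se <- pmin(pmax(stats::rnorm(n_eyes, -1, 2), -7), 4)
  cyl <- -abs(stats::rnorm(n_eyes, 0, 0.75))
  sph <- se - cyl / 2
  dominant <- integer(n_eyes)
  dominant[seq(1, n_eyes, by = 2) + (stats::runif(n_subjects) < 0.5)] <- 1L

  z <- matrix(0, n_eyes, 36)
  colnames(z) <- paste0("z", 0:35)
  z[, 5] <- diopter_to_z20(se, pupil_radius_mm)             # j = 4 defocus
  axis <- stats::runif(n_eyes, 0, pi)
  c_ast <- cyl * pupil_radius_mm^2 / (4 * sqrt(6))
  z[, 4] <- c_ast * sin(2 * axis)                            # j = 3
  z[, 6] <- c_ast * cos(2 * axis)                            # j = 5
  z[, 7:36] <- stats::rnorm(n_eyes * 30, 0, hoa_sd)          # j = 6..35

  noisy_va <- function(delta_total, cyl_res) {
    v <- blur_rule_va(delta_total, cyl_res, aa, age) +
      stats::rnorm(n_eyes, 0, va_noise_sd)
    round(v, 2)
  }
  va_unc <- noisy_va(se, cyl)
  va_cor <- noisy_va(0, 0)
  dc <- sapply(defocus_levels(), function(d) noisy_va(d, 0))
  colnames(dc) <- defocus_colnames()
  dc[dominant == 0, ] <- NA  # defocus curves measured on the dominant eye only

  cohort <- data.frame(subject_id = subj,
                       eye = rep(c("OD", "OS"), n_subjects),
                       dominant = dominant, age = age, aa_d = aa,
                       sphere_d = sph, cylinder_d = cyl,
                       va_uncorrected_logmar = va_unc,
                       va_corrected_logmar = va_cor,
                       check.names = FALSE, stringsAsFactors = FALSE)
  cohort <- cbind(cohort, as.data.frame(dc, check.names = FALSE),
                  as.data.frame(z), pupil_radius_mm = pupil_radius_mm)

  if (missing_va > 0) {
    cells <- rbind(
      cbind(seq_len(n_eyes), match("va_uncorrected_logmar", names(cohort))),
      cbind(seq_len(n_eyes), match("va_corrected_logmar", names(cohort))),
      as.matrix(expand.grid(which(dominant == 1),
                            match(defocus_colnames(), names(cohort)))))
    if (missing_va > nrow(cells)) stop("missing_va exceeds the number of VA cells")
    drop <- cells[sample(nrow(cells), missing_va), , drop = FALSE]
    for (i in seq_len(nrow(drop))) cohort[drop[i, 1], drop[i, 2]] <- NA
  }
  rownames(cohort) <- NULL
  cohort
}

# ages arrive repeated per eye; recover the per-subject vector
unique_by_subject <- function(x) x[seq(1, length(x), by = 2)]

#' Recognition probability of the simulated observer
#'
#' Logistic psychometric function of the margin between the presented level
#' and the subject's true VA, floored at the guess rate:
#' `p = guess + (1 - guess) * logistic((va_presented - va_true) / slope)`.
#'
#' @param va_presented Presented letter size, logMAR.
#' @param va_true Subject's ground-truth VA for the condition, logMAR.
#' @param slope Psychometric slope, logMAR (default 0.05).
#' @param guess Guess rate floor (default 0.1, one of ten Sloan letters).
#' @return Probability of recognition.
#' @export
observer_probability <- function(va_presented, va_true, slope = 0.05,
                                 guess = 0.1) {
  guess + (1 - guess) * stats::plogis((va_presented - va_true) / slope)
}

#' Simulated observer: seeded per-letter recognition draw
#'
#' @inheritParams observer_probability
#' @param seed Optional seed.
#' @return Logical: recognized?
#' @export
simulated_observer <- function(va_presented, va_true, slope = 0.05,
                               guess = 0.1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stats::runif(length(va_presented)) <
    observer_probability(va_presented, va_true, slope, guess)
}

#' End-to-end offline fixture
#'
#' Chains [generate_cohort()], [generate_image_set()] (labels from the
#' simulated observer) and [build_observation_table()], guaranteeing both
#' the recognizer and the boosting stack are trainable without clinical
#' data.
#'
#' @param n_subjects,seed,missing_va Passed to [generate_cohort()].
#' @param va_levels,letters_per_level Passed to [generate_image_set()].
#' @return List with `cohort`, `manifest` and `observations`.
#' @export
end_to_end_fixture <- function(n_subjects = 10, seed = 1, missing_va = 0,
                               va_levels = round(seq(1.0, -0.3, by = -0.1), 2),
                               letters_per_level = 5) {
  cohort <- generate_cohort(n_subjects, seed = seed, missing_va = missing_va)
  manifest <- generate_image_set(cohort, va_levels, letters_per_level,
                                 seed = seed + 1)
  obs <- build_observation_table(cohort)
  list(cohort = cohort, manifest = manifest, observations = obs)
}
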