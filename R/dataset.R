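# Observation-table construction for the boosting models: per-eye rows
# under uncorrected, corrected and defocus-curve conditions, with the
# accommodation gating rule, train/test splitting, Zernike feature subsets
# and stratified analyses.

#' OSA indices of a Zernike feature subset
#'
#' Subsets of 5, 9 and 14 coefficients start at the first (j = 1) OSA
#' coefficient; the full subset of 36 starts at piston (j = 0).
#'
#' @param k One of 5, 9, 14, 36.
#' @return Integer vector of OSA indices.
#' @export
zernike_subset <- function(k) {
  if (!k %in% c(5, 9, 14, 36)) stop("k must be one of 5, 9, 14, 36")
  if (k == 36) 0:35 else 1:k
}

#' Build the tabular observation set from a cohort
#'
#' Emits one row per (eye, uncorrected), one per (eye, corrected as in
#' [apply_correction()]: second-order terms zeroed) and, for each dominant
#' eye, one per defocus level (-3.00 to +1.00 D in 0.50 D steps, as in
#' [apply_defocus_condition()]: astigmatism zeroed, defocus set from the
#' trial-lens power). Rows with missing VA are dropped (counts kept in
#' attributes `n_built` and `n_dropped`). The amplitude of accommodation is
#' gated: defocus rows carry the subject's AA only when the trial-lens
#' power is negative (accommodation can compensate), uncorrected rows only
#' when the eye's spherical equivalent is negative, zero otherwise.
#' Eyes with a missing dominant flag are skipped with a warning.
#'
#' @param cohort Cohort table, one row per eye (see [generate_cohort()] or
#'   [read_cohort()]).
#' @return `data.frame` with columns `subject_id`, `eye`, `condition`,
#'   `delta_d`, `age`, `aa_gated`, `sphere_d`, `cylinder_d`, `z0`..`z35`
#'   (condition-adjusted coefficients) and `va` (logMAR target).
#' @export
build_observation_table <- function(cohort) {
  zcols <- paste0("z", 0:35)
  need <- c("subject_id", "eye", "dominant", "age", "aa_d",
            "va_uncorrected_logmar", "va_corrected_logmar", zcols,
            "pupil_radius_mm")
  miss <- setdiff(need, names(cohort))
  if (length(miss)) stop("cohort lacks columns: ", paste(miss, collapse = ", "))
  bad <- is.na(cohort$dominant)
  if (any(bad)) {
    warning(sum(bad), " eye(s) with missing dominant-eye flag skipped")
    cohort <- cohort[!bad, , drop = FALSE]
  }
  z <- as.matrix(cohort[, zcols])
  has_refr <- all(c("sphere_d", "cylinder_d") %in% names(cohort))
  se <- if (has_refr) spherical_equivalent(cohort$sphere_d, cohort$cylinder_d)
        else rep(NA_real_, nrow(cohort))
  sph <- if (has_refr) cohort$sphere_d else rep(NA_real_, nrow(cohort))
  cyl <- if (has_refr) cohort$cylinder_d else rep(NA_real_, nrow(cohort))

  block <- function(idx, zmat, condition, delta_d, va, aa_gated) {
    cbind(data.frame(subject_id = cohort$subject_id[idx],
                     eye = cohort$eye[idx], condition = condition,
                     delta_d = delta_d, age = cohort$age[idx],
                     aa_gated = aa_gated, sphere_d = sph[idx],
                     cylinder_d = cyl[idx], stringsAsFactors = FALSE),
          as.data.frame(zmat), va = va)
  }

  all_idx <- seq_len(nrow(cohort))
  # uncorrected: measured coefficients; AA gated on the eye's SE sign
  unc <- block(all_idx, z, "uncorrected", NA_real_,
               cohort$va_uncorrected_logmar,
               ifelse(is.finite(se) & se < 0, cohort$aa_d, 0))
  # corrected: second-order terms zeroed
  zc <- z; zc[, c("z3", "z4", "z5")] <- 0
  cor <- block(all_idx, zc, "corrected", 0, cohort$va_corrected_logmar, 0)
  # defocus curve: dominant eyes only, astigmatism zeroed, z4 per level
  dom <- which(cohort$dominant == 1)
  def <- NULL
  if (length(dom)) {
    blocks <- lapply(defocus_levels(), function(d) {
      zd <- z[dom, , drop = FALSE]
      zd[, c("z3", "z5")] <- 0
      zd[, "z4"] <- diopter_to_z20(d, cohort$pupil_radius_mm[dom])
      col <- paste0("va_defocus_", sprintf("%+.2f", d))
      va <- if (col %in% names(cohort)) cohort[[col]][dom]
            else rep(NA_real_, length(dom))
      block(dom, zd, "defocus", d, va, if (d < 0) cohort$aa_d[dom] else 0)
    })
    def <- do.call(rbind, blocks)
  }
  tab <- rbind(unc, cor, def)
  keep <- !is.na(tab$va)
  res <- tab[keep, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_built") <- nrow(tab)
  attr(res, "n_dropped") <- sum(!keep)
  res
}

#' Feature matrix for the boosting models
#'
#' @param table Observation table from [build_observation_table()].
#' @param k_zernike Zernike subset size, see [zernike_subset()].
#' @param use_aa Include the gated amplitude of accommodation.
#' @param use_age Include age (default TRUE).
#' @return Numeric matrix with named columns.
#' @export
observation_features <- function(table, k_zernike = 9, use_aa = FALSE,
                                 use_age = TRUE) {
  cols <- paste0("z", zernike_subset(k_zernike))
  if (use_age) cols <- c(cols, "age")
  if (use_aa) cols <- c(cols, "aa_gated")
  as.matrix(table[, cols, drop = FALSE])
}

#' Seeded train/test split
#'
#' Uniform random partition without replacement; the test set takes
#' `floor(n * (1 - fraction))` rows (1744 rows at 80/20 give a 348-row test
#' set).
#'
#' @param table Observation table (or any data frame).
#' @param fraction Training fraction (default 0.8).
#' @param seed Integer seed.
#' @return List with `train` and `test` data frames.
#' @export
split_train_test <- function(table, fraction = 0.8, seed = 1) {
  n <- nrow(table)
  if (n < 1) stop("empty table")
  set.seed(seed)
  n_test <- floor(n * (1 - fraction) + 1e-9)  # guard binary-fraction drift
  test_idx <- sample.int(n, n_test)
  list(train = table[setdiff(seq_len(n), test_idx), , drop = FALSE],
       test = table[test_idx, , drop = FALSE])
}

#' Stratify an observation table
#'
#' `"age_bins"` splits into the six inclusive age groups 30-40, 41-44,
#' 45-50, 51-55, 56-60 and 61-65 years. `"se_groups"` first restricts to
#' the original uncorrected measurement rows (the rows reflecting each
#' eye's real refractive state) and groups by spherical equivalent:
#' myopic SE < -0.5 D, emmetropic -0.5 <= SE <= 0.5 D, hyperopic
#' SE > 0.5 D. Rows outside every bin are excluded with a message.
#'
#' @param table Observation table.
#' @param scheme `"age_bins"` or `"se_groups"`.
#' @return Named list of sub-tables.
#' @export
stratify <- function(table, scheme = c("age_bins", "se_groups")) {
  scheme <- match.arg(scheme)
  if (scheme == "age_bins") {
    breaks <- c(30, 41, 45, 51, 56, 61, 66)
    labels <- c("30-40", "41-44", "45-50", "51-55", "56-60", "61-65")
    bin <- cut(table$age, breaks = breaks, labels = labels, right = FALSE)
    if (any(is.na(bin)))
      message(sum(is.na(bin)), " rows outside the 30-65 age range excluded")
    split(table[!is.na(bin), , drop = FALSE], droplevels(bin[!is.na(bin)]))
  } else {
    tab <- table[table$condition == "uncorrected", , drop = FALSE]
    se <- spherical_equivalent(tab$sphere_d, tab$cylinder_d)
    grp <- ifelse(se < -0.5, "myopic", ifelse(se <= 0.5, "emmetropic", "hyperopic"))
    split(tab, factor(grp, levels = c("myopic", "emmetropic", "hyperopic")))
  }
}
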