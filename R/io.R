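# Cohort CSV reading/writing with schema validation. The schema (one row
# per eye) is: subject_id, eye (OD/OS), dominant (0/1), age, aa_d,
# sphere_d, cylinder_d, va_uncorrected_logmar, va_corrected_logmar,
# va_defocus_-3.00 .. va_defocus_+1.00, z0..z35, pupil_radius_mm.
# Decimal points (not commas), empty fields for missing values, UTF-8.

cohort_schema <- function() {
  c("subject_id", "eye", "dominant", "age", "aa_d", "sphere_d", "cylinder_d",
    "va_uncorrected_logmar", "va_corrected_logmar", defocus_colnames(),
    paste0("z", 0:35), "pupil_radius_mm")
}

#' Write a cohort table to CSV
#'
#' @param cohort Cohort table (see [generate_cohort()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  miss <- setdiff(cohort_schema(), names(cohort))
  if (length(miss)) stop("cohort lacks columns: ", paste(miss, collapse = ", "))
  utils::write.csv(cohort[, cohort_schema()], path, row.names = FALSE,
                   quote = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a cohort CSV
#'
#' Validates the header against the schema, rejects comma-decimal dialects
#' and non-numeric cells with row-level diagnostics, and attaches a
#' validation report: rows with missing VA cells and rows outside the
#' eligibility window (age 30-65, spherical equivalent -7 to +4 D) are
#' flagged as warnings, not errors.
#'
#' @param path CSV path.
#' @return Cohort `data.frame` with attribute `validation` (list with
#'   `n_missing_va` and `out_of_range` row indices).
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                         fileEncoding = "UTF-8")
  miss <- setdiff(cohort_schema(), names(raw))
  if (length(miss))
    stop("malformed header; missing columns: ", paste(miss, collapse = ", "))
  num_cols <- setdiff(cohort_schema(), c("subject_id", "eye"))
  out <- raw
  for (cn in num_cols) {
    v <- trimws(raw[[cn]])
    if (any(grepl(",", v)))
      stop(sprintf("column '%s' uses comma decimals; use '.' as the decimal mark", cn))
    x <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & v != "" & is.na(x))
    if (length(bad))
      stop(sprintf("non-numeric value in column '%s', line %d: '%s'",
                   cn, bad[1] + 1L, v[bad[1]]))
    out[[cn]] <- x
  }
  dom <- out$dominant == 1 & !is.na(out$dominant)
  n_missing <- sum(is.na(out$va_uncorrected_logmar)) +
    sum(is.na(out$va_corrected_logmar)) +
    sum(is.na(as.matrix(out[dom, defocus_colnames()])))
  se <- spherical_equivalent(out$sphere_d, out$cylinder_d)
  oor <- which(out$age < 30 | out$age > 65 | se < -7 | se > 4)
  if (length(oor))
    warning(length(oor), " row(s) outside the eligibility window (age 30-65, SE -7..+4 D)")
  attr(out, "validation") <- list(n_missing_va = n_missing, out_of_range = oor)
  out
}

#' Write a filter curve as two-column CSV
#'
#' @param curve Output of [filter_curve()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_filter_curve <- function(curve, path) {
  utils::write.csv(curve, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
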