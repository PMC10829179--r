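#' Literature-fixed biomarker positivity cutoffs
#'
#' The three analytes are thresholded at previously reported cutoffs:
#' NGAL 38.0 ng/mL, IL-8 20.6 pg/mL, IL-1beta 12.4 pg/mL. Comparison is
#' inclusive ("at or above") for all three. No data-driven cutoff
#' optimization is performed anywhere in the package.
#'
#' @param ngal,il8,il1b Positive cutoffs in the analyte's units.
#' @return Named list of the three cutoffs.
#' @export
default_cutoffs <- function(ngal = 38.0, il8 = 20.6, il1b = 12.4) {
  stopifnot(ngal > 0, il8 > 0, il1b > 0)
  list(ngal = ngal, il8 = il8, il1b = il1b)
}

#' Threshold a biomarker panel and derive consensus calls
#'
#' Each analyte is called positive when its concentration is at or above its
#' cutoff. `consensus` is the 2-of-3 vote (at least two analytes positive);
#' `all_three` requires all three. Values at the assay floor are ordinary
#' numbers below cutoff; no censoring logic applies at call time. A missing
#' concentration is an error naming the analyte -- the panel is never
#' imputed.
#'
#' @param ngal,il8,il1b Numeric concentration vectors (ng/mL, pg/mL, pg/mL).
#' @param cutoffs A [default_cutoffs()] list.
#' @return Tibble with logical columns `ngal_pos`, `il8_pos`, `il1b_pos`,
#'   integer `n_positive`, logical `consensus` and `all_three`.
#' @export
call_panel <- function(ngal, il8, il1b, cutoffs = default_cutoffs()) {
  vals <- list(ngal = ngal, il8 = il8, il1b = il1b)
  n <- unique(lengths(vals))
  if (length(n) != 1) abort("ngal, il8 and il1b must have equal length")
  for (analyte in names(vals)) {
    if (anyNA(vals[[analyte]])) {
      abort(sprintf("missing %s value at position %d; panels are not imputed",
                    analyte, which(is.na(vals[[analyte]]))[1]))
    }
  }
  ngal_pos <- ngal >= cutoffs$ngal
  il8_pos <- il8 >= cutoffs$il8
  il1b_pos <- il1b >= cutoffs$il1b
  n_positive <- as.integer(ngal_pos) + as.integer(il8_pos) + as.integer(il1b_pos)
  tibble(
    ngal_pos = ngal_pos, il8_pos = il8_pos, il1b_pos = il1b_pos,
    n_positive = n_positive,
    consensus = n_positive >= 2L,
    all_three = n_positive == 3L
  )
}

#' Call biomarker panels for a whole cohort
#'
#' Applies [call_panel()] row-wise to a subject table, preserving order and
#' carrying the subject id. A subject with a missing analyte raises an error
#' naming both the analyte and the subject.
#'
#' @param subjects Subject tibble.
#' @param cutoffs A [default_cutoffs()] list.
#' @return Tibble with an `id` column followed by the [call_panel()] columns.
#' @export
call_cohort <- function(subjects, cutoffs = default_cutoffs()) {
  if (nrow(subjects) == 0) {
    out <- call_panel(numeric(), numeric(), numeric(), cutoffs)
    return(tibble(id = character(), !!!out))
  }
  for (analyte in c(ngal = "ngal_ng_ml", il8 = "il8_pg_ml", il1b = "il1b_pg_ml")) {
    bad <- which(is.na(subjects[[analyte]]))
    if (length(bad) > 0) {
      abort(sprintf("subject '%s' has a missing %s value; panels are not imputed",
                    subjects$id[bad[1]], analyte))
    }
  }
  calls <- call_panel(subjects$ngal_ng_ml, subjects$il8_pg_ml,
                      subjects$il1b_pg_ml, cutoffs)
  tibble(id = subjects$id, !!!calls)
}
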