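#' Microbial density criterion for definitive-case classification
#'
#' Two thresholds are in clinical use for significant bacteriuria. Criterion
#' 1 treats a bacterial density of at least 10,000 organisms/mL (cells/mL by
#' M-PCR, CFU/mL by culture) as positive; criterion 2 uses the traditional
#' 100,000 organisms/mL. Under both, any non-zero yeast count is positive.
#' Boundaries are inclusive.
#'
#' @param name `"criterion1"` (10,000, the primary analysis) or
#'   `"criterion2"` (100,000).
#' @return A list with `name`, `bacterial_threshold` and `yeast_rule`.
#' @export
criterion_spec <- function(name = c("criterion1", "criterion2")) {
  name <- match.arg(name)
  list(
    name = name,
    bacterial_threshold = if (name == "criterion1") 1e4 else 1e5,
    yeast_rule = "any non-zero count"
  )
}

#' Classify a symptom questionnaire as asymptomatic
#'
#' A subject is asymptomatic when the four FDA symptom scores (urinary
#' frequency, urgency, dysuria, suprapubic pain) sum to less than 4, none of
#' the four exceeds 1, and there is no visible blood in the urine. All
#' arguments are vectorized; any `NA` score yields `NA` (symptom status
#' unknown).
#'
#' @param freq,urg,dys,pain Integer scores 0--3 for the four FDA symptoms.
#' @param blood Integer score 0--3 for visible blood in urine.
#' @return Logical vector.
#' @export
is_asymptomatic <- function(freq, urg, dys, pain, blood) {
  fda_sum <- freq + urg + dys + pain
  fda_max <- pmax(freq, urg, dys, pain)
  fda_sum < 4 & fda_max <= 1 & blood == 0
}

#' Is a detection modality positive for a subject?
#'
#' A modality is positive when it detected a bacterial density at or above
#' the criterion threshold, or any non-zero yeast density. `NA` densities
#' mean the modality did not report that organism class and never count as
#' positive.
#'
#' @param subjects Subject tibble (see [subject_columns()]).
#' @param modality `"mpcr"` or `"suc"`.
#' @param spec A [criterion_spec()].
#' @return Logical vector, one element per subject.
#' @export
modality_positive <- function(subjects, modality = c("mpcr", "suc"),
                              spec = criterion_spec("criterion1")) {
  modality <- match.arg(modality)
  bact <- subjects[[paste0(modality, "_bact_density")]]
  yeast <- subjects[[paste0(modality, "_yeast_density")]]
  bact_pos <- !is.na(bact) & bact >= spec$bacterial_threshold
  yeast_pos <- !is.na(yeast) & yeast > 0
  bact_pos | yeast_pos
}

#' Microbial detection category per subject
#'
#' @inheritParams modality_positive
#' @return Factor with levels `none`, `single_modality`, `dual`: `dual` when
#'   both M-PCR and culture are positive, `single_modality` when exactly one
#'   is, `none` otherwise.
#' @export
detection_category <- function(subjects, spec = criterion_spec("criterion1")) {
  m <- modality_positive(subjects, "mpcr", spec)
  s <- modality_positive(subjects, "suc", spec)
  out <- ifelse(m & s, "dual", ifelse(m | s, "single_modality", "none"))
  factor(out, levels = c("none", "single_modality", "dual"))
}

#' Assign definitive-case labels
#'
#' Implements the study's case definitions. Asymptomatic-cohort subjects are
#' definitive non-UTI regardless of microbial detection (asymptomatic
#' bacteriuria stays in the control group). Symptomatic-cohort subjects are
#' definitive UTI only when both modalities are positive under the chosen
#' criterion ("Both Detected"); symptomatic subjects without dual detection
#' are retained with label `excluded` so the case funnel is auditable.
#'
#' Symptomatic cohort membership comes from the cohort column, not the
#' symptom scores: biorepository symptomatic subjects carry no questionnaire.
#'
#' @inheritParams modality_positive
#' @return The input tibble with `detection_category` and `case_label`
#'   columns appended. `case_label` is a factor with levels
#'   `definitive_uti`, `definitive_non_uti`, `excluded`.
#' @export
classify_cases <- function(subjects, spec = criterion_spec("criterion1")) {
  det <- detection_category(subjects, spec)
  label <- ifelse(subjects$cohort == "asymptomatic", "definitive_non_uti",
                  ifelse(det == "dual", "definitive_uti", "excluded"))
  subjects$detection_category <- det
  subjects$case_label <- factor(
    label, levels = c("definitive_uti", "definitive_non_uti", "excluded"))
  subjects
}
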