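#' Subject table schema
#'
#' A cohort is a plain tibble with one row per subject. Columns follow the
#' study's per-subject record: identity and demographics, the five acute
#' cystitis symptom scores (four FDA-designated symptoms plus visible blood,
#' each graded 0--3), per-modality semi-quantitative microbial densities
#' (M-PCR in cells/mL, standard urine culture in CFU/mL, bacterial and yeast
#' separately), and the three biomarker concentrations.
#'
#' An empty cell (`NA`) means "not measured": biorepository symptomatic
#' subjects carry no symptom questionnaire, and a modality without a
#' detection is recorded as density 0, not `NA`.
#'
#' @return Character vector of the canonical column names, in order.
#' @export
subject_columns <- function() {
  c("id", "cohort", "age", "sex",
    "freq", "urg", "dys", "pain", "blood",
    "mpcr_bact_density", "mpcr_yeast_density",
    "suc_bact_density", "suc_yeast_density",
    "ngal_ng_ml", "il8_pg_ml", "il1b_pg_ml")
}

subject_col_types <- function() {
  readr::cols(
    id = readr::col_character(),
    cohort = readr::col_character(),
    age = readr::col_double(),
    sex = readr::col_character(),
    freq = readr::col_double(),
    urg = readr::col_double(),
    dys = readr::col_double(),
    pain = readr::col_double(),
    blood = readr::col_double(),
    mpcr_bact_density = readr::col_double(),
    mpcr_yeast_density = readr::col_double(),
    suc_bact_density = readr::col_double(),
    suc_yeast_density = readr::col_double(),
    ngal_ng_ml = readr::col_double(),
    il8_pg_ml = readr::col_double(),
    il1b_pg_ml = readr::col_double()
  )
}

#' Read a subject table from CSV
#'
#' Tolerant-reader policy: unknown extra columns are dropped with a warning;
#' missing schema columns or malformed numeric cells are an error naming the
#' offending location.
#'
#' @param path Path to a CSV file with the [subject_columns()] schema.
#' @return A tibble with exactly the schema columns.
#' @export
read_subjects <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("subject file not found: ", path))
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, show_col_types = FALSE)
  missing <- setdiff(subject_columns(), names(raw))
  if (length(missing) > 0) {
    abort(paste0("subject file is missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  extra <- setdiff(names(raw), subject_columns())
  if (length(extra) > 0) {
    warn(paste0("ignoring unknown column(s): ", paste(extra, collapse = ", ")))
    raw <- raw[subject_columns()]
  }
  raw <- raw[subject_columns()]
  num_cols <- setdiff(subject_columns(), c("id", "cohort", "sex"))
  for (col in num_cols) {
    txt <- raw[[col]]
    parsed <- suppressWarnings(as.numeric(txt))
    bad <- which(!is.na(txt) & txt != "" & is.na(parsed))
    if (length(bad) > 0) {
      abort(sprintf("malformed numeric cell in column '%s', row %d: '%s'",
                    col, bad[1], txt[bad[1]]))
    }
    parsed[!is.na(txt) & txt == ""] <- NA_real_
    raw[[col]] <- parsed
  }
  as_tibble(raw)
}

#' Write a subject table to CSV
#'
#' Inverse of [read_subjects()]: a write/read round trip preserves every
#' field. Output is deterministic for identical input.
#'
#' @param subjects Subject tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_subjects <- function(subjects, path) {
  stopifnot(is.data.frame(subjects))
  missing <- setdiff(subject_columns(), names(subjects))
  if (length(missing) > 0) {
    abort(paste0("subject table is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  readr::write_csv(subjects[subject_columns()], path, na = "", progress = FALSE)
  invisible(path)
}

#' Validate a subject table against the domain rules
#'
#' Checks, per subject: symptom scores in 0--3; densities non-negative;
#' biomarker values non-negative and below generous assay ceilings
#' (NGAL 500 ng/mL, IL-8 2000 pg/mL, IL-1beta 2500 pg/mL); cohort and sex
#' drawn from their enumerations; unique ids; age at or above the study
#' minimum. Validation reports violations, it never raises.
#'
#' @param subjects Subject tibble.
#' @param min_age Minimum enrolment age (default 60, the study population).
#' @return Tibble with columns `id`, `field`, `rule`; zero rows when the
#'   table is fully valid.
#' @export
validate_subjects <- function(subjects, min_age = 60) {
  v <- list()
  add <- function(ids, field, rule) {
    if (length(ids) > 0) {
      v[[length(v) + 1]] <<- tibble(id = as.character(ids), field = field, rule = rule)
    }
  }
  dup <- subjects$id[duplicated(subjects$id)]
  add(unique(dup), "id", "id must be unique within a cohort file")
  add(subjects$id[!subjects$cohort %in% c("symptomatic", "asymptomatic")],
      "cohort", "cohort must be 'symptomatic' or 'asymptomatic'")
  add(subjects$id[!is.na(subjects$sex) & !subjects$sex %in% c("female", "male", "unknown")],
      "sex", "sex must be 'female', 'male' or 'unknown'")
  add(subjects$id[!is.na(subjects$age) & subjects$age < min_age],
      "age", sprintf("age must be >= %g", min_age))
  for (col in c("freq", "urg", "dys", "pain", "blood")) {
    x <- subjects[[col]]
    add(subjects$id[!is.na(x) & !(x %in% 0:3)],
        col, "symptom score must be an integer in 0..3")
  }
  for (col in c("mpcr_bact_density", "mpcr_yeast_density",
                "suc_bact_density", "suc_yeast_density")) {
    x <- subjects[[col]]
    add(subjects$id[!is.na(x) & x < 0], col, "density must be >= 0")
  }
  ceilings <- c(ngal_ng_ml = 500, il8_pg_ml = 2000, il1b_pg_ml = 2500)
  for (col in names(ceilings)) {
    x <- subjects[[col]]
    add(subjects$id[!is.na(x) & x < 0], col, "concentration must be >= 0")
    add(subjects$id[!is.na(x) & x > ceilings[[col]]],
        col, sprintf("concentration exceeds assay ceiling %g", ceilings[[col]]))
  }
  if (length(v) == 0) {
    tibble(id = character(), field = character(), rule = character())
  } else {
    dplyr::bind_rows(v)
  }
}
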