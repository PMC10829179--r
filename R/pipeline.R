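#' Run the full biomarker evaluation pipeline
#'
#' Chains the analysis stages on one subject table: validation, case
#' labelling under the chosen density criterion, biomarker calls, 2x2
#' tables and diagnostic performance for the five classifiers (three
#' individual markers, 2-of-3 consensus, all-three), probit dose-response
#' fits per modality for each classifier, descriptive summaries per
#' comparison group (definitive UTI; non-UTI split by detection category)
#' and rank-based group comparisons.
#'
#' The report is a plain list, pure in its inputs: running the same
#' configuration twice yields identical output.
#'
#' @param subjects Subject tibble (e.g. from [read_subjects()]).
#' @param criterion `"criterion1"` or `"criterion2"`.
#' @param cutoffs A [default_cutoffs()] list.
#' @param level Confidence level for all intervals.
#' @return A `uromarker_report` list with elements `provenance`, `funnel`,
#'   `performance`, `probit`, `descriptives`, `group_comparisons`.
#' @export
run_pipeline <- function(subjects, criterion = "criterion1",
                         cutoffs = default_cutoffs(), level = 0.95) {
  violations <- validate_subjects(subjects)
  if (nrow(violations) > 0) {
    abort(sprintf("subject table fails validation (%d violation(s); first: %s/%s: %s)",
                  nrow(violations), violations$id[1], violations$field[1],
                  violations$rule[1]))
  }
  spec <- criterion_spec(criterion)
  labeled <- classify_cases(subjects, spec)
  n_uti <- sum(labeled$case_label == "definitive_uti")
  n_non <- sum(labeled$case_label == "definitive_non_uti")
  if (n_uti == 0 || n_non == 0) {
    abort("empty analyzable set: need at least one definitive UTI and one definitive non-UTI subject")
  }
  calls <- call_cohort(labeled, cutoffs)

  classifiers <- c(ngal = "ngal_pos", il8 = "il8_pos", il1b = "il1b_pos",
                   consensus = "consensus", all_three = "all_three")
  performance <- lapply(classifiers, function(col) {
    ct <- suppressMessages(build_contingency(labeled$case_label, calls[[col]]))
    list(contingency = ct, performance = dx_performance(ct, level = level))
  })

  probit <- lapply(c(mpcr = "mpcr", suc = "suc"), function(mod) {
    dens <- max_density(labeled, mod)
    bins <- standard_bins(mod)
    lapply(classifiers, function(col) {
      tryCatch(fit_probit(dens, calls[[col]], bins),
               error = function(e) list(error = conditionMessage(e)))
    })
  })

  groups <- list(
    definitive_uti = labeled$case_label == "definitive_uti",
    non_uti_no_microbes = labeled$case_label == "definitive_non_uti" &
      labeled$detection_category == "none",
    non_uti_single = labeled$case_label == "definitive_non_uti" &
      labeled$detection_category == "single_modality",
    non_uti_dual = labeled$case_label == "definitive_non_uti" &
      labeled$detection_category == "dual"
  )
  markers <- c(ngal = "ngal_ng_ml", il8 = "il8_pg_ml", il1b = "il1b_pg_ml")
  descriptives <- lapply(markers, function(col) {
    lapply(groups, function(g) {
      if (sum(g) >= 2) describe(labeled[[col]][g], level = level) else NULL
    })
  })
  group_comparisons <- lapply(markers, function(col) {
    a <- labeled[[col]][labeled$case_label == "definitive_uti"]
    b <- labeled[[col]][labeled$case_label == "definitive_non_uti"]
    list(comparison = "definitive_uti vs all definitive_non_uti",
         p_value = group_compare(a, b))
  })

  structure(list(
    provenance = list(
      package = "uromarker",
      version = as.character(utils::packageVersion("uromarker")),
      criterion = spec$name, cutoffs = cutoffs, level = level,
      n_subjects = nrow(subjects)
    ),
    funnel = list(
      n_symptomatic = sum(subjects$cohort == "symptomatic"),
      n_asymptomatic = sum(subjects$cohort == "asymptomatic"),
      n_definitive_uti = n_uti,
      n_definitive_non_uti = n_non,
      n_excluded = sum(labeled$case_label == "excluded")
    ),
    performance = performance,
    probit = probit,
    descriptives = descriptives,
    group_comparisons = group_comparisons
  ), class = "uromarker_report")
}

report_to_list <- function(x) {
  strip <- function(obj) {
    if (inherits(obj, "estimate_ci")) {
      list(estimate = obj$estimate, lower = obj$lower, upper = obj$upper,
           level = obj$level)
    } else if (inherits(obj, "contingency")) {
      list(tp = obj$tp, fp = obj$fp, fn = obj$fn, tn = obj$tn,
           n_excluded = obj$n_excluded)
    } else if (inherits(obj, "probit_fit")) {
      list(intercept = obj$intercept, slope = obj$slope,
           slope_se = obj$slope_se, slope_p_value = obj$slope_p_value,
           r_squared = obj$r_squared, n_bins = obj$n_bins, n = obj$n,
           binned = as.data.frame(obj$binned))
    } else if (inherits(obj, "dx_performance")) {
      lapply(obj[c("sensitivity", "specificity", "ppv", "npv", "accuracy",
                   "lr_plus", "lr_minus")], strip)
    } else if (is.data.frame(obj)) {
      as.data.frame(obj)
    } else if (is.list(obj)) {
      lapply(obj, strip)
    } else {
      obj
    }
  }
  strip(unclass(x))
}

#' Write a pipeline report as JSON
#'
#' Keys are stable across versions; numbers keep full precision. Output is
#' byte-identical for identical reports.
#'
#' @param report A `uromarker_report` from [run_pipeline()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "uromarker_report"))
  jsonlite::write_json(report_to_list(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}
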