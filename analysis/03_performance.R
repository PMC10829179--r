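#!/usr/bin/env Rscript
# Stage 3: diagnostic performance of the five classifiers.
# First on the deterministic study-pattern cohort (whose 2x2 tables equal
# the published contingency tables), then on the simulated cohort from
# stages 1-2, for comparison.
suppressPackageStartupMessages(library(uromarker))

perf_table <- function(subjects, label) {
  lab <- classify_cases(subjects)
  calls <- call_cohort(lab)
  classifiers <- c(ngal = "ngal_pos", il8 = "il8_pos", il1b = "il1b_pos",
                   consensus = "consensus", all_three = "all_three")
  rows <- lapply(names(classifiers), function(nm) {
    ct <- suppressMessages(build_contingency(lab$case_label, calls[[classifiers[[nm]]]]))
    p <- dx_performance(ct)
    tibble::tibble(
      cohort = label, classifier = nm,
      tp = ct$tp, fp = ct$fp, fn = ct$fn, tn = ct$tn,
      sensitivity = p$sensitivity$estimate, sens_lo = p$sensitivity$lower,
      sens_hi = p$sensitivity$upper,
      specificity = p$specificity$estimate, spec_lo = p$specificity$lower,
      spec_hi = p$specificity$upper,
      ppv = p$ppv$estimate, npv = p$npv$estimate, accuracy = p$accuracy$estimate,
      lr_plus = p$lr_plus$estimate, lr_minus = p$lr_minus$estimate)
  })
  dplyr::bind_rows(rows)
}

fixture <- perf_table(study_pattern_fixture(), "study_pattern")
simulated <- perf_table(read_subjects("results/subjects.csv"), "simulated")
out <- dplyr::bind_rows(fixture, simulated)
readr::write_csv(out, "results/performance.csv")

cat("Study-pattern cohort (counts equal the published tables):\n\n")
fx <- classify_cases(study_pattern_fixture())
print(dx_performance(suppressMessages(
  build_contingency(fx$case_label, call_cohort(fx)$consensus))))
cat("\nConsensus on the simulated cohort:\n\n")
sim <- classify_cases(read_subjects("results/subjects.csv"))
print(dx_performance(suppressMessages(
  build_contingency(sim$case_label, call_cohort(sim)$consensus))))

# sensitivity comparisons between classifiers (pooled two-proportion z)
cat("\nSensitivity comparisons (study-pattern counts, two-proportion z):\n")
sens <- c(ngal = 290, il8 = 320, il1b = 245, consensus = 295)
for (pair in list(c("ngal", "il8"), c("il1b", "il8"), c("consensus", "all3" ))) {
  if (pair[2] == "all3") { k2 <- 232; nm2 <- "all_three" } else { k2 <- sens[[pair[2]]]; nm2 <- pair[2] }
  zt <- two_proportion_z(sens[[pair[1]]], 351, k2, 351)
  cat(sprintf("  %s vs %s: z = %.3f, p = %.3g\n", pair[1], nm2,
              zt$statistic, zt$p_value))
}
cat("\nWrote results/performance.csv\n")
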