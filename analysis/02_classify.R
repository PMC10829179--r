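#!/usr/bin/env Rscript
# Stage 2: apply the dual-modality case definitions to the simulated cohort
# under both density criteria and report the case funnel.
suppressPackageStartupMessages(library(uromarker))

subjects <- read_subjects("results/subjects.csv")

for (crit in c("criterion1", "criterion2")) {
  lab <- classify_cases(subjects, criterion_spec(crit))
  cat(sprintf("\n%s (bacterial threshold %s organisms/mL):\n", crit,
              format(criterion_spec(crit)$bacterial_threshold, big.mark = ",")))
  print(table(lab$cohort, lab$case_label))
  if (crit == "criterion1") {
    readr::write_csv(lab, "results/labeled.csv")
  }
}
cat("\nWrote results/labeled.csv (criterion 1 labels)\n")
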