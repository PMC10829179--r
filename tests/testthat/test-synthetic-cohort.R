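test_that("default configuration encodes the study conditions", {
  cfg <- default_config()
  expect_identical(cfg$n_symptomatic, 583L)
  expect_identical(cfg$n_asymptomatic, 228L)
  expect_equal(cfg$floors[["ngal"]], 0.16)
  expect_equal(cfg$floors[["il1b"]], 3.9)
  expect_equal(cfg$ceilings[["ngal"]], 500)
  probs <- c(cfg$p_sym_dual, cfg$p_sym_single, cfg$p_asym_any_detection,
             cfg$p_asym_dual, cfg$p_single_mpcr, cfg$p_female)
  expect_true(all(probs >= 0 & probs <= 1))
  expect_lte(cfg$p_asym_dual, cfg$p_asym_any_detection)
  for (w in cfg$density_bin_weights) expect_equal(sum(w), 1)
})

test_that("invalid configurations fail before any sampling", {
  cfg <- default_config()
  cfg$p_asym_dual <- 0.9
  expect_error(generate_cohort(cfg), "p_asym_dual")
  cfg2 <- default_config()
  cfg2$density_bin_weights$symptomatic <- c(0.5, 0.5, 0.5, 0, 0)
  expect_error(generate_cohort(cfg2), "sum to 1")
  cfg3 <- default_config()
  cfg3$n_symptomatic <- 0L
  expect_error(generate_cohort(cfg3), "at least 1")
})

test_that("generation is deterministic given the seed, down to the CSV bytes", {
  g1 <- generate_cohort(default_config(seed = 12))
  g2 <- generate_cohort(default_config(seed = 12))
  expect_identical(g1$subjects, g2$subjects)
  expect_identical(g1$truth, g2$truth)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_subjects(g1$subjects, p1)
  write_subjects(g2$subjects, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  g3 <- generate_cohort(default_config(seed = 13))
  expect_false(identical(g1$subjects, g3$subjects))
})

test_that("generated subjects are valid and aligned with their truth records", {
  g <- generate_cohort(default_config(seed = 3))
  expect_identical(nrow(validate_subjects(g$subjects)), 0L)
  expect_identical(g$truth$id, g$subjects$id)
  expect_identical(nrow(g$subjects), 583L + 228L)
  # intended positivity matches thresholded values exactly (truncation draws)
  calls <- call_cohort(g$subjects)
  expect_identical(calls$ngal_pos, g$truth$ngal_pos)
  expect_identical(calls$il8_pos, g$truth$il8_pos)
  expect_identical(calls$il1b_pos, g$truth$il1b_pos)
  # asymptomatic volunteers carry questionnaire scores satisfying the rule;
  # biorepository symptomatic subjects carry none
  asym <- g$subjects[g$subjects$cohort == "asymptomatic", ]
  expect_true(all(is_asymptomatic(asym$freq, asym$urg, asym$dys, asym$pain,
                                  asym$blood)))
  sym <- g$subjects[g$subjects$cohort == "symptomatic", ]
  expect_true(all(is.na(sym$freq)))
  # biomarker floors and ceilings are respected
  expect_true(all(g$subjects$ngal_ng_ml >= 0.16 & g$subjects$ngal_ng_ml <= 500))
  expect_true(all(g$subjects$il1b_pg_ml >= 3.9 & g$subjects$il1b_pg_ml <= 2500))
})

test_that("a zero-slope configuration yields flat positivity across bins", {
  cfg <- default_config(seed = 9)
  cfg$probit$symptomatic$slope <- 0
  cfg$probit$symptomatic$latent_sd <- 0
  cfg$probit$symptomatic$intercept <- c(ngal = 0, il8 = 0, il1b = 0)
  cfg$n_symptomatic <- 4000L
  g <- generate_cohort(cfg)
  sym <- g$subjects[g$subjects$cohort == "symptomatic", ]
  calls <- call_cohort(sym)
  bp <- bin_positivity(max_density(sym, "mpcr"), calls$ngal_pos)
  # every bin proportion near 0.5 within binomial noise
  expect_true(all(abs(bp$proportion - 0.5) < 4 * sqrt(0.25 / bp$n)))
})

test_that("pipeline closure: generate -> classify -> call -> evaluate over random configs", {
  set.seed(77)
  for (i in 1:5) {
    cfg <- default_config(seed = i)
    cfg$n_symptomatic <- sample(50:150, 1)
    cfg$n_asymptomatic <- sample(50:150, 1)
    cfg$p_sym_dual <- runif(1, 0.3, 0.8)
    cfg$p_asym_dual <- runif(1, 0.1, 0.3)
    cfg$p_asym_any_detection <- cfg$p_asym_dual + runif(1, 0.1, 0.3)
    g <- generate_cohort(cfg)
    lab <- classify_cases(g$subjects)
    calls <- call_cohort(lab)
    ct <- suppressMessages(build_contingency(lab$case_label, calls$consensus))
    perf <- suppressWarnings(dx_performance(ct))
    expect_s3_class(perf, "dx_performance")
    expect_identical(ct_total <- ct$tp + ct$fp + ct$fn + ct$tn + ct$n_excluded,
                     nrow(g$subjects))
  }
})

test_that("study-pattern fixture reproduces all five published 2x2 tables", {
  fx <- study_pattern_fixture()
  expect_identical(nrow(fx), 579L)
  expect_identical(nrow(validate_subjects(fx)), 0L)
  lab <- classify_cases(fx)
  expect_identical(sum(lab$case_label == "definitive_uti"), 351L)
  expect_identical(sum(lab$case_label == "definitive_non_uti"), 228L)
  det <- table(lab$detection_category[lab$cohort == "asymptomatic"])
  expect_identical(as.integer(det[c("dual", "single_modality", "none")]),
                   c(66L, 56L, 106L))
  calls <- call_cohort(fx)
  expected <- list(
    ngal_pos = c(290L, 21L, 61L, 207L),
    il8_pos = c(320L, 53L, 31L, 175L),
    il1b_pos = c(245L, 7L, 106L, 221L),
    consensus = c(295L, 20L, 56L, 208L),
    all_three = c(232L, 6L, 119L, 222L)
  )
  for (col in names(expected)) {
    ct <- build_contingency(lab$case_label, calls[[col]])
    expect_identical(c(ct$tp, ct$fp, ct$fn, ct$tn), expected[[col]],
                     info = col)
  }
})
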