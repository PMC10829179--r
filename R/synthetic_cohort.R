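#' Default synthetic-cohort generator configuration
#'
#' Encodes the study conditions the generator emulates: 583 symptomatic
#' subjects recruited through a urology biorepository (no symptom
#' questionnaire) and 228 asymptomatic community volunteers; a 351/583
#' dual-detection rate among symptomatic subjects; asymptomatic detection
#' rates of 53.1% by either modality and 28.9% by both; heavily
#' right-skewed biomarker distributions with hard assay floors (NGAL 0.16
#' ng/mL, IL-1beta 3.9 pg/mL) and ceilings (NGAL 500, IL-8 2000); and a
#' monotone probit link between log10 microbial density and the
#' probability that each biomarker exceeds its cutoff.
#'
#' Cross-biomarker dependence beyond shared density is induced by a
#' standard-normal per-subject latent inflammation factor entering each
#' marker's probit linear predictor with cohort-specific loading
#' (`latent_sd`). Link intercepts were calibrated once, analytically,
#' so the end-to-end marginal positivity rates of the three markers and of
#' the 2-of-3 consensus match the study's observed rates (see the methods
#' vignette).
#'
#' @param seed Integer seed; the single source of randomness for
#'   [generate_cohort()].
#' @return A `generator_config` list.
#' @export
default_config <- function(seed = 1L) {
  structure(list(
    n_symptomatic = 583L,
    n_asymptomatic = 228L,
    p_sym_dual = 351 / 583,
    p_sym_single = 0.25,
    p_asym_any_detection = 0.531,
    p_asym_dual = 0.289,
    # single-modality detections are mostly PCR-only: culture under-detects
    p_single_mpcr = 0.8,
    # weights over the five detected M-PCR bins [1e4,1e5) ... [1e8, Inf)
    density_bin_weights = list(
      symptomatic = c(0.20, 0.25, 0.20, 0.175, 0.175),
      asymptomatic = c(0.60, 0.30, 0.10, 0.00, 0.00)
    ),
    probit = list(
      symptomatic = list(
        intercept = c(ngal = -1.954, il8 = -1.144, il1b = -2.787),
        slope = 0.6, latent_sd = 1.5),
      asymptomatic = list(
        intercept = c(ngal = -4.952, il8 = -3.593, il1b = -6.188),
        slope = 0.45, latent_sd = 2.0)
    ),
    # truncated log-normal (meanlog, sdlog) per cohort, marker and call state
    biomarker_lognormal = list(
      symptomatic = list(
        ngal = list(pos = c(5.5, 1.2), neg = c(1.6, 1.5)),
        il8 = list(pos = c(6.0, 1.3), neg = c(0.5, 1.5)),
        il1b = list(pos = c(4.1, 1.2), neg = c(0.5, 1.5))),
      asymptomatic = list(
        ngal = list(pos = c(4.0, 0.8), neg = c(-1.0, 2.0)),
        il8 = list(pos = c(4.0, 1.0), neg = c(0.0, 1.5)),
        il1b = list(pos = c(2.8, 0.5), neg = c(0.3, 1.2)))
    ),
    floors = c(ngal = 0.16, il8 = 0, il1b = 3.9),
    lod = c(ngal = 0.16, il8 = 0.1, il1b = 3.9),
    ceilings = c(ngal = 500, il8 = 2000, il1b = 2500),
    cutoffs = default_cutoffs(),
    age = list(symptomatic = c(mean = 76.6, sd = 8, min = 60, max = 99),
               asymptomatic = c(mean = 68.8, sd = 7, min = 60, max = 94)),
    p_female = c(symptomatic = 0.683, asymptomatic = 0.557),
    seed = as.integer(seed)
  ), class = "generator_config")
}

validate_config <- function(config) {
  probs <- c(config$p_sym_dual, config$p_sym_single,
             config$p_asym_any_detection, config$p_asym_dual,
             config$p_single_mpcr, config$p_female)
  if (any(probs < 0 | probs > 1)) abort("config probabilities must lie in [0, 1]")
  if (config$p_asym_dual > config$p_asym_any_detection) {
    abort("p_asym_dual cannot exceed p_asym_any_detection")
  }
  if (config$p_sym_dual + config$p_sym_single > 1) {
    abort("p_sym_dual + p_sym_single cannot exceed 1")
  }
  for (w in config$density_bin_weights) {
    if (any(w < 0) || abs(sum(w) - 1) > 1e-8) {
      abort("density bin weights must be non-negative and sum to 1")
    }
  }
  if (config$n_symptomatic < 1 || config$n_asymptomatic < 1) {
    abort("cohort sizes must be at least 1")
  }
  invisible(config)
}

rlnorm_trunc <- function(n, meanlog, sdlog, lower, upper) {
  p_lo <- plnorm(lower, meanlog, sdlog)
  p_hi <- plnorm(upper, meanlog, sdlog)
  qlnorm(runif(n, p_lo, p_hi), meanlog, sdlog)
}

# draw a value consistent with the intended call state, then apply assay
# floor/ceiling censoring (which never flips the state: the ceiling is above
# the cutoff and the floor below it)
draw_marker_values <- function(pos, params, cutoff, floor, lod, ceiling) {
  n <- length(pos)
  out <- numeric(n)
  if (any(pos)) {
    out[pos] <- pmin(rlnorm_trunc(sum(pos), params$pos[1], params$pos[2],
                                  cutoff, Inf), ceiling)
  }
  if (any(!pos)) {
    v <- rlnorm_trunc(sum(!pos), params$neg[1], params$neg[2], 0, cutoff)
    v[v < lod] <- floor
    out[!pos] <- v
  }
  out
}

generate_one_cohort <- function(cohort, n, config, bins) {
  p_dual <- if (cohort == "symptomatic") config$p_sym_dual else config$p_asym_dual
  p_single <- if (cohort == "symptomatic") {
    config$p_sym_single
  } else {
    config$p_asym_any_detection - config$p_asym_dual
  }
  detection <- sample(c("dual", "single_modality", "none"), n, replace = TRUE,
                      prob = c(p_dual, p_single, 1 - p_dual - p_single))
  detected <- detection != "none"
  # detected bins are rows 2..6 of the M-PCR bin table
  w <- config$density_bin_weights[[cohort]]
  bin_idx <- rep(1L, n)
  bin_idx[detected] <- 1L + sample.int(length(w), sum(detected),
                                       replace = TRUE, prob = w)
  x <- bins$x[bin_idx]
  # a point density drawn log-uniformly within the bin (top bin: one decade)
  density <- numeric(n)
  if (any(detected)) {
    lo <- bins$lower[bin_idx[detected]]
    hi <- pmin(bins$upper[bin_idx[detected]], 10 * lo)
    density[detected] <- 10^runif(sum(detected), log10(lo), log10(hi))
  }

  mpcr_first <- runif(n) < config$p_single_mpcr  # modality of a single detection
  mpcr <- ifelse(detection == "dual" | (detection == "single_modality" & mpcr_first),
                 density, 0)
  suc <- ifelse(detection == "dual" | (detection == "single_modality" & !mpcr_first),
                density, 0)

  link <- config$probit[[cohort]]
  u <- rnorm(n)
  pos <- lapply(c(ngal = "ngal", il8 = "il8", il1b = "il1b"), function(m) {
    runif(n) < pnorm(link$intercept[[m]] + link$slope * x + link$latent_sd * u)
  })
  vals <- lapply(names(pos), function(m) {
    draw_marker_values(pos[[m]], config$biomarker_lognormal[[cohort]][[m]],
                       config$cutoffs[[m]], config$floors[[m]],
                       config$lod[[m]], config$ceilings[[m]])
  })
  names(vals) <- names(pos)

  ag <- config$age[[cohort]]
  age <- round(pmin(pmax(rnorm(n, ag[["mean"]], ag[["sd"]]), ag[["min"]]),
                    ag[["max"]]), 1)
  sex <- ifelse(runif(n) < config$p_female[[cohort]], "female", "male")

  if (cohort == "asymptomatic") {
    # volunteers fill the questionnaire; scores drawn to satisfy the
    # asymptomatic rule (sum of the four FDA scores < 4, none > 1, no blood)
    sc <- matrix(as.numeric(runif(4 * n) < 0.15), ncol = 4)
    over <- rowSums(sc) >= 4
    sc[over, 4] <- 0
    freq <- sc[, 1]; urg <- sc[, 2]; dys <- sc[, 3]; pain <- sc[, 4]
    blood <- rep(0, n)
  } else {
    # biorepository records carry no questionnaire
    freq <- urg <- dys <- pain <- blood <- rep(NA_real_, n)
  }

  prefix <- if (cohort == "symptomatic") "S" else "A"
  subjects <- tibble(
    id = sprintf("%s%04d", prefix, seq_len(n)),
    cohort = cohort, age = age, sex = sex,
    freq = freq, urg = urg, dys = dys, pain = pain, blood = blood,
    mpcr_bact_density = mpcr, mpcr_yeast_density = 0,
    suc_bact_density = suc, suc_yeast_density = 0,
    ngal_ng_ml = vals$ngal, il8_pg_ml = vals$il8, il1b_pg_ml = vals$il1b
  )
  truth <- tibble(
    id = subjects$id, cohort = cohort, detection = detection,
    bin_label = bins$label[bin_idx], x = x, latent = u,
    ngal_pos = pos$ngal, il8_pos = pos$il8, il1b_pos = pos$il1b
  )
  list(subjects = subjects, truth = truth)
}

#' Generate a synthetic two-cohort study
#'
#' Deterministic given `config$seed`; the returned subjects pass
#' [validate_subjects()] and the `truth` table records the generating state
#' (detection category, density bin, latent factor, intended per-marker
#' positivity) aligned one-to-one with the subjects.
#'
#' @param config A [default_config()] list, possibly modified.
#' @return A `generated_cohort`: list with tibbles `subjects` and `truth`.
#' @export
generate_cohort <- function(config = default_config()) {
  validate_config(config)
  bins <- standard_bins("mpcr")
  withr::with_seed(config$seed, {
    sym <- generate_one_cohort("symptomatic", config$n_symptomatic, config, bins)
    asym <- generate_one_cohort("asymptomatic", config$n_asymptomatic, config, bins)
  })
  structure(list(
    subjects = dplyr::bind_rows(sym$subjects, asym$subjects),
    truth = dplyr::bind_rows(sym$truth, asym$truth),
    config = config
  ), class = "generated_cohort")
}

# joint positivity patterns (ngal, il8, il1b) consistent with all five
# published 2x2 tables at once; any joint with these margins is equivalent
# for every downstream statistic computed here
study_pattern_counts <- function() {
  pat <- expand.grid(ngal = c(TRUE, FALSE), il8 = c(TRUE, FALSE),
                     il1b = c(TRUE, FALSE))
  key <- paste0(as.integer(pat$ngal), as.integer(pat$il8), as.integer(pat$il1b))
  uti <- c("111" = 232, "110" = 50, "101" = 0, "011" = 13,
           "100" = 8, "010" = 25, "001" = 0, "000" = 23)
  non <- c("111" = 6, "110" = 13, "101" = 0, "011" = 1,
           "100" = 2, "010" = 33, "001" = 0, "000" = 173)
  list(patterns = pat[match(names(uti), key), ], uti = uti, non = non)
}

#' Deterministic fixture reproducing the study's contingency structure
#'
#' Builds 579 analyzable subjects -- 351 dual-detection symptomatic
#' (definitive UTI) and 228 asymptomatic (definitive non-UTI, of whom 66
#' are dual-detected, 56 single-modality and 106 microbe-free) -- whose
#' per-classifier 2x2 tables against the case labels equal the published
#' tables exactly for NGAL, IL-8, IL-1beta, the 2-of-3 consensus and the
#' all-three rule simultaneously. Only the margins of the joint
#' cross-classifier distribution are published; the joint used here is one
#' fixed allocation consistent with all of them.
#'
#' Marker concentrations are representative constants (the published group
#' medians for positives, floor-level values for negatives), so the fixture
#' exercises thresholding, not distributional shape.
#'
#' @return Subject tibble of 579 rows.
#' @export
study_pattern_fixture <- function() {
  sp <- study_pattern_counts()
  rep_val <- list(
    ngal = c(pos = 211.09, neg = 0.16),
    il8 = c(pos = 355.32, neg = 0.34),
    il1b = c(pos = 47.07, neg = 3.9)
  )
  build <- function(counts) {
    idx <- rep(seq_len(nrow(sp$patterns)), counts)
    tibble(
      ngal_ng_ml = ifelse(sp$patterns$ngal[idx], rep_val$ngal[["pos"]], rep_val$ngal[["neg"]]),
      il8_pg_ml = ifelse(sp$patterns$il8[idx], rep_val$il8[["pos"]], rep_val$il8[["neg"]]),
      il1b_pg_ml = ifelse(sp$patterns$il1b[idx], rep_val$il1b[["pos"]], rep_val$il1b[["neg"]])
    )
  }
  uti_markers <- build(sp$uti)
  non_markers <- build(sp$non)
  dens <- 5e4
  uti <- tibble(
    id = sprintf("U%04d", seq_len(351)), cohort = "symptomatic",
    age = 76.3, sex = "female",
    freq = NA_real_, urg = NA_real_, dys = NA_real_, pain = NA_real_,
    blood = NA_real_,
    mpcr_bact_density = dens, mpcr_yeast_density = 0,
    suc_bact_density = dens, suc_yeast_density = 0,
    !!!uti_markers
  )
  det <- rep(c("dual", "single_modality", "none"), c(66, 56, 106))
  non <- tibble(
    id = sprintf("N%04d", seq_len(228)), cohort = "asymptomatic",
    age = 67.5, sex = "female",
    freq = 0, urg = 0, dys = 0, pain = 0, blood = 0,
    mpcr_bact_density = ifelse(det == "none", 0, dens),
    mpcr_yeast_density = 0,
    suc_bact_density = ifelse(det == "dual", dens, 0),
    suc_yeast_density = 0,
    !!!non_markers
  )
  dplyr::bind_rows(uti, non)
}
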