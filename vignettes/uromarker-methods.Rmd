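---
title: "Methods: biomarker-based discrimination of UTI from asymptomatic bacteriuria"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: biomarker-based discrimination of UTI from asymptomatic bacteriuria}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uromarker)
```

## The problem

Standard urine culture (SUC) under-detects fastidious and non-*E. coli*
uropathogens, while highly sensitive molecular tests such as multiplex PCR
(M-PCR) detect organisms even in people without urinary symptoms.
Asymptomatic bacteriuria is common in adults 60 and older, so microbial
detection alone cannot separate an active urinary tract infection (UTI)
from harmless colonization. Infection-associated urinary biomarkers —
neutrophil gelatinase-associated lipocalin (NGAL), interleukin-8 (IL-8)
and interleukin-1β (IL-1β) — report on host inflammation rather than
microbial presence, and are therefore candidates for resolving that
ambiguity.

`uromarker` implements the complete evaluation of such a three-marker
panel on a two-cohort design: a symptomatic cohort drawn from a urology
biorepository and an asymptomatic community-volunteer cohort, both aged 60
or older, each subject tested side-by-side by M-PCR (cells/mL) and SUC
(CFU/mL) and assayed for the three biomarkers by ELISA.

## Case definitions

Symptom status is operationalized by the Acute Cystitis Symptom Score:
four FDA-designated symptoms (frequency, urgency, dysuria, suprapubic
pain) plus visible blood, each graded 0–3. A subject is *asymptomatic*
when the four FDA scores sum to less than 4, none exceeds 1 (mild), and
there is no visible blood. Biorepository subjects carry no questionnaire;
their symptomatic status is cohort membership itself.

A modality is *positive* when it detects a bacterial density at or above
the criterion threshold — 10,000 organisms/mL for the primary criterion 1,
100,000 for the supplemental criterion 2 — or any non-zero yeast count.
Both M-PCR cells/mL and SUC CFU/mL are treated as densities on the same
log scale, because identical thresholds apply to both. Thresholds are
inclusive: the operative definitions say "at or above", and the package's
density bins are half-open `[lower, upper)` so that 10^4 is an exact bin
boundary.

- **Definitive UTI**: symptomatic cohort, positive by *both* modalities.
- **Definitive non-UTI**: the entire asymptomatic cohort, with or without
  detectable microbes — asymptomatic bacteriuria deliberately stays in the
  control group, since distinguishing it from UTI is the point.
- Symptomatic subjects without dual detection are *excluded* but retained
  in outputs with an explicit label, so the case funnel is auditable.

## The classifier

Each biomarker is thresholded at a literature-fixed cutoff (NGAL 38.0
ng/mL, IL-8 20.6 pg/mL, IL-1β 12.4 pg/mL; inclusive comparison). No
ROC-based re-optimization is performed. Derived calls:

- *consensus*: at least 2 of the 3 markers positive;
- *all three*: all markers positive.

Panels with a missing analyte raise an error naming the analyte and
subject; the package never imputes.

## Performance statistics

From the 2×2 table of calls against case labels the package computes
sensitivity, specificity, PPV, NPV and accuracy, each with a
Clopper–Pearson exact interval (beta-quantile form; coverage is verified
in the test suite by exhaustive binomial enumeration for n ≤ 30), and the
likelihood ratios LR+ = sens/(1−spec), LR− = (1−sens)/spec with log-scale
Wald intervals.

Two conventions exist for the LR− interval's standard error. The textbook
Katz form uses the negative-call cells,
√(1/fn − 1/(tp+fn) + 1/tn − 1/(fp+tn)). Common diagnostic-report software,
however, reuses the LR+ standard error
√(1/tp − 1/(tp+fn) + 1/fp − 1/(fp+tn)) for LR− as well, and it is that
convention that reproduces the reference report this package validates
against; it is therefore the default (`lr_minus_se = "positive_row"`),
with the textbook form available as `"negative_row"`. The difference is
visible: on the consensus table the default gives (0.11, 0.27) and the
textbook form (0.14, 0.22) around LR− = 0.17.

Zero cells leave a likelihood ratio infinite (or zero) with an undefined
interval and a warning; a 0.5 continuity correction is available as an
explicit flag, never a silent default.

Sensitivities of different classifiers are compared with a pooled,
unpaired, two-sided two-proportion z-test without continuity correction.
That is the stated analysis convention even though classifier
sensitivities computed on the *same* definitive-UTI subjects are paired;
a McNemar-style paired comparison would be more efficient but is out of
scope, and the unpaired test is conservative in the common
positive-dependence case.

Descriptive summaries use type-7 (linear-interpolation) quantiles and a
Student-t interval for the mean, mean ± t(0.975, n−1)·sd/√n — the
convention validated against the reference descriptive table (mean
251.83, SD 193.96, n 351 → CI 231.47–272.19). Group-level biomarker
comparisons use the Mann–Whitney rank-sum test; small tie-free samples
get the exact null distribution and larger or tied samples the
normal approximation with tie correction (the `stats::wilcox.test`
policy), so the small-sample p-values agree with exact enumeration.

The minimal detectable standardized effect size uses the two-sample
normal approximation d = (z₁₋α/₂ + z_power)·√(1/n₁ + 1/n₂); at the study's
351/228 split with α = 0.05 and power 0.80 this is d = 0.24.

## Probit dose–response

Biomarker positivity rises with microbial density. The package bins
subjects by their semi-quantitative density — six M-PCR bins from below
10^4 to 10^8 and above, three SUC bins — and fits a maximum-likelihood
probit regression of the per-subject binary call on x = log10 of the
bin's representative density, P(positive) = Φ(a + b·x).

Design choices, made where the convention was genuinely open:

- **Representative density**: geometric midpoint √(lower·upper) of the
  bin, i.e. the arithmetic midpoint on the log axis; the open-ended bins
  use a half-decade shift (bottom bin upper/√10, top bin lower·√10).
- **Per-subject vs binned fitting**: the default fits per-subject
  Bernoulli outcomes; fitting the aggregated binomial counts per bin
  (`data = "binned"`) gives the identical likelihood and estimates. The
  binned option exists because only binned proportions are visible in a
  dose–response plot.
- **R²**: probit regression has no canonical R²; the package reports the
  squared Pearson correlation between observed bin proportions and fitted
  probabilities at the bin x values, matching how a binned
  positivity-versus-density plot is read.
- **Significance**: the slope's Wald test.
- **Multiple densities per subject**: a subject with bacterial and yeast
  densities (or several organisms) is binned by the maximum density for
  the modality.
- **Degenerate inputs** — all outcomes identical, a single occupied bin,
  or (quasi-)separation — raise errors rather than returning silent
  garbage. The test suite verifies the MLE against a grid-search oracle
  and checks parameter recovery (median slope error below 10% at
  n = 2000 over 20 replicates).

## The synthetic cohort generator

No subject-level data are distributable, so the generator emulates the
study's statistical structure and every pipeline stage runs against it.
Per subject:

1. **Detection state.** Symptomatic: dual-modality detection with
   probability 351/583, single-modality 0.25 (the study reports only the
   dual rate; 0.25 is our choice of a plausible single rate), none
   otherwise. Asymptomatic: dual 0.289, any-detection 0.531 (the study's
   asymptomatic-bacteriuria rates). Single-modality detections are
   carried by M-PCR with probability 0.8 — molecular detection without
   culture growth is the dominant discordance direction, culture's poor
   sensitivity being the motivating limitation of the design.
2. **Density.** Detected subjects draw a density bin (cohort-specific
   weights, symptomatic skewed high) and a point density log-uniform
   within it; undetected subjects have density 0 and sit in the bottom
   bin.
3. **Biomarker positivity.** Each marker is Bernoulli with probability
   Φ(a_m + b·x + σ·u), where x is the bin's representative log10 density
   and u is a standard-normal per-subject latent inflammation factor.
   The latent factor induces the cross-marker dependence that real
   inflammation produces and that the consensus rate requires: under
   independence given density, three markers with the study's marginal
   sensitivities would give a consensus sensitivity near 0.91, visibly
   above the observed 0.84.
4. **Concentration.** Given the intended call, the value is drawn from a
   log-normal truncated to the correct side of the cutoff, then censored
   at the assay floor (NGAL 0.16 ng/mL, IL-1β 3.9 pg/mL, IL-8 reported
   down to 0) and ceiling (NGAL 500, IL-8 2000), reproducing the heavy
   right skew, floor pile-up and ceiling saturation of the reference
   descriptive table. Truncation guarantees the thresholded call equals
   the generating state, so the truth table is exact.

Link slopes are 0.6 (symptomatic) and 0.45 (asymptomatic) per log10
density; intercepts and latent loadings (σ = 1.5 symptomatic, 2.0
asymptomatic) were calibrated once, analytically — by integrating the
link over the bin mixture and latent factor and root-finding the
intercepts — so the expected marginal positivity of each marker and of
the consensus match the study's rates. They are frozen constants, not
fitting parameters.

All randomness flows from one seed through a single stream
(`withr::with_seed`); identical configurations give byte-identical CSV
output.

**What the generator does not emulate:** organism species composition,
age/sex effects on biomarkers, the dependence of concentration *values*
(beyond positivity) on density, within-bin density–positivity gradients,
and any difference between volunteer and biorepository measurement
conditions. Tests passing on synthetic cohorts therefore demonstrate the
pipeline's correctness and calibration under the modeled structure, not
clinical performance on new data.

Separately from the generator, `study_pattern_fixture()` builds a
deterministic 579-subject cohort whose per-classifier contingency tables
equal the published tables *exactly* for all five classifiers at once.
Only the margins of the joint positivity distribution are published; the
fixture uses one fixed joint allocation consistent with all five margins
(any such joint yields identical downstream statistics, because every
statistic here is a margin functional). Marker values in the fixture are
representative constants — group medians for positives, floor-level
values for negatives — so it exercises thresholding and the metrics
engine, not distributional shape.

## Problem sizes and numerical conventions

The analysis scripts under `analysis/` run the simulated study at the
study's own size (583/228). Calibration-style checks — consensus
sensitivity/specificity within 5 percentage points of 84.0%/91.2%, binned
R² above 0.90 — are run at tenfold size (5830/2280) so that bin-level
binomial noise does not dominate the quantity being checked; parameter
recovery uses n = 2000 per replicate over 20 seeded replicates. Exact-CI
coverage is enumerated exhaustively for n ≤ 30.

Interval level defaults to 0.95 everywhere. Human-readable report output
rounds percentages to one decimal and likelihood ratios to two, matching
clinical-reporting convention; serialized JSON keeps full precision.

## Known limitations

- The consensus rule's joint behaviour across markers is emulated only
  through the latent factor; the true cross-marker dependence is
  unpublished.
- The unpaired z-test for sensitivity comparisons ignores pairing (see
  above).
- Criterion 2 logic is implemented and tested, but no reference numbers
  exist to validate a criterion-2 fixture against.
- The probit R² convention is package-defined; other software may report
  a likelihood-based pseudo-R² that is not comparable.
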