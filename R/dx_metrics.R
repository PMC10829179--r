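estimate_ci <- function(estimate, lower, upper, level = 0.95) {
  structure(list(estimate = estimate, lower = lower, upper = upper,
                 level = level),
            class = "estimate_ci")
}

#' @export
print.estimate_ci <- function(x, digits = 3, ...) {
  cat(sprintf("%.*f (%.*f, %.*f) [%g%% CI]\n", digits, x$estimate,
              digits, x$lower, digits, x$upper, 100 * x$level))
  invisible(x)
}

#' Clopper-Pearson exact binomial confidence interval
#'
#' The exact two-sided interval from beta-distribution quantiles:
#' lower bound `qbeta(alpha/2, k, n - k + 1)` (0 when `k = 0`), upper bound
#' `qbeta(1 - alpha/2, k + 1, n - k)` (1 when `k = n`). Guarantees coverage
#' at least the nominal level for every true proportion.
#'
#' @param successes Number of successes, `0 <= successes <= n`.
#' @param n Number of trials, at least 1.
#' @param level Confidence level (default 0.95).
#' @return An `estimate_ci` with `estimate = successes / n`.
#' @export
clopper_pearson <- function(successes, n, level = 0.95) {
  stopifnot(length(successes) == 1, length(n) == 1)
  if (n < 1) abort("clopper_pearson requires n >= 1")
  if (successes < 0 || successes > n) abort("successes must lie in [0, n]")
  if (level <= 0 || level >= 1) abort("level must be in (0, 1)")
  alpha <- 1 - level
  lower <- if (successes == 0) 0 else qbeta(alpha / 2, successes, n - successes + 1)
  upper <- if (successes == n) 1 else qbeta(1 - alpha / 2, successes + 1, n - successes)
  estimate_ci(successes / n, lower, upper, level)
}

#' Build a 2x2 contingency table of calls against case labels
#'
#' Rows with label `excluded` are skipped (with a message); true condition
#' positive is `definitive_uti`, negative is `definitive_non_uti`.
#'
#' @param labels Factor/character vector of case labels as produced by
#'   [classify_cases()].
#' @param calls Logical vector of classifier calls, same length.
#' @return A `contingency` object: list with counts `tp`, `fp`, `fn`, `tn`
#'   and `n_excluded`.
#' @export
build_contingency <- function(labels, calls) {
  if (length(labels) != length(calls)) {
    abort("labels and calls must have the same length")
  }
  labels <- as.character(labels)
  keep <- labels != "excluded"
  n_excluded <- sum(!keep)
  if (n_excluded > 0) {
    message(sprintf("skipping %d excluded subject(s)", n_excluded))
  }
  labels <- labels[keep]
  calls <- calls[keep]
  uti <- labels == "definitive_uti"
  ct <- structure(list(
    tp = sum(calls & uti), fp = sum(calls & !uti),
    fn = sum(!calls & uti), tn = sum(!calls & !uti),
    n_excluded = n_excluded
  ), class = "contingency")
  ct
}

#' @export
print.contingency <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), nrow = 2,
              dimnames = list(call = c("positive", "negative"),
                              truth = c("definitive_uti", "definitive_non_uti")))
  print(m)
  if (x$n_excluded > 0) cat(sprintf("(%d excluded)\n", x$n_excluded))
  invisible(x)
}

ct_total <- function(ct) ct$tp + ct$fp + ct$fn + ct$tn

#' Diagnostic performance of a classifier from a 2x2 table
#'
#' Computes sensitivity, specificity, positive and negative predictive
#' value and accuracy, each with a Clopper-Pearson exact confidence
#' interval, and the likelihood ratios LR+ = sens / (1 - spec) and
#' LR- = (1 - sens) / spec with log-scale (Katz-style) intervals.
#'
#' Two conventions exist for the LR- standard error on the log scale. The
#' default, `"positive_row"`, reuses the LR+ standard error
#' `sqrt(1/tp - 1/(tp+fn) + 1/fp - 1/(fp+tn))` for LR- as well, which is
#' what common diagnostic-report software emits and what this package's
#' reference tables reproduce. `"negative_row"` is the textbook analogue
#' built from the negative-call cells, `sqrt(1/fn - 1/(tp+fn) + 1/tn -
#' 1/(fp+tn))`; it gives narrower LR- intervals here. Both are Wald
#' intervals for the log likelihood ratio.
#'
#' A zero denominator leaves the affected statistic `NA` (proportions) or
#' infinite with an `NA` interval (likelihood ratios), with a warning; an
#' optional 0.5 continuity correction for zero cells can be requested
#' explicitly and is never applied silently.
#'
#' @param ct A `contingency` object from [build_contingency()].
#' @param level Confidence level (default 0.95).
#' @param lr_minus_se `"positive_row"` (default, matches standard report
#'   output) or `"negative_row"`.
#' @param continuity If `TRUE`, add 0.5 to every cell before computing
#'   likelihood ratios when any cell is zero.
#' @return A `dx_performance` object: named list of `estimate_ci` for
#'   `sensitivity`, `specificity`, `ppv`, `npv`, `accuracy`, `lr_plus`,
#'   `lr_minus`, plus the source `contingency`.
#' @export
dx_performance <- function(ct, level = 0.95,
                           lr_minus_se = c("positive_row", "negative_row"),
                           continuity = FALSE) {
  stopifnot(inherits(ct, "contingency"))
  lr_minus_se <- match.arg(lr_minus_se)
  if (ct_total(ct) == 0) abort("contingency table is empty")
  prop_ci <- function(k, n) {
    if (n == 0) {
      warn("zero denominator; statistic undefined")
      return(estimate_ci(NA_real_, NA_real_, NA_real_, level))
    }
    clopper_pearson(k, n, level)
  }
  p_pos <- ct$tp + ct$fn   # condition positives
  n_neg <- ct$fp + ct$tn   # condition negatives
  sens <- prop_ci(ct$tp, p_pos)
  spec <- prop_ci(ct$tn, n_neg)
  ppv <- prop_ci(ct$tp, ct$tp + ct$fp)
  npv <- prop_ci(ct$tn, ct$tn + ct$fn)
  acc <- prop_ci(ct$tp + ct$tn, ct_total(ct))

  cells <- c(tp = ct$tp, fp = ct$fp, fn = ct$fn, tn = ct$tn)
  if (continuity && any(cells == 0)) cells <- cells + 0.5
  z <- qnorm(1 - (1 - level) / 2)
  lr_ci <- function(lr, se) {
    if (!is.finite(lr) || lr <= 0 || !is.finite(se)) {
      warn("likelihood ratio undefined or infinite; CI not available")
      return(estimate_ci(lr, NA_real_, NA_real_, level))
    }
    estimate_ci(lr, exp(log(lr) - z * se), exp(log(lr) + z * se), level)
  }
  with(as.list(cells), {
    sens_hat <- tp / (tp + fn)
    spec_hat <- tn / (fp + tn)
    lrp <- sens_hat / (1 - spec_hat)
    lrm <- (1 - sens_hat) / spec_hat
    se_pos <- sqrt(1 / tp - 1 / (tp + fn) + 1 / fp - 1 / (fp + tn))
    se_neg <- sqrt(1 / fn - 1 / (tp + fn) + 1 / tn - 1 / (fp + tn))
    se_m <- if (lr_minus_se == "positive_row") se_pos else se_neg
    structure(list(
      sensitivity = sens, specificity = spec, ppv = ppv, npv = npv,
      accuracy = acc,
      lr_plus = lr_ci(lrp, se_pos),
      lr_minus = lr_ci(lrm, se_m),
      contingency = ct, level = level
    ), class = "dx_performance")
  })
}

#' @export
print.dx_performance <- function(x, ...) {
  pct <- function(e) sprintf("%.1f%% (%.1f%%, %.1f%%)",
                             100 * e$estimate, 100 * e$lower, 100 * e$upper)
  lr <- function(e) sprintf("%.2f (%.2f, %.2f)", e$estimate, e$lower, e$upper)
  cat("Sensitivity (95% CI): ", pct(x$sensitivity), "\n", sep = "")
  cat("Specificity (95% CI): ", pct(x$specificity), "\n", sep = "")
  cat("PPV (95% CI):         ", pct(x$ppv), "\n", sep = "")
  cat("NPV (95% CI):         ", pct(x$npv), "\n", sep = "")
  cat("Accuracy (95% CI):    ", pct(x$accuracy), "\n", sep = "")
  cat("LR+ (95% CI):         ", lr(x$lr_plus), "\n", sep = "")
  cat("LR- (95% CI):         ", lr(x$lr_minus), "\n", sep = "")
  invisible(x)
}

#' Pooled two-proportion Z-test
#'
#' Unpaired two-sided z-test for equality of two binomial proportions using
#' the pooled variance estimate, without continuity correction.
#'
#' @param k1,n1 Successes and trials in group 1.
#' @param k2,n2 Successes and trials in group 2.
#' @return List with `statistic` (z) and `p_value` (two-sided).
#' @export
two_proportion_z <- function(k1, n1, k2, n2) {
  stopifnot(n1 >= 1, n2 >= 1, k1 >= 0, k2 >= 0, k1 <= n1, k2 <= n2)
  pooled <- (k1 + k2) / (n1 + n2)
  if (pooled == 0 || pooled == 1) {
    abort("pooled proportion is 0 or 1; z statistic undefined")
  }
  se <- sqrt(pooled * (1 - pooled) * (1 / n1 + 1 / n2))
  z <- (k1 / n1 - k2 / n2) / se
  list(statistic = z, p_value = 2 * pnorm(-abs(z)))
}

#' Descriptive summary of a concentration vector
#'
#' Quartiles by linear interpolation between order statistics (the default
#' "type 7" convention); the mean's confidence interval uses the Student-t
#' quantile, `mean +/- t(1 - alpha/2, n - 1) * sd / sqrt(n)`.
#'
#' @param values Numeric vector, `n >= 2` (sd is undefined below that).
#' @param level Confidence level for the mean CI.
#' @return One-row tibble: `n`, `minimum`, `q25`, `median`, `q75`,
#'   `maximum`, `mean`, `sd`, `se`, `ci_lower`, `ci_upper`.
#' @export
describe <- function(values, level = 0.95) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2) abort("describe requires at least 2 non-missing values")
  q <- quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  m <- mean(values)
  s <- sd(values)
  se <- s / sqrt(n)
  half <- qt(1 - (1 - level) / 2, df = n - 1) * se
  tibble(
    n = n, minimum = min(values), q25 = q[1], median = q[2], q75 = q[3],
    maximum = max(values), mean = m, sd = s, se = se,
    ci_lower = m - half, ci_upper = m + half
  )
}

#' Rank-based comparison of two groups
#'
#' Two-sided Mann-Whitney / Wilcoxon rank-sum test. Small tie-free samples
#' use the exact null distribution; otherwise the normal approximation with
#' tie correction applies (the `stats::wilcox.test` policy).
#'
#' @param values_a,values_b Numeric vectors, each non-empty.
#' @return Two-sided p-value.
#' @export
group_compare <- function(values_a, values_b) {
  values_a <- values_a[!is.na(values_a)]
  values_b <- values_b[!is.na(values_b)]
  if (length(values_a) == 0 || length(values_b) == 0) {
    abort("both groups must be non-empty")
  }
  suppressWarnings(
    wilcox.test(values_a, values_b, alternative = "two.sided")$p.value
  )
}

#' Minimal detectable standardized effect size
#'
#' Smallest Cohen's d detectable with the target power in a two-sample
#' comparison with unequal group sizes, by the normal approximation:
#' `d = (z[1 - alpha/2] + z[power]) * sqrt(1/n1 + 1/n2)`.
#'
#' @param n1,n2 Group sizes, each at least 2.
#' @param alpha Two-sided significance level (default 0.05).
#' @param power Target power (default 0.80).
#' @return Cohen's d.
#' @export
detectable_effect_size <- function(n1, n2, alpha = 0.05, power = 0.80) {
  stopifnot(n1 >= 2, n2 >= 2, alpha > 0, alpha < 1, power > 0, power < 1)
  (qnorm(1 - alpha / 2) + qnorm(power)) * sqrt(1 / n1 + 1 / n2)
}
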