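test_that("contingency construction maps calls against case labels", {
  labels <- c("definitive_uti", "definitive_uti", "definitive_non_uti",
              "definitive_non_uti", "excluded")
  calls <- c(TRUE, FALSE, TRUE, FALSE, TRUE)
  expect_message(ct <- build_contingency(labels, calls), "1 excluded")
  expect_identical(ct[c("tp", "fp", "fn", "tn")],
                   list(tp = 1L, fp = 1L, fn = 1L, tn = 1L))
  expect_identical(ct$n_excluded, 1L)
  # all-negative calls give an empty positive row
  ct0 <- build_contingency(labels[1:4], rep(FALSE, 4))
  expect_identical(ct0$tp + ct0$fp, 0L)
  expect_error(build_contingency(labels, calls[1:3]), "length")
})

test_that("Clopper-Pearson endpoints satisfy the exact binomial tail conditions", {
  # oracle: the bounds are the p at which the binomial tail equals alpha/2
  tail_ge <- function(p, k, n) sum(dbinom(k:n, n, p))
  tail_le <- function(p, k, n) sum(dbinom(0:k, n, p))
  set.seed(5)
  for (i in 1:25) {
    n <- sample(1:80, 1)
    k <- sample(0:n, 1)
    ci <- clopper_pearson(k, n, 0.95)
    expect_equal(ci$estimate, k / n)
    expect_true(ci$lower <= ci$estimate && ci$estimate <= ci$upper)
    if (k == 0) expect_identical(ci$lower, 0) else
      expect_equal(tail_ge(ci$lower, k, n), 0.025, tolerance = 1e-9)
    if (k == n) expect_identical(ci$upper, 1) else
      expect_equal(tail_le(ci$upper, k, n), 0.025, tolerance = 1e-9)
  }
  expect_error(clopper_pearson(1, 0), "n >= 1")
  expect_error(clopper_pearson(5, 4))
})

test_that("Clopper-Pearson coverage is at least nominal for all n <= 30", {
  # exhaustive enumeration over k, probability grid over p
  p_grid <- seq(0.01, 0.99, by = 0.01)
  for (n in c(1:10, 15, 20, 25, 30)) {
    ci <- lapply(0:n, clopper_pearson, n = n, level = 0.95)
    lower <- vapply(ci, `[[`, numeric(1), "lower")
    upper <- vapply(ci, `[[`, numeric(1), "upper")
    for (p in p_grid) {
      cover <- sum(dbinom(0:n, n, p)[lower <= p & p <= upper])
      expect_gte(cover, 0.95)
    }
  }
})

test_that("performance statistics are internally consistent", {
  set.seed(13)
  for (i in 1:20) {
    cells <- sample(1:200, 4, replace = TRUE)
    ct <- structure(list(tp = cells[1], fp = cells[2], fn = cells[3],
                         tn = cells[4], n_excluded = 0L), class = "contingency")
    perf <- dx_performance(ct)
    P <- cells[1] + cells[3]
    N <- cells[2] + cells[4]
    sens <- perf$sensitivity$estimate
    spec <- perf$specificity$estimate
    expect_equal(perf$accuracy$estimate, (sens * P + spec * N) / (P + N))
    # PPV by Bayes' rule from sensitivity, specificity and table prevalence
    prev <- P / (P + N)
    expect_equal(perf$ppv$estimate,
                 sens * prev / (sens * prev + (1 - spec) * (1 - prev)))
    expect_equal(perf$lr_plus$estimate, sens / (1 - spec))
    expect_equal(perf$lr_minus$estimate, (1 - sens) / spec)
  }
})

test_that("a perfect classifier scores 1 everywhere and flags infinite LR+", {
  ct <- structure(list(tp = 40L, fp = 0L, fn = 0L, tn = 60L, n_excluded = 0L),
                  class = "contingency")
  expect_warning(expect_warning(dx_performance(ct), "undefined"), "undefined")
  perf <- suppressWarnings(dx_performance(ct))
  for (stat in c("sensitivity", "specificity", "ppv", "npv", "accuracy")) {
    expect_equal(perf[[stat]]$estimate, 1)
  }
  expect_identical(perf$lr_plus$estimate, Inf)
  expect_true(is.na(perf$lr_plus$lower))
  # explicit continuity correction makes the LR finite
  perf_cc <- dx_performance(ct, continuity = TRUE)
  expect_true(is.finite(perf_cc$lr_plus$estimate))
})

test_that("LR- interval conventions differ as documented", {
  ct <- structure(list(tp = 295L, fp = 20L, fn = 56L, tn = 208L,
                       n_excluded = 0L), class = "contingency")
  pos <- dx_performance(ct, lr_minus_se = "positive_row")$lr_minus
  neg <- dx_performance(ct, lr_minus_se = "negative_row")$lr_minus
  expect_equal(pos$estimate, neg$estimate)
  # the negative-row SE is smaller here, giving a narrower interval
  expect_lt(neg$upper - neg$lower, pos$upper - pos$lower)
  # negative-row form agrees with the direct Katz computation
  se_neg <- sqrt(1 / 56 - 1 / 351 + 1 / 208 - 1 / 228)
  expect_equal(neg$lower, exp(log(pos$estimate) - qnorm(0.975) * se_neg))
})

test_that("two-proportion z: closed form, antisymmetry, degenerate input", {
  # verified against an independent normal-CDF evaluation of the closed form
  res <- two_proportion_z(290, 351, 320, 351)
  expect_equal(res$statistic, -3.3553, tolerance = 1e-4)
  expect_equal(res$p_value, 7.928e-4, tolerance = 1e-3)
  expect_lt(two_proportion_z(245, 351, 320, 351)$p_value, 1e-4)
  # equal proportions give z = 0, p = 1
  eq <- two_proportion_z(30, 100, 30, 100)
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p_value, 1)
  # swapping groups negates z and preserves p
  a <- two_proportion_z(40, 90, 55, 110)
  b <- two_proportion_z(55, 110, 40, 90)
  expect_equal(a$statistic, -b$statistic)
  expect_equal(a$p_value, b$p_value)
  # cross-check against the chi-square equivalence (z^2 = X^2, no correction)
  pt <- suppressWarnings(prop.test(c(40, 55), c(90, 110), correct = FALSE))
  expect_equal(a$statistic^2, unname(pt$statistic))
  expect_equal(a$p_value, pt$p.value)
  expect_error(two_proportion_z(0, 10, 0, 10), "pooled")
})

test_that("describe follows the type-7 quantile and Student-t conventions", {
  d <- describe(c(1, 2, 3, 4, 5))
  expect_equal(d$median, 3)
  expect_equal(d$mean, 3)
  expect_equal(d$q25, 2)
  expect_equal(d$q75, 4)
  # constant vector: sd 0, interval degenerate at the mean
  dc <- describe(rep(7, 10))
  expect_equal(dc$sd, 0)
  expect_equal(dc$ci_lower, 7)
  expect_equal(dc$ci_upper, 7)
  expect_error(describe(c(1)), "at least 2")
  # se identity and t-interval identity on random data
  set.seed(2)
  x <- rlnorm(40, 3, 1)
  d2 <- describe(x)
  expect_equal(d2$se, d2$sd / sqrt(40))
  expect_equal(unname(d2$ci_upper - d2$mean), unname(qt(0.975, 39) * d2$se))
})

test_that("group comparison: identical groups, separation, exact small-n floor", {
  expect_equal(group_compare(1:10, 1:10), 1, tolerance = 0.01)
  # disjoint support at small n hits the exact rank-test minimum 2/choose(n1+n2,n1)
  expect_equal(group_compare(1:4, 11:14), 2 / choose(8, 4))
  expect_equal(group_compare(c(1, 2, 3), c(10, 11, 12, 13)), 2 / choose(7, 3))
  # synthetic UTI-like vs non-UTI-like NGAL draws separate decisively
  set.seed(31)
  uti_like <- pmin(rlnorm(150, 5.5, 1.2), 500)
  non_like <- pmax(rlnorm(150, -1, 2), 0.16)
  expect_lt(group_compare(uti_like, non_like), 1e-4)
  expect_error(group_compare(numeric(), 1:3), "non-empty")
})

test_that("detectable effect size matches the power-function inverse", {
  # oracle: numerically invert power(d) = Phi(d / sqrt(1/n1 + 1/n2) - z_{1-a/2})
  invert <- function(n1, n2, alpha, power) {
    uniroot(function(d) {
      pnorm(d / sqrt(1 / n1 + 1 / n2) - qnorm(1 - alpha / 2)) - power
    }, c(1e-6, 10), tol = 1e-10)$root
  }
  expect_equal(detectable_effect_size(100, 100, 0.05, 0.80),
               invert(100, 100, 0.05, 0.80), tolerance = 1e-6)
  expect_equal(detectable_effect_size(100, 100, 0.05, 0.80), 0.397, tolerance = 5e-3)
  # scaling law: doubling both n divides d by sqrt(2)
  expect_equal(detectable_effect_size(200, 200),
               detectable_effect_size(100, 100) / sqrt(2))
  # strictly decreasing in each group size
  expect_lt(detectable_effect_size(351, 229), detectable_effect_size(351, 228))
  expect_lt(detectable_effect_size(352, 228), detectable_effect_size(351, 228))
})
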