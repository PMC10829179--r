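#' Semi-quantitative density bins per detection modality
#'
#' The reporting bins used for the dose-response analysis: M-PCR reports six
#' bins (below 10^4; 10^4--10^5; 10^5--10^6; 10^6--10^7; 10^7--10^8; at or
#' above 10^8 cells/mL), culture three (below 10^4; 10^4--10^5; at or above
#' 10^5 CFU/mL). Bins are half-open `[lower, upper)` so the clinically
#' significant 10^4 boundary is exact; together they tile `[0, Inf)`.
#'
#' @param modality `"mpcr"` or `"suc"`.
#' @return Tibble with `label`, `lower`, `upper` (Inf for the open top bin)
#'   and `x`, the log10 of the bin's representative density (geometric
#'   midpoint; bounded edges of the open bins are shifted half a decade).
#' @export
standard_bins <- function(modality = c("mpcr", "suc")) {
  modality <- match.arg(modality)
  edges <- if (modality == "mpcr") c(0, 10^(4:8), Inf) else c(0, 1e4, 1e5, Inf)
  lower <- edges[-length(edges)]
  upper <- edges[-1]
  x <- ifelse(lower == 0, log10(upper) - 0.5,
              ifelse(is.infinite(upper), log10(lower) + 0.5,
                     (log10(lower) + log10(upper)) / 2))
  label <- ifelse(lower == 0, sprintf("<1e%g", log10(upper)),
                  ifelse(is.infinite(upper), sprintf(">=1e%g", log10(lower)),
                         sprintf("1e%g-1e%g", log10(lower), log10(upper))))
  tibble(label = label, lower = lower, upper = upper, x = x)
}

#' Per-subject maximal density for one modality
#'
#' A subject reporting both a bacterial and a yeast density for the modality
#' is binned by the larger of the two. `NA` in both fields means no density
#' record; `NA` in one field is ignored.
#'
#' @param subjects Subject tibble.
#' @param modality `"mpcr"` or `"suc"`.
#' @return Numeric vector of densities (organisms/mL), `NA` where the
#'   modality reported nothing.
#' @export
max_density <- function(subjects, modality = c("mpcr", "suc")) {
  modality <- match.arg(modality)
  bact <- subjects[[paste0(modality, "_bact_density")]]
  yeast <- subjects[[paste0(modality, "_yeast_density")]]
  out <- pmax(bact, yeast, na.rm = TRUE)
  out[is.na(bact) & is.na(yeast)] <- NA_real_
  out
}

assign_bin <- function(density, bins) {
  idx <- findInterval(density, c(bins$lower, Inf), rightmost.closed = FALSE)
  idx[is.na(density)] <- NA_integer_
  idx
}

#' Binned biomarker positivity along the density axis
#'
#' Groups subjects into the modality's density bins and computes the
#' proportion with a positive call in each non-empty bin -- the data points
#' of a positivity-versus-density dose-response plot.
#'
#' @param density Numeric densities (e.g. [max_density()]); `NA` entries are
#'   dropped.
#' @param positive Logical calls aligned with `density`.
#' @param bins Bin table from [standard_bins()].
#' @return Tibble with one row per non-empty bin: `label`, `lower`, `upper`,
#'   `x`, `n`, `k`, `proportion`.
#' @export
bin_positivity <- function(density, positive, bins = standard_bins("mpcr")) {
  if (length(density) != length(positive)) {
    abort("density and positive must have the same length")
  }
  keep <- !is.na(density)
  density <- density[keep]
  positive <- positive[keep]
  idx <- assign_bin(density, bins)
  n <- tabulate(idx, nbins = nrow(bins))
  k <- vapply(seq_len(nrow(bins)), function(i) sum(positive[idx == i]), integer(1))
  out <- bins
  out$n <- n
  out$k <- k
  out$proportion <- ifelse(n > 0, k / n, NA_real_)
  out[out$n > 0, ]
}

#' Probit dose-response of biomarker positivity on log density
#'
#' Fits a maximum-likelihood probit regression of the per-subject binary
#' call on `x = log10` representative density of the subject's bin:
#' `P(positive) = Phi(intercept + slope * x)`. The slope p-value is the
#' Wald test. Because the dose-response is conventionally displayed as
#' binned proportions, `r_squared` is the squared Pearson correlation
#' between the observed bin proportions and the fitted probabilities at the
#' bin x values (bins with fewer than `min_bin_n` subjects are ignored for
#' R^2 only).
#'
#' Alternatively `data = "binned"` fits the aggregated binomial counts per
#' bin; estimates coincide with the per-subject fit, which is the default.
#'
#' @param density Numeric densities; `NA` dropped (paired with `positive`).
#' @param positive Logical calls.
#' @param bins Bin table from [standard_bins()].
#' @param data Fit per-subject Bernoulli outcomes (`"subject"`, default) or
#'   binned binomial counts (`"binned"`).
#' @param min_bin_n Minimum bin size entering the R^2 computation.
#' @return A `probit_fit`: list with `intercept`, `slope`, `slope_se`,
#'   `slope_p_value`, `r_squared`, `n_bins`, `n`, `binned` (the
#'   [bin_positivity()] table) and `log_lik`.
#' @export
fit_probit <- function(density, positive, bins = standard_bins("mpcr"),
                       data = c("subject", "binned"), min_bin_n = 1) {
  data <- match.arg(data)
  keep <- !is.na(density) & !is.na(positive)
  density <- density[keep]
  positive <- as.logical(positive[keep])
  if (length(density) == 0) abort("no usable observations")
  if (all(positive) || all(!positive)) {
    abort("all outcomes identical; probit MLE does not exist")
  }
  idx <- assign_bin(density, bins)
  x <- bins$x[idx]
  if (length(unique(x)) < 2) {
    abort("need at least 2 distinct density bins to fit a dose-response")
  }
  binned <- bin_positivity(density, positive, bins)
  fit <- if (data == "subject") {
    glm(positive ~ x, family = binomial(link = "probit"))
  } else {
    glm(cbind(k, n - k) ~ x, family = binomial(link = "probit"), data = binned)
  }
  if (!fit$converged) abort("probit fit did not converge (separation?)")
  cf <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  if (!all(is.finite(se)) || se[2] > 1e3) {
    abort("probit fit is degenerate (quasi-separation); standard errors unusable")
  }
  wald_z <- cf[[2]] / se[[2]]
  use <- binned$n >= min_bin_n
  fitted_at_bins <- pnorm(cf[[1]] + cf[[2]] * binned$x[use])
  r2 <- if (sum(use) >= 2 && sd(binned$proportion[use]) > 0 && sd(fitted_at_bins) > 0) {
    stats::cor(binned$proportion[use], fitted_at_bins)^2
  } else {
    NA_real_
  }
  structure(list(
    intercept = cf[[1]], slope = cf[[2]],
    intercept_se = se[[1]], slope_se = se[[2]],
    slope_p_value = 2 * pnorm(-abs(wald_z)),
    r_squared = r2,
    n_bins = nrow(binned), n = length(density),
    binned = binned,
    log_lik = as.numeric(logLik(fit)),
    vcov = vcov(fit)
  ), class = "probit_fit")
}

#' Predicted positivity probability from a probit fit
#'
#' @param fit A `probit_fit`.
#' @param x log10 density value(s).
#' @return Probabilities in (0, 1).
#' @export
predict_probit <- function(fit, x) {
  stopifnot(inherits(fit, "probit_fit"))
  pnorm(fit$intercept + fit$slope * x)
}

#' @export
print.probit_fit <- function(x, ...) {
  cat(sprintf("Probit dose-response: Phi(%.3f + %.3f * log10(density))\n",
              x$intercept, x$slope))
  cat(sprintf("  slope Wald p = %.3g; binned R^2 = %.3f; %d bins, n = %d\n",
              x$slope_p_value, x$r_squared, x$n_bins, x$n))
  invisible(x)
}
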