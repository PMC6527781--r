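#' Analysis control parameters
#'
#' @param min_class_count minimum called individuals in each of the three
#'   genotype classes for the dominance contrast to be testable (all three
#'   classes must be present).
#' @param empirical_coeffs coefficient and exponent `(c, b)` of the
#'   empirical extreme-p power law `log10(1/p) = c * t^b`, used when the
#'   exact two-sided t-tail underflows below `10^-underflow_log10p`.
#' @param underflow_log10p the `-log10 p` beyond which the exact tail is
#'   considered to underflow (double precision floor, 308).
#' @param maf_reporting_min minor-allele-frequency floor for reporting
#'   effect size and direction; SNPs below it are still tested but their
#'   effect fields are flagged as suppressed.
#' @param alpha_genomewide genome-wide false-positive rate for the
#'   Bonferroni threshold.
#' @param top_fraction fraction defining "top" effects per trait (0.01 =
#'   top 1 percent).
#' @param pattern_thresholds `(lower, upper)` allelic-effect magnitude-ratio
#'   cutoffs for the uni-allelic / asymmetric / symmetric typology.
#' @param complete_dom_tol relative tolerance for calling complete
#'   dominance (heterozygote equal to one homozygote).
#' @return A list of class `agls_control`.
#' @export
agls_control <- function(min_class_count = 5L,
                         empirical_coeffs = c(0.2416, 1.9713),
                         underflow_log10p = 308,
                         maf_reporting_min = 0.05,
                         alpha_genomewide = 0.05,
                         top_fraction = 0.01,
                         pattern_thresholds = c(0.2, 0.8),
                         complete_dom_tol = 0.05) {
  stopifnot(min_class_count >= 1, length(empirical_coeffs) == 2,
            empirical_coeffs[1] > 0, empirical_coeffs[2] > 0,
            underflow_log10p > 0,
            maf_reporting_min >= 0, maf_reporting_min <= 0.5,
            alpha_genomewide > 0, alpha_genomewide < 1,
            top_fraction > 0, top_fraction <= 1,
            length(pattern_thresholds) == 2,
            pattern_thresholds[1] < pattern_thresholds[2])
  structure(list(min_class_count = as.integer(min_class_count),
                 empirical_coeffs = as.numeric(empirical_coeffs),
                 underflow_log10p = underflow_log10p,
                 maf_reporting_min = maf_reporting_min,
                 alpha_genomewide = alpha_genomewide,
                 top_fraction = top_fraction,
                 pattern_thresholds = as.numeric(pattern_thresholds),
                 complete_dom_tol = complete_dom_tol),
            class = "agls_control")
}

#' Adjust phenotypes by removing twice the PTA
#'
#' The AGLS pre-adjustment: `y* = y - 2*PTA`, where 2*PTA approximates the
#' additive polygenic value from routine genetic evaluation.  Individuals
#' missing either the phenotype or the PTA for the trait are dropped.
#'
#' @param pheno a [trait_table] of yield deviations.
#' @param pta a [trait_table] of PTAs.
#' @param trait trait name.
#' @return Named numeric vector `y*` (names = retained individual ids),
#'   with attribute `n_dropped` = individuals with a phenotype but no PTA.
#' @export
adjust_phenotypes <- function(pheno, pta, trait) {
  y <- trait_values(pheno, trait)
  a2 <- trait_values(pta, trait)
  common <- intersect(names(y), names(a2))
  if (length(common) == 0L)
    stop("no individuals with both phenotype and PTA for trait '", trait, "'")
  ystar <- y[common] - 2 * a2[common]
  attr(ystar, "n_dropped") <- length(y) - length(common)
  ystar
}

#' Fit one SNP by cell means on adjusted phenotypes
#'
#' Least-squares fit of the genotypic values under the cell-means
#' parameterization: the estimate for each genotype class present is the
#' class mean of `y*`, the residual variance is `RSS/(n - k)` with `k` the
#' number of classes present.  Contrasts of the genotypic values are
#' invariant to this resolution of the (mean + class dummies) rank
#' deficiency.
#'
#' @param y_star named numeric vector of adjusted phenotypes.
#' @param codes genotype codes aligned with `y_star` (same individuals,
#'   same order), NAs allowed.
#' @param min_class_count minimum per-class count for dominance testability.
#' @return Object of class `snp_fit`: `g_hat` (length-3, NA for absent
#'   classes), `counts`, `v2`, `n`, `k`, `xtx_gg_inv_diag` (diagonal of the
#'   genotype block of the inverse crossproduct, `1/n_c` for present
#'   classes), `dominance_untestable`.
#' @export
fit_snp <- function(y_star, codes, min_class_count = 5L) {
  keep <- !is.na(codes) & !is.na(y_star)
  y <- as.numeric(y_star[keep])
  x <- codes[keep]
  cnt <- tabulate(x + 1L, nbins = 3L)
  k <- sum(cnt > 0L)
  if (k < 2L) stop("SNP monomorphic in sample")
  n <- length(y)
  sums <- c(sum(y[x == 0L]), sum(y[x == 1L]), sum(y[x == 2L]))
  g_hat <- ifelse(cnt > 0L, sums / pmax(cnt, 1L), NA_real_)
  rss <- sum((y - g_hat[x + 1L])^2)
  v2 <- rss / (n - k)
  structure(list(g_hat = g_hat, counts = cnt, v2 = v2, n = n, k = k,
                 xtx_gg_inv_diag = ifelse(cnt > 0L, 1 / pmax(cnt, 1L),
                                          NA_real_),
                 dominance_untestable = any(cnt < min_class_count)),
            class = "snp_fit")
}

#' Empirical extreme-p extrapolation
#'
#' Power-law mapping from the t-statistic to `log10(1/p)` for p-values
#' below the double-precision floor: `log10(1/p) = c * t^b`, defaults
#' `c = 0.2416`, `b = 1.9713`.  Over the representable range this tracks
#' the exact two-sided t-tail almost perfectly (log-log linearity of the
#' extreme tail), so it extends the significance scale smoothly past
#' `p = 1e-308`.
#'
#' @param t non-negative t-statistic (vectorized).
#' @param coeffs `(c, b)`.
#' @return `log10(1/p)` values.
#' @export
empirical_log10p <- function(t, coeffs = c(0.2416, 1.9713)) {
  if (any(t < 0, na.rm = TRUE)) stop("t must be non-negative")
  coeffs[1] * t^coeffs[2]
}

#' Refit the empirical extreme-p coefficients
#'
#' Least squares on the log-log scale over (t, log10(1/p)) pairs from the
#' representable range of a run, giving run-specific power-law
#' coefficients.
#'
#' @param t t-statistics (positive).
#' @param log10invp matching exact `-log10 p` values (positive).
#' @return `(c, b)` coefficient vector.
#' @export
refit_empirical_coeffs <- function(t, log10invp) {
  keep <- is.finite(t) & is.finite(log10invp) & t > 0 & log10invp > 0
  if (sum(keep) < 3L) stop("need at least 3 positive (t, log10invp) pairs")
  fit <- stats::lm(log(log10invp[keep]) ~ log(t[keep]))
  c(exp(unname(stats::coef(fit)[1L])), unname(stats::coef(fit)[2L]))
}

# Exact -log10 two-sided p from the t-tail, computed in log space so it is
# representable at any t.
.exact_log10invp <- function(t, df) {
  lp <- stats::pt(t, df = df, lower.tail = FALSE, log.p = TRUE) + log(2)
  lip <- -lp / log(10)
  # two-sided p caps at 1 (t = 0): log10(1/p) floors at 0
  pmax(lip, 0)
}

#' Additive and dominance contrast t-tests for one SNP
#'
#' The AGLS t-statistic for contrast `s` of the genotypic values:
#' \deqn{t = |s'\hat g| / \sqrt{v^2 \, s' (X'X)^-_{gg} s}}
#' with the additive contrast from [additive_contrast] (HWD-robust) and
#' the dominance contrast (-0.5, 1, -0.5).  Two-sided p-values come from
#' the t distribution with `n - k` degrees of freedom; when the exact tail
#' underflows below `10^-308` the empirical power law takes over and
#' `empirical_p_used` is set.
#'
#' @param fit a [fit_snp] result.
#' @param freq a [genotype_frequencies] result from the same individuals.
#' @param control an [agls_control].
#' @return List: `t_add`, `log10invp_add`, `p_add`, `t_dom`,
#'   `log10invp_dom`, `p_dom`, `empirical_p_used_add`,
#'   `empirical_p_used_dom`, `dominance_untestable`, `alpha`
#'   (signed additive contrast `s_a' g`), `df`.
#' @export
snp_tests <- function(fit, freq, control = agls_control()) {
  df <- fit$n - fit$k
  present <- fit$counts > 0L
  s_a <- additive_contrast(freq)
  # absent classes have zero frequency hence zero additive coefficient
  La <- sum(s_a[present] * fit$g_hat[present])
  var_a <- fit$v2 * sum(s_a[present]^2 * fit$xtx_gg_inv_diag[present])
  t_add <- if (var_a > 0) abs(La) / sqrt(var_a) else 0
  add <- .p_with_fallback(t_add, df, control)

  dom_untest <- fit$dominance_untestable ||
    any(fit$counts < control$min_class_count)
  if (!dom_untest) {
    s_d <- dominance_contrast()
    Ld <- sum(s_d * fit$g_hat)
    var_d <- fit$v2 * sum(s_d^2 * fit$xtx_gg_inv_diag)
    t_dom <- if (var_d > 0) abs(Ld) / sqrt(var_d) else 0
    dom <- .p_with_fallback(t_dom, df, control)
  } else {
    t_dom <- NA_real_
    dom <- list(p = NA_real_, log10invp = NA_real_, empirical = FALSE)
  }
  list(t_add = t_add, p_add = add$p, log10invp_add = add$log10invp,
       empirical_p_used_add = add$empirical,
       t_dom = t_dom, p_dom = dom$p, log10invp_dom = dom$log10invp,
       empirical_p_used_dom = dom$empirical,
       dominance_untestable = dom_untest, alpha = La, df = df)
}

.p_with_fallback <- function(t, df, control) {
  lip <- .exact_log10invp(t, df)
  if (lip > control$underflow_log10p) {
    list(p = 0, log10invp = empirical_log10p(t, control$empirical_coeffs),
         empirical = TRUE)
  } else {
    list(p = 10^(-lip), log10invp = lip, empirical = FALSE)
  }
}
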