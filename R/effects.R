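#' Allelic decomposition of a SNP
#'
#' Quantitative-genetic decomposition of the three estimated genotypic
#' values into allelic means, allelic effects and the average effect of
#' gene substitution, valid under Hardy-Weinberg disequilibrium:
#' \deqn{\mu_1 = (P_{11}/p_1) g_{11} + 0.5 (P_{12}/p_1) g_{12}}
#' \deqn{\mu_2 = 0.5 (P_{12}/p_2) g_{12} + (P_{22}/p_2) g_{22}}
#' \deqn{\mu = p_1\mu_1 + p_2\mu_2,\quad a_i = \mu_i - \mu,\quad
#'       \alpha = \mu_1 - \mu_2}
#' Allelic effects about the SNP's own mean are not comparable across SNPs
#' (each SNP has its own genotypic mean); the comparable versions replace
#' \eqn{\mu} with `mu_all`, the average genotypic mean over the reporting
#' SNP set.
#'
#' @param g_hat length-3 vector of genotypic-value estimates
#'   (g11, g12, g22); all three must be present.
#' @param freq a [genotype_frequencies] result.
#' @param mu_all average of SNP genotypic means over the reporting set
#'   (default the SNP's own mean, making comparable = plain effects).
#' @return Object of class `allelic_effects`: `mu1`, `mu2`, `mu`, `mu_all`,
#'   `a1`, `a2`, `a1_comparable`, `a2_comparable`, `alpha`, `delta`.
#' @export
allelic_decomposition <- function(g_hat, freq, mu_all = NULL) {
  if (anyNA(g_hat) || length(g_hat) != 3L)
    stop("decomposition requires all three genotype classes")
  if (freq$p1 <= 0 || freq$p2 <= 0)
    stop("decomposition requires both alleles present")
  mu1 <- (freq$P11 / freq$p1) * g_hat[1L] +
    0.5 * (freq$P12 / freq$p1) * g_hat[2L]
  mu2 <- 0.5 * (freq$P12 / freq$p2) * g_hat[2L] +
    (freq$P22 / freq$p2) * g_hat[3L]
  mu <- freq$p1 * mu1 + freq$p2 * mu2
  if (is.null(mu_all)) mu_all <- mu
  structure(list(mu1 = mu1, mu2 = mu2, mu = mu, mu_all = mu_all,
                 a1 = mu1 - mu, a2 = mu2 - mu,
                 a1_comparable = mu1 - mu_all, a2_comparable = mu2 - mu_all,
                 alpha = mu1 - mu2, delta = dominance_effect(g_hat)),
            class = "allelic_effects")
}

#' Dominance effect of a SNP
#'
#' Heterozygote genotypic value minus the homozygote midpoint:
#' \eqn{\delta = g_{12} - (g_{11} + g_{22})/2}.  Invariant under allele
#' relabeling.
#'
#' @param g_hat length-3 vector (g11, g12, g22).
#' @return `delta`, or `NA` with a warning if a class is absent.
#' @export
dominance_effect <- function(g_hat) {
  if (anyNA(g_hat)) return(NA_real_)
  g_hat[2L] - (g_hat[1L] + g_hat[3L]) / 2
}

#' Classify the dominance mode of a SNP
#'
#' Overdominance (positive/negative) when the heterozygote genotypic value
#' lies above/below both homozygotes; complete dominance when the
#' heterozygote equals one homozygote within a tolerance relative to the
#' homozygote spread; partial dominance when strictly between with a
#' nonzero dominance effect; none when the heterozygote sits at the
#' midpoint.
#'
#' @param g_hat length-3 vector (g11, g12, g22).
#' @param delta dominance effect (recomputed if missing).
#' @param tol relative tolerance for "equal" comparisons, as a fraction of
#'   `|g11 - g22|` (absolute when the homozygotes coincide).
#' @return One of `"none"`, `"partial"`, `"complete"`,
#'   `"overdominant_positive"`, `"overdominant_negative"`.
#' @export
classify_dominance_mode <- function(g_hat, delta = dominance_effect(g_hat),
                                    tol = 0.05) {
  if (anyNA(g_hat)) return(NA_character_)
  spread <- abs(g_hat[1L] - g_hat[3L])
  eps <- if (spread > 0) tol * spread else tol
  if (abs(delta) <= eps) return("none")
  hi <- max(g_hat[1L], g_hat[3L])
  lo <- min(g_hat[1L], g_hat[3L])
  if (g_hat[2L] > hi + eps) return("overdominant_positive")
  if (g_hat[2L] < lo - eps) return("overdominant_negative")
  if (abs(g_hat[2L] - hi) <= eps || abs(g_hat[2L] - lo) <= eps)
    return("complete")
  "partial"
}

#' Classify the allelic-effect pattern of a SNP
#'
#' Typology of the two (cross-SNP comparable) allelic effects by the ratio
#' `r = min(|a1|,|a2|) / max(|a1|,|a2|)`:
#' uni-allelic (`r <= lower`: one allele carries essentially all the
#' effect, the other is near-neutral), symmetric (`r >= upper` with
#' opposing signs), otherwise asymmetric.  Signed variants carry the sign
#' of the dominant-magnitude (non-neutral) allele.
#'
#' @param a1,a2 comparable allelic effects.
#' @param thresholds `(lower, upper)` ratio cutoffs, defaults (0.2, 0.8).
#' @return One of `"none"`, `"symmetric"`, `"asymmetric_positive"`,
#'   `"asymmetric_negative"`, `"uniallelic_positive"`,
#'   `"uniallelic_negative"`.
#' @export
classify_allelic_pattern <- function(a1, a2, thresholds = c(0.2, 0.8)) {
  if (is.na(a1) || is.na(a2)) return(NA_character_)
  m <- c(abs(a1), abs(a2))
  if (max(m) == 0) return("none")
  r <- min(m) / max(m)
  major_sign <- if (abs(a1) >= abs(a2)) sign(a1) else sign(a2)
  suffix <- if (major_sign >= 0) "positive" else "negative"
  if (r <= thresholds[1L]) return(paste0("uniallelic_", suffix))
  if (r >= thresholds[2L] && sign(a1) * sign(a2) < 0) return("symmetric")
  paste0("asymmetric_", suffix)
}

#' Average genotypic mean over the reporting SNP set
#'
#' Unweighted mean of per-SNP genotypic means `mu`, taken (per trait) over
#' SNPs that pass the MAF reporting filter; used as the common reference
#' point for cross-SNP comparable allelic effects.
#'
#' @param mu numeric vector of per-SNP genotypic means (reporting set).
#' @return `mu_all`.
#' @export
compute_mu_all <- function(mu) {
  mu <- mu[!is.na(mu)]
  if (length(mu) == 0L) stop("empty reporting set: cannot compute mu_all")
  mean(mu)
}
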