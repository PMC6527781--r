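#' Genotype and allele frequencies of one SNP
#'
#' Frequencies are computed over called (non-missing) genotypes only; an
#' individual missing at this SNP does not enter this SNP's analysis
#' (pairwise deletion).
#'
#' @param codes integer vector of allele2-dosage codes (0/1/2/NA) for one SNP.
#' @return Object of class `snp_freq` with elements `n_called`, `n11`,
#'   `n12`, `n22`, `P11`, `P12`, `P22` (genotype frequencies), `p1`, `p2`
#'   (allele frequencies of A1 and A2) and `maf`.
#' @export
genotype_frequencies <- function(codes) {
  codes <- codes[!is.na(codes)]
  n <- length(codes)
  if (n == 0L) stop("no called genotypes")
  cnt <- tabulate(codes + 1L, nbins = 3L)
  P <- cnt / n
  p1 <- P[1L] + P[2L] / 2
  p2 <- P[3L] + P[2L] / 2
  structure(list(n_called = n, n11 = cnt[1L], n12 = cnt[2L], n22 = cnt[3L],
                 P11 = P[1L], P12 = P[2L], P22 = P[3L],
                 p1 = p1, p2 = p2, maf = min(p1, p2)),
            class = "snp_freq")
}

#' Additive contrast coefficients
#'
#' The Hardy-Weinberg-disequilibrium-robust additive contrast over the
#' three genotypic values (g11, g12, g22):
#' \deqn{s_a = (P_{11}/p_1,\; 0.5 P_{12}(p_2-p_1)/(p_1 p_2),\; -P_{22}/p_2)}
#' which reduces to \eqn{(p_1, p_2-p_1, -p_2)} under Hardy-Weinberg
#' equilibrium.  Applied to the genotypic values it yields the average
#' effect of gene substitution, \eqn{\alpha = s_a \hat g = \mu_1 - \mu_2}.
#' The coefficients always sum to zero.
#'
#' @param freq a `snp_freq` from [genotype_frequencies].
#' @return Numeric vector of length 3 with attribute `kind = "additive"`.
#' @export
additive_contrast <- function(freq) {
  if (freq$p1 <= 0 || freq$p2 <= 0)
    stop("additive contrast undefined: SNP is monomorphic")
  s <- c(freq$P11 / freq$p1,
         0.5 * freq$P12 * (freq$p2 - freq$p1) / (freq$p1 * freq$p2),
         -freq$P22 / freq$p2)
  attr(s, "kind") <- "additive"
  s
}

#' Dominance contrast coefficients
#'
#' The constant contrast (-0.5, 1, -0.5): heterozygote genotypic value
#' minus the homozygote midpoint, i.e. the dominance effect
#' \eqn{\delta = g_{12} - (g_{11}+g_{22})/2}.
#'
#' @return Numeric vector `c(-0.5, 1, -0.5)` with attribute
#'   `kind = "dominance"`.
#' @export
dominance_contrast <- function() {
  s <- c(-0.5, 1, -0.5)
  attr(s, "kind") <- "dominance"
  s
}
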