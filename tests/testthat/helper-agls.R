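# Shared fixture builders: everything is generated in code at test time.

# A snp_freq object from explicit genotype counts.
freq_from_counts <- function(n11, n12, n22) {
  genotype_frequencies(c(rep(0L, n11), rep(1L, n12), rep(2L, n22)))
}

# Hardy-Weinberg snp_freq at allele frequency p1 (exact proportions).
freq_hwe <- function(p1) {
  q <- 1 - p1
  structure(list(n_called = NA_integer_, n11 = NA, n12 = NA, n22 = NA,
                 P11 = p1^2, P12 = 2 * p1 * q, P22 = q^2,
                 p1 = p1, p2 = q, maf = min(p1, q)),
            class = "snp_freq")
}

# Small deterministic cohort with one strong causal SNP, for pipeline tests.
small_cohort <- function(n = 400, m = 20, seed = 42, alpha = 2, delta = 0) {
  cfg <- sim_config(n, m,
                    causal = data.frame(snp = 3L, trait = "milk",
                                        alpha = alpha, delta = delta),
                    traits = list(milk = list(sigma_a2 = 1, sigma_e2 = 1,
                                              reliability = 0.8)),
                    n_background_loci = 100L, seed = seed)
  simulate_dataset(cfg)
}

# Independent one-way-layout contrast t via lm(): the textbook oracle for
# the AGLS least-squares contrast statistic.
lm_contrast_t <- function(y, codes, s) {
  f <- factor(codes, levels = sort(unique(codes)))
  fit <- stats::lm(y ~ 0 + f)
  present <- sort(unique(codes)) + 1L
  sc <- s[present]
  est <- sum(sc * stats::coef(fit))
  se <- sqrt(as.numeric(t(sc) %*% stats::vcov(fit) %*% sc))
  abs(est) / se
}
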