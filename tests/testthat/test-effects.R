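test_that("allelic decomposition reproduces the hand-worked example", {
  # g = (10, 8, 2) at HWE p1 = 0.6
  dec <- allelic_decomposition(c(10, 8, 2), freq_hwe(0.6))
  expect_equal(dec$mu1, 9.2)
  expect_equal(dec$mu2, 5.6)
  expect_equal(dec$mu, 7.76)
  expect_equal(dec$a1, 1.44)
  expect_equal(dec$a2, -2.16)
  expect_equal(dec$alpha, 3.6)
  # cross-check: s_a . g gives the same average effect of substitution
  s <- additive_contrast(freq_hwe(0.6))
  expect_equal(sum(s * c(10, 8, 2)), 3.6, tolerance = 1e-12)
})

test_that("flat genotypic values decompose to zero effects", {
  dec <- allelic_decomposition(c(3, 3, 3), freq_hwe(0.3))
  expect_equal(dec$mu1, 3)
  expect_equal(dec$mu2, 3)
  expect_equal(c(dec$a1, dec$a2, dec$alpha, dec$delta), rep(0, 4))
})

test_that("decomposition requires all classes and both alleles", {
  expect_error(allelic_decomposition(c(1, NA, 2), freq_hwe(0.5)),
               "all three")
  expect_error(allelic_decomposition(c(1, 2, 3), freq_hwe(1)), "alleles")
})

test_that("three routes to alpha coincide and allelic effects conserve", {
  set.seed(55)
  for (i in 1:100) {
    cnt <- rmultinom(1, 300, prob = runif(3, 0.05, 1))
    if (any(cnt == 0)) next
    f <- freq_from_counts(cnt[1], cnt[2], cnt[3])
    g <- rnorm(3, 0, 5)
    dec <- allelic_decomposition(g, f)
    s <- as.numeric(additive_contrast(f))
    expect_equal(dec$alpha, dec$mu1 - dec$mu2, tolerance = 1e-10)
    expect_equal(dec$alpha, dec$a1 - dec$a2, tolerance = 1e-10)
    expect_equal(dec$alpha, sum(s * g), tolerance = 1e-10)
    expect_lt(abs(f$p1 * dec$a1 + f$p2 * dec$a2), 1e-10)
  }
})

test_that("relabeling alleles negates alpha and preserves delta", {
  set.seed(66)
  for (i in 1:50) {
    cnt <- rmultinom(1, 200, prob = c(1, 1, 1))
    if (any(cnt == 0)) next
    f <- freq_from_counts(cnt[1], cnt[2], cnt[3])
    f_swap <- freq_from_counts(cnt[3], cnt[2], cnt[1])
    g <- rnorm(3)
    dec <- allelic_decomposition(g, f)
    dec_swap <- allelic_decomposition(rev(g), f_swap)
    expect_equal(dec_swap$alpha, -dec$alpha, tolerance = 1e-10)
    expect_equal(dec_swap$delta, dec$delta, tolerance = 1e-12)
  }
})

test_that("dominance effect is the heterozygote minus homozygote midpoint", {
  expect_equal(dominance_effect(c(10, 8, 2)), 2)
  expect_equal(dominance_effect(c(5, 9, 6)), 3.5)
  expect_equal(dominance_effect(c(0, 1, 2)), 0)
  expect_true(is.na(dominance_effect(c(0, NA, 2))))
})

test_that("dominance modes classify by heterozygote position", {
  expect_equal(classify_dominance_mode(c(5, 9, 6)), "overdominant_positive")
  expect_equal(classify_dominance_mode(c(5, 1, 6)), "overdominant_negative")
  expect_equal(classify_dominance_mode(c(0, 1, 2)), "none")
  expect_equal(classify_dominance_mode(c(0, 2, 2)), "complete")
  expect_equal(classify_dominance_mode(c(0, 1.5, 2)), "partial")
})

test_that("allelic patterns follow the magnitude-ratio typology", {
  expect_equal(classify_allelic_pattern(1, -1), "symmetric")
  expect_equal(classify_allelic_pattern(2, -0.1), "uniallelic_positive")
  expect_equal(classify_allelic_pattern(-2, 0.1), "uniallelic_negative")
  expect_equal(classify_allelic_pattern(2, -0.8), "asymmetric_positive")
  expect_equal(classify_allelic_pattern(-2, 0.8), "asymmetric_negative")
  expect_equal(classify_allelic_pattern(0, 0), "none")
  # same-sign near-equal magnitudes are asymmetric, not symmetric
  expect_equal(classify_allelic_pattern(1, 0.9), "asymmetric_positive")
})

test_that("mu_all averages genotypic means of the reporting set", {
  expect_equal(compute_mu_all(c(0, 2)), 1)
  expect_equal(compute_mu_all(5), 5)
  expect_error(compute_mu_all(numeric(0)), "empty")
  # single-SNP reporting set: comparable effects equal plain effects
  dec <- allelic_decomposition(c(10, 8, 2), freq_hwe(0.6),
                               mu_all = compute_mu_all(7.76))
  expect_equal(dec$a1_comparable, dec$a1)
  expect_equal(dec$a2_comparable, dec$a2)
  # general mu_all: shift identity a_comparable - a = mu - mu_all
  dec2 <- allelic_decomposition(c(10, 8, 2), freq_hwe(0.6), mu_all = 5)
  expect_equal(dec2$a1_comparable - dec2$a1, dec2$mu - 5, tolerance = 1e-10)
})

test_that("shifting phenotypes shifts mu_all but not alpha, delta or pattern", {
  d <- small_cohort(n = 300, m = 10, seed = 91, alpha = 2)
  res <- run_gwas(d$genotypes, d$phenotypes, d$pta)
  ph2 <- d$phenotypes
  ph2$value <- ph2$value + 100
  res2 <- run_gwas(d$genotypes, ph2, d$pta)
  m <- match(res$snp_id, res2$snp_id)
  expect_equal(res2$alpha[m], res$alpha, tolerance = 1e-8)
  expect_equal(res2$delta[m], res$delta, tolerance = 1e-8)
  expect_equal(res2$mu[m], res$mu + 100, tolerance = 1e-8)
  expect_equal(res2$pattern[m], res$pattern)
  expect_equal(res2$a1_comparable[m], res$a1_comparable, tolerance = 1e-8)
})

test_that("parameter recovery over replicates is unbiased", {
  reps <- 60
  est <- matrix(NA_real_, reps, 2)
  for (s in seq_len(reps)) {
    cfg <- sim_config(1500, 1, p1 = 0.4,
                      causal = data.frame(snp = 1, trait = "t",
                                          alpha = 1, delta = 0.5),
                      traits = list(t = list(sigma_a2 = 1, sigma_e2 = 1,
                                             reliability = 0.8)),
                      n_background_loci = 50L, seed = 9000 + s)
    d <- simulate_dataset(cfg)
    ystar <- adjust_phenotypes(d$phenotypes, d$pta, "t")
    col <- d$genotypes$codes[names(ystar), 1]
    fit <- fit_snp(ystar, col, 1L)
    dec <- allelic_decomposition(fit$g_hat, genotype_frequencies(col))
    est[s, ] <- c(dec$alpha, dec$delta)
  }
  se <- apply(est, 2, sd) / sqrt(reps)
  expect_lt(abs(mean(est[, 1]) - 1), 2 * se[1] + 1e-12)
  expect_lt(abs(mean(est[, 2]) - 0.5), 2 * se[2] + 1e-12)
})
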