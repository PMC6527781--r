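# Internal per-SNP scan shared by run_gwas() and conditional_scan().
# ystar_list: named list trait -> named numeric vector of adjusted (or
# residualized) phenotypes.  Returns one row per (tested SNP, trait);
# monomorphic-in-sample SNPs are skipped and counted in attr "n_skipped".
.agls_scan <- function(geno, ystar_list, snp_idx = NULL,
                       control = agls_control()) {
  codes <- geno$codes
  map <- geno$map
  if (is.null(snp_idx)) snp_idx <- seq_len(ncol(codes))
  traits <- names(ystar_list)
  rows <- vector("list", length(snp_idx) * length(traits))
  ri <- 0L
  n_skipped <- 0L
  for (tr in traits) {
    ystar <- ystar_list[[tr]]
    ids <- intersect(rownames(codes), names(ystar))
    if (length(ids) == 0L) next
    y <- ystar[ids]
    sub <- codes[ids, snp_idx, drop = FALSE]
    for (j in seq_along(snp_idx)) {
      col <- sub[, j]
      fit <- tryCatch(fit_snp(y, col, control$min_class_count),
                      error = function(e) NULL)
      if (is.null(fit)) { n_skipped <- n_skipped + 1L; next }
      freq <- genotype_frequencies(col[!is.na(y)])
      tst <- snp_tests(fit, freq, control)
      all_present <- all(fit$counts > 0L)
      if (all_present) {
        dec <- allelic_decomposition(fit$g_hat, freq)
        a1 <- dec$a1; a2 <- dec$a2; mu <- dec$mu; delta <- dec$delta
      } else {
        a1 <- a2 <- mu <- delta <- NA_real_
      }
      ri <- ri + 1L
      mrow <- map[snp_idx[j], ]
      rows[[ri]] <- data.frame(
        snp_id = mrow$snp_id, chrom = mrow$chrom, pos_bp = mrow$pos_bp,
        allele1 = mrow$allele1, allele2 = mrow$allele2, trait = tr,
        n_used = fit$n,
        p1 = freq$p1, p2 = freq$p2,
        P11 = freq$P11, P12 = freq$P12, P22 = freq$P22, maf = freq$maf,
        g11_hat = fit$g_hat[1L], g12_hat = fit$g_hat[2L],
        g22_hat = fit$g_hat[3L],
        alpha = tst$alpha, a1 = a1, a2 = a2,
        a1_comparable = NA_real_, a2_comparable = NA_real_, delta = delta,
        t_add = tst$t_add, log10invp_add = tst$log10invp_add,
        t_dom = tst$t_dom, log10invp_dom = tst$log10invp_dom,
        rank_add = NA_integer_, rank_dom = NA_integer_,
        dominance_untestable = tst$dominance_untestable,
        effect_suppressed_low_maf = freq$maf < control$maf_reporting_min,
        empirical_p_used = tst$empirical_p_used_add ||
          isTRUE(tst$empirical_p_used_dom),
        mu = mu,
        stringsAsFactors = FALSE)
    }
  }
  if (ri == 0L) stop("no testable (SNP, trait) pairs")
  out <- do.call(rbind, rows[seq_len(ri)])
  rownames(out) <- NULL
  attr(out, "n_skipped") <- n_skipped
  out
}

# Comparable allelic effects about the per-trait mu_all (mean genotypic
# mean over SNPs passing the MAF reporting filter), plus pattern and
# dominance-mode labels.
.add_comparable_effects <- function(rows, control) {
  rows$pattern <- NA_character_
  rows$dominance_mode <- NA_character_
  for (tr in unique(rows$trait)) {
    sel <- rows$trait == tr
    rep_set <- sel & !rows$effect_suppressed_low_maf & !is.na(rows$mu)
    mu_all <- if (any(rep_set)) compute_mu_all(rows$mu[rep_set])
              else NA_real_
    has <- sel & !is.na(rows$mu)
    rows$a1_comparable[has] <- rows$a1[has] + rows$mu[has] - mu_all
    rows$a2_comparable[has] <- rows$a2[has] + rows$mu[has] - mu_all
    idx <- which(has)
    for (i in idx) {
      rows$pattern[i] <- classify_allelic_pattern(
        rows$a1_comparable[i], rows$a2_comparable[i],
        control$pattern_thresholds)
      rows$dominance_mode[i] <- classify_dominance_mode(
        c(rows$g11_hat[i], rows$g12_hat[i], rows$g22_hat[i]),
        rows$delta[i], control$complete_dom_tol)
    }
  }
  rows
}

#' Run the AGLS genome scan
#'
#' For each trait: adjust phenotypes by `y* = y - 2*PTA`, then for every
#' SNP fit the genotype-class means by least squares, test the additive
#' (HWD-robust) and dominance contrasts, decompose into allelic effects,
#' and rank.  Missing genotypes are handled per SNP (pairwise deletion);
#' SNPs monomorphic among the analyzed individuals are skipped.
#'
#' @param geno a [genotype_matrix].
#' @param pheno phenotype [trait_table] (yield deviations).
#' @param pta PTA [trait_table].
#' @param traits traits to analyze (default: traits present in both
#'   tables).
#' @param control an [agls_control].
#' @param verbose log per-trait sample sizes and drop counts.
#' @return data.frame with one row per (tested SNP, trait): identity,
#'   frequencies, genotypic-value estimates, allelic effects (plain and
#'   cross-SNP comparable), average effect of gene substitution `alpha`,
#'   dominance effect `delta`, t-statistics and `log10(1/p)` for both
#'   contrasts, per-trait ranks, status flags, pattern and dominance-mode
#'   labels, and Bonferroni significance flags.  Attributes:
#'   `bonferroni` (threshold list), `log` (per-trait sample-size records).
#' @export
run_gwas <- function(geno, pheno, pta, traits = NULL,
                     control = agls_control(), verbose = FALSE) {
  if (is.null(traits))
    traits <- intersect(trait_names(pheno), trait_names(pta))
  if (length(traits) == 0L) stop("no traits shared by phenotype and PTA tables")
  ystar_list <- list()
  log <- list()
  for (tr in traits) {
    ystar <- adjust_phenotypes(pheno, pta, tr)
    keep <- intersect(rownames(geno$codes), names(ystar))
    if (length(keep) == 0L) next
    ystar_list[[tr]] <- ystar[keep]
    log[[tr]] <- list(n_phenotyped = length(ystar) + attr(ystar, "n_dropped"),
                      n_with_pta = length(ystar),
                      n_genotyped = length(keep))
    if (verbose)
      message(sprintf("trait %s: %d with y and PTA, %d also genotyped",
                      tr, length(ystar), length(keep)))
  }
  if (length(ystar_list) == 0L)
    stop("no overlapping individuals between genotypes and trait tables")
  rows <- .agls_scan(geno, ystar_list, NULL, control)
  rows <- .add_comparable_effects(rows, control)
  rows <- rank_and_filter(rows, control)
  attr(rows, "log") <- log
  rows
}
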