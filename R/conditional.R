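#' Remove an index SNP's genotypic effects from adjusted phenotypes
#'
#' Each individual's residual is `y* - g_hat(class at index SNP)`, where
#' `g_hat` are the index SNP's estimated genotypic values.  Individuals
#' with a missing index genotype are dropped.  Re-analyzing a region with
#' these residuals shows which associations are merely linked to the index
#' SNP (they vanish) and which are independent (they persist).
#'
#' @param y_star named adjusted-phenotype vector.
#' @param index_codes genotype codes at the index SNP, aligned with
#'   `y_star`.
#' @param index_fit the index SNP's [fit_snp] on the same individuals.
#' @return Named residual vector.
#' @export
residualize_on_index <- function(y_star, index_codes, index_fit) {
  if (index_fit$k < 2L) stop("index SNP monomorphic")
  keep <- !is.na(index_codes) & !is.na(y_star)
  g <- index_fit$g_hat[index_codes[keep] + 1L]
  res <- y_star[keep] - g
  res[!is.na(g)]
}

# Resolve a region spec ("chr:start-end" or list(chrom, start, end)) to
# SNP column indices.
.region_snps <- function(geno, region) {
  if (is.character(region) && length(region) == 1L) {
    m <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1L]]
    if (length(m) != 4L) stop("region must be 'chrom:start-end'")
    region <- list(chrom = m[2L], start = as.numeric(m[3L]),
                   end = as.numeric(m[4L]))
  }
  idx <- which(geno$map$chrom == as.character(region$chrom) &
               geno$map$pos_bp >= region$start &
               geno$map$pos_bp <= region$end)
  if (length(idx) == 0L) stop("empty region")
  idx
}

#' Conditional regional scan
#'
#' The same per-SNP AGLS machinery as [run_gwas], applied to residual
#' phenotypes (typically from [residualize_on_index]) and restricted to
#' the SNPs of a genomic region.
#'
#' @param geno a [genotype_matrix].
#' @param region `"chrom:start-end"` string or
#'   `list(chrom=, start=, end=)`; `NULL` scans every SNP.
#' @param y_resid named list `trait -> named residual vector`.
#' @param control an [agls_control].
#' @return Ranked result data.frame (same shape as [run_gwas] output).
#' @export
conditional_scan <- function(geno, region, y_resid,
                             control = agls_control()) {
  idx <- if (is.null(region)) seq_len(ncol(geno$codes))
         else .region_snps(geno, region)
  rows <- .agls_scan(geno, y_resid, idx, control)
  rows <- .add_comparable_effects(rows, control)
  rank_and_filter(rows, control)
}

#' Top-fraction retention summary of a conditional analysis
#'
#' A (SNP, trait) effect is "top fraction" when its unconditional rank is
#' at most `ceiling(fraction * SNPs tested for the trait)` among the
#' `before` rows.  After conditioning, survival is judged against the
#' unconditional per-trait `log10(1/p)` cutoff (the smallest top-fraction
#' value) applied to the conditional results, so the yardstick is fixed by
#' the unconditional scan.
#'
#' @param before unconditional result rows (e.g. [run_gwas] output
#'   restricted to the region).
#' @param after conditional result rows over the same (SNP, trait) grid.
#' @param fraction top fraction, default 0.01.
#' @return Object of class `conditional_report`: `summary` data.frame
#'   (trait, n_snps, top_k, cutoff_log10invp, n_top_before, n_top_after)
#'   and `pairs` data.frame of per-(SNP, trait) before/after
#'   `log10(1/p)` values.
#' @export
retention_summary <- function(before, after, fraction = 0.01) {
  key_b <- paste(before$snp_id, before$trait)
  key_a <- paste(after$snp_id, after$trait)
  if (!setequal(key_b, key_a))
    stop("before/after rows do not cover the same (SNP, trait) grid")
  traits <- unique(before$trait)
  summ <- vector("list", length(traits))
  for (i in seq_along(traits)) {
    tr <- traits[i]
    b <- before[before$trait == tr, ]
    a <- after[after$trait == tr, ]
    n <- nrow(b)
    k <- ceiling(fraction * n)
    ord <- order(-b$log10invp_add, -abs(b$alpha), b$snp_id)
    cutoff <- b$log10invp_add[ord[k]]
    n_before <- k
    n_after <- sum(a$log10invp_add >= cutoff, na.rm = TRUE)
    summ[[i]] <- data.frame(trait = tr, n_snps = n, top_k = k,
                            cutoff_log10invp = cutoff,
                            n_top_before = n_before, n_top_after = n_after,
                            stringsAsFactors = FALSE)
  }
  pairs <- merge(
    data.frame(snp_id = before$snp_id, trait = before$trait,
               log10invp_before = before$log10invp_add,
               stringsAsFactors = FALSE),
    data.frame(snp_id = after$snp_id, trait = after$trait,
               log10invp_after = after$log10invp_add,
               stringsAsFactors = FALSE),
    by = c("snp_id", "trait"))
  structure(list(summary = do.call(rbind, summ), pairs = pairs,
                 fraction = fraction),
            class = "conditional_report")
}

#' @export
print.conditional_report <- function(x, ...) {
  cat(sprintf("Top-%.3g%% retention with index-SNP effects removed:\n",
              100 * x$fraction))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' End-to-end conditional analysis
#'
#' Convenience wrapper: adjusts phenotypes, fits the index SNP per trait,
#' removes its genotypic effects, rescans the region on the residuals, and
#' summarizes top-fraction retention against the unconditional scan of the
#' same region.
#'
#' @param geno a [genotype_matrix].
#' @param pheno,pta trait tables.
#' @param index_snp snp_id of the index SNP.
#' @param region region spec (default: `NULL`, the whole panel).
#' @param traits traits to analyze.
#' @param fraction top fraction for the retention summary.
#' @param control an [agls_control].
#' @return List: `before`, `after` (result data.frames) and `report`
#'   (a `conditional_report`).
#' @export
conditional_analysis <- function(geno, pheno, pta, index_snp, region = NULL,
                                 traits = NULL, fraction = 0.01,
                                 control = agls_control()) {
  j <- match(index_snp, geno$map$snp_id)
  if (is.na(j)) stop("index SNP not found: ", index_snp)
  if (is.null(traits))
    traits <- intersect(trait_names(pheno), trait_names(pta))
  ystar_list <- list()
  resid_list <- list()
  for (tr in traits) {
    ystar <- adjust_phenotypes(pheno, pta, tr)
    ids <- intersect(rownames(geno$codes), names(ystar))
    ystar <- ystar[ids]
    icodes <- geno$codes[ids, j]
    ifit <- fit_snp(ystar, icodes, min_class_count = 1L)
    resid_list[[tr]] <- residualize_on_index(ystar, icodes, ifit)
    # keep both arms on the individuals with a called index genotype
    ystar_list[[tr]] <- ystar[names(resid_list[[tr]])]
  }
  before <- conditional_scan(geno, region, ystar_list, control)
  after <- conditional_scan(geno, region, resid_list, control)
  list(before = before, after = after,
       report = retention_summary(before, after, fraction))
}
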