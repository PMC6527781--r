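#' Bonferroni genome-wide significance threshold
#'
#' `alpha / (n_snps * n_traits)`, returned both exactly and rounded to one
#' significant order of magnitude (the operational form: 0.05 over
#' 57,067 SNPs and 9 traits gives 9.73e-8, used as 1e-7).
#'
#' @param alpha genome-wide false-positive rate.
#' @param n_snps number of SNPs entering the correction.
#' @param n_traits number of traits.
#' @return List with `exact`, `rounded` and `log10invp` (the `-log10` of
#'   the exact threshold, for comparisons on the log scale).
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_snps, n_traits = 1) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0,1)")
  if (n_snps < 1 || n_traits < 1) stop("zero tests: threshold undefined")
  exact <- alpha / (n_snps * n_traits)
  list(exact = exact, rounded = 10^round(log10(exact)),
       log10invp = -log10(exact))
}

#' Rank results and apply reporting filters
#'
#' Per trait, additive and dominance results are ranked by `log10(1/p)`
#' descending with ties broken by `|alpha|` descending then `snp_id`
#' (a total order, so ranks are unique).  Effect-size fields of SNPs below
#' the MAF reporting floor are flagged as suppressed (never deleted), and
#' Bonferroni significance flags are attached; the correction uses the
#' count of SNPs passing the MAF filter times the number of traits.
#'
#' @param rows scan result data.frame.
#' @param control an [agls_control].
#' @return `rows` with `rank_add`, `rank_dom`, `sig_add`, `sig_dom` filled
#'   in and attribute `bonferroni`.
#' @export
rank_and_filter <- function(rows, control = agls_control()) {
  rows$effect_suppressed_low_maf <- rows$maf < control$maf_reporting_min
  traits <- unique(rows$trait)
  n_report_snps <- length(unique(rows$snp_id[!rows$effect_suppressed_low_maf]))
  bon <- bonferroni_threshold(control$alpha_genomewide,
                              max(n_report_snps, 1L), length(traits))
  rows$sig_add <- !is.na(rows$log10invp_add) &
    rows$log10invp_add > bon$log10invp
  rows$sig_dom <- !is.na(rows$log10invp_dom) &
    rows$log10invp_dom > bon$log10invp
  for (tr in traits) {
    sel <- which(rows$trait == tr)
    o <- order(-rows$log10invp_add[sel], -abs(rows$alpha[sel]),
               rows$snp_id[sel])
    rows$rank_add[sel[o]] <- seq_along(sel)
    dsel <- sel[!is.na(rows$log10invp_dom[sel])]
    if (length(dsel)) {
      o <- order(-rows$log10invp_dom[dsel], -abs(rows$delta[dsel]),
                 rows$snp_id[dsel])
      rows$rank_dom[dsel[o]] <- seq_along(dsel)
    }
  }
  attr(rows, "bonferroni") <- bon
  rows
}

#' Manhattan plot data table
#'
#' Per-trait plot-ready table: chromosome, position, `log10(1/p)` of the
#' additive test and a genome-wide significance flag, sorted by chromosome
#' then position (numeric chromosome names sort numerically).
#'
#' @param rows ranked result data.frame from [run_gwas].
#' @param which `"add"` or `"dom"`.
#' @return data.frame with columns trait, chrom, pos_bp, snp_id,
#'   log10invp, significant.
#' @export
manhattan_table <- function(rows, which = c("add", "dom")) {
  which <- match.arg(which)
  lip <- if (which == "add") rows$log10invp_add else rows$log10invp_dom
  sig <- if (which == "add") rows$sig_add else rows$sig_dom
  out <- data.frame(trait = rows$trait, chrom = rows$chrom,
                    pos_bp = rows$pos_bp, snp_id = rows$snp_id,
                    log10invp = lip, significant = sig,
                    stringsAsFactors = FALSE)
  cnum <- suppressWarnings(as.numeric(out$chrom))
  key <- if (anyNA(cnum)) order(out$trait, out$chrom, out$pos_bp)
         else order(out$trait, cnum, out$pos_bp)
  out <- out[key, , drop = FALSE]
  rownames(out) <- NULL
  out
}
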