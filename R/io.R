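#' Read a genotype matrix
#'
#' Three dialects are supported:
#' \describe{
#'   \item{`tsv`}{header `id<TAB>snp1<TAB>...`, codes 0/1/2, missing `NA`;
#'     a companion SNP map (`map` argument) supplies identity columns.}
#'   \item{`plink_raw`}{PLINK `--recode A` additive dosage; the counted
#'     allele in the `SNP_A` header is allele2.}
#'   \item{`vcf`}{GT fields only; the ALT allele is allele2; non-biallelic
#'     records are skipped with a warning.  Requires the `vcfR` package.}
#' }
#' Codes are always oriented as counts of allele2.
#'
#' @param path file path.
#' @param dialect one of `"tsv"`, `"plink_raw"`, `"vcf"`.
#' @param map for `tsv` (required) and `plink_raw` (optional), path to a SNP
#'   map file `snp_id<TAB>chrom<TAB>pos<TAB>allele1<TAB>allele2` (no header),
#'   or a data.frame with those columns.
#' @return A [genotype_matrix].
#' @export
read_genotypes <- function(path, dialect = c("tsv", "plink_raw", "vcf"),
                           map = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(dialect,
         tsv = .read_genotypes_tsv(path, map),
         plink_raw = .read_genotypes_raw(path, map),
         vcf = .read_genotypes_vcf(path))
}

.read_snp_map <- function(map) {
  if (is.data.frame(map)) {
    m <- map
    if (!"pos_bp" %in% names(m) && "pos" %in% names(m))
      names(m)[names(m) == "pos"] <- "pos_bp"
    return(m)
  }
  m <- utils::read.table(map, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE,
                         col.names = c("snp_id", "chrom", "pos_bp",
                                       "allele1", "allele2"),
                         colClasses = c("character", "character", "integer",
                                        "character", "character"))
  m
}

.read_genotypes_tsv <- function(path, map) {
  if (is.null(map)) stop("tsv dialect requires a SNP map")
  lines <- readLines(path)
  if (length(lines) < 1L) stop("empty genotype file: ", path)
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (header[1L] != "id")
    stop("parse error at line 1: header must start with 'id'")
  snp_ids <- header[-1L]
  n <- length(lines) - 1L
  ids <- character(n)
  codes <- matrix(NA_integer_, n, length(snp_ids))
  for (i in seq_len(n)) {
    f <- strsplit(lines[i + 1L], "\t", fixed = TRUE)[[1L]]
    if (length(f) != length(header))
      stop("parse error at line ", i + 1L, ": expected ", length(header),
           " fields, found ", length(f))
    ids[i] <- f[1L]
    v <- f[-1L]
    bad <- !(v %in% c("0", "1", "2", "NA"))
    if (any(bad))
      stop("parse error at line ", i + 1L, ": invalid code '",
           v[which(bad)[1L]], "'")
    codes[i, ] <- suppressWarnings(as.integer(v))
  }
  m <- .read_snp_map(map)
  m <- m[match(snp_ids, m$snp_id), , drop = FALSE]
  if (anyNA(m$snp_id))
    stop("SNP map missing entries for: ",
         paste(utils::head(snp_ids[is.na(m$snp_id)], 5L), collapse = ", "))
  genotype_matrix(codes, ids, m)
}

.read_genotypes_raw <- function(path, map) {
  raw <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                           check.names = FALSE)
  fixed <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  if (!all(fixed %in% names(raw)))
    stop("parse error: PLINK .raw header must contain ",
         paste(fixed, collapse = " "))
  gcols <- setdiff(names(raw), fixed)
  # header tokens are SNP_<counted allele>; the counted allele is allele2
  snp_ids <- sub("_[^_]*$", "", gcols)
  counted <- sub("^.*_", "", gcols)
  codes <- as.matrix(raw[, gcols, drop = FALSE])
  storage.mode(codes) <- "integer"
  if (!is.null(map)) {
    m <- .read_snp_map(map)
    m <- m[match(snp_ids, m$snp_id), , drop = FALSE]
    if (anyNA(m$snp_id)) stop("SNP map missing entries for PLINK .raw SNPs")
    flip <- m$allele1 == counted  # counted allele must be allele2
    if (any(flip)) {
      codes[, flip] <- 2L - codes[, flip, drop = FALSE]
      a1 <- m$allele1
      m$allele1[flip] <- m$allele2[flip]
      m$allele2[flip] <- a1[flip]
    }
  } else {
    m <- data.frame(snp_id = snp_ids, chrom = "0",
                    pos_bp = seq_along(snp_ids), allele1 = "X",
                    allele2 = counted, stringsAsFactors = FALSE)
    m$allele1[m$allele1 == m$allele2] <- "Y"
  }
  genotype_matrix(codes, raw$IID, m)
}

.read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("the vcf dialect requires the 'vcfR' package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  fix <- matrix(fix, ncol = ncol(fix), dimnames = dimnames(fix))
  alt <- fix[, "ALT"]
  ref <- fix[, "REF"]
  multi <- grepl(",", alt) | nchar(ref) == 0L
  if (any(multi)) {
    warning(sum(multi), " non-biallelic VCF record(s) skipped")
  }
  keep <- which(!multi)
  if (length(keep) == 0L) stop("no biallelic records in VCF")
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  # ALT dosage: count '1' alleles in the GT string; '.' makes the call missing
  dose <- function(s) {
    if (is.na(s)) return(NA_integer_)
    al <- strsplit(s, "[/|]")[[1L]]
    if (any(al == ".")) return(NA_integer_)
    sum(al == "1")
  }
  codes <- t(apply(gt, c(1L, 2L), dose))
  ids <- colnames(gt)
  snp_id <- fix[keep, "ID"]
  noid <- is.na(snp_id) | snp_id == "."
  snp_id[noid] <- paste0(fix[keep, "CHROM"], ":", fix[keep, "POS"])[noid]
  m <- data.frame(snp_id = snp_id, chrom = fix[keep, "CHROM"],
                  pos_bp = as.integer(fix[keep, "POS"]),
                  allele1 = ref[keep], allele2 = alt[keep],
                  stringsAsFactors = FALSE)
  genotype_matrix(codes, ids, m)
}

#' Write a genotype matrix in the TSV dialect
#'
#' Emits the genotype table (`id` column + one column per SNP, missing as
#' `NA`) and the companion SNP map.
#'
#' @param geno a [genotype_matrix].
#' @param path genotype file path.
#' @param map_path SNP map file path.
#' @export
write_genotypes <- function(geno, path, map_path) {
  codes <- geno$codes
  lines <- c(paste(c("id", colnames(codes)), collapse = "\t"),
             vapply(seq_len(nrow(codes)), function(i) {
               paste(c(rownames(codes)[i],
                       ifelse(is.na(codes[i, ]), "NA", codes[i, ])),
                     collapse = "\t")
             }, character(1)))
  writeLines(lines, path)
  utils::write.table(geno$map, map_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(NULL)
}

#' Read a phenotype or PTA table
#'
#' Wide plain-text table: header `id<TAB>trait1<TAB>trait2...`, one row per
#' individual.  Empty cells or `NA` become absent entries (never zeros).
#'
#' @param path file path.
#' @param kind `"phenotype"` or `"pta"`.
#' @return A [trait_table].
#' @export
read_trait_table <- function(path, kind = c("phenotype", "pta")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character", na.strings = c("NA", ""))
  if (!"id" %in% names(df)) stop("trait table must have an 'id' column")
  if (anyDuplicated(df$id))
    stop("duplicated individual id: ", df$id[duplicated(df$id)][1L])
  for (tr in setdiff(names(df), "id")) {
    v <- df[[tr]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(num))
    if (length(bad))
      stop("non-numeric cell at (", df$id[bad[1L]], ", ", tr, "): '",
           v[bad[1L]], "'")
    df[[tr]] <- num
  }
  trait_table(df, kind = kind)
}

#' Write a trait table (wide TSV)
#'
#' @param tab a [trait_table].
#' @param path file path.
#' @export
write_trait_table <- function(tab, path) {
  traits <- trait_names(tab)
  ids <- unique(tab$id)
  wide <- data.frame(id = ids, stringsAsFactors = FALSE)
  for (tr in traits) {
    v <- trait_values(tab, tr)
    wide[[tr]] <- format(v[ids], digits = 12, trim = TRUE, scientific = FALSE)
    wide[[tr]][is.na(v[ids])] <- NA
  }
  utils::write.table(wide, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(NULL)
}

# Stable column order of the per-(SNP, trait) result table.
.result_columns <- c(
  "snp_id", "chrom", "pos_bp", "allele1", "allele2", "trait", "n_used",
  "p1", "p2", "P11", "P12", "P22", "maf",
  "g11_hat", "g12_hat", "g22_hat",
  "alpha", "a1", "a2", "a1_comparable", "a2_comparable", "delta",
  "t_add", "log10invp_add", "t_dom", "log10invp_dom",
  "rank_add", "rank_dom",
  "dominance_untestable", "effect_suppressed_low_maf", "empirical_p_used")

#' Write a result table
#'
#' Tab-separated with a single header row, columns in the stable order
#' (identity, trait, frequencies, genotypic values, effects, tests, ranks,
#' status flags, then any extra columns such as significance flags).
#' Numeric values are written with 10 significant digits so that a
#' read-back reproduces them.
#'
#' @param rows result data.frame from [run_gwas] or [conditional_scan].
#' @param path output file path.
#' @export
write_results <- function(rows, path) {
  if (is.null(rows) || nrow(rows) == 0L) stop("no result rows to write")
  cols <- c(intersect(.result_columns, names(rows)),
            setdiff(names(rows), .result_columns))
  out <- rows[, cols, drop = FALSE]
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]]))
      out[[j]] <- trimws(formatC(out[[j]], digits = 10, format = "g"))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(NULL)
}

#' Read back a result table written by [write_results]
#' @param path file path.
#' @return data.frame.
#' @export
read_results <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}
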