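#' Construct a genotype matrix
#'
#' The central genotype container: an individuals x SNPs matrix of allele2
#' dosage codes (0 = A1A1, 1 = A1A2, 2 = A2A2, `NA` = missing) together with
#' a SNP map carrying identity, position and allele labels.  Allele2 is
#' always the counted allele; A1 is the first-listed allele of the source
#' file.
#'
#' @param codes integer matrix, individuals in rows and SNPs in columns;
#'   entries must be 0, 1, 2 or `NA`.
#' @param individuals character vector of individual ids (row order).
#' @param map data.frame with columns `snp_id`, `chrom`, `pos_bp`,
#'   `allele1`, `allele2` (column order of `codes`).
#' @return An object of class `genotype_matrix` with elements `codes`
#'   (dimnames set to ids and SNP ids) and `map`.
#' @export
genotype_matrix <- function(codes, individuals, map) {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  individuals <- as.character(individuals)
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  req <- c("snp_id", "chrom", "pos_bp", "allele1", "allele2")
  if (!all(req %in% names(map)))
    stop("SNP map must have columns: ", paste(req, collapse = ", "))
  map <- map[, req]
  map$snp_id <- as.character(map$snp_id)
  map$chrom <- as.character(map$chrom)
  map$pos_bp <- as.integer(map$pos_bp)
  map$allele1 <- as.character(map$allele1)
  map$allele2 <- as.character(map$allele2)
  if (nrow(codes) != length(individuals))
    stop("row count (", nrow(codes), ") != individual count (",
         length(individuals), ")")
  if (ncol(codes) != nrow(map))
    stop("column count (", ncol(codes), ") != SNP count (", nrow(map), ")")
  if (anyDuplicated(individuals))
    stop("duplicated individual ids")
  if (anyDuplicated(map$snp_id))
    stop("duplicated snp_id in map")
  if (any(map$pos_bp < 1L, na.rm = TRUE))
    stop("pos_bp must be >= 1")
  if (any(map$allele1 == map$allele2))
    stop("allele1 and allele2 must differ")
  bad <- !(codes %in% c(0L, 1L, 2L) | is.na(codes))
  if (any(bad))
    stop("genotype codes must be 0, 1, 2 or NA")
  dimnames(codes) <- list(individuals, map$snp_id)
  structure(list(codes = codes, map = map), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$codes), "individuals x",
      ncol(x$codes), "SNPs\n")
  miss <- mean(is.na(x$codes))
  cat(sprintf("  missing rate: %.4f\n", miss))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$codes)

#' Construct a trait table
#'
#' Long-format container mapping (individual, trait) to a numeric value.
#' Used for both phenotypes (yield deviations, trait units) and PTAs
#' (half breeding-value units).  Missing cells are absent rows, never zeros.
#'
#' @param df data.frame with columns `id`, `trait`, `value` (long) or a wide
#'   data.frame with an `id` column plus one numeric column per trait.
#' @param kind `"phenotype"` or `"pta"` (informational).
#' @return Object of class `trait_table`: a long data.frame with attribute
#'   `kind`.
#' @export
trait_table <- function(df, kind = c("phenotype", "pta")) {
  kind <- match.arg(kind)
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!all(c("id", "trait", "value") %in% names(df))) {
    if (!"id" %in% names(df))
      stop("trait table needs an 'id' column")
    traits <- setdiff(names(df), "id")
    long <- do.call(rbind, lapply(traits, function(tr) {
      data.frame(id = as.character(df$id), trait = tr,
                 value = as.numeric(df[[tr]]), stringsAsFactors = FALSE)
    }))
    df <- long[!is.na(long$value), , drop = FALSE]
  } else {
    df <- df[, c("id", "trait", "value")]
    df$id <- as.character(df$id)
    df$trait <- as.character(df$trait)
    df$value <- as.numeric(df$value)
    df <- df[!is.na(df$value), , drop = FALSE]
  }
  if (anyDuplicated(df[, c("id", "trait")]))
    stop("duplicated (id, trait) pair in trait table")
  if (any(!is.finite(df$value)))
    stop("non-finite value in trait table")
  rownames(df) <- NULL
  structure(df, class = c("trait_table", "data.frame"), kind = kind)
}

#' Extract one trait as a named vector
#'
#' @param tab a `trait_table`.
#' @param trait trait name.
#' @return Named numeric vector (names = individual ids); individuals
#'   without a value for the trait are absent.
#' @export
trait_values <- function(tab, trait) {
  sub <- tab[tab$trait == trait, , drop = FALSE]
  stats::setNames(sub$value, sub$id)
}

#' List traits present in a trait table
#' @param tab a `trait_table`.
#' @return Character vector of trait names.
#' @export
trait_names <- function(tab) unique(tab$trait)
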