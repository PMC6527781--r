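#' Simulation configuration
#'
#' Defines a synthetic cohort with the statistical structure the AGLS
#' analysis assumes: biallelic genotypes with configurable allele
#' frequency and inbreeding-style Hardy-Weinberg disequilibrium, a
#' polygenic value with genuine genetic structure, PTAs correlated with
#' the polygenic value at a stated reliability, and per-SNP causal
#' additive/dominance effects.
#'
#' @param n_individuals cohort size.
#' @param n_snps SNP panel size.
#' @param maf_range range from which per-SNP A1 frequencies are drawn
#'   uniformly (ignored when `p1` is given).
#' @param p1 optional fixed A1 frequency (scalar or per-SNP vector).
#' @param inbreeding_f Wright's inbreeding-style HWD coefficient (scalar
#'   or per SNP, `0 <= f < 1`): genotype probabilities are
#'   `(p1^2 + f p1 p2, 2 p1 p2 (1-f), p2^2 + f p1 p2)`.
#' @param causal data.frame with columns `snp` (panel index), `trait`,
#'   `alpha` (average effect of gene substitution, trait units), `delta`
#'   (dominance effect); `NULL` for a null panel.
#' @param traits named list, one element per trait, each a list with
#'   `sigma_a2` (additive polygenic variance), `sigma_e2` (residual
#'   variance), `reliability` (squared correlation of 2*PTA with the
#'   polygenic value, in `[0,1]`) and `mean`.  Defaults emulate a
#'   moderate-heritability production trait: `sigma_a2 = 1`,
#'   `sigma_e2 = 2` (h2 = 1/3), `reliability = 0.8`, `mean = 0`.
#' @param n_background_loci loci building the polygenic value (independent
#'   of the tested panel).
#' @param polygenic_mode `"background"` (sum of background-locus effects,
#'   scales to large n) or `"mvn"` (multivariate normal with an explicit
#'   relationship matrix kept in the truth record, for oracle tests).
#' @param ld optional data.frame `source`, `target`, `flip_prob`: panel
#'   column `target` is rebuilt as a copy of `source` whose genotypes are
#'   independently redrawn from the marginal with probability `flip_prob`
#'   (0 = perfect LD).
#' @param missing_rate probability a genotype call is set missing.
#' @param seed RNG seed; all randomness derives from it.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_individuals, n_snps,
                       maf_range = c(0.1, 0.5), p1 = NULL,
                       inbreeding_f = 0, causal = NULL,
                       traits = list(trait1 = list()),
                       n_background_loci = 300L,
                       polygenic_mode = c("background", "mvn"),
                       ld = NULL, missing_rate = 0, seed = 1L) {
  polygenic_mode <- match.arg(polygenic_mode)
  stopifnot(n_individuals >= 2, n_snps >= 1,
            all(inbreeding_f >= 0), all(inbreeding_f < 1),
            missing_rate >= 0, missing_rate < 1)
  defaults <- list(sigma_a2 = 1, sigma_e2 = 2, reliability = 0.8, mean = 0)
  traits <- lapply(traits, function(tr) {
    tr <- utils::modifyList(defaults, tr)
    stopifnot(tr$sigma_a2 >= 0, tr$sigma_e2 >= 0,
              tr$reliability >= 0, tr$reliability <= 1)
    tr
  })
  if (!is.null(causal)) {
    stopifnot(all(c("snp", "trait", "alpha", "delta") %in% names(causal)),
              all(causal$snp >= 1), all(causal$snp <= n_snps),
              all(causal$trait %in% names(traits)))
  }
  structure(list(n_individuals = as.integer(n_individuals),
                 n_snps = as.integer(n_snps), maf_range = maf_range,
                 p1 = p1, inbreeding_f = inbreeding_f, causal = causal,
                 traits = traits,
                 n_background_loci = as.integer(n_background_loci),
                 polygenic_mode = polygenic_mode, ld = ld,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a genotype panel
#'
#' Per SNP, genotype classes are drawn independently across individuals
#' with probabilities `(p1^2 + f p1 p2, 2 p1 p2 (1-f), p2^2 + f p1 p2)`,
#' which reduce to Hardy-Weinberg proportions at `f = 0` and create excess
#' homozygosity (inbreeding-style HWD) at `f > 0`.  SNPs are independent
#' unless linked through the `ld` specification.
#'
#' @param config a [sim_config].
#' @return A [genotype_matrix] with attribute `p1` (the frequencies used).
#' @export
simulate_genotypes <- function(config) {
  set.seed(config$seed)
  n <- config$n_individuals
  m <- config$n_snps
  p1 <- if (!is.null(config$p1)) rep_len(config$p1, m)
        else stats::runif(m, config$maf_range[1L], config$maf_range[2L])
  f <- rep_len(config$inbreeding_f, m)
  codes <- matrix(NA_integer_, n, m)
  for (j in seq_len(m)) {
    q <- 1 - p1[j]
    pr <- c(p1[j]^2 + f[j] * p1[j] * q,
            2 * p1[j] * q * (1 - f[j]),
            q^2 + f[j] * p1[j] * q)
    codes[, j] <- sample.int(3L, n, replace = TRUE, prob = pr) - 1L
  }
  if (!is.null(config$ld)) {
    for (r in seq_len(nrow(config$ld))) {
      src <- config$ld$source[r]; tgt <- config$ld$target[r]
      fp <- config$ld$flip_prob[r]
      col <- codes[, src]
      if (fp > 0) {
        q <- 1 - p1[src]
        pr <- c(p1[src]^2 + f[src] * p1[src] * q,
                2 * p1[src] * q * (1 - f[src]),
                q^2 + f[src] * p1[src] * q)
        redraw <- stats::runif(n) < fp
        col[redraw] <- sample.int(3L, sum(redraw), replace = TRUE,
                                  prob = pr) - 1L
      }
      codes[, tgt] <- col
      p1[tgt] <- p1[src]
    }
  }
  if (config$missing_rate > 0)
    codes[stats::runif(n * m) < config$missing_rate] <- NA_integer_
  ids <- sprintf("ind%05d", seq_len(n))
  map <- data.frame(snp_id = sprintf("snp%05d", seq_len(m)),
                    chrom = "1", pos_bp = seq_len(m) * 1000L,
                    allele1 = "A", allele2 = "B", stringsAsFactors = FALSE)
  g <- genotype_matrix(codes, ids, map)
  attr(g, "p1") <- p1
  g
}

# Causal genotypic values realizing a requested (alpha, delta) under the
# realized sample frequencies: g = x*(-2 p2, p1 - p2, 2 p1) + (0, delta, 0)
# with x solved so that the additive contrast of g equals alpha.
.causal_class_values <- function(col, alpha, delta) {
  freq <- genotype_frequencies(col)
  s_a <- additive_contrast(freq)
  v <- c(-2 * freq$p2, freq$p1 - freq$p2, 2 * freq$p1)
  denom <- sum(s_a * v)
  x <- (alpha - delta * s_a[2L]) / denom
  list(g = x * v + c(0, delta, 0), p1 = freq$p1)
}

#' Simulate phenotypes over a genotype panel
#'
#' `y_i = mean + sum of causal genotypic values + a_i + e_i`, with the
#' polygenic value `a` built from many small background-locus effects
#' (shared background genotypes across traits, independent effect draws),
#' standardized to variance `sigma_a2`, or in `"mvn"` mode drawn
#' multivariate normal with an explicit relationship matrix recorded in
#' the truth.  Causal class values are parameterized so the allelic
#' decomposition of the true values under the realized frequencies
#' returns exactly the requested `alpha` and `delta`.
#'
#' @param geno a [genotype_matrix] from [simulate_genotypes].
#' @param config the same [sim_config].
#' @return List: `phenotypes` (a [trait_table]) and `truth` (polygenic
#'   matrix `a`, per-trait `sigma_a`, causal class values, relationship
#'   matrix `A` in mvn mode).
#' @export
simulate_phenotypes <- function(geno, config) {
  set.seed(config$seed + 1L)
  n <- config$n_individuals
  ids <- rownames(geno$codes)
  tnames <- names(config$traits)
  W <- matrix(stats::rbinom(n * config$n_background_loci, 2L, 0.5),
              n, config$n_background_loci)
  A <- NULL
  a <- matrix(0, n, length(tnames), dimnames = list(ids, tnames))
  if (config$polygenic_mode == "mvn") {
    Ws <- scale(W)
    Ws[is.nan(Ws)] <- 0
    A <- tcrossprod(Ws) / ncol(W) + diag(0.05, n)
    L <- t(chol(A))
  }
  for (i in seq_along(tnames)) {
    sa2 <- config$traits[[i]]$sigma_a2
    if (sa2 > 0) {
      if (config$polygenic_mode == "mvn") {
        raw <- as.numeric(L %*% stats::rnorm(n))
      } else {
        raw <- as.numeric(W %*% stats::rnorm(ncol(W)))
      }
      raw <- raw - mean(raw)
      s <- stats::sd(raw)
      a[, i] <- if (s > 0) raw / s * sqrt(sa2) else 0
    }
  }
  causal_truth <- NULL
  g_contrib <- matrix(0, n, length(tnames), dimnames = list(ids, tnames))
  if (!is.null(config$causal)) {
    ct <- config$causal
    ct$g11 <- ct$g12 <- ct$g22 <- ct$p1_realized <- NA_real_
    for (r in seq_len(nrow(ct))) {
      col <- geno$codes[, ct$snp[r]]
      cv <- .causal_class_values(col, ct$alpha[r], ct$delta[r])
      ct[r, c("g11", "g12", "g22")] <- cv$g
      ct$p1_realized[r] <- cv$p1
      contrib <- cv$g[col + 1L]
      contrib[is.na(contrib)] <- 0
      g_contrib[, ct$trait[r]] <- g_contrib[, ct$trait[r]] + contrib
    }
    causal_truth <- ct
  }
  ph <- data.frame(id = ids, stringsAsFactors = FALSE)
  for (i in seq_along(tnames)) {
    tr <- config$traits[[i]]
    e <- stats::rnorm(n, 0, sqrt(tr$sigma_e2))
    ph[[tnames[i]]] <- tr$mean + g_contrib[, i] + a[, i] + e
  }
  truth <- list(a = a,
                sigma_a = vapply(config$traits,
                                 function(t) sqrt(t$sigma_a2), numeric(1)),
                causal = causal_truth, A = A, seed = config$seed)
  list(phenotypes = trait_table(ph, kind = "phenotype"), truth = truth)
}

#' Simulate PTAs at a stated reliability
#'
#' Emulates routine genetic evaluation output: for each trait,
#' `PTA_i = 0.5 * (r * a_i / sigma_a + sqrt(1 - r^2) * z_i) * sigma_a`
#' with `r = sqrt(reliability)` and `z_i` standard normal, so that
#' `cor(2*PTA, a) = r`; reliability 1 gives `PTA = a/2` exactly.
#'
#' @param truth truth record from [simulate_phenotypes].
#' @param config the [sim_config].
#' @return A PTA [trait_table].
#' @export
simulate_pta <- function(truth, config) {
  set.seed(config$seed + 2L)
  a <- truth$a
  tnames <- colnames(a)
  out <- data.frame(id = rownames(a), stringsAsFactors = FALSE)
  for (i in seq_along(tnames)) {
    tr <- config$traits[[i]]
    r <- sqrt(tr$reliability)
    sa <- truth$sigma_a[i]
    if (tr$reliability >= 1 || sa == 0) {
      pta <- a[, i] / 2
    } else {
      z <- stats::rnorm(nrow(a))
      pta <- 0.5 * (r * a[, i] / sa + sqrt(1 - r^2) * z) * sa
    }
    out[[tnames[i]]] <- pta
  }
  trait_table(out, kind = "pta")
}

#' Simulate a complete dataset
#'
#' Runs [simulate_genotypes], [simulate_phenotypes] and [simulate_pta]
#' under one seed and returns genotypes, phenotypes, PTAs and the truth
#' record sufficient to reproduce every phenotype.
#'
#' @param config a [sim_config].
#' @return Object of class `sim_dataset`: `genotypes`, `phenotypes`,
#'   `pta`, `truth`, `config`.
#' @export
simulate_dataset <- function(config) {
  geno <- simulate_genotypes(config)
  ph <- simulate_phenotypes(geno, config)
  pta <- simulate_pta(ph$truth, config)
  structure(list(genotypes = geno, phenotypes = ph$phenotypes, pta = pta,
                 truth = ph$truth, config = config),
            class = "sim_dataset")
}
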