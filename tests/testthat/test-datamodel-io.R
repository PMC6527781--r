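test_that("TSV genotype dialect parses codes as allele2 counts", {
  gdir <- withr::local_tempdir()
  gfile <- file.path(gdir, "g.tsv")
  mfile <- file.path(gdir, "g.map")
  writeLines(c("id\tsnpA", "c1\t0", "c2\t2"), gfile)
  writeLines("snpA\t1\t100\tA\tB", mfile)
  g <- read_genotypes(gfile, "tsv", map = mfile)
  expect_equal(unname(g$codes), matrix(c(0L, 2L), 2, 1))
  expect_equal(rownames(g$codes), c("c1", "c2"))
  expect_equal(g$map$allele2, "B")
})

test_that("TSV round trip reproduces a random matrix exactly", {
  set.seed(11)
  codes <- matrix(sample(c(0:2, NA), 50, replace = TRUE), 10, 5)
  map <- data.frame(snp_id = paste0("s", 1:5), chrom = "2",
                    pos_bp = (1:5) * 10L, allele1 = "A", allele2 = "C")
  g <- genotype_matrix(codes, paste0("i", 1:10), map)
  d <- withr::local_tempdir()
  write_genotypes(g, file.path(d, "g.tsv"), file.path(d, "g.map"))
  g2 <- read_genotypes(file.path(d, "g.tsv"), "tsv",
                       map = file.path(d, "g.map"))
  expect_identical(g2$codes, g$codes)
  expect_identical(g2$map, g$map)
})

test_that("malformed genotype lines raise errors naming the line", {
  d <- withr::local_tempdir()
  f <- file.path(d, "bad.tsv")
  writeLines(c("id\ts1", "c1\t0", "c2\t3"), f)
  m <- data.frame(snp_id = "s1", chrom = "1", pos_bp = 1L,
                  allele1 = "A", allele2 = "B")
  expect_error(read_genotypes(f, "tsv", map = m), "line 3")
  writeLines(c("id\ts1", "c1\t0\t1"), f)
  expect_error(read_genotypes(f, "tsv", map = m), "line 2")
})

test_that("PLINK .raw dialect counts the header allele as allele2", {
  d <- withr::local_tempdir()
  f <- file.path(d, "g.raw")
  writeLines(c("FID IID PAT MAT SEX PHENOTYPE s1_B s2_A",
               "f1 c1 0 0 0 -9 0 1",
               "f2 c2 0 0 0 -9 2 2"), f)
  m <- data.frame(snp_id = c("s1", "s2"), chrom = "1", pos_bp = c(1L, 2L),
                  allele1 = c("A", "A"), allele2 = c("B", "B"))
  g <- read_genotypes(f, "plink_raw", map = m)
  # s1 counts B = allele2: codes unchanged
  expect_equal(unname(g$codes[, "s1"]), c(0L, 2L))
  # s2 counts A = allele1: codes flipped to count allele2, alleles swapped
  expect_equal(unname(g$codes[, "s2"]), c(1L, 0L))
  expect_equal(g$map$allele2[2], "A")
})

test_that("the same cohort encoded as TSV and PLINK .raw yields one matrix", {
  set.seed(5)
  codes <- matrix(sample(0:2, 40, replace = TRUE), 8, 5)
  ids <- paste0("c", 1:8)
  map <- data.frame(snp_id = paste0("s", 1:5), chrom = "1",
                    pos_bp = (1:5) * 100L, allele1 = "A", allele2 = "B")
  g <- genotype_matrix(codes, ids, map)
  d <- withr::local_tempdir()
  write_genotypes(g, file.path(d, "g.tsv"), file.path(d, "g.map"))
  raw <- file.path(d, "g.raw")
  hdr <- paste(c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE",
                 paste0(map$snp_id, "_B")), collapse = " ")
  body <- vapply(seq_len(8), function(i)
    paste(c("f", ids[i], "0", "0", "0", "-9", codes[i, ]), collapse = " "),
    character(1))
  writeLines(c(hdr, body), raw)
  g_tsv <- read_genotypes(file.path(d, "g.tsv"), "tsv",
                          map = file.path(d, "g.map"))
  g_raw <- read_genotypes(raw, "plink_raw", map = file.path(d, "g.map"))
  expect_identical(g_tsv$codes, g_raw$codes)
})

test_that("VCF GT fields become ALT-dosage codes; multiallelic rows skipped", {
  skip_if_not_installed("vcfR")
  d <- withr::local_tempdir()
  f <- file.path(d, "g.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tc1\tc2\tc3",
    "1\t100\trs1\tA\tG\t.\t.\t.\tGT\t0/0\t0/1\t1/1",
    "1\t200\trs2\tA\tG,T\t.\t.\t.\tGT\t0/0\t0/1\t1/1",
    "1\t300\trs3\tC\tT\t.\t.\t.\tGT\t0|1\t./.\t1|1"), f)
  expect_warning(g <- read_genotypes(f, "vcf"), "non-biallelic")
  expect_equal(ncol(g$codes), 2L)
  expect_equal(unname(g$codes[, "rs1"]), c(0L, 1L, 2L))
  expect_equal(unname(g$codes[, "rs3"]), c(1L, NA, 2L))
  expect_equal(g$map$allele1, c("A", "C"))  # REF is allele1
  expect_equal(g$map$allele2, c("G", "T"))  # ALT is allele2
})

test_that("trait tables parse, keep absences absent, and reject defects", {
  d <- withr::local_tempdir()
  f <- file.path(d, "ph.tsv")
  writeLines(c("id\tMY\tFY", "c1\t100\t5", "c2\t-50\t"), f)
  tab <- read_trait_table(f, "phenotype")
  expect_equal(trait_values(tab, "MY"), c(c1 = 100, c2 = -50))
  expect_equal(names(trait_values(tab, "FY")), "c1")  # (c2, FY) absent
  writeLines(c("id\tMY", "c1\t1", "c1\t2"), f)
  expect_error(read_trait_table(f), "duplicated")
  writeLines(c("id\tMY", "c1\tabc"), f)
  expect_error(read_trait_table(f), "c1.*MY")
})

test_that("trait table round trip is lossless at 10 significant digits", {
  set.seed(3)
  wide <- data.frame(id = paste0("c", 1:6),
                     MY = rnorm(6) * 1000, FY = rnorm(6))
  tab <- trait_table(wide, "phenotype")
  d <- withr::local_tempdir()
  f <- file.path(d, "t.tsv")
  write_trait_table(tab, f)
  tab2 <- read_trait_table(f)
  expect_equal(trait_values(tab2, "MY"), trait_values(tab, "MY"),
               tolerance = 1e-10)
  expect_equal(trait_values(tab2, "FY"), trait_values(tab, "FY"),
               tolerance = 1e-10)
})

test_that("result tables round-trip alpha to 10 significant digits", {
  d <- small_cohort(n = 200, m = 5)
  res <- run_gwas(d$genotypes, d$phenotypes, d$pta)
  td <- withr::local_tempdir()
  f <- file.path(td, "res.tsv")
  write_results(res, f)
  back <- read_results(f)
  expect_equal(nrow(back), nrow(res))
  expect_equal(back$alpha, res$alpha, tolerance = 1e-9)
  expect_equal(back$log10invp_add, res$log10invp_add, tolerance = 1e-9)
  # stable header order starts with the identity columns
  expect_equal(names(back)[1:7],
               c("snp_id", "chrom", "pos_bp", "allele1", "allele2",
                 "trait", "n_used"))
  expect_error(write_results(res[0, ], f), "no result rows")
})

test_that("genotype_matrix validates its invariants", {
  map <- data.frame(snp_id = "s1", chrom = "1", pos_bp = 1L,
                    allele1 = "A", allele2 = "B")
  expect_error(genotype_matrix(matrix(3L, 1, 1), "c1", map), "codes")
  expect_error(genotype_matrix(matrix(0L, 2, 1), "c1", map), "row count")
  badmap <- map; badmap$allele2 <- "A"
  expect_error(genotype_matrix(matrix(0L, 1, 1), "c1", badmap), "differ")
})
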