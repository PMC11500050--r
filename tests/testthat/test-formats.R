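make_sumstats <- function(n = 5, seed = 1) {
  set.seed(seed)
  data.frame(chrom = as.character(sample(1:22, n, replace = TRUE)),
             pos = sort(sample(1e6, n)),
             id = paste0("rs", seq_len(n)),
             ea = sample(c("A", "C"), n, replace = TRUE),
             oa = sample(c("G", "T"), n, replace = TRUE),
             beta = rnorm(n), se = runif(n, 0.01, 0.2),
             p = runif(n), eaf = runif(n),
             stringsAsFactors = FALSE)
}

test_that("summary-statistics write -> read round trip is lossless", {
  x <- make_sumstats(8)
  path <- tempfile(fileext = ".tsv")
  write_sumstats(x, path)
  y <- read_sumstats(path)
  for (col in c("pos", "beta", "se", "p", "eaf")) {
    expect_equal(y[[col]], x[[col]], tolerance = 1e-12, ignore_attr = TRUE)
  }
  expect_identical(y$id, x$id)
  expect_identical(y$ea, x$ea)
})

test_that("OR/CI rows are converted and invalid rows reported, not dropped silently", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("CHR\tPOS\tID\tEA\tOA\tP\tOR\tOR_L95\tOR_U95",
               "9\t100259252\trs2806689\tT\tC\t2.47e-2\t0.74\t0.57\t0.96",
               "1\t500\trs_bad\tA\tG\t0.5\t0\t0\t0",
               "1\t600\trs_id\tA\tG\t1\t1\t0.5\t2"), path)
  expect_warning(x <- read_sumstats(path), "failed validation")
  expect_equal(nrow(x), 2)
  # published row: beta = ln(0.74), se from the CI width
  expect_equal(x$beta[1], log(0.74), tolerance = 1e-9)
  expect_equal(x$se[1], (log(0.96) - log(0.57)) / (2 * 1.959964),
               tolerance = 1e-6)
  # symmetric CI about 1
  expect_equal(x$beta[2], 0)
  expect_equal(x$se[2], log(4) / (2 * 1.959964), tolerance = 1e-6)
  rej <- attr(x, "rejected")
  expect_equal(rej$ID, "rs_bad")
  expect_match(rej$reason, "invalid_or_ci")
})

test_that("an identity row (beta 0, se 1, p 1) passes validation unchanged", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("CHR\tPOS\tID\tEA\tOA\tP\tBETA\tSE",
               "1\t100\trs1\tA\tG\t1\t0\t1"), path)
  x <- read_sumstats(path)
  expect_equal(nrow(x), 1)
  expect_equal(x$beta, 0)
  expect_equal(x$se, 1)
  expect_equal(x$p, 1)
})

test_that("missing mandatory columns give an error naming the column", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("CHR\tPOS\tID\tEA\tP\tBETA\tSE", "1\t1\tr\tA\t1\t0\t1"), path)
  expect_error(read_sumstats(path), "OA")
})

test_that("OR/CI conversion round-trips the odds ratio", {
  for (or in c(0.47, 0.88, 1.16, 1.76, 2.46)) {
    # asymmetric interval: the OR and the log-scale CI width survive
    bs <- beta_se_from_or_ci(or, or * 0.8, or * 1.3)
    back <- or_ci_from_beta_se(bs[["beta"]], bs[["se"]])
    expect_equal(unname(back[["or"]]), or, tolerance = 1e-9)
    expect_equal(log(back[["ci_high"]]) - log(back[["ci_low"]]),
                 log(1.3 / 0.8), tolerance = 1e-9, ignore_attr = TRUE)
    # log-symmetric interval: the bounds themselves round trip
    bs2 <- beta_se_from_or_ci(or, or / 1.4, or * 1.4)
    back2 <- or_ci_from_beta_se(bs2[["beta"]], bs2[["se"]])
    expect_equal(unname(back2[["ci_low"]]), or / 1.4, tolerance = 1e-9)
    expect_equal(unname(back2[["ci_high"]]), or * 1.4, tolerance = 1e-9)
  }
})

test_that("dosage TSV round trip preserves the matrix", {
  cfg <- sim_config(n_samples = 12, n_variants = 6, n_blocks = 2)
  ds <- generate_genotypes(cfg, seed = 4)
  path <- tempfile(fileext = ".tsv")
  write_dosage_tsv(ds, path)
  back <- read_genotypes(path, format = "dosage_tsv")
  expect_equal(back$dosages, ds$dosages, tolerance = 1e-12)
  expect_identical(back$variants$id, ds$variants$id)
  expect_identical(back$sample_ids, ds$sample_ids)
})

test_that("VCF GT genotypes become ALT-allele dosages", {
  path <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", "S1", "S2", sep = "\t"),
               "1\t100\trs1\tG\tA\t.\tPASS\t.\tGT\t0/1\t1/1",
               "1\t200\trs2\tG\tA\t.\tPASS\t.\tGT\t0/0\t./."), path)
  ds <- read_genotypes(path, format = "vcf")
  expect_equal(unname(ds$dosages["S1", "rs1"]), 1)
  expect_equal(unname(ds$dosages["S2", "rs1"]), 2)
  expect_equal(unname(ds$dosages["S1", "rs2"]), 0)
  expect_true(is.na(ds$dosages["S2", "rs2"]))
  expect_equal(ds$variants$ea, c("A", "A"))
})

test_that("VCF DS dosages pass through and multi-allelic sites are rejected", {
  path <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", "S1", sep = "\t"),
               "1\t100\trs1\tG\tA\t.\tPASS\t.\tGT:DS\t0/1:1.37"), path)
  ds <- read_genotypes(path, format = "vcf")
  expect_equal(unname(ds$dosages["S1", "rs1"]), 1.37)

  bad <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", "S1", sep = "\t"),
               "1\t100\trs1\tG\tA,C\t.\tPASS\t.\tGT\t1/2"), bad)
  expect_error(read_genotypes(bad, format = "vcf"), "multi-allelic")
})

test_that("LD matrix reader validates symmetry and unit diagonal", {
  m <- matrix(c(1, 0.6, 0.6, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  path <- tempfile(fileext = ".tsv")
  write_ld_matrix(m, path)
  back <- read_ld_matrix(path)
  expect_equal(back, m, tolerance = 1e-12)

  m2 <- m; m2[1, 2] <- 0.7
  write_ld_matrix(m2, path)
  expect_error(read_ld_matrix(path), "asymmetric")
})

test_that("annotation table round trips and rejects invalid categories", {
  ann <- generate_annotations(paste0("G", 1:5), seed = 2)
  path <- tempfile(fileext = ".tsv")
  write_annotation_table(ann, path)
  back <- read_annotation_table(path)
  expect_equal(back$cadd, ann$cadd, tolerance = 1e-12)
  expect_identical(back$rdb, ann$rdb)
  expect_identical(back$eqtl, ann$eqtl)

  bad <- ann
  bad$rdb[1] <- "8"
  write_annotation_table(bad, path)
  expect_error(read_annotation_table(path), "RDB")
})

test_that("drug table parses status enum and round trips", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("DRUG\tSTATUS\tTARGET\tACTION",
               "acetylcysteine\tapproved\tGENE1\tantioxidant",
               "drugX\tinvestigational\tGENE2\tinhibitor"), path)
  d <- read_drug_table(path)
  expect_equal(d$status, c("approved", "investigational"))
  write_drug_table(d, path)
  expect_identical(read_drug_table(path)$drug, d$drug)

  writeLines(c("DRUG\tSTATUS\tTARGET\tACTION",
               "drugY\tbanned\tGENE1\tx"), path)
  expect_error(read_drug_table(path), "STATUS")
})

test_that("genotype dataset enforces dimension and range invariants", {
  v <- data.frame(chrom = "1", pos = 1L, id = "rs1", ea = "A", oa = "G")
  expect_error(genotype_dataset(matrix(0, 2, 2), v), "dimensions")
  expect_error(genotype_dataset(matrix(3, 2, 1), v), "\\[0, 2\\]")
  expect_error(genotype_dataset(matrix(1, 2, 1), v, phenotype = c(1, 2)),
               "binary")
})
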