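# small helper: dataset from an explicit dosage matrix
toy_dataset <- function(dos, phenotype = NULL, chrom = "1") {
  p <- ncol(dos)
  v <- data.frame(chrom = chrom, pos = seq_len(p) * 1000L,
                  id = paste0("v", seq_len(p)), ea = "A", oa = "G",
                  stringsAsFactors = FALSE)
  genotype_dataset(dos, v, phenotype = phenotype)
}

test_that("exact HWE p-values match an independent binomial-coefficient route", {
  cases <- list(c(81, 18, 1), c(50, 25, 25), c(30, 40, 30), c(5, 0, 5),
                c(0, 10, 0), c(88, 10, 2))
  for (cc in cases) {
    expect_equal(hwe_exact_p(cc[1], cc[2], cc[3]),
                 oracle_hwe_choose(cc[1], cc[2], cc[3]), tolerance = 1e-10)
  }
  # the (81,18,1) table sits at the HWE expectation, so it is retained at
  # any sane threshold
  expect_gte(hwe_exact_p(81, 18, 1), 1e-6)
  expect_lt(hwe_exact_p(50, 25, 25), 1e-5)
})

test_that("the exact-test null distribution matches random allele pairing", {
  set.seed(31)
  # implementation's conditional distribution of het counts
  n_aa <- 30; n_ab <- 40; n_bb <- 30
  n <- 100; na <- 100
  hets <- seq(0, 100, 2)
  logp <- lfactorial(n) - (lfactorial((na - hets) / 2) + lfactorial(hets) +
                             lfactorial((2 * n - na - hets) / 2)) +
    hets * log(2) + lfactorial(na) + lfactorial(2 * n - na) - lfactorial(2 * n)
  exact <- exp(logp)
  emp <- oracle_hwe_pairing(n_aa, n_ab, n_bb, B = 20000)
  expect_lt(sum(abs(exact - as.numeric(emp))) / 2, 0.02)  # total variation
})

test_that("QC removes variants and samples for the documented reasons", {
  set.seed(8)
  n <- 100
  dos <- cbind(
    matrix(rbinom(n * 20, 2, 0.3), n, 20), # clean background
    c(1, rep(0, n - 1)),                   # MAF 0.005: fails MAF
    rbinom(n, 2, 0.3),                     # fails variant missingness
    rep(c(2, 0), 50)                       # no heterozygotes: out of HWE
  )
  dos[1:10, 22] <- NA            # 10% missing on one variant
  dos[n, 1:10] <- NA             # last sample missing at 10 / 23 variants
  ds <- toy_dataset(dos, phenotype = rep(c(1, 0), each = 50))
  out <- qc_filter(ds, qc_thresholds())
  expect_true("v21" %in% out$report$removed$maf)
  expect_true("v22" %in% out$report$removed$variant_missingness)
  expect_true("v23" %in% out$report$removed$hwe)
  expect_true("S100" %in% out$report$removed$sample_missingness)
  expect_equal(out$dataset$variants$id, paste0("v", 1:20))
  expect_equal(out$report$n_samples_kept, 99)
})

test_that("an all-passing dataset is unchanged by QC and emptiness errors", {
  set.seed(9)
  dos <- matrix(rbinom(200 * 4, 2, 0.4), 200, 4)
  ds <- toy_dataset(dos, phenotype = rep(c(0, 1), 100))
  out <- qc_filter(ds)
  expect_equal(out$dataset$dosages, ds$dosages)
  expect_true(all(out$report$n_removed == 0))

  mono <- toy_dataset(matrix(0, 50, 1), phenotype = rep(c(0, 1), 25))
  expect_error(qc_filter(mono), "survive")
})

test_that("PC1 separates two diverged subpopulations", {
  cfg <- sim_config(n_samples = 200, n_variants = 500, n_blocks = 500)
  ds <- generate_genotypes(cfg, seed = 3, two_subpops = TRUE, fst = 0.05)
  pcs <- compute_pcs(ds, k = 2)
  expect_gt(abs(cor(pcs[, 1], attr(ds, "subpop"))), 0.9)
  expect_equal(ncol(pcs), 2)
})

test_that("duplicated samples receive identical PC scores", {
  cfg <- sim_config(n_samples = 30, n_variants = 40, n_blocks = 8)
  ds <- generate_genotypes(cfg, seed = 5)
  dup <- genotype_dataset(ds$dosages[c(1:30, 1), ], ds$variants,
                          sample_ids = c(ds$sample_ids, "dup1"))
  pcs <- compute_pcs(dup, k = 3)
  expect_equal(unname(pcs["S1", ]), unname(pcs["dup1", ]), tolerance = 1e-8)
})

test_that("a rank-1 dosage matrix is explained by one component", {
  base <- rbinom(60, 2, 0.5)
  dos <- cbind(base, base, base, 2 - base)
  ds <- toy_dataset(dos)
  pcs <- compute_pcs(ds, k = 1, thin_r2 = 1)
  expect_gt(attr(pcs, "var_explained")[1], 0.999)
})

test_that("allelic logistic regression approximates the contingency-table odds ratio", {
  # case alleles 30/170, control alleles 10/190 treated as unit exposures
  dos <- matrix(c(rep(1, 30), rep(0, 170), rep(1, 10), rep(0, 190)), ncol = 1)
  y <- c(rep(1, 200), rep(0, 200))
  ds <- toy_dataset(dos, phenotype = y)
  res <- logistic_assoc(ds)
  or_table <- (30 * 190) / (170 * 10)
  expect_equal(res$beta[1], log(or_table), tolerance = 0.05)
})

test_that("null p-values are approximately uniform", {
  cfg <- sim_config(n_samples = 500, case_fraction = 0.5, n_variants = 300,
                    n_blocks = 300)
  set.seed(17)
  ds <- generate_genotypes(cfg)
  ds <- simulate_phenotype(ds, case_fraction = 0.5)
  res <- logistic_assoc(ds)
  ks <- suppressWarnings(stats::ks.test(res$p, "punif"))
  expect_lt(unname(ks$statistic), 0.08)
})

test_that("separation triggers the Firth fallback and returns finite estimates", {
  y <- rep(c(0, 1), each = 25)
  ds <- toy_dataset(matrix(2 * y, ncol = 1), phenotype = y)
  res <- logistic_assoc(ds, firth_fallback = TRUE)
  expect_identical(res$method[1], "firth")
  expect_true(is.finite(res$beta[1]))
  expect_true(is.finite(res$se[1]))
  res_no <- logistic_assoc(ds, firth_fallback = FALSE)
  expect_true(is.na(res_no$beta[1]))
  expect_identical(res_no$reason[1], "separation")
})

test_that("monomorphic variants are flagged rather than fitted", {
  ds <- toy_dataset(cbind(rep(1, 40), rbinom(40, 2, 0.4)),
                    phenotype = rep(c(0, 1), 20))
  res <- logistic_assoc(ds)
  expect_identical(res$reason[1], "monomorphic")
  expect_true(is.na(res$beta[1]))
  expect_false(is.na(res$beta[2]))
})

test_that("swapping case/control labels flips beta and preserves p", {
  set.seed(23)
  dos <- matrix(rbinom(300 * 3, 2, 0.3), 300, 3)
  y <- rbinom(300, 1, 0.4)
  r1 <- logistic_assoc(toy_dataset(dos, phenotype = y))
  r2 <- logistic_assoc(toy_dataset(dos, phenotype = 1 - y))
  expect_equal(r1$beta, -r2$beta, tolerance = 1e-6)
  expect_equal(r1$p, r2$p, tolerance = 1e-6)
})

test_that("true effects are recovered within confidence intervals", {
  cfg <- sim_config(n_samples = 1000, case_fraction = 0.3, n_variants = 1,
                    n_blocks = 1)
  set.seed(29)
  cover <- 0
  for (r in 1:100) {
    ds <- generate_genotypes(cfg, maf = 0.3)
    ds <- simulate_phenotype(ds, stats::setNames(log(2), "snp_0001"),
                             case_fraction = 0.3)
    res <- logistic_assoc(ds)
    lo <- res$beta[1] - 1.959964 * res$se[1]
    hi <- res$beta[1] + 1.959964 * res$se[1]
    if (log(2) >= lo && log(2) <= hi) cover <- cover + 1
  }
  expect_gte(cover, 90)
})

test_that("association output feeds the meta module via the sumstats dialect", {
  cfg <- sim_config(n_samples = 300, case_fraction = 0.4, n_variants = 10,
                    n_blocks = 5)
  set.seed(33)
  ds <- generate_genotypes(cfg)
  ds <- simulate_phenotype(ds, case_fraction = 0.4)
  ss <- assoc_to_sumstats(logistic_assoc(ds), ds)
  path <- tempfile(fileext = ".tsv")
  write_sumstats(ss, path)
  back <- read_sumstats(path)
  expect_equal(back$beta, ss$beta, tolerance = 1e-12, ignore_attr = TRUE)
  expect_true(all(back$eaf >= 0 & back$eaf <= 1))
})
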