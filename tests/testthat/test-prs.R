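base_frame <- function(id, chrom, pos, p, beta = 0.1) {
  data.frame(id = id, chrom = chrom, pos = pos, p = p, beta = beta,
             se = 0.05, ea = "A", oa = "G", eaf = 0.3,
             stringsAsFactors = FALSE)
}

test_that("clumping keeps the lower-p SNP of a correlated nearby pair", {
  ld <- matrix(c(1, 0.5, 0.5, 1), 2,
               dimnames = list(c("a", "b"), c("a", "b")))
  base <- base_frame(c("a", "b"), "1", c(100000, 110000), c(1e-6, 1e-4))
  expect_identical(clump(base, ld), "a")
  ld2 <- ld; ld2[1, 2] <- ld2[2, 1] <- 0.05
  expect_setequal(clump(base, ld2), c("a", "b"))
})

test_that("distant SNPs are not clumped even at high r2", {
  ld <- matrix(c(1, 0.9, 0.9, 1), 2,
               dimnames = list(c("a", "b"), c("a", "b")))
  base <- base_frame(c("a", "b"), "1", c(1e6, 2e6), c(1e-6, 1e-4))
  expect_setequal(clump(base, ld, window_kb = 250), c("a", "b"))
})

test_that("clumping matches a brute-force greedy check on random instances", {
  for (i in 1:10) {
    cfg <- sim_config(n_samples = 120, n_variants = 50, n_blocks = 8,
                      rho = 0.8, variant_spacing_bp = 100000)
    ds <- generate_genotypes(cfg, seed = 400 + i)
    ld <- ld_from_dosages(ds)
    base <- data.frame(id = ds$variants$id, chrom = ds$variants$chrom,
                       pos = ds$variants$pos,
                       p = stats::runif(50), stringsAsFactors = FALSE)
    kept <- clump(base, ld, window_kb = 250, r2 = 0.1)
    # invariant: kept SNPs are mutually unclumpable; dropped SNPs are
    # clumped by an earlier kept SNP
    ord <- base[order(base$p, base$chrom, base$pos), ]
    for (a_i in seq_along(kept)) {
      for (b_i in seq_len(a_i - 1)) {
        a <- kept[a_i]; b <- kept[b_i]
        same_win <- base$chrom[base$id == a] == base$chrom[base$id == b] &&
          abs(base$pos[base$id == a] - base$pos[base$id == b]) <= 250000
        expect_false(same_win && ld[a, b] >= 0.1)
      }
    }
    for (d in setdiff(base$id, kept)) {
      earlier <- kept[match(kept, ord$id) < match(d, ord$id)]
      blocked <- vapply(earlier, function(k) {
        ord$chrom[ord$id == k] == ord$chrom[ord$id == d] &&
          abs(ord$pos[ord$id == k] - ord$pos[ord$id == d]) <= 250000 &&
          ld[k, d] >= 0.1
      }, logical(1))
      expect_true(any(blocked))
    }
  }
})

test_that("individual scores follow the sum convention", {
  ds <- genotype_dataset(matrix(c(2, 0), 2, 1),
                         data.frame(chrom = "1", pos = 1L, id = "v1",
                                    ea = "A", oa = "G"))
  s <- score_individuals(ds, c(v1 = log(2)))
  expect_equal(unname(s[1]), 2 * log(2))
  expect_equal(unname(s[2]), 0)
})

test_that("scores equal a naive per-sample loop and missing weight SNPs are skipped", {
  cfg <- sim_config(n_samples = 40, n_variants = 10, n_blocks = 2)
  ds <- generate_genotypes(cfg, seed = 44)
  w <- stats::setNames(rnorm(10), ds$variants$id)
  expect_equal(unname(score_individuals(ds, w)),
               oracle_score_individuals(ds$dosages, w), tolerance = 1e-12)
  w2 <- c(w, absent = 1)
  expect_warning(s2 <- score_individuals(ds, w2), "missing from target")
  expect_equal(s2, score_individuals(ds, w))
  expect_error(score_individuals(ds, c(nope = 1)), "overlap")
})

test_that("AUC matches exhaustive pair enumeration and pROC", {
  expect_equal(rank_auc(c(2, 3, 0, 1), c(1, 1, 0, 0)), 1.0)
  expect_equal(rank_auc(c(1, 3, 2, 0), c(1, 1, 0, 0)), 0.75)
  set.seed(55)
  for (i in 1:20) {
    y <- c(rep(1, 15), rep(0, 25))
    s <- round(rnorm(40), 1)  # rounding forces ties
    expect_equal(rank_auc(s, y), oracle_auc_pairs(s, y), tolerance = 1e-12)
    proc_auc <- as.numeric(pROC::auc(pROC::roc(y, s, levels = c(0, 1),
                                               direction = "<", quiet = TRUE)))
    expect_equal(rank_auc(s, y), proc_auc, tolerance = 1e-10)
  }
})

test_that("AUC is invariant under strictly increasing transforms and symmetric under negation", {
  set.seed(56)
  y <- rbinom(60, 1, 0.5)
  s <- rnorm(60)
  a <- rank_auc(s, y)
  expect_equal(rank_auc(exp(s), y), a, tolerance = 1e-12)
  expect_equal(rank_auc(3 * s + 7, y), a, tolerance = 1e-12)
  expect_equal(rank_auc(-s, y), 1 - a, tolerance = 1e-12)
})

test_that("identical case/control distributions give AUC near one half", {
  set.seed(57)
  s <- rnorm(2000)
  y <- rep(c(0, 1), 1000)
  expect_lt(abs(rank_auc(s, y) - 0.5), 0.05)
})

test_that("evaluation reports a DeLong interval containing the point AUC", {
  set.seed(58)
  y <- rbinom(300, 1, 0.4)
  s <- rnorm(300) + 0.8 * y
  ev <- prs_evaluate(s, y)
  expect_gt(ev$auc, 0.6)
  expect_lte(ev$auc_ci[["lower"]], ev$auc)
  expect_gte(ev$auc_ci[["upper"]], ev$auc)
  expect_lt(ev$t_p, 0.01)
  expect_gt(ev$case_mean, ev$control_mean)
})

test_that("a single-SNP base gives the same model at both grid cutoffs", {
  cfg <- sim_config(n_samples = 400, case_fraction = 0.5, n_variants = 1,
                    n_blocks = 1)
  set.seed(59)
  ds <- generate_genotypes(cfg, maf = 0.3)
  ds <- simulate_phenotype(ds, stats::setNames(0.5, "snp_0001"),
                           case_fraction = 0.5)
  base <- base_frame("snp_0001", "1", 1e6, 1e-9, beta = 0.5)
  model <- threshold_search(base, ds, grid = c(5e-8, 1))
  expect_equal(model$table$n_snps, c(1, 1))
  expect_equal(model$table$fit_r2[1], model$table$fit_r2[2], tolerance = 1e-12)
})

test_that("null phenotypes give near-zero delta-R2 at every cutoff", {
  cfg <- sim_config(n_samples = 2000, case_fraction = 0.5, n_variants = 50,
                    n_blocks = 10)
  set.seed(60)
  two <- generate_two_cohorts(cfg)
  base <- two$study_b
  model <- suppressWarnings(threshold_search(base, two$cohort_a))
  expect_true(all(model$table$fit_r2 < 0.01, na.rm = TRUE))
})

test_that("the permutation floor is attained with a strong signal at small B", {
  cfg <- sim_config(n_samples = 500, case_fraction = 0.5, n_variants = 20,
                    n_blocks = 10)
  set.seed(61)
  betas <- stats::setNames(rep(0.6, 10), sprintf("snp_%04d", 1:10))
  two <- generate_two_cohorts(cfg, effects_a = betas, effects_b = betas)
  pp <- permutation_p(two$study_b, two$cohort_a, B = 19, seed = 62)
  expect_equal(pp$perm_p, 1 / 20)
  expect_equal(min(pp$perm_p), 1 / (pp$B + 1))
})

test_that("B = 1 permutation p is either one half or one", {
  cfg <- sim_config(n_samples = 200, case_fraction = 0.5, n_variants = 10,
                    n_blocks = 5)
  set.seed(63)
  two <- generate_two_cohorts(cfg)
  pp <- suppressWarnings(permutation_p(two$study_b, two$cohort_a, B = 1,
                                       seed = 64))
  expect_true(pp$perm_p %in% c(0.5, 1))
})

test_that("null permutation p-values are roughly uniform", {
  cfg <- sim_config(n_samples = 150, case_fraction = 0.5, n_variants = 12,
                    n_blocks = 6)
  set.seed(65)
  ps <- replicate(40, {
    two <- generate_two_cohorts(cfg)
    suppressWarnings(permutation_p(two$study_b, two$cohort_a, B = 39)$perm_p)
  })
  # coarse calibration check: mean near 0.5, mass on both halves
  expect_gt(mean(ps), 0.3)
  expect_lt(mean(ps), 0.7)
  expect_gt(mean(ps <= 0.5), 0.25)
  expect_gt(mean(ps > 0.5), 0.25)
})

test_that("AUC grows with the planted liability-scale effect size", {
  cfg <- sim_config(n_samples = 700, case_fraction = 0.5, n_variants = 30,
                    n_blocks = 15)
  aucs <- vapply(c(0, 0.15, 0.4), function(b) {
    set.seed(66)
    betas <- stats::setNames(rep(b, 15), sprintf("snp_%04d", 1:15))
    two <- generate_two_cohorts(cfg, effects_a = betas, effects_b = betas)
    s <- score_individuals(two$cohort_a,
                           stats::setNames(two$study_b$beta, two$study_b$id))
    rank_auc(s, two$cohort_a$phenotype)
  }, numeric(1))
  expect_true(all(diff(aucs) > 0))
})
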