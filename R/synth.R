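# Synthetic-data generator: LD-blocked genotypes via a Gaussian copula
# (per-haplotype latent AR(1) normals thresholded at allele-frequency
# quantiles), additive logistic disease risk, a second cohort supplied as
# summary statistics, annotation tables spanning all evidence tiers, and
# a drug-target table.  Everything is deterministic given the seed.

#' Simulation configuration
#'
#' Defaults emulate the two-cohort study design this package targets: a
#' newly genotyped cohort of 1116 samples with a 133/1116 case fraction,
#' meta-analyzed against a large published scan of 121216 samples with
#' 4669 cases supplied as summary statistics.
#'
#' @param n_samples cohort-A sample count.
#' @param case_fraction cohort-A case fraction (Bernoulli expectation).
#' @param n_b,case_fraction_b cohort-B (summary-statistics) sample count
#'   and case fraction, used for its standard errors.
#' @param n_variants,n_blocks variant count and LD-block count.
#' @param rho within-block latent correlation decay (`rho^|i-j|`),
#'   in \[0, 1).
#' @param maf_range minor-allele-frequency range for simulated variants.
#' @param block_spacing_bp gap between block start positions.
#' @param variant_spacing_bp gap between adjacent variants in a block.
#' @return list of class `kc_sim_config`.
#' @export
sim_config <- function(n_samples = 1116, case_fraction = 133 / 1116,
                       n_b = 121216, case_fraction_b = 4669 / 121216,
                       n_variants = 200, n_blocks = 20, rho = 0.8,
                       maf_range = c(0.05, 0.5),
                       block_spacing_bp = 1e6, variant_spacing_bp = 5000) {
  stopifnot(n_samples > 0, n_variants > 0, n_blocks > 0,
            rho >= 0, rho < 1,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2])
  if (n_blocks > n_variants) stop("more blocks than variants", call. = FALSE)
  structure(list(n_samples = n_samples, case_fraction = case_fraction,
                 n_b = n_b, case_fraction_b = case_fraction_b,
                 n_variants = n_variants, n_blocks = n_blocks, rho = rho,
                 maf_range = maf_range, block_spacing_bp = block_spacing_bp,
                 variant_spacing_bp = variant_spacing_bp),
            class = "kc_sim_config")
}

# latent AR(1) haplotype matrix (rows = haplotypes) with corr rho^|i-j|
.ar1_latent <- function(n_hap, p, rho) {
  z <- matrix(stats::rnorm(n_hap * p), n_hap, p)
  if (rho > 0 && p > 1) {
    scale <- sqrt(1 - rho^2)
    for (j in 2:p) z[, j] <- rho * z[, j - 1] + scale * z[, j]
  }
  z
}

#' Generate LD-blocked genotype dosages
#'
#' Variants are laid out in `n_blocks` blocks spread across chromosomes
#' 1-22; within a block the two latent haplotype normals have correlation
#' `rho^|i-j|` and are thresholded at the allele-frequency quantile, so
#' adjacent variants are in LD while blocks are independent.  Dosages are
#' the haplotype sums in {0, 1, 2}.
#'
#' @param cfg [sim_config()].
#' @param seed optional RNG seed.
#' @param maf optional vector of target allele frequencies (defaults to
#'   uniform draws within `cfg$maf_range`).
#' @param two_subpops simulate two subpopulations with diverged allele
#'   frequencies (for stratification/PCA testing); the subpopulation
#'   label is stored in the `"subpop"` attribute.
#' @param fst divergence scale used when `two_subpops = TRUE` (allele
#'   frequencies perturbed by `N(0, fst * f * (1 - f))` per
#'   subpopulation).
#' @return [genotype_dataset()] (no phenotype); target frequencies in the
#'   `"target_maf"` attribute.
#' @export
generate_genotypes <- function(cfg = sim_config(), seed = NULL, maf = NULL,
                               two_subpops = FALSE, fst = 0.05) {
  if (!is.null(seed)) set.seed(seed)
  p <- cfg$n_variants
  n <- cfg$n_samples
  if (is.null(maf)) maf <- stats::runif(p, cfg$maf_range[1], cfg$maf_range[2])
  if (length(maf) != p) stop("maf length must equal n_variants", call. = FALSE)
  block <- sort(rep_len(seq_len(cfg$n_blocks), p))
  chrom <- as.character((block - 1L) %% 22L + 1L)
  pos <- integer(p)
  for (b in seq_len(cfg$n_blocks)) {
    idx <- which(block == b)
    # blocks cycle over chromosomes; successive blocks on the same
    # chromosome are spaced block_spacing_bp apart
    pos[idx] <- as.integer(1e6 + ((b - 1L) %/% 22L) * cfg$block_spacing_bp +
                             seq_along(idx) * cfg$variant_spacing_bp)
  }
  subpop <- NULL
  freq <- matrix(rep(maf, each = n), n, p)
  if (two_subpops) {
    subpop <- rep(c(1L, 2L), length.out = n)
    for (s in 1:2) {
      fs <- maf + stats::rnorm(p, 0, sqrt(fst * maf * (1 - maf)))
      fs <- pmin(pmax(fs, 0.01), 0.99)
      freq[subpop == s, ] <- matrix(rep(fs, each = sum(subpop == s)),
                                    sum(subpop == s), p)
    }
  }
  dos <- matrix(0, n, p)
  for (b in seq_len(cfg$n_blocks)) {
    idx <- which(block == b)
    h1 <- .ar1_latent(n, length(idx), cfg$rho)
    h2 <- .ar1_latent(n, length(idx), cfg$rho)
    thr <- stats::qnorm(freq[, idx, drop = FALSE])
    dos[, idx] <- (h1 < thr) + (h2 < thr)
  }
  variants <- data.frame(chrom = chrom, pos = pos,
                         id = sprintf("snp_%04d", seq_len(p)),
                         ea = "A", oa = "G", stringsAsFactors = FALSE)
  ds <- genotype_dataset(dos, variants)
  attr(ds, "target_maf") <- maf
  attr(ds, "subpop") <- subpop
  ds
}

#' Simulate a binary phenotype under additive logistic risk
#'
#' `P(case) = plogis(intercept + sum_j beta_j * dosage_j)` with Bernoulli
#' draws.  When `intercept` is `NULL` it is solved (by root finding on
#' the realized genetic scores) so the expected case fraction equals
#' `case_fraction`.
#'
#' @param ds [genotype_dataset()].
#' @param effects named numeric vector of causal log odds ratios
#'   (variant ID -> beta); may be empty.
#' @param intercept logistic intercept, or `NULL` to target
#'   `case_fraction`.
#' @param case_fraction target expected case fraction (used when
#'   `intercept` is `NULL`).
#' @param seed optional RNG seed.
#' @return the dataset with `phenotype` filled in; the linear predictor
#'   is stored in the `"eta"` attribute.
#' @export
simulate_phenotype <- function(ds, effects = numeric(0), intercept = NULL,
                               case_fraction = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  eta_g <- rep(0, length(ds$sample_ids))
  if (length(effects)) {
    missing <- setdiff(names(effects), ds$variants$id)
    if (length(missing)) {
      stop("causal variant(s) absent from dataset: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    eta_g <- drop(impute_mean(ds$dosages[, names(effects), drop = FALSE]) %*%
                    effects)
  }
  if (is.null(intercept)) {
    intercept <- stats::uniroot(function(a) {
      mean(stats::plogis(a + eta_g)) - case_fraction
    }, interval = c(-20, 20))$root
  }
  eta <- intercept + eta_g
  ds$phenotype <- stats::rbinom(length(eta), 1, stats::plogis(eta))
  attr(ds, "eta") <- eta
  attr(ds, "intercept") <- intercept
  ds
}

# expected SE of a per-allele log-OR in a case-control cohort, from the
# standard 1 / sqrt(2 n f (1-f) v (1-v)) approximation
.expected_se <- function(n, maf, case_fraction) {
  1 / sqrt(2 * n * maf * (1 - maf) * case_fraction * (1 - case_fraction))
}

#' Generate a two-cohort design: genotypes for A, summary statistics for B
#'
#' Cohort A is a genotype-level dataset with phenotype simulated under
#' `effects_a`.  Cohort B is returned as summary statistics only: its
#' effect estimates are drawn as
#' `betahat = effects_b + N(0, heterogeneity_sd^2) + N(0, se_b^2)` with
#' `se_b` from the large-sample case-control approximation at cohort B's
#' size and case fraction, mirroring a published scan available only as
#' summary data.
#'
#' @param cfg [sim_config()].
#' @param effects_a named vector of causal log-ORs in cohort A.
#' @param effects_b named vector of cohort-B true log-ORs (defaults to
#'   `effects_a`); unnamed variants have true effect 0.
#' @param heterogeneity_sd SD of the between-cohort effect perturbation.
#' @param maf optional target allele frequencies (useful to align planted
#'   effects calibrated via [grayzone_effects()] with the realized data).
#' @param seed optional RNG seed.
#' @return list: `cohort_a` ([genotype_dataset()] with phenotype),
#'   `study_b` (`kc_sumstats` data frame), `maf` (target frequencies).
#' @export
generate_two_cohorts <- function(cfg = sim_config(), effects_a = numeric(0),
                                 effects_b = effects_a,
                                 heterogeneity_sd = 0, maf = NULL,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ds <- generate_genotypes(cfg, maf = maf)
  ds <- simulate_phenotype(ds, effects_a, case_fraction = cfg$case_fraction)
  maf <- attr(ds, "target_maf")
  p <- cfg$n_variants
  beta_true <- stats::setNames(rep(0, p), ds$variants$id)
  beta_true[names(effects_b)] <- effects_b
  se_b <- .expected_se(cfg$n_b, maf, cfg$case_fraction_b)
  betahat <- beta_true + stats::rnorm(p, 0, heterogeneity_sd) +
    stats::rnorm(p, 0, se_b)
  study_b <- data.frame(chrom = ds$variants$chrom, pos = ds$variants$pos,
                        id = ds$variants$id, ea = ds$variants$ea,
                        oa = ds$variants$oa, beta = betahat, se = se_b,
                        p = .p_from_z(betahat / se_b), eaf = maf,
                        stringsAsFactors = FALSE)
  class(study_b) <- c("kc_sumstats", "data.frame")
  list(cohort_a = ds, study_b = study_b, maf = maf)
}

#' Cohort effects for planted gray-zone signals
#'
#' Converts target expected z-scores into per-cohort log odds ratios via
#' the expected standard errors at the configured cohort sizes.  With the
#' defaults (`z_a = 3.2`, `z_b = 5.1`) the planted variants are expected
#' to be nominal-only in cohort A (p around 1e-3) and just short of
#' genome-wide significance in cohort B (p around 1e-6 to 1e-7),
#' mirroring gray-zone signals rescued by meta-analysis.
#'
#' @param cfg [sim_config()].
#' @param variant_ids IDs of the planted variants.
#' @param maf their allele frequencies (for the expected SEs).
#' @param z_a,z_b target expected z-scores in cohorts A and B.
#' @return list with named vectors `effects_a` and `effects_b`.
#' @export
grayzone_effects <- function(cfg, variant_ids, maf, z_a = 3.2, z_b = 5.1) {
  se_a <- .expected_se(cfg$n_samples, maf, cfg$case_fraction)
  se_b <- .expected_se(cfg$n_b, maf, cfg$case_fraction_b)
  list(effects_a = stats::setNames(z_a * se_a, variant_ids),
       effects_b = stats::setNames(z_b * se_b, variant_ids))
}

#' Generate an annotation table spanning all evidence tiers
#'
#' Draws per-(variant, gene) evidence from distributions that cover every
#' scoring criterion: pLI uniform, CADD from a scale-10 exponential
#' (crossing both the 10 and 20 cutoffs), ncRVIS standard normal,
#' RegulomeDB categories uniform over 1-7, Bernoulli flags.  With
#' `include_extremes = TRUE` the first gene is forced to maximal
#' non-coding evidence and the second to minimal evidence, pinning the
#' score range ends.
#'
#' @param genes character vector of gene IDs.
#' @param snps_per_gene range of SNP counts per gene.
#' @param coding_fraction probability a gene's SNPs are coding-effect.
#' @param seed optional RNG seed.
#' @param include_extremes force an all-maximal and an all-minimal gene.
#' @return `kc_annotation` data frame (one row per variant-gene pair).
#' @export
generate_annotations <- function(genes, snps_per_gene = 1:3,
                                 coding_fraction = 0.3, seed = NULL,
                                 include_extremes = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  snp_counter <- 0L
  for (gi in seq_along(genes)) {
    g <- genes[gi]
    n_snp <- if (length(snps_per_gene) == 1) snps_per_gene else
      sample(snps_per_gene, 1)
    coding <- stats::runif(1) < coding_fraction
    pli <- stats::runif(1)
    ncrvis <- stats::rnorm(1)
    protein_coding <- stats::runif(1) < 0.7
    for (s in seq_len(n_snp)) {
      snp_counter <- snp_counter + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        id = sprintf("asnp_%05d", snp_counter), gene = g,
        is_coding = coding,
        consequence = if (coding) {
          sample(c("synonymous", "nonsynonymous", "frameshift", "inframe"), 1)
        } else "noncoding",
        cadd = min(stats::rexp(1, rate = 1 / 10), 45),
        pli = pli, ncrvis = ncrvis,
        rdb = sample(as.character(1:7), 1),
        eqtl = stats::runif(1) < 0.4,
        ci_mapped = stats::runif(1) < 0.3,
        protein_coding = protein_coding,
        stringsAsFactors = FALSE)
    }
  }
  ann <- do.call(rbind, rows)
  if (include_extremes && length(genes) >= 2) {
    hi <- ann$gene == genes[1]
    ann$is_coding[hi] <- FALSE
    ann$consequence[hi] <- "noncoding"
    ann$pli[hi] <- 0.99; ann$cadd[hi] <- 30; ann$ncrvis[hi] <- -1
    ann$rdb[hi] <- "1"; ann$eqtl[hi] <- TRUE; ann$ci_mapped[hi] <- TRUE
    ann$protein_coding[hi] <- TRUE
    lo <- ann$gene == genes[2]
    ann$is_coding[lo] <- FALSE
    ann$consequence[lo] <- "noncoding"
    ann$pli[lo] <- 0; ann$cadd[lo] <- 1; ann$ncrvis[lo] <- 1
    ann$rdb[lo] <- "7"; ann$eqtl[lo] <- FALSE; ann$ci_mapped[lo] <- FALSE
    ann$protein_coding[lo] <- FALSE
  }
  rownames(ann) <- NULL
  class(ann) <- c("kc_annotation", "data.frame")
  ann
}

#' Generate a drug-target table
#'
#' Samples drugs targeting the supplied genes with statuses over the four
#' categories; when any tier-1 gene is present, at least one approved
#' drug targeting a tier-1 gene is guaranteed.
#'
#' @param genes_with_tiers data frame `gene, tier` (see [gene_tiers()]),
#'   or a character vector of genes (treated as tier NA, no guarantee).
#' @param n_drugs number of drug-target rows drawn.
#' @param seed optional RNG seed.
#' @return `kc_drugs` data frame.
#' @export
generate_drug_table <- function(genes_with_tiers, n_drugs = 30, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.character(genes_with_tiers)) {
    genes_with_tiers <- data.frame(gene = genes_with_tiers,
                                   tier = rep(NA_integer_,
                                              length(genes_with_tiers)),
                                   stringsAsFactors = FALSE)
  }
  genes <- genes_with_tiers$gene
  if (!length(genes)) {
    out <- data.frame(drug = character(), status = character(),
                      target = character(), action = character(),
                      stringsAsFactors = FALSE)
    class(out) <- c("kc_drugs", "data.frame")
    return(out)
  }
  statuses <- sample(.VALID_STATUS, n_drugs, replace = TRUE,
                     prob = c(0.5, 0.25, 0.1, 0.15))
  out <- data.frame(
    drug = sprintf("drug_%03d", seq_len(n_drugs)),
    status = statuses,
    target = sample(genes, n_drugs, replace = TRUE),
    action = sample(c("inhibitor", "agonist", "antagonist", "modulator"),
                    n_drugs, replace = TRUE),
    stringsAsFactors = FALSE)
  tier1 <- genes_with_tiers$gene[!is.na(genes_with_tiers$tier) &
                                   genes_with_tiers$tier == 1]
  if (length(tier1) &&
      !any(out$status == "approved" & out$target %in% tier1)) {
    out$status[1] <- "approved"
    out$target[1] <- tier1[1]
  }
  class(out) <- c("kc_drugs", "data.frame")
  out
}

#' Write a complete set of synthetic fixture files
#'
#' Emits, into `out_dir`, every input the pipeline consumes in the
#' package's on-disk dialects: cohort-A dosages, phenotype and PC
#' covariates, cohort-B summary statistics, the empirical LD matrix, an
#' annotation table, a drug-target table and a network edge list over
#' the annotated genes.
#'
#' @param out_dir output directory (created if needed).
#' @param cfg [sim_config()].
#' @param seed RNG seed.
#' @param n_genes number of annotated genes.
#' @return named character vector of written paths, invisibly.
#' @export
write_synthetic_fixtures <- function(out_dir, cfg = sim_config(), seed = 1,
                                     n_genes = 20) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  planted <- sprintf("snp_%04d", c(5, max(6, cfg$n_variants %/% 2)))
  maf <- stats::runif(cfg$n_variants, cfg$maf_range[1], cfg$maf_range[2])
  eff <- grayzone_effects(cfg, planted, maf[match(planted,
                                                  sprintf("snp_%04d",
                                                          seq_len(cfg$n_variants)))])
  two <- generate_two_cohorts(cfg, effects_a = eff$effects_a,
                              effects_b = eff$effects_b)
  genes <- sprintf("GENE%02d", seq_len(n_genes))
  ann <- generate_annotations(genes, include_extremes = TRUE)
  sc <- score_genes(aggregate_evidence(ann))
  tiers <- gene_tiers(sc)
  drugs <- generate_drug_table(tiers)
  edges <- data.frame(GENE_A = sample(genes, 3 * n_genes, replace = TRUE),
                      GENE_B = sample(genes, 3 * n_genes, replace = TRUE))
  edges <- edges[edges$GENE_A != edges$GENE_B, ]
  # keep the written network a simple undirected graph
  key <- paste(pmin(edges$GENE_A, edges$GENE_B),
               pmax(edges$GENE_A, edges$GENE_B))
  edges <- edges[!duplicated(key), ]
  paths <- c(
    dosages = file.path(out_dir, "cohort_a_dosages.tsv"),
    phenotype = file.path(out_dir, "cohort_a_phenotype.tsv"),
    covariates = file.path(out_dir, "cohort_a_covariates.tsv"),
    sumstats_b = file.path(out_dir, "study_b_sumstats.tsv"),
    ld = file.path(out_dir, "ld_matrix.tsv"),
    annotation = file.path(out_dir, "annotation.tsv"),
    drugs = file.path(out_dir, "drug_targets.tsv"),
    network = file.path(out_dir, "network_edges.tsv")
  )
  write_dosage_tsv(two$cohort_a, paths["dosages"])
  utils::write.table(data.frame(SAMPLE = two$cohort_a$sample_ids,
                                PHENO = two$cohort_a$phenotype),
                     paths["phenotype"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  pcs <- compute_pcs(two$cohort_a, k = min(4, cfg$n_samples - 1))
  utils::write.table(data.frame(SAMPLE = rownames(pcs), pcs,
                                check.names = FALSE),
                     paths["covariates"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_sumstats(two$study_b, paths["sumstats_b"])
  write_ld_matrix(ld_from_dosages(two$cohort_a), paths["ld"])
  write_annotation_table(ann, paths["annotation"])
  write_drug_table(drugs, paths["drugs"])
  utils::write.table(unique(edges), paths["network"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
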