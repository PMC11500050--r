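# Per-SNP case-control association with covariate adjustment and basic
# QC, emulating the newly genotyped cohort stage of a two-cohort GWAS.

#' Quality-control thresholds
#'
#' @param min_maf minimum minor-allele frequency.
#' @param max_missing_per_variant maximum per-variant missing fraction.
#' @param max_missing_per_sample maximum per-sample missing fraction.
#' @param hwe_p_min minimum Hardy-Weinberg exact-test p in controls.
#' @return list of class `kc_qc_thresholds`.
#' @export
qc_thresholds <- function(min_maf = 0.01, max_missing_per_variant = 0.05,
                          max_missing_per_sample = 0.05, hwe_p_min = 1e-6) {
  vals <- c(min_maf, max_missing_per_variant, max_missing_per_sample, hwe_p_min)
  if (any(vals < 0 | vals > 1)) stop("QC thresholds must lie in [0, 1]", call. = FALSE)
  structure(list(min_maf = min_maf,
                 max_missing_per_variant = max_missing_per_variant,
                 max_missing_per_sample = max_missing_per_sample,
                 hwe_p_min = hwe_p_min),
            class = "kc_qc_thresholds")
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact test on genotype counts: the conditional probability
#' of each heterozygote count given the allele counts is evaluated in
#' closed form, and the p-value sums the probabilities of all tables no
#' more probable than the observed one.
#'
#' @param n_aa,n_ab,n_bb counts of the three genotype classes
#'   (homozygous reference, heterozygous, homozygous alternate).
#' @return exact two-sided p-value.
#' @export
hwe_exact_p <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  if (n == 0) return(1)
  n_a <- 2 * n_aa + n_ab
  hets <- seq.int(n_a %% 2, min(n_a, 2 * n - n_a), by = 2)
  log_p <- lfactorial(n) -
    (lfactorial((n_a - hets) / 2) + lfactorial(hets) +
       lfactorial((2 * n - n_a - hets) / 2)) +
    hets * log(2) +
    lfactorial(n_a) + lfactorial(2 * n - n_a) - lfactorial(2 * n)
  p_tab <- exp(log_p)
  p_obs <- p_tab[match(n_ab, hets)]
  min(1, sum(p_tab[p_tab <= p_obs * (1 + 1e-12)]))
}

# dosages -> hard genotype counts (AA, Aa, aa) rounding fractional dosages
.genotype_counts <- function(dose) {
  g <- round(dose)
  c(n_aa = sum(g == 0, na.rm = TRUE), n_ab = sum(g == 1, na.rm = TRUE),
    n_bb = sum(g == 2, na.rm = TRUE))
}

.variant_maf <- function(dose) {
  f <- mean(dose, na.rm = TRUE) / 2
  if (is.nan(f)) return(NA_real_)
  min(f, 1 - f)
}

#' Apply quality-control filters
#'
#' Filters are applied in a fixed order: sample missingness, variant
#' missingness, minor-allele frequency, then Hardy-Weinberg exact test on
#' control genotypes only.  The report counts removals per criterion.
#'
#' @param ds [genotype_dataset()] (phenotype required for the HWE step;
#'   without a phenotype the HWE filter is skipped).
#' @param thresholds [qc_thresholds()].
#' @return list with elements `dataset` (filtered) and `report` (class
#'   `kc_qc_report`: per-criterion removal counts and the removed IDs).
#' @export
qc_filter <- function(ds, thresholds = qc_thresholds()) {
  th <- thresholds
  dos <- ds$dosages
  removed <- list()

  sample_miss <- rowMeans(is.na(dos))
  drop_s <- sample_miss > th$max_missing_per_sample
  removed$sample_missingness <- ds$sample_ids[drop_s]
  dos <- dos[!drop_s, , drop = FALSE]
  pheno <- if (is.null(ds$phenotype)) NULL else ds$phenotype[!drop_s]
  covar <- if (is.null(ds$covariates)) NULL else
    ds$covariates[!drop_s, , drop = FALSE]

  var_miss <- colMeans(is.na(dos))
  drop_miss <- var_miss > th$max_missing_per_variant
  removed$variant_missingness <- ds$variants$id[drop_miss]

  maf <- apply(dos, 2, .variant_maf)
  drop_maf <- !drop_miss & (is.na(maf) | maf < th$min_maf)
  removed$maf <- ds$variants$id[drop_maf]

  drop_hwe <- rep(FALSE, ncol(dos))
  if (!is.null(pheno)) {
    ctrl <- which(pheno == 0)
    for (j in which(!drop_miss & !drop_maf)) {
      cnt <- .genotype_counts(dos[ctrl, j])
      if (hwe_exact_p(cnt[1], cnt[2], cnt[3]) < th$hwe_p_min) drop_hwe[j] <- TRUE
    }
  }
  removed$hwe <- ds$variants$id[drop_hwe]

  keep <- !(drop_miss | drop_maf | drop_hwe)
  if (!any(keep) || nrow(dos) == 0) {
    stop("no samples/variants survive quality control", call. = FALSE)
  }
  out <- genotype_dataset(dos[, keep, drop = FALSE],
                          ds$variants[keep, , drop = FALSE],
                          sample_ids = rownames(dos),
                          phenotype = pheno, covariates = covar)
  report <- structure(list(
    n_removed = vapply(removed, length, integer(1)),
    removed = removed,
    n_samples_kept = nrow(dos), n_variants_kept = sum(keep),
    thresholds = th), class = "kc_qc_report")
  list(dataset = out, report = report)
}

#' @export
print.kc_qc_report <- function(x, ...) {
  cat("<kc_qc_report>\n")
  for (nm in names(x$n_removed)) {
    cat(sprintf("  removed by %-20s %d\n", paste0(nm, ":"), x$n_removed[[nm]]))
  }
  cat(sprintf("  kept: %d samples x %d variants\n", x$n_samples_kept,
              x$n_variants_kept))
  invisible(x)
}

# greedy LD thinning in variant order: keep a variant iff its r2 with all
# previously kept variants is below the threshold
.ld_thin <- function(G, r2_max = 0.2) {
  p <- ncol(G)
  kept <- integer(0)
  for (j in seq_len(p)) {
    if (!length(kept)) { kept <- j; next }
    r <- suppressWarnings(stats::cor(G[, j], G[, kept, drop = FALSE]))
    r[is.na(r)] <- 0
    if (all(r^2 < r2_max)) kept <- c(kept, j)
  }
  kept
}

#' Principal components of the dosage matrix
#'
#' Computes sample-level principal-component scores for population-
#' stratification adjustment.  Variants are greedily LD-thinned
#' (`r2 < thin_r2` against all previously kept variants) to avoid local
#' LD dominating the leading components, zero-variance variants are
#' excluded, missing dosages mean-imputed, and columns standardized
#' before the singular-value decomposition.  Scores are deterministic up
#' to sign.
#'
#' @param ds [genotype_dataset()].
#' @param k number of components (`k < min(n_samples, n_variants)`).
#' @param thin_r2 LD-thinning r-squared threshold (set to 1 to disable).
#' @return numeric matrix (samples x k) of PC scores, ordered by
#'   decreasing variance explained; attribute `var_explained` holds the
#'   per-component fraction of variance.
#' @export
compute_pcs <- function(ds, k = 10, thin_r2 = 0.2) {
  G <- impute_mean(ds$dosages)
  sds <- apply(G, 2, stats::sd)
  G <- G[, sds > 0, drop = FALSE]
  if (k >= min(nrow(G), ncol(G))) {
    stop("k must be smaller than min(n_samples, n_variants)", call. = FALSE)
  }
  if (thin_r2 < 1) G <- G[, .ld_thin(G, thin_r2), drop = FALSE]
  S <- scale(G)
  pr <- stats::prcomp(S, center = FALSE, scale. = FALSE)
  scores <- pr$x[, seq_len(k), drop = FALSE]
  rownames(scores) <- ds$sample_ids
  attr(scores, "var_explained") <- (pr$sdev^2 / sum(pr$sdev^2))[seq_len(k)]
  scores
}

# Firth-penalized logistic regression (Jeffreys-prior penalty); used as
# the fallback under separation where maximum likelihood diverges.
firth_logistic <- function(X, y, maxit = 100, tol = 1e-8) {
  b <- rep(0, ncol(X))
  info <- NULL
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% b)
    p <- stats::plogis(eta)
    W <- p * (1 - p)
    info <- crossprod(X, X * W)
    info_inv <- tryCatch(solve(info), error = function(e) NULL)
    if (is.null(info_inv)) return(NULL)
    h <- W * rowSums((X %*% info_inv) * X)
    U <- crossprod(X, y - p + h * (0.5 - p))
    delta <- drop(info_inv %*% U)
    # step-halving for stability
    while (max(abs(delta)) > 5) delta <- delta / 2
    b <- b + delta
    if (max(abs(delta)) < tol) break
  }
  eta <- drop(X %*% b)
  W <- stats::plogis(eta) * (1 - stats::plogis(eta))
  info <- crossprod(X, X * W)
  se <- sqrt(diag(solve(info)))
  list(coef = b, se = se, converged = it < maxit)
}

# single-variant logistic fit; returns c(beta, se) for the dosage term or
# NULL when ML fails/separates
.ml_logistic <- function(X, y) {
  fit <- suppressWarnings(stats::glm.fit(X, y, family = stats::binomial()))
  if (!fit$converged || fit$rank < ncol(X)) return(NULL)
  coefs <- fit$coefficients
  # covariance from the unscaled qr decomposition of the final IRLS step
  covmat <- tryCatch(chol2inv(fit$qr$qr[seq_len(fit$rank), seq_len(fit$rank),
                                        drop = FALSE]),
                     error = function(e) NULL)
  if (is.null(covmat)) return(NULL)
  se <- sqrt(diag(covmat))
  if (!all(is.finite(se)) || abs(coefs[2]) > 10 || se[2] > 10) return(NULL)
  c(beta = unname(coefs[2]), se = unname(se[2]))
}

#' Per-variant logistic case-control association
#'
#' Fits, for each variant, a maximum-likelihood logistic regression of
#' the binary phenotype on effect-allele dosage plus covariates, and
#' reports the Wald z test (two-sided p).  Under separation or
#' non-convergence the fit falls back to Firth's penalized likelihood
#' when `firth_fallback` is `TRUE`, otherwise the variant is flagged
#' `NA`.  Monomorphic variants are flagged with reason `"monomorphic"`.
#' Missing dosages are mean-imputed per variant.
#'
#' @param ds [genotype_dataset()] with phenotype.
#' @param covariates optional numeric matrix (samples x covariates);
#'   defaults to the dataset's own covariate matrix.
#' @param firth_fallback use Firth penalized likelihood on ML failure.
#' @return data frame of class `kc_assoc` with columns `id, chrom, pos,
#'   ea, oa, beta, se, z, p, maf, n_cases, n_controls, method, reason`.
#' @export
logistic_assoc <- function(ds, covariates = NULL, firth_fallback = TRUE) {
  y <- ds$phenotype
  if (is.null(y)) stop("dataset has no phenotype", call. = FALSE)
  if (!any(y == 1) || !any(y == 0)) {
    stop("need at least one case and one control", call. = FALSE)
  }
  if (is.null(covariates)) covariates <- ds$covariates
  covm <- if (is.null(covariates)) NULL else as.matrix(covariates)
  G <- impute_mean(ds$dosages)
  p_var <- ncol(G)
  beta <- se <- z <- pval <- maf <- rep(NA_real_, p_var)
  method <- rep(NA_character_, p_var)
  reason <- rep(NA_character_, p_var)
  for (j in seq_len(p_var)) {
    dose <- G[, j]
    maf[j] <- .variant_maf(dose)
    if (stats::sd(dose) == 0) { reason[j] <- "monomorphic"; next }
    X <- if (is.null(covm)) cbind(1, dose) else cbind(1, dose, covm)
    fit <- .ml_logistic(X, y)
    if (!is.null(fit)) {
      beta[j] <- fit[["beta"]]; se[j] <- fit[["se"]]; method[j] <- "ml"
    } else if (firth_fallback) {
      ff <- firth_logistic(X, y)
      if (!is.null(ff) && all(is.finite(ff$se))) {
        beta[j] <- ff$coef[2]; se[j] <- ff$se[2]; method[j] <- "firth"
      } else reason[j] <- "fit_failed"
    } else {
      reason[j] <- "separation"
    }
  }
  z <- beta / se
  pval <- .p_from_z(z)
  out <- data.frame(id = ds$variants$id, chrom = ds$variants$chrom,
                    pos = ds$variants$pos, ea = ds$variants$ea,
                    oa = ds$variants$oa, beta = beta, se = se, z = z,
                    p = pval, maf = maf,
                    n_cases = sum(y == 1), n_controls = sum(y == 0),
                    method = method, reason = reason,
                    stringsAsFactors = FALSE)
  class(out) <- c("kc_assoc", "data.frame")
  out
}

#' Convert association results to the summary-statistics dialect
#'
#' Drops failed fits so the output feeds [run_meta_table()] directly.
#'
#' @param assoc `kc_assoc` data frame from [logistic_assoc()].
#' @param ds the dataset the associations came from (for allele
#'   frequencies).
#' @return `kc_sumstats` data frame.
#' @export
assoc_to_sumstats <- function(assoc, ds = NULL) {
  ok <- !is.na(assoc$beta) & !is.na(assoc$se) & assoc$se > 0
  eaf <- rep(NA_real_, nrow(assoc))
  if (!is.null(ds)) {
    eaf <- colMeans(ds$dosages, na.rm = TRUE)[match(assoc$id, ds$variants$id)] / 2
  }
  out <- data.frame(chrom = assoc$chrom[ok], pos = assoc$pos[ok],
                    id = assoc$id[ok], ea = assoc$ea[ok], oa = assoc$oa[ok],
                    beta = assoc$beta[ok], se = assoc$se[ok], p = assoc$p[ok],
                    eaf = eaf[ok], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("kc_sumstats", "data.frame")
  out
}
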