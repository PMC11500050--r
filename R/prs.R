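# Clumping-and-thresholding polygenic risk scoring: greedy LD clumping of
# base summary statistics, per-individual weighted allele-dosage scores,
# grid search over p-value cutoffs scored by Nagelkerke delta-R2, rank
# AUC with DeLong confidence interval, and label-permutation calibration
# of the best-fit model (the permutations re-optimize the cutoff, so the
# reported p is corrected for threshold-selection optimism).

#' Default p-value threshold grid
#'
#' Coarse PRSice-like grid; pass `fine = TRUE` for additional steps of
#' 5e-5 between 5e-5 and 0.05.
#'
#' @param fine add fine steps.
#' @return increasing numeric vector of cutoffs ending at 1.
#' @export
prs_default_grid <- function(fine = FALSE) {
  grid <- c(5e-8, 1e-6, 1e-4, 1e-3, 0.01, 0.05, 0.1, 0.5, 1)
  if (fine) grid <- sort(unique(c(grid, seq(5e-5, 0.05, by = 5e-5))))
  grid
}

#' Greedy LD clumping of base summary statistics
#'
#' PLINK/PRSice-style clumping: visit variants in ascending p order
#' (ties by chromosome, position); keep the best remaining variant and
#' remove every unprocessed variant on the same chromosome within
#' `window_kb` kilobases whose r-squared with it is at least `r2`.
#'
#' @param base summary statistics (`id, chrom, pos, p` columns).
#' @param ld r-squared matrix covering the base variants.
#' @param window_kb clumping window half-width in kb.
#' @param r2 removal threshold.
#' @return character vector of retained (index) variant IDs.
#' @export
clump <- function(base, ld, window_kb = 250, r2 = 0.1) {
  ord <- order(base$p, base$chrom, base$pos)
  b <- base[ord, , drop = FALSE]
  alive <- rep(TRUE, nrow(b))
  kept <- character(0)
  for (i in seq_len(nrow(b))) {
    if (!alive[i]) next
    kept <- c(kept, b$id[i])
    later <- which(alive & seq_len(nrow(b)) > i &
                     b$chrom == b$chrom[i] &
                     abs(b$pos - b$pos[i]) <= window_kb * 1000)
    if (length(later)) {
      r2v <- ld[b$id[i], b$id[later]]
      alive[later[r2v >= r2]] <- FALSE
    }
  }
  kept
}

#' Score individuals with SNP weights
#'
#' `score_s = sum_j beta_j * dosage_sj` (sum convention; an average over
#' SNPs would rescale all scores equally and leave rank-based metrics and
#' model fits unchanged).  Weight SNPs absent from the target are skipped
#' with a warning; missing dosages are mean-imputed.
#'
#' @param target [genotype_dataset()].
#' @param weights named numeric vector (variant ID -> log-OR weight).
#' @return numeric vector of per-sample scores (named by sample ID).
#' @export
score_individuals <- function(target, weights) {
  hit <- names(weights) %in% target$variants$id
  if (!any(hit)) stop("no weight SNPs overlap the target dataset", call. = FALSE)
  if (any(!hit)) {
    warning(sprintf("%d weight SNP(s) missing from target; skipped",
                    sum(!hit)), call. = FALSE)
  }
  w <- weights[hit]
  G <- impute_mean(target$dosages[, names(w), drop = FALSE])
  drop(G %*% w)
}

# Nagelkerke pseudo-R2 of a fitted deviance against the intercept-only
# deviance
.nagelkerke <- function(dev_model, dev_null, n) {
  cs <- 1 - exp((dev_model - dev_null) / n)
  cs / (1 - exp(-dev_null / n))
}

# logistic fit of y on (score, covariates); returns deviance and Wald p of
# the score term, or NULL on failure
.fit_score_model <- function(score, y, covm) {
  X <- if (is.null(covm)) cbind(1, score) else cbind(1, score, covm)
  fit <- tryCatch(
    suppressWarnings(stats::glm.fit(X, y, family = stats::binomial())),
    error = function(e) NULL)
  if (is.null(fit) || !fit$converged) return(NULL)
  covmat <- tryCatch(chol2inv(fit$qr$qr[seq_len(fit$rank), seq_len(fit$rank),
                                        drop = FALSE]),
                     error = function(e) NULL)
  if (is.null(covmat)) return(NULL)
  se <- sqrt(diag(covmat))
  list(deviance = fit$deviance, p_score = .p_from_z(fit$coefficients[2] / se[2]))
}

# deviances needed by every grid fit: intercept-only and covariate-only
.null_deviances <- function(y, covm) {
  dev0 <- suppressWarnings(stats::glm.fit(matrix(1, length(y)), y,
                                          family = stats::binomial()))$deviance
  dev_cov <- if (is.null(covm)) dev0 else
    suppressWarnings(stats::glm.fit(cbind(1, covm), y,
                                    family = stats::binomial()))$deviance
  list(dev0 = dev0, dev_cov = dev_cov)
}

# core grid evaluation on a precomputed score matrix (n x thresholds):
# returns per-threshold Nagelkerke delta-R2 and score-term p
.prs_grid_fit <- function(score_mat, y, covm) {
  n <- length(y)
  nd <- .null_deviances(y, covm)
  r2_cov <- .nagelkerke(nd$dev_cov, nd$dev0, n)
  fit_r2 <- fit_p <- rep(NA_real_, ncol(score_mat))
  for (t in seq_len(ncol(score_mat))) {
    s <- score_mat[, t]
    if (all(!is.finite(s)) || stats::sd(s) == 0) next
    f <- .fit_score_model(s, y, covm)
    if (is.null(f)) next
    fit_r2[t] <- .nagelkerke(f$deviance, nd$dev0, n) - r2_cov
    fit_p[t] <- f$p_score
  }
  list(fit_r2 = fit_r2, fit_p = fit_p)
}

# score matrix: one column per threshold, NA column when no SNP passes
.prs_score_matrix <- function(base, target, grid) {
  n <- length(target$sample_ids)
  sm <- matrix(NA_real_, n, length(grid))
  n_snps <- integer(length(grid))
  weights_by_t <- vector("list", length(grid))
  for (t in seq_along(grid)) {
    sel <- base[base$p <= grid[t], , drop = FALSE]
    sel <- sel[sel$id %in% target$variants$id, , drop = FALSE]
    n_snps[t] <- nrow(sel)
    if (!nrow(sel)) next
    w <- stats::setNames(sel$beta, sel$id)
    weights_by_t[[t]] <- w
    sm[, t] <- suppressWarnings(score_individuals(target, w))
  }
  list(scores = sm, n_snps = n_snps, weights = weights_by_t)
}

#' Grid search over p-value thresholds
#'
#' For each cutoff in `grid`, scores the target with the (already
#' clumped) base SNPs passing the cutoff and fits
#' `phenotype ~ score + covariates` by logistic regression; the model fit
#' is summarized as the Nagelkerke pseudo-R2 of the full model minus that
#' of the covariate-only model (both against the intercept-only null).
#' The best threshold maximizes this delta-R2.  Cutoffs where no SNP
#' passes or the fit fails are skipped with a warning.
#'
#' @param base clumped base summary statistics (see [clump()]).
#' @param target [genotype_dataset()] with phenotype.
#' @param covariates optional numeric matrix.
#' @param grid increasing p-value cutoffs, see [prs_default_grid()].
#' @return list of class `kc_prs_model`: `table` (threshold, n_snps,
#'   fit_r2, fit_p), `best_threshold`, `best_n_snps`, `best_fit_r2`,
#'   `snp_weights` (named vector for the best model), `scores` (matrix
#'   reusable by [permutation_p()]).
#' @export
threshold_search <- function(base, target, covariates = NULL,
                             grid = prs_default_grid()) {
  y <- target$phenotype
  if (is.null(y) || !all(y %in% c(0, 1))) {
    stop("target phenotype must be binary 0/1", call. = FALSE)
  }
  covm <- if (is.null(covariates)) NULL else as.matrix(covariates)
  smat <- .prs_score_matrix(base, target, grid)
  gf <- .prs_grid_fit(smat$scores, y, covm)
  skipped <- smat$n_snps > 0 & is.na(gf$fit_r2)
  if (any(skipped)) {
    warning("grid cutoff(s) skipped (non-converging fit): ",
            paste(signif(grid[skipped], 3), collapse = ", "), call. = FALSE)
  }
  if (all(is.na(gf$fit_r2))) stop("no usable cutoff in the grid", call. = FALSE)
  best <- which.max(gf$fit_r2)
  structure(list(
    table = data.frame(threshold = grid, n_snps = smat$n_snps,
                       fit_r2 = gf$fit_r2, fit_p = gf$fit_p),
    best_threshold = grid[best],
    best_n_snps = smat$n_snps[best],
    best_fit_r2 = gf$fit_r2[best],
    best_fit_p = gf$fit_p[best],
    snp_weights = smat$weights[[best]],
    scores = smat$scores,
    grid = grid
  ), class = "kc_prs_model")
}

#' @export
print.kc_prs_model <- function(x, ...) {
  cat(sprintf("<kc_prs_model> best threshold %.3g (%d SNPs), delta-R2 = %.4f, p = %.3g\n",
              x$best_threshold, x$best_n_snps, x$best_fit_r2, x$best_fit_p))
  invisible(x)
}

#' Rank-statistic AUC
#'
#' Probability that a random case outscores a random control, with ties
#' receiving half credit (Wilcoxon form).
#'
#' @param scores numeric vector.
#' @param phenotype binary 0/1 vector.
#' @return AUC in \[0, 1\].
#' @export
rank_auc <- function(scores, phenotype) {
  n1 <- sum(phenotype == 1)
  n0 <- sum(phenotype == 0)
  if (n1 == 0 || n0 == 0) stop("need both cases and controls", call. = FALSE)
  r <- rank(scores)
  (sum(r[phenotype == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate polygenic score discrimination
#'
#' Rank-statistic AUC ([rank_auc()]) with a DeLong asymptotic-covariance
#' confidence interval, case/control score means, and a Welch two-sample
#' t-test on the scores.
#'
#' @param scores numeric vector of per-sample scores.
#' @param phenotype binary 0/1 vector.
#' @param level confidence level for the AUC interval.
#' @return list of class `kc_prs_eval`: `auc, auc_ci, case_mean,
#'   control_mean, t_stat, t_p, n_cases, n_controls`.
#' @export
prs_evaluate <- function(scores, phenotype, level = 0.95) {
  auc <- rank_auc(scores, phenotype)
  roc <- pROC::roc(response = phenotype, predictor = scores,
                   levels = c(0, 1), direction = "<", quiet = TRUE)
  ci <- as.numeric(pROC::ci.auc(roc, conf.level = level, method = "delong"))
  tt <- stats::t.test(scores[phenotype == 1], scores[phenotype == 0])
  structure(list(
    auc = auc, auc_ci = c(lower = ci[1], upper = ci[3]),
    case_mean = mean(scores[phenotype == 1]),
    control_mean = mean(scores[phenotype == 0]),
    t_stat = unname(tt$statistic), t_p = tt$p.value,
    n_cases = sum(phenotype == 1), n_controls = sum(phenotype == 0)
  ), class = "kc_prs_eval")
}

#' @export
print.kc_prs_eval <- function(x, ...) {
  cat(sprintf("<kc_prs_eval> AUC = %.3f [%.3f, %.3f]; case mean %.3g vs control mean %.3g (Welch p = %.3g)\n",
              x$auc, x$auc_ci[1], x$auc_ci[2], x$case_mean, x$control_mean,
              x$t_p))
  invisible(x)
}

#' Label-permutation p-value for the best-fit PRS model
#'
#' Permutes phenotype labels `B` times and re-runs the full threshold
#' search on each permutation (re-optimizing the cutoff, so the null
#' distribution carries the same selection optimism as the observed
#' statistic).  `perm_p = (1 + #{permuted best delta-R2 >= observed}) /
#' (B + 1)`; the attainable minimum is `1/(B+1)` (9.99e-4 at B = 1000).
#'
#' @param base clumped base summary statistics.
#' @param target [genotype_dataset()] with phenotype.
#' @param covariates optional numeric matrix.
#' @param grid p-value cutoffs.
#' @param B number of permutations (>= 1).
#' @param seed optional RNG seed.
#' @param model optional pre-computed [threshold_search()] result for the
#'   observed labels (avoids recomputing scores).
#' @return list: `perm_p`, `observed` (best delta-R2), `B`,
#'   `perm_best_r2` (null draws).
#' @export
permutation_p <- function(base, target, covariates = NULL,
                          grid = prs_default_grid(), B = 1000, seed = NULL,
                          model = NULL) {
  if (B < 1) stop("B must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(model)) model <- threshold_search(base, target, covariates, grid)
  y <- target$phenotype
  covm <- if (is.null(covariates)) NULL else as.matrix(covariates)
  score_mat <- model$scores
  obs <- model$best_fit_r2
  perm_best <- vapply(seq_len(B), function(b) {
    yp <- sample(y)
    gf <- .prs_grid_fit(score_mat, yp, covm)
    max(gf$fit_r2, na.rm = TRUE)
  }, numeric(1))
  list(perm_p = (1 + sum(perm_best >= obs)) / (B + 1),
       observed = obs, B = B, perm_best_r2 = perm_best)
}
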