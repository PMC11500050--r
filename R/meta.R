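# Inverse-variance fixed-effects meta-analysis with Cochran's Q / I2
# heterogeneity and gray-zone signal classification.
#
# Effects are natural-log odds ratios throughout.  Note on reporting: in
# the published summary table this package reproduces, the column headed
# "Q" holds the *tail probability* of Cochran's Q test (chi-square, k-1
# df), not the Q statistic itself -- recomputation from the printed
# per-study ORs/CIs matches the printed values only under that reading.
# `fixed_effects_meta()` therefore reports both `q_stat` and `q_p`.

#' Convert an odds ratio with confidence interval to log-odds and SE
#'
#' `beta = ln(OR)`, `se = (ln U - ln L) / (2 * z)` with
#' `z = qnorm((1 + level)/2)` (1.959964 for 95% intervals).
#'
#' @param or_value odds ratio (> 0).
#' @param ci_low,ci_high confidence bounds with
#'   `0 < ci_low <= or_value <= ci_high` and `ci_low < ci_high`.
#' @param level confidence level of the interval.
#' @return named numeric vector `c(beta =, se =)`.
#' @export
beta_se_from_or_ci <- function(or_value, ci_low, ci_high, level = 0.95) {
  if (any(is.na(c(or_value, ci_low, ci_high)))) {
    stop("OR and CI bounds must be non-missing", call. = FALSE)
  }
  if (ci_low <= 0 || or_value <= 0 || ci_high <= 0) {
    stop("OR and CI bounds must be positive", call. = FALSE)
  }
  if (ci_low >= ci_high) stop("zero-width or inverted CI", call. = FALSE)
  if (or_value < ci_low || or_value > ci_high) {
    stop("OR must lie within its CI", call. = FALSE)
  }
  z <- .ci_z(level)
  c(beta = log(or_value), se = (log(ci_high) - log(ci_low)) / (2 * z))
}

#' Inverse of [beta_se_from_or_ci()]
#' @param beta log odds ratio.
#' @param se standard error of `beta`.
#' @param level confidence level.
#' @return named vector `c(or =, ci_low =, ci_high =)`.
#' @export
or_ci_from_beta_se <- function(beta, se, level = 0.95) {
  z <- .ci_z(level)
  c(or = exp(beta), ci_low = exp(beta - z * se), ci_high = exp(beta + z * se))
}

#' Fixed-effects inverse-variance meta-analysis of one variant
#'
#' Pools per-study log odds ratios with weights `w_i = 1/se_i^2`:
#' `beta = sum(w b) / sum(w)`, `se = sum(w)^(-1/2)`, Wald z and two-sided
#' p.  Heterogeneity: `Q = sum(w (b - beta)^2)` on `k - 1` df with
#' chi-square tail probability `q_p`, and
#' `I2 = 100 * max(0, (Q - (k-1)) / Q)` (0 when `Q = 0`).  With a single
#' study the pooled effect equals the input and `q_p`/`i2` are `NA`.
#'
#' @param beta numeric vector of per-study log odds ratios.
#' @param se numeric vector of per-study standard errors (> 0).
#' @param labels optional study labels.
#' @return list of class `kc_meta` with elements `beta_meta, se_meta, z,
#'   p_meta, k, q_stat, q_df, q_p, i2`.
#' @export
fixed_effects_meta <- function(beta, se, labels = NULL) {
  if (length(beta) != length(se) || !length(beta)) {
    stop("need >= 1 study with matching beta and se", call. = FALSE)
  }
  if (any(!is.finite(beta)) || any(!(se > 0))) {
    stop("betas must be finite and ses positive", call. = FALSE)
  }
  k <- length(beta)
  w <- 1 / se^2
  beta_meta <- sum(w * beta) / sum(w)
  se_meta <- 1 / sqrt(sum(w))
  z <- beta_meta / se_meta
  if (k == 1L) {
    q_stat <- NA_real_; q_p <- NA_real_; i2 <- NA_real_
  } else {
    q_stat <- sum(w * (beta - beta_meta)^2)
    q_p <- stats::pchisq(q_stat, df = k - 1, lower.tail = FALSE)
    i2 <- if (q_stat <= 0) 0 else 100 * max(0, (q_stat - (k - 1)) / q_stat)
  }
  structure(list(beta_meta = beta_meta, se_meta = se_meta, z = z,
                 p_meta = .p_from_z(z), k = k,
                 q_stat = q_stat, q_df = k - 1L, q_p = q_p, i2 = i2,
                 labels = labels),
            class = "kc_meta")
}

#' @export
print.kc_meta <- function(x, ...) {
  cat(sprintf("<kc_meta> k=%d OR=%.3f (beta=%.4f, se=%.4f) p=%.3g",
              x$k, exp(x$beta_meta), x$beta_meta, x$se_meta, x$p_meta))
  if (x$k > 1) cat(sprintf(" Q=%.3f (p=%.3f) I2=%.1f", x$q_stat, x$q_p, x$i2))
  cat("\n")
  invisible(x)
}

#' Classify a meta-analysis signal
#'
#' Gray-zone rescue logic: a variant genome-wide significant in the meta
#' but not in the prior large scan is a novel signal; it is *firm* when
#' the new cohort supports it at the nominal level, otherwise
#' *suggestive*.  Variants genome-wide significant in both the meta and
#' the prior scan are replicated known signals.
#'
#' @param p_meta pooled p-value.
#' @param p_new p-value in the newly genotyped cohort.
#' @param p_prior p-value in the previously published scan.
#' @param gw_threshold genome-wide significance threshold.
#' @param nominal nominal significance threshold for the new cohort.
#' @return one of `"firm_novel"`, `"suggestive"`, `"replicated_known"`,
#'   `"not_significant"`.
#' @export
classify_signal <- function(p_meta, p_new, p_prior,
                            gw_threshold = 5e-8, nominal = 0.05) {
  if (any(is.na(c(p_meta, p_new, p_prior)))) {
    stop("all three p-values are required for classification", call. = FALSE)
  }
  if (p_meta >= gw_threshold) return("not_significant")
  if (p_prior < gw_threshold) return("replicated_known")
  if (p_new < nominal) "firm_novel" else "suggestive"
}

# Harmonize one study-B record onto study A's effect-allele orientation.
# Returns multiplier +1/-1, or NA with a reason attribute when the variant
# must be skipped.
.harmonize_alleles <- function(ea_a, oa_a, ea_b, oa_b, eaf_a = NA, eaf_b = NA,
                               freq_tol = 0.2) {
  flip_for <- function(mult, flipped_eaf_b) {
    if (.is_ambiguous(ea_a, oa_a)) {
      # A/T or C/G variant: orientation is only trusted when frequencies agree
      if (is.na(eaf_a) || is.na(flipped_eaf_b) ||
          abs(eaf_a - flipped_eaf_b) > freq_tol) {
        return(structure(NA_real_, reason = "strand_ambiguous"))
      }
    }
    mult
  }
  if (ea_b == ea_a && oa_b == oa_a) return(flip_for(1, eaf_b))
  if (ea_b == oa_a && oa_b == ea_a) return(flip_for(-1, 1 - eaf_b))
  cea <- .complement(ea_b); coa <- .complement(oa_b)
  if (cea == ea_a && coa == oa_a) return(flip_for(1, eaf_b))
  if (cea == oa_a && coa == ea_a) return(flip_for(-1, 1 - eaf_b))
  structure(NA_real_, reason = "allele_mismatch")
}

#' Meta-analyze two studies' summary statistics
#'
#' Matches variants by ID (falling back to `chrom:pos` for unmatched IDs),
#' harmonizes study B onto study A's effect allele (sign flip when the
#' allele pair is swapped, strand complement handled; strand-ambiguous
#' A/T and C/G variants require allele frequencies agreeing within
#' `freq_tol` to confirm orientation), then applies
#' [fixed_effects_meta()] and [classify_signal()] per shared variant.
#' Unharmonizable variants are reported in the `"skipped"` attribute.
#'
#' @param study_a summary statistics of the new cohort
#'   (see [read_sumstats()]).
#' @param study_b summary statistics of the prior scan.
#' @param gw_threshold,nominal classification thresholds.
#' @param freq_tol allele-frequency tolerance for ambiguous variants.
#' @return data frame of class `kc_meta_results`: per shared variant the
#'   per-study effects, pooled effect, heterogeneity statistics and
#'   classification; attribute `skipped` lists dropped variants with
#'   reasons.
#' @export
run_meta_table <- function(study_a, study_b, gw_threshold = 5e-8,
                           nominal = 0.05, freq_tol = 0.2) {
  if (!nrow(study_b)) {
    warning("study B is empty; no variants to meta-analyze", call. = FALSE)
    return(structure(data.frame(), class = c("kc_meta_results", "data.frame"),
                     skipped = data.frame()))
  }
  key_a <- study_a$id
  key_b <- study_b$id
  idx_b <- match(key_a, key_b)
  # fall back to positional matching where IDs failed
  pos_a <- paste0(study_a$chrom, ":", study_a$pos)
  pos_b <- paste0(study_b$chrom, ":", study_b$pos)
  miss <- is.na(idx_b)
  idx_b[miss] <- match(pos_a[miss], pos_b)
  shared <- which(!is.na(idx_b))
  skipped <- list()
  rows <- vector("list", length(shared))
  for (i in seq_along(shared)) {
    a <- study_a[shared[i], ]
    b <- study_b[idx_b[shared[i]], ]
    mult <- .harmonize_alleles(a$ea, a$oa, b$ea, b$oa,
                               eaf_a = if (is.null(a$eaf)) NA else a$eaf,
                               eaf_b = if (is.null(b$eaf)) NA else b$eaf,
                               freq_tol = freq_tol)
    if (is.na(mult)) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(id = a$id, reason = attr(mult, "reason"),
                   stringsAsFactors = FALSE)
      next
    }
    beta_b <- mult * b$beta
    m <- fixed_effects_meta(c(a$beta, beta_b), c(a$se, b$se))
    rows[[i]] <- data.frame(
      id = a$id, chrom = a$chrom, pos = a$pos, ea = a$ea, oa = a$oa,
      beta_a = a$beta, se_a = a$se, p_a = a$p,
      beta_b = beta_b, se_b = b$se, p_b = b$p,
      beta_meta = m$beta_meta, se_meta = m$se_meta, z = m$z,
      p_meta = m$p_meta, k = m$k, q_stat = m$q_stat, q_df = m$q_df,
      q_p = m$q_p, i2 = m$i2,
      classification = classify_signal(m$p_meta, a$p, b$p,
                                       gw_threshold, nominal),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) out <- data.frame()
  rownames(out) <- NULL
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(id = character(), reason = character())
  class(out) <- c("kc_meta_results", "data.frame")
  out
}

#' Meta-analyze a wide two-study table of printed ORs and CIs
#'
#' Consumes the packaged summary-table fixture layout (one row per
#' variant, per-study odds ratios with 95% CIs and p-values; see
#' [kc_table1()]), converts each study via [beta_se_from_or_ci()], pools
#' with [fixed_effects_meta()] and classifies with [classify_signal()].
#'
#' When the table carries a published pooled p-value column
#' (`p_meta_printed`), classification uses it in place of the p-value
#' recomputed from the rounded CIs: published full-precision p-values
#' take precedence over quantities reconstructed from 2-decimal ORs/CIs,
#' whose rounding error is large relative to genome-wide significance
#' margins.  The recomputed pooled statistics are always reported.
#'
#' @param x data frame with columns `id, chrom, pos, p_a, or_a, l95_a,
#'   u95_a, p_b, or_b, l95_b, u95_b` (study A = new cohort, study B =
#'   prior scan) and optionally `p_meta_printed`.
#' @param gw_threshold,nominal classification thresholds.
#' @return data frame with pooled OR, heterogeneity and classification
#'   per row.
#' @export
meta_from_wide <- function(x, gw_threshold = 5e-8, nominal = 0.05) {
  rows <- lapply(seq_len(nrow(x)), function(i) {
    a <- beta_se_from_or_ci(x$or_a[i], x$l95_a[i], x$u95_a[i])
    b <- beta_se_from_or_ci(x$or_b[i], x$l95_b[i], x$u95_b[i])
    m <- fixed_effects_meta(c(a[["beta"]], b[["beta"]]),
                            c(a[["se"]], b[["se"]]))
    p_class <- if (!is.null(x$p_meta_printed)) x$p_meta_printed[i] else m$p_meta
    data.frame(id = x$id[i], chrom = x$chrom[i], pos = x$pos[i],
               or_meta = exp(m$beta_meta), beta_meta = m$beta_meta,
               se_meta = m$se_meta, p_meta = m$p_meta,
               q_stat = m$q_stat, q_p = m$q_p, i2 = m$i2,
               classification = classify_signal(p_class, x$p_a[i], x$p_b[i],
                                                gw_threshold, nominal),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write meta-analysis results
#'
#' Summary-statistics dialect (pooled effect) plus extra columns
#' `Q_STAT Q_P I2 CLASSIFICATION P_A P_B`.
#'
#' @param x `kc_meta_results` data frame from [run_meta_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_meta_results <- function(x, path) {
  base <- data.frame(chrom = x$chrom, pos = x$pos, id = x$id, ea = x$ea,
                     oa = x$oa, beta = x$beta_meta, se = x$se_meta,
                     p = x$p_meta, eaf = NA_real_, stringsAsFactors = FALSE)
  extra <- data.frame(Q_STAT = .fmt_num(x$q_stat), Q_P = .fmt_num(x$q_p),
                      I2 = .fmt_num(x$i2), CLASSIFICATION = x$classification,
                      P_A = .fmt_num(x$p_a), P_B = .fmt_num(x$p_b),
                      stringsAsFactors = FALSE)
  write_sumstats(base, path, extra = extra)
}
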