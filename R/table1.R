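# Packaged worked example: the 42 genome-wide-significant keratoconus
# meta-analysis variants with per-study odds ratios, 95% CIs and
# p-values, as printed in the source study's summary table (study A =
# Spanish cohort, N = 1116; study B = prior UK scan, N = 121216).  The
# printed pooled OR, Q-test tail probability and I2 columns are retained
# for cross-checking recomputation; all positions are GRCh38.

#' Load the packaged keratoconus meta-analysis summary table
#'
#' Returns the 42-variant worked example shipped with the package: for
#' each variant, per-study p-values and odds ratios with 95% confidence
#' intervals, plus the published pooled OR, Cochran's Q tail probability
#' and I2 for comparison.  The published "Q" column is a tail
#' probability, not the Q statistic (recomputation from the printed
#' ORs/CIs reproduces it only under that reading).
#'
#' Feed this table to [meta_from_wide()] to recompute the pooled
#' statistics and signal classification.
#'
#' @return data frame with columns `chrom, pos, id, ref, p_a, or_a,
#'   l95_a, u95_a, p_b, or_b, l95_b, u95_b, p_meta_printed,
#'   or_meta_printed, q_p_printed, i2_printed`.
#' @examples
#' tab <- kc_table1()
#' res <- meta_from_wide(tab)
#' table(res$classification)
#' @export
kc_table1 <- function() {
  path <- system.file("extdata", "table1_kc_meta.tsv", package = "kcmeta",
                      mustWork = TRUE)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE)
  data.frame(
    chrom = as.character(raw$CHR), pos = as.integer(raw$POS),
    id = raw$ID, ref = raw$REF,
    p_a = raw$P_A, or_a = raw$OR_A, l95_a = raw$L95_A, u95_a = raw$U95_A,
    p_b = raw$P_B, or_b = raw$OR_B, l95_b = raw$L95_B, u95_b = raw$U95_B,
    p_meta_printed = raw$P_META, or_meta_printed = raw$OR_META,
    q_p_printed = raw$Q_P, i2_printed = raw$I2,
    stringsAsFactors = FALSE
  )
}
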