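# Tier-based variant-to-gene evidence ledger.  Genes are scored on two
# separate tracks depending on whether their associated candidate SNPs
# have coding or non-coding effects:
#
# coding track (0-5):     +1 pLI >= 0.9; +1 best CADD >= 10 / +2 >= 20
#                         (non-cumulative); +1 synonymous or non-frame-
#                         changing effect / +2 nonsynonymous or frame-
#                         changing effect.
#                         tier 1 = 4-5, tier 2 = 2-3, tier 3 = 0-1.
# non-coding track (0-9): +1 pLI >= 0.9; CADD points as above; +1 ncRVIS
#                         < 0; +1 protein-coding gene; +1 eQTL effect;
#                         +2 RegulomeDB category 1/2 or +1 category 3/4;
#                         +1 chromatin-interaction mapped.
#                         tier 1 = 6-9, tier 2 = 3-5, tier 3 = 0-2.
#
# Per-gene aggregation over SNPs is best-evidence: max CADD, most
# significant (lowest) RegulomeDB category, OR over flags.

.cadd_points <- function(cadd) {
  if (is.na(cadd)) return(0L)
  if (cadd >= 20) 2L else if (cadd >= 10) 1L else 0L
}

.rdb_points <- function(rdb) {
  if (is.na(rdb)) return(0L)
  d <- substr(rdb, 1, 1)
  if (d %in% c("1", "2")) 2L else if (d %in% c("3", "4")) 1L else 0L
}

.pli_points <- function(pli) as.integer(!is.na(pli) && pli >= 0.9)

.tier_coding <- function(score) if (score >= 4) 1L else if (score >= 2) 2L else 3L
.tier_noncoding <- function(score) if (score >= 6) 1L else if (score >= 3) 2L else 3L

#' Score a gene's coding-track evidence
#'
#' @param pli probability of loss-of-function intolerance in \[0, 1\]
#'   (NA allowed, scores 0).
#' @param best_cadd maximum CADD deleteriousness score over the gene's
#'   candidate SNPs.
#' @param consequence_class `"synonymous_or_inframe"` (1 point) or
#'   `"nonsynonymous_or_frameshift"` (2 points).
#' @return list of class `kc_gene_score`: `score` (0-5), `tier` (1-3),
#'   `track = "coding"`.
#' @export
score_coding <- function(pli, best_cadd, consequence_class) {
  if (is.na(consequence_class) ||
      !consequence_class %in% c("synonymous_or_inframe",
                                "nonsynonymous_or_frameshift")) {
    stop("missing or invalid consequence class", call. = FALSE)
  }
  cons_pts <- if (consequence_class == "nonsynonymous_or_frameshift") 2L else 1L
  score <- .pli_points(pli) + .cadd_points(best_cadd) + cons_pts
  structure(list(score = score, tier = .tier_coding(score), track = "coding"),
            class = "kc_gene_score")
}

#' Score a gene's non-coding-track evidence
#'
#' @param pli,best_cadd as in [score_coding()].
#' @param ncrvis non-coding residual variation intolerance score
#'   (1 point when < 0).
#' @param protein_coding logical flag (1 point).
#' @param eqtl logical flag: any eQTL effect (1 point).
#' @param best_rdb most significant RegulomeDB category over the gene's
#'   SNPs (sub-categories such as "2b" count by leading digit; "1"/"2"
#'   give 2 points, "3"/"4" 1 point).
#' @param ci_mapped logical flag: chromatin-interaction mapped (1 point).
#' @return list of class `kc_gene_score`: `score` (0-9), `tier` (1-3),
#'   `track = "noncoding"`.
#' @export
score_noncoding <- function(pli, best_cadd, ncrvis, protein_coding, eqtl,
                            best_rdb, ci_mapped) {
  score <- .pli_points(pli) + .cadd_points(best_cadd) +
    as.integer(!is.na(ncrvis) && ncrvis < 0) +
    as.integer(isTRUE(protein_coding)) +
    as.integer(isTRUE(eqtl)) +
    .rdb_points(best_rdb) +
    as.integer(isTRUE(ci_mapped))
  structure(list(score = score, tier = .tier_noncoding(score),
                 track = "noncoding"),
            class = "kc_gene_score")
}

#' Aggregate per-SNP annotations into per-(gene, track) evidence
#'
#' Restricts the annotation table to the locus-stage candidate SNPs, then
#' aggregates per gene and track with best-evidence rules: maximum CADD,
#' lowest RegulomeDB category digit, OR over eQTL / chromatin /
#' protein-coding flags; the coding consequence class is
#' frame-changing/nonsynonymous if any SNP is.  A gene hit by both coding
#' and non-coding SNPs yields one evidence row per track.
#'
#' @param annotations annotation table (see [read_annotation_table()]).
#' @param candidate_snps character vector of candidate SNP IDs (NULL to
#'   use all annotation rows).
#' @return data frame of class `kc_gene_evidence`: one row per
#'   (gene, track) with the aggregated fields.
#' @export
aggregate_evidence <- function(annotations, candidate_snps = NULL) {
  ann <- annotations
  if (!is.null(candidate_snps)) {
    ann <- ann[ann$id %in% candidate_snps, , drop = FALSE]
  }
  if (!nrow(ann)) {
    return(structure(data.frame(), class = c("kc_gene_evidence", "data.frame")))
  }
  ann$track <- ifelse(ann$is_coding, "coding", "noncoding")
  max_na <- function(x) if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE)
  min_na <- function(x) if (all(is.na(x))) NA_real_ else min(x, na.rm = TRUE)
  rows <- lapply(split(ann, list(ann$gene, ann$track), drop = TRUE),
                 function(g) {
    frame_changing <- any(g$consequence %in% c("nonsynonymous", "frameshift"))
    rdb_digits <- suppressWarnings(as.integer(substr(g$rdb, 1, 1)))
    best_digit <- min_na(rdb_digits)
    data.frame(
      gene = g$gene[1], track = g$track[1],
      pli = max_na(g$pli),
      best_cadd = max_na(g$cadd),
      ncrvis = min_na(g$ncrvis),
      protein_coding = any(g$protein_coding, na.rm = TRUE),
      eqtl = any(g$eqtl, na.rm = TRUE),
      best_rdb = if (is.na(best_digit)) NA_character_ else
        as.character(best_digit),
      ci_mapped = any(g$ci_mapped, na.rm = TRUE),
      consequence_class = if (g$track[1] == "coding") {
        if (frame_changing) "nonsynonymous_or_frameshift" else
          "synonymous_or_inframe"
      } else NA_character_,
      n_snps = nrow(g),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$gene, out$track), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("kc_gene_evidence", "data.frame")
  out
}

#' Score aggregated gene evidence
#'
#' Applies [score_coding()] / [score_noncoding()] row-wise to
#' [aggregate_evidence()] output.
#'
#' @param evidence `kc_gene_evidence` data frame.
#' @return data frame with columns `gene, track, score, tier`.
#' @export
score_genes <- function(evidence) {
  if (!nrow(evidence)) {
    return(data.frame(gene = character(), track = character(),
                      score = integer(), tier = integer()))
  }
  rows <- lapply(seq_len(nrow(evidence)), function(i) {
    e <- evidence[i, ]
    gs <- if (e$track == "coding") {
      score_coding(e$pli, e$best_cadd, e$consequence_class)
    } else {
      score_noncoding(e$pli, e$best_cadd, e$ncrvis, e$protein_coding,
                      e$eqtl, e$best_rdb, e$ci_mapped)
    }
    data.frame(gene = e$gene, track = e$track, score = gs$score,
               tier = gs$tier, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Combined per-gene tier across tracks
#'
#' A gene scored on both tracks gets, by default, the better (lower) of
#' its two tiers (`rule = "either"`); `rule = "both"` requires the same
#' tier on both tracks and otherwise reports the worse one.
#'
#' @param scores data frame from [score_genes()].
#' @param rule `"either"` or `"both"`.
#' @return data frame `gene, tier` (one row per gene).
#' @export
gene_tiers <- function(scores, rule = c("either", "both")) {
  rule <- match.arg(rule)
  if (!nrow(scores)) {
    return(data.frame(gene = character(), tier = integer(),
                      stringsAsFactors = FALSE))
  }
  agg <- if (rule == "either") {
    tapply(scores$tier, scores$gene, min)
  } else {
    tapply(scores$tier, scores$gene, max)
  }
  data.frame(gene = names(agg), tier = as.integer(agg),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Hypergeometric geneset enrichment
#'
#' One-sided upper-tail hypergeometric test of the overlap between a
#' selected gene list and a geneset within a background universe of
#' `background_n` genes.
#'
#' @param selected_genes character vector (subset of the universe).
#' @param geneset character vector (subset of the universe; non-empty).
#' @param background_n size of the gene universe.
#' @return list: `overlap`, `expected`, `p`.
#' @export
geneset_enrichment <- function(selected_genes, geneset, background_n) {
  if (!length(geneset)) stop("geneset is empty", call. = FALSE)
  selected_genes <- unique(selected_genes)
  geneset <- unique(geneset)
  if (length(selected_genes) > background_n || length(geneset) > background_n) {
    stop("selection/geneset larger than the background universe", call. = FALSE)
  }
  overlap <- length(intersect(selected_genes, geneset))
  expected <- length(selected_genes) * length(geneset) / background_n
  p <- stats::phyper(overlap - 1, length(geneset),
                     background_n - length(geneset),
                     length(selected_genes), lower.tail = FALSE)
  list(overlap = overlap, expected = expected, p = p)
}

#' Write gene scores
#' @param scores data frame from [score_genes()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_scores <- function(scores, path) {
  out <- data.frame(GENE = scores$gene, TRACK = scores$track,
                    SCORE = scores$score, TIER = scores$tier,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
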