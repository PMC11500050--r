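# FUMA-style locus definition from meta-analysis output plus LD:
# independent significant SNPs (is-SNPs: p < 5e-8, mutual r2 < 0.6),
# candidate SNPs (r2 >= 0.6 with an is-SNP), independent lead SNPs
# (is-SNPs with mutual r2 < 0.1) and genomic risk loci merged within a
# 250-kb window.

# r2 lookup with an informative error naming the missing pair
.ld_lookup <- function(ld, a, b) {
  if (!(a %in% rownames(ld)) || !(b %in% rownames(ld))) {
    stop(sprintf("missing LD entry for pair (%s, %s)", a, b), call. = FALSE)
  }
  ld[a, b]
}

# deterministic analysis order: ascending p, ties broken by (chrom, pos)
.p_order <- function(results) {
  order(results$p_meta %||% results$p, results$chrom, results$pos)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# p column accessor: meta results carry p_meta, plain sumstats carry p
.pcol <- function(results) results$p_meta %||% results$p

#' Greedy selection of independent significant SNPs
#'
#' Scans genome-wide-significant variants in ascending p order (ties by
#' chromosome, position) and keeps a SNP iff its r-squared with every
#' already-kept SNP is below `r2_indep`.
#'
#' @param results data frame with columns `id, chrom, pos` and `p` (or
#'   `p_meta`), e.g. [run_meta_table()] output.
#' @param ld symmetric r-squared matrix keyed by variant ID; must cover
#'   all significant variants.
#' @param p_thresh genome-wide significance threshold.
#' @param r2_indep mutual-independence r-squared threshold.
#' @return character vector of is-SNP IDs (in selection order).
#' @export
find_is_snps <- function(results, ld, p_thresh = 5e-8, r2_indep = 0.6) {
  p <- .pcol(results)
  sig <- results[!is.na(p) & p < p_thresh, , drop = FALSE]
  sig <- sig[order(.pcol(sig), sig$chrom, sig$pos), , drop = FALSE]
  kept <- character(0)
  for (id in sig$id) {
    ok <- TRUE
    for (k in kept) {
      if (.ld_lookup(ld, id, k) >= r2_indep) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, id)
  }
  kept
}

#' Candidate SNPs in LD with independent significant SNPs
#'
#' Every SNP (regardless of p-value) with `r2 >= r2_cand` to at least one
#' is-SNP is a candidate; is-SNPs are their own candidates (r2 = 1 with
#' themselves).
#'
#' @param is_snps character vector from [find_is_snps()].
#' @param all_results data frame of all tested variants (`id` column).
#' @param ld r-squared matrix covering all variants.
#' @param r2_cand inclusion threshold (boundary inclusive).
#' @return character vector of candidate SNP IDs.
#' @export
find_candidate_snps <- function(is_snps, all_results, ld, r2_cand = 0.6) {
  if (!length(is_snps)) return(character(0))
  ids <- all_results$id
  missing <- setdiff(c(ids, is_snps), rownames(ld))
  if (length(missing)) {
    stop("missing LD entries for: ", paste(utils::head(missing), collapse = ", "),
         call. = FALSE)
  }
  sub <- ld[ids, is_snps, drop = FALSE]
  cand <- ids[apply(sub, 1, max) >= r2_cand]
  union(cand, is_snps)
}

#' Independent lead SNPs among the is-SNPs
#'
#' Same greedy rule as [find_is_snps()] restricted to the is-SNP set with
#' the tighter `r2_lead` threshold.
#'
#' @param is_snps character vector from [find_is_snps()].
#' @param results data frame with `id, chrom, pos` and p column (for the
#'   greedy ordering).
#' @param ld r-squared matrix.
#' @param r2_lead mutual-independence threshold for leads.
#' @return character vector of lead SNP IDs.
#' @export
find_lead_snps <- function(is_snps, results, ld, r2_lead = 0.1) {
  sub <- results[results$id %in% is_snps, , drop = FALSE]
  find_is_snps(sub, ld, p_thresh = Inf, r2_indep = r2_lead)
}

#' Merge lead-SNP intervals into genomic risk loci
#'
#' Each is-SNP is assigned to its highest-r2 lead, each candidate SNP to
#' its highest-r2 is-SNP; a lead's interval spans the positions of the
#' lead, its is-SNPs and their candidates.  Same-chromosome intervals are
#' merged transitively whenever the gap between interval boundaries is at
#' most `merge_window` base pairs.  Coordinates are 1-based and closed in
#' the returned table.
#'
#' @param leads,is_snps,candidates ID vectors from the selection steps.
#' @param results data frame with `id, chrom, pos` covering all
#'   candidates.
#' @param ld r-squared matrix.
#' @param merge_window maximum inter-interval gap merged, in bp.
#' @return data frame of class `kc_loci`: `locus_id, chrom, start, end,
#'   n_leads, n_is, n_cand` plus list columns `lead_snps,
#'   is_snps, candidate_snps`, sorted by (chrom, start).
#' @export
merge_risk_loci <- function(leads, is_snps, candidates, results, ld,
                            merge_window = 250000) {
  if (!length(leads)) {
    return(structure(data.frame(), class = c("kc_loci", "data.frame")))
  }
  pos <- stats::setNames(results$pos, results$id)
  chrom <- stats::setNames(as.character(results$chrom), results$id)
  # assign each is-SNP to the lead with maximal r2 (leads map to themselves)
  assign_max <- function(ids, targets) {
    vapply(ids, function(id) {
      targets[which.max(ld[id, targets])]
    }, character(1))
  }
  is_lead <- assign_max(is_snps, leads)
  cand_is <- assign_max(setdiff(candidates, is_snps), is_snps)
  cand_lead <- c(stats::setNames(is_lead, is_snps),
                 stats::setNames(is_lead[cand_is], names(cand_is)))
  members <- split(names(cand_lead), cand_lead)
  intervals <- do.call(rbind, lapply(leads, function(l) {
    mem <- unique(c(l, members[[l]]))
    data.frame(lead = l, chrom = chrom[l],
               start = min(pos[mem]), end = max(pos[mem]),
               stringsAsFactors = FALSE)
  }))
  intervals <- intervals[order(intervals$chrom, intervals$start,
                               intervals$end), , drop = FALSE]
  # sweep-merge within chromosome: gap between boundaries <= merge_window
  groups <- integer(nrow(intervals))
  g <- 0L
  cur_end <- -Inf; cur_chrom <- ""
  for (i in seq_len(nrow(intervals))) {
    if (intervals$chrom[i] != cur_chrom ||
        intervals$start[i] - cur_end > merge_window) {
      g <- g + 1L
      cur_chrom <- intervals$chrom[i]
      cur_end <- intervals$end[i]
    } else {
      cur_end <- max(cur_end, intervals$end[i])
    }
    groups[i] <- g
  }
  loci <- lapply(split(seq_len(nrow(intervals)), groups), function(idx) {
    ls <- intervals$lead[idx]
    mem <- unique(unlist(c(ls, members[ls])))
    iss <- intersect(is_snps, mem)
    data.frame(chrom = intervals$chrom[idx[1]],
               start = min(intervals$start[idx]),
               end = max(intervals$end[idx]),
               n_leads = length(ls), n_is = length(iss),
               n_cand = length(mem),
               lead_snps = I(list(ls)), is_snps = I(list(iss)),
               candidate_snps = I(list(mem)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, loci)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  out <- cbind(locus_id = paste0("locus_", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("kc_loci", "data.frame")
  out
}

#' Run the full locus-definition stage
#'
#' Convenience wrapper chaining [find_is_snps()], [find_candidate_snps()],
#' [find_lead_snps()] and [merge_risk_loci()].
#'
#' @param results meta-analysis (or association) results data frame.
#' @param ld r-squared matrix.
#' @param p_thresh,r2_indep,r2_cand,r2_lead,merge_window stage thresholds.
#' @return list with `is_snps, candidates, leads, loci`.
#' @export
define_risk_loci <- function(results, ld, p_thresh = 5e-8, r2_indep = 0.6,
                             r2_cand = 0.6, r2_lead = 0.1,
                             merge_window = 250000) {
  is_snps <- find_is_snps(results, ld, p_thresh, r2_indep)
  candidates <- find_candidate_snps(is_snps, results, ld, r2_cand)
  leads <- find_lead_snps(is_snps, results, ld, r2_lead)
  loci <- merge_risk_loci(leads, is_snps, candidates, results, ld,
                          merge_window)
  list(is_snps = is_snps, candidates = candidates, leads = leads, loci = loci)
}

#' Write risk loci as a BED-like table
#'
#' On-disk convention is 0-based half-open (BED); in-memory loci are
#' 1-based closed.
#'
#' @param loci `kc_loci` data frame from [merge_risk_loci()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_loci_bed <- function(loci, path) {
  out <- data.frame(CHROM = loci$chrom, START = loci$start - 1L,
                    END = loci$end, LOCUS_ID = loci$locus_id,
                    N_LEADS = loci$n_leads, N_IS = loci$n_is,
                    N_CAND = loci$n_cand, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Empirical r-squared LD matrix from dosages
#'
#' Squared Pearson correlation between dosage columns, keyed by variant
#' ID; monomorphic variants get r2 = 0 off-diagonal.
#'
#' @param ds [genotype_dataset()].
#' @return symmetric r-squared matrix.
#' @export
ld_from_dosages <- function(ds) {
  G <- impute_mean(ds$dosages)
  r <- suppressWarnings(stats::cor(G))
  r[is.na(r)] <- 0
  m <- r^2
  diag(m) <- 1
  dimnames(m) <- list(ds$variants$id, ds$variants$id)
  m
}
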