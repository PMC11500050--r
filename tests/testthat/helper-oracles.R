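# Independent oracles used to cross-check the package implementations.
# These are deliberately written as straight-line/naive code paths.

# naive-loop fixed-effects meta: plain accumulators, no vectorization
oracle_meta <- function(beta, se) {
  sw <- 0; swb <- 0
  for (i in seq_along(beta)) {
    w <- 1 / (se[i] * se[i])
    sw <- sw + w
    swb <- swb + w * beta[i]
  }
  bm <- swb / sw
  q <- 0
  for (i in seq_along(beta)) q <- q + (beta[i] - bm)^2 / (se[i] * se[i])
  k <- length(beta)
  list(beta_meta = bm, se_meta = sqrt(1 / sw),
       p_meta = 2 * pnorm(-abs(bm / sqrt(1 / sw))),
       q_stat = q,
       q_p = pchisq(q, k - 1, lower.tail = FALSE),
       i2 = if (q <= 0) 0 else max(0, 100 * (q - (k - 1)) / q))
}

# exact HWE p computed through binomial coefficients (different route
# from the package's factorial-based implementation)
oracle_hwe_choose <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  na <- 2 * n_aa + n_ab
  hs <- seq(na %% 2, min(na, 2 * n - na), 2)
  pr <- sapply(hs, function(h) {
    a <- (na - h) / 2
    exp(lchoose(n, a) + lchoose(n - a, h) + h * log(2) - lchoose(2 * n, na))
  })
  po <- pr[hs == n_ab]
  min(1, sum(pr[pr <= po * (1 + 1e-12)]))
}

# Monte-Carlo null distribution of heterozygote counts by random pairing
# of the allele pool (the physical model behind the exact test)
oracle_hwe_pairing <- function(n_aa, n_ab, n_bb, B = 20000) {
  n <- n_aa + n_ab + n_bb
  na <- 2 * n_aa + n_ab
  pool <- c(rep(1L, na), rep(0L, 2 * n - na))
  hets <- replicate(B, {
    s <- sample(pool)
    sum(s[seq(1, 2 * n, 2)] != s[seq(2, 2 * n, 2)])
  })
  table(factor(hets, levels = seq(na %% 2, min(na, 2 * n - na), 2))) / B
}

# brute-force verification that a greedy clump/selection result is valid:
# all kept pairs below threshold, every dropped significant SNP blocked
# by an earlier-ordered kept SNP
oracle_check_greedy <- function(kept, results, ld, p_thresh, r2_thr) {
  p <- if (!is.null(results$p_meta)) results$p_meta else results$p
  ord <- order(p, results$chrom, results$pos)
  sig <- results$id[ord][p[ord] < p_thresh]
  for (i in seq_along(kept)) {
    for (j in seq_len(i - 1)) {
      if (ld[kept[i], kept[j]] >= r2_thr) return(FALSE)
    }
  }
  for (id in setdiff(sig, kept)) {
    pos_id <- match(id, sig)
    blockers <- kept[match(kept, sig) < pos_id]
    if (!any(ld[id, blockers] >= r2_thr)) return(FALSE)
  }
  setequal(union(kept, setdiff(sig, kept)), sig)
}

# brute-force candidate set: double loop over (snp, is-snp) pairs
oracle_candidates <- function(is_snps, all_ids, ld, r2_cand) {
  out <- character(0)
  for (id in all_ids) {
    for (s in is_snps) {
      if (ld[id, s] >= r2_cand) { out <- c(out, id); break }
    }
  }
  union(out, is_snps)
}

# union-find transitive closure over intervals within merge_window
oracle_merge <- function(intervals, merge_window) {
  n <- nrow(intervals)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (intervals$chrom[i] != intervals$chrom[j]) next
      gap <- max(intervals$start[i], intervals$start[j]) -
        min(intervals$end[i], intervals$end[j])
      if (gap <= merge_window) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  merged <- lapply(split(seq_len(n), roots), function(idx) {
    data.frame(chrom = intervals$chrom[idx[1]],
               start = min(intervals$start[idx]),
               end = max(intervals$end[idx]))
  })
  out <- do.call(rbind, merged)
  out[order(out$chrom, out$start), , drop = FALSE]
}

# straight-line lookup implementation of the tier ledger
oracle_score_coding <- function(pli, cadd, consequence_class) {
  s <- 0
  if (!is.na(pli) && pli >= 0.9) s <- s + 1
  if (!is.na(cadd)) {
    if (cadd >= 20) s <- s + 2 else if (cadd >= 10) s <- s + 1
  }
  if (consequence_class == "nonsynonymous_or_frameshift") s <- s + 2 else s <- s + 1
  tier <- if (s == 4 || s == 5) 1 else if (s == 2 || s == 3) 2 else 3
  list(score = s, tier = tier)
}

oracle_score_noncoding <- function(pli, cadd, ncrvis, protein_coding, eqtl,
                                   rdb, ci_mapped) {
  s <- 0
  if (!is.na(pli) && pli >= 0.9) s <- s + 1
  if (!is.na(cadd)) {
    if (cadd >= 20) s <- s + 2 else if (cadd >= 10) s <- s + 1
  }
  if (!is.na(ncrvis) && ncrvis < 0) s <- s + 1
  if (isTRUE(protein_coding)) s <- s + 1
  if (isTRUE(eqtl)) s <- s + 1
  if (!is.na(rdb)) {
    d <- substr(rdb, 1, 1)
    if (d == "1" || d == "2") s <- s + 2
    if (d == "3" || d == "4") s <- s + 1
  }
  if (isTRUE(ci_mapped)) s <- s + 1
  tier <- if (s >= 6) 1 else if (s >= 3) 2 else 3
  list(score = s, tier = tier)
}

# per-gene group-by aggregation with explicit loops
oracle_aggregate <- function(ann) {
  out <- list()
  for (g in unique(ann$gene)) {
    for (tr in c("coding", "noncoding")) {
      rows <- ann[ann$gene == g & (ann$is_coding == (tr == "coding")), ,
                  drop = FALSE]
      if (!nrow(rows)) next
      out[[paste(g, tr)]] <- list(
        gene = g, track = tr,
        pli = suppressWarnings(max(rows$pli, na.rm = TRUE)),
        best_cadd = suppressWarnings(max(rows$cadd, na.rm = TRUE)),
        ncrvis = suppressWarnings(min(rows$ncrvis, na.rm = TRUE)),
        protein_coding = any(rows$protein_coding),
        eqtl = any(rows$eqtl),
        best_rdb = {
          d <- suppressWarnings(as.integer(substr(rows$rdb, 1, 1)))
          if (all(is.na(d))) NA_character_ else as.character(min(d, na.rm = TRUE))
        },
        ci_mapped = any(rows$ci_mapped),
        consequence_class = if (tr == "coding") {
          if (any(rows$consequence %in% c("nonsynonymous", "frameshift")))
            "nonsynonymous_or_frameshift" else "synonymous_or_inframe"
        } else NA_character_)
    }
  }
  out
}

# naive per-sample weighted score
oracle_score_individuals <- function(dosages, weights) {
  out <- numeric(nrow(dosages))
  for (s in seq_len(nrow(dosages))) {
    acc <- 0
    for (id in names(weights)) acc <- acc + weights[[id]] * dosages[s, id]
    out[s] <- acc
  }
  out
}

# AUC by exhaustive case/control pair enumeration
oracle_auc_pairs <- function(scores, phenotype) {
  cases <- scores[phenotype == 1]
  controls <- scores[phenotype == 0]
  tot <- 0
  for (a in cases) for (b in controls) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(cases) * length(controls))
}

# nested-loop drug-target join
oracle_drug_join <- function(tiers, drugs, keep_tiers, statuses) {
  hits <- list()
  seen <- character(0)
  for (i in seq_len(nrow(drugs))) {
    for (j in seq_len(nrow(tiers))) {
      if (drugs$target[i] == tiers$gene[j] && tiers$tier[j] %in% keep_tiers &&
          drugs$status[i] %in% statuses) {
        key <- paste(drugs$drug[i], drugs$target[i])
        if (!(key %in% seen)) {
          seen <- c(seen, key)
          hits[[key]] <- drugs[i, ]
        }
      }
    }
  }
  length(hits)
}
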