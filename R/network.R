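# Protein-interaction edge-count enrichment (permutation null) and the
# drug-target repositioning join.

#' Build an interaction network from an edge list
#'
#' Undirected simple graph over gene IDs: self-loops and duplicate edges
#' are removed (with a warning when present).
#'
#' @param edges two-column data frame or matrix of gene-ID pairs.
#' @return \pkg{igraph} graph object.
#' @export
interaction_network <- function(edges) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges[, 1:2], directed = FALSE)
  simple <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  if (igraph::ecount(simple) != igraph::ecount(g)) {
    warning("self-loops/duplicate edges removed from the network", call. = FALSE)
  }
  simple
}

#' Read a network edge list
#'
#' Two-column TSV `GENE_A GENE_B`, one undirected edge per row.
#'
#' @param path input file.
#' @return \pkg{igraph} graph.
#' @export
read_edge_list <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE)
  .stop_missing_cols(names(raw), c("GENE_A", "GENE_B"), "edge list")
  interaction_network(raw[, c("GENE_A", "GENE_B")])
}

#' Permutation edge-count enrichment of a geneset
#'
#' Counts edges in the subgraph induced by `genes` and compares against a
#' null of `B` equal-size node sets.  The default null resamples nodes
#' uniformly from the network's node universe (a simplification of
#' database-style background models); `method = "degree"` resamples
#' within degree quintiles to preserve the geneset's degree profile.
#' Genes absent from the network are tolerated as isolated nodes (they
#' contribute no edges but count toward the set size).
#'
#' @param genes character vector of gene IDs.
#' @param network \pkg{igraph} graph from [interaction_network()].
#' @param B number of null draws (>= 1).
#' @param seed optional RNG seed.
#' @param method `"uniform"` or `"degree"` (degree-stratified) null.
#' @return list: `observed_edges`, `expected_edges` (null mean), `p`
#'   (`(1 + #{null >= observed}) / (B + 1)`), `B`.
#' @export
edge_enrichment <- function(genes, network, B = 10000, seed = NULL,
                            method = c("uniform", "degree")) {
  method <- match.arg(method)
  if (B < 1) stop("B must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  genes <- unique(genes)
  nodes <- igraph::V(network)$name
  if (length(genes) > length(nodes)) {
    stop("geneset larger than the network's node universe", call. = FALSE)
  }
  el <- igraph::as_edgelist(network, names = TRUE)
  count_edges <- function(set) {
    memb <- nodes %in% set
    names(memb) <- nodes
    sum(memb[el[, 1]] & memb[el[, 2]])
  }
  observed <- count_edges(genes)
  m <- length(genes)
  if (method == "uniform") {
    null_draw <- function() sample(nodes, m)
  } else {
    deg <- igraph::degree(network)
    qs <- unique(stats::quantile(deg, probs = seq(0, 1, 0.2)))
    bins <- cut(deg, breaks = qs, include.lowest = TRUE)
    present <- intersect(genes, nodes)
    gene_bins <- bins[match(present, nodes)]
    n_outside <- m - length(present)
    bin_counts <- table(gene_bins)
    null_draw <- function() {
      picks <- unlist(lapply(names(bin_counts), function(bn) {
        pool <- nodes[bins == bn]
        sample(pool, min(bin_counts[[bn]], length(pool)))
      }))
      extra <- setdiff(nodes, picks)
      c(picks, sample(extra, min(n_outside, length(extra))))
    }
  }
  null_edges <- vapply(seq_len(B), function(b) count_edges(null_draw()),
                       numeric(1))
  list(observed_edges = observed,
       expected_edges = mean(null_edges),
       p = (1 + sum(null_edges >= observed)) / (B + 1),
       B = B)
}

#' Drug-target repositioning join
#'
#' Joins the prioritized genes (restricted to the requested tiers,
#' default tiers 1 and 2) against a drug-target table, deduplicated by
#' (drug, gene).  Counts are reported for all statuses and for the
#' status-filtered subset.
#'
#' @param genes_with_tiers data frame `gene, tier` (see [gene_tiers()]).
#' @param drugs drug table (see [read_drug_table()]).
#' @param tiers tiers considered as targets.
#' @param status_filter statuses retained in the filtered hit list.
#' @return list of class `kc_drug_hits`: `hits` (filtered; columns
#'   `drug, status, target, gene_tier`), `all_hits` (unfiltered),
#'   `counts_by_status`, `n_drugs_all`, `n_drugs_filtered`.
#' @export
drug_reposition <- function(genes_with_tiers, drugs, tiers = c(1, 2),
                            status_filter = "approved") {
  sel <- genes_with_tiers[genes_with_tiers$tier %in% tiers, , drop = FALSE]
  idx <- match(drugs$target, sel$gene)
  all_hits <- drugs[!is.na(idx), , drop = FALSE]
  all_hits$gene_tier <- sel$tier[idx[!is.na(idx)]]
  all_hits <- all_hits[!duplicated(all_hits[, c("drug", "target")]), ,
                       drop = FALSE]
  rownames(all_hits) <- NULL
  hits <- all_hits[all_hits$status %in% status_filter, , drop = FALSE]
  rownames(hits) <- NULL
  counts <- table(factor(all_hits$status, levels = .VALID_STATUS))
  structure(list(hits = hits, all_hits = all_hits,
                 counts_by_status = counts,
                 n_drugs_all = length(unique(all_hits$drug)),
                 n_drugs_filtered = length(unique(hits$drug))),
            class = "kc_drug_hits")
}

#' @export
print.kc_drug_hits <- function(x, ...) {
  cat(sprintf("<kc_drug_hits> %d drugs target prioritized genes (%d after status filter)\n",
              x$n_drugs_all, x$n_drugs_filtered))
  invisible(x)
}

#' Write drug hits
#' @param x `kc_drug_hits` from [drug_reposition()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_drug_hits <- function(x, path) {
  out <- data.frame(DRUG = x$hits$drug, STATUS = x$hits$status,
                    TARGET = x$hits$target, ACTION = x$hits$action,
                    GENE_TIER = x$hits$gene_tier, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
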