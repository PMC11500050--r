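# Pipeline orchestration: a fixed stage order (assoc -> meta -> locus ->
# prs -> prioritize -> drugs) driven by a config list or YAML file, with
# intermediate files in the package's dialects as the interface between
# stages and a run manifest (versions, seed, row counts, checksums) for
# reproducibility.

.default_params <- function() {
  list(gw_threshold = 5e-8, nominal = 0.05,
       r2_indep = 0.6, r2_cand = 0.6, r2_lead = 0.1, merge_window = 250000,
       clump_window_kb = 250, clump_r2 = 0.1,
       grid = prs_default_grid(), permutations = 0,
       n_pcs = 0, firth_fallback = TRUE,
       tier_rule = "either", status_filter = "approved",
       enrichment_B = 1000)
}

#' Validate a pipeline configuration
#'
#' A config is a list with elements `out_dir`, `stages` (subset of
#' assoc, meta, locus, prs, prioritize, drugs), `seed`, `inputs` (named
#' paths) and `params` (threshold overrides; see the pipeline
#' documentation).  Referenced input files must exist.
#'
#' @param config list, or path to a YAML file encoding one.
#' @return normalized config list.
#' @export
pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$out_dir)) stop("config needs out_dir", call. = FALSE)
  config$stages <- config$stages %||% character(0)
  valid_stages <- c("assoc", "meta", "locus", "prs", "prioritize", "drugs")
  bad <- setdiff(config$stages, valid_stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  config$seed <- config$seed %||% 1L
  config$inputs <- config$inputs %||% list()
  for (nm in names(config$inputs)) {
    if (!file.exists(config$inputs[[nm]])) {
      stop(sprintf("input '%s' not found: %s", nm, config$inputs[[nm]]),
           call. = FALSE)
    }
  }
  params <- .default_params()
  for (nm in names(config$params %||% list())) params[[nm]] <- config$params[[nm]]
  config$params <- params
  config
}

.stage_fail <- function(stage, e) {
  stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
       call. = FALSE)
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in the fixed order assoc, meta, locus,
#' prs, prioritize, drugs.  Any prefix (or subset whose inputs are
#' available as files) is runnable: every stage reads its inputs from
#' disk and writes its outputs into `out_dir`, so a later run can resume
#' from intermediate files.  An empty stage list writes the manifest
#' only.  Identical config and seed give identical output checksums.
#'
#' Expected inputs per stage: assoc needs `dosages` + `phenotype`
#' (optional `covariates`); meta needs `sumstats_b` plus either the
#' assoc output or `sumstats_a` (alternatively `sumstats_wide` for a
#' printed two-study OR/CI table); locus needs the meta output and `ld`;
#' prs needs `sumstats_b` (base), `dosages`, `phenotype`, `ld`;
#' prioritize needs `annotation` (and uses locus candidates when that
#' stage ran); drugs needs `drugs` and the prioritize output, plus an
#' optional `network` edge list for the interaction enrichment.
#'
#' @param config list or YAML path (see [pipeline_config()]).
#' @return run manifest (list), invisibly written to
#'   `out_dir/manifest.json`.
#' @export
run_pipeline <- function(config) {
  cfg <- pipeline_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  par <- cfg$params
  inp <- cfg$inputs
  outputs <- character(0)
  counts <- list()
  path_out <- function(name) file.path(cfg$out_dir, name)

  load_target <- function() {
    ds <- read_genotypes(inp$dosages, format = "dosage_tsv")
    ph <- read_phenotypes(inp$phenotype)
    ds$phenotype <- unname(ph[ds$sample_ids])
    if (!is.null(inp$covariates)) {
      cov <- read_covariates(inp$covariates)
      ds$covariates <- cov[ds$sample_ids, , drop = FALSE]
    }
    ds
  }

  if ("assoc" %in% cfg$stages) {
    tryCatch({
      ds <- load_target()
      qc <- qc_filter(ds)
      covm <- qc$dataset$covariates
      if (par$n_pcs > 0) {
        pcs <- compute_pcs(qc$dataset, k = par$n_pcs)
        covm <- if (is.null(covm)) pcs else cbind(covm, pcs)
      }
      res <- logistic_assoc(qc$dataset, covariates = covm,
                            firth_fallback = par$firth_fallback)
      ss <- assoc_to_sumstats(res, qc$dataset)
      write_sumstats(ss, path_out("sumstats_a.tsv"))
      outputs <- c(outputs, path_out("sumstats_a.tsv"))
      counts$assoc <- nrow(ss)
    }, error = function(e) .stage_fail("assoc", e))
  }

  if ("meta" %in% cfg$stages) {
    tryCatch({
      if (!is.null(inp$sumstats_wide)) {
        wide <- utils::read.delim(inp$sumstats_wide, stringsAsFactors = FALSE)
        x <- data.frame(id = wide$ID, chrom = as.character(wide$CHR),
                        pos = wide$POS, p_a = wide$P_A, or_a = wide$OR_A,
                        l95_a = wide$L95_A, u95_a = wide$U95_A,
                        p_b = wide$P_B, or_b = wide$OR_B, l95_b = wide$L95_B,
                        u95_b = wide$U95_B, stringsAsFactors = FALSE)
        if (!is.null(wide$P_META)) x$p_meta_printed <- wide$P_META
        res <- meta_from_wide(x, par$gw_threshold, par$nominal)
        utils::write.table(res, path_out("meta_results.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
      } else {
        a_path <- inp$sumstats_a %||% path_out("sumstats_a.tsv")
        study_a <- read_sumstats(a_path)
        study_b <- read_sumstats(inp$sumstats_b)
        res <- run_meta_table(study_a, study_b, par$gw_threshold, par$nominal)
        write_meta_results(res, path_out("meta_results.tsv"))
      }
      outputs <- c(outputs, path_out("meta_results.tsv"))
      counts$meta <- nrow(res)
      counts$meta_classification <- as.list(table(res$classification))
    }, error = function(e) .stage_fail("meta", e))
  }

  if ("locus" %in% cfg$stages) {
    tryCatch({
      meta <- utils::read.delim(path_out("meta_results.tsv"),
                                stringsAsFactors = FALSE)
      res <- data.frame(id = meta$ID, chrom = as.character(meta$CHR),
                        pos = meta$POS, p = as.numeric(meta$P),
                        stringsAsFactors = FALSE)
      ld <- read_ld_matrix(inp$ld)
      loci <- define_risk_loci(res, ld, par$gw_threshold, par$r2_indep,
                               par$r2_cand, par$r2_lead, par$merge_window)
      write_loci_bed(loci$loci, path_out("risk_loci.tsv"))
      writeLines(loci$candidates, path_out("candidate_snps.txt"))
      outputs <- c(outputs, path_out("risk_loci.tsv"),
                   path_out("candidate_snps.txt"))
      counts$locus <- list(is_snps = length(loci$is_snps),
                           leads = length(loci$leads),
                           candidates = length(loci$candidates),
                           loci = nrow(loci$loci))
    }, error = function(e) .stage_fail("locus", e))
  }

  if ("prs" %in% cfg$stages) {
    tryCatch({
      base <- read_sumstats(inp$sumstats_b)
      target <- load_target()
      ld <- read_ld_matrix(inp$ld)
      kept <- clump(base, ld, par$clump_window_kb, par$clump_r2)
      base_c <- base[base$id %in% kept, , drop = FALSE]
      model <- threshold_search(base_c, target, target$covariates,
                                grid = par$grid)
      ev <- prs_evaluate(score_individuals(target, model$snp_weights),
                         target$phenotype)
      eval_out <- list(auc = ev$auc, auc_ci = unname(ev$auc_ci),
                       case_mean = ev$case_mean,
                       control_mean = ev$control_mean,
                       t_stat = ev$t_stat, t_p = ev$t_p,
                       best_threshold = model$best_threshold,
                       best_n_snps = model$best_n_snps,
                       best_fit_r2 = model$best_fit_r2)
      if (par$permutations > 0) {
        pp <- permutation_p(base_c, target, target$covariates, par$grid,
                            B = par$permutations, seed = cfg$seed,
                            model = model)
        eval_out$perm_p <- pp$perm_p
        eval_out$n_permutations <- pp$B
      }
      utils::write.table(model$table, path_out("prs_thresholds.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(data.frame(ID = names(model$snp_weights),
                                    BETA = .fmt_num(model$snp_weights)),
                         path_out("prs_weights.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      jsonlite::write_json(eval_out, path_out("prs_evaluation.json"),
                           auto_unbox = TRUE, digits = NA)
      outputs <- c(outputs, path_out("prs_thresholds.tsv"),
                   path_out("prs_weights.tsv"), path_out("prs_evaluation.json"))
      counts$prs <- list(best_n_snps = model$best_n_snps)
    }, error = function(e) .stage_fail("prs", e))
  }

  if ("prioritize" %in% cfg$stages) {
    tryCatch({
      ann <- read_annotation_table(inp$annotation)
      cand <- if (file.exists(path_out("candidate_snps.txt"))) {
        readLines(path_out("candidate_snps.txt"))
      } else NULL
      ev <- aggregate_evidence(ann, cand)
      sc <- score_genes(ev)
      tiers <- gene_tiers(sc, rule = par$tier_rule)
      write_gene_scores(sc, path_out("gene_scores.tsv"))
      utils::write.table(data.frame(GENE = tiers$gene, TIER = tiers$tier),
                         path_out("gene_tiers.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      outputs <- c(outputs, path_out("gene_scores.tsv"),
                   path_out("gene_tiers.tsv"))
      counts$prioritize <- as.list(table(tiers$tier))
    }, error = function(e) .stage_fail("prioritize", e))
  }

  if ("drugs" %in% cfg$stages) {
    tryCatch({
      drugs <- read_drug_table(inp$drugs)
      tiers <- utils::read.delim(path_out("gene_tiers.tsv"),
                                 stringsAsFactors = FALSE)
      names(tiers) <- tolower(names(tiers))
      hits <- drug_reposition(tiers, drugs,
                              status_filter = par$status_filter)
      write_drug_hits(hits, path_out("drug_hits.tsv"))
      outputs <- c(outputs, path_out("drug_hits.tsv"))
      counts$drugs <- list(all = hits$n_drugs_all,
                           filtered = hits$n_drugs_filtered)
      if (!is.null(inp$network)) {
        net <- read_edge_list(inp$network)
        sel <- tiers$gene[tiers$tier %in% c(1, 2)]
        enr <- edge_enrichment(intersect(sel, igraph::V(net)$name), net,
                               B = par$enrichment_B, seed = cfg$seed)
        jsonlite::write_json(enr, path_out("network_enrichment.json"),
                             auto_unbox = TRUE, digits = NA)
        outputs <- c(outputs, path_out("network_enrichment.json"))
      }
    }, error = function(e) .stage_fail("drugs", e))
  }

  manifest <- list(
    package = "kcmeta",
    version = as.character(utils::packageVersion("kcmeta")),
    seed = cfg$seed,
    stages = cfg$stages,
    counts = counts,
    checksums = as.list(tools::md5sum(outputs))
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
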