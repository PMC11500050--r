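# Readers/writers for every table the pipeline touches.  All on-disk
# formats are plain tab-separated text with a header; coordinates are
# 1-based GRCh38 positions in memory and in summary-statistics files
# (locus BED output is the one 0-based, half-open exception).

.VALID_ALLELES <- c("A", "C", "G", "T")
.VALID_RDB <- as.character(1:7)
.VALID_STATUS <- c("approved", "investigational", "withdrawn", "experimental")
.VALID_CONSEQUENCE <- c("synonymous", "nonsynonymous", "frameshift",
                        "inframe", "noncoding")

# full-precision numeric formatting so write -> read round trips are
# lossless to double precision
.fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "NA" else format(v, digits = 17, scientific = TRUE)
  }, character(1))
  out
}

.stop_missing_cols <- function(have, need, what) {
  missing <- setdiff(need, have)
  if (length(missing)) {
    stop(sprintf("%s: missing mandatory column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
}

#' Validate a summary-statistics data frame
#'
#' Checks the per-row invariants of the summary-statistics dialect:
#' alleles in A/C/G/T with effect != other, `se > 0`, `p` in (0, 1],
#' `pos >= 1`, and `eaf` in \[0, 1\] when present.
#'
#' @param x data frame with columns `chrom, pos, id, ea, oa, beta, se, p`
#'   and optionally `eaf`.
#' @return character vector, one element per row: `""` for valid rows,
#'   otherwise a semicolon-separated list of violated rules.
#' @export
validate_sumstats <- function(x) {
  n <- nrow(x)
  reasons <- rep("", n)
  add <- function(bad, msg) {
    bad[is.na(bad)] <- TRUE
    reasons[bad] <<- ifelse(nchar(reasons[bad]), paste0(reasons[bad], ";", msg), msg)
  }
  add(!(x$ea %in% .VALID_ALLELES), "bad_effect_allele")
  add(!(x$oa %in% .VALID_ALLELES), "bad_other_allele")
  add(x$ea == x$oa, "identical_alleles")
  add(!(x$se > 0), "nonpositive_se")
  add(!(x$p > 0 & x$p <= 1), "p_out_of_range")
  add(!(x$pos >= 1), "bad_position")
  if (!is.null(x$eaf)) {
    bad_eaf <- !is.na(x$eaf) & !(x$eaf >= 0 & x$eaf <= 1)
    reasons[bad_eaf] <- ifelse(nchar(reasons[bad_eaf]),
                               paste0(reasons[bad_eaf], ";eaf_out_of_range"),
                               "eaf_out_of_range")
  }
  reasons
}

#' Read GWAS summary statistics
#'
#' Reads the tab-separated summary-statistics dialect with header columns
#' `CHR POS ID EA OA P` plus either `BETA SE` or the odds-ratio trio
#' `OR OR_L95 OR_U95` (converted to log-odds scale via
#' [beta_se_from_or_ci()]), and optionally `EAF`.  Rows failing validation
#' (non-positive odds ratio or confidence bound, invalid alleles, bad p or
#' SE) are reported via a warning and returned in the `"rejected"`
#' attribute rather than silently dropped.
#'
#' @param path path to a TSV file with header.
#' @param level confidence level of the `OR_L95`/`OR_U95` interval.
#' @return data frame of class `kc_sumstats` with columns
#'   `chrom, pos, id, ea, oa, beta, se, p, eaf`; attribute `rejected` holds
#'   the invalid input rows with a `reason` column.
#' @export
read_sumstats <- function(path, level = 0.95) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  .stop_missing_cols(names(raw), c("CHR", "POS", "ID", "EA", "OA", "P"),
                     "summary statistics")
  has_beta <- all(c("BETA", "SE") %in% names(raw))
  has_or <- all(c("OR", "OR_L95", "OR_U95") %in% names(raw))
  if (!has_beta && !has_or) {
    stop("summary statistics: need columns BETA,SE or OR,OR_L95,OR_U95",
         call. = FALSE)
  }
  out <- data.frame(
    chrom = as.character(raw$CHR),
    pos = as.integer(raw$POS),
    id = as.character(raw$ID),
    ea = toupper(as.character(raw$EA)),
    oa = toupper(as.character(raw$OA)),
    beta = NA_real_, se = NA_real_,
    p = as.numeric(raw$P),
    eaf = if ("EAF" %in% names(raw)) as.numeric(raw$EAF) else NA_real_,
    stringsAsFactors = FALSE
  )
  conv_reason <- rep("", nrow(out))
  if (has_beta) {
    out$beta <- as.numeric(raw$BETA)
    out$se <- as.numeric(raw$SE)
  } else {
    orv <- as.numeric(raw$OR)
    lo <- as.numeric(raw$OR_L95)
    hi <- as.numeric(raw$OR_U95)
    for (i in seq_len(nrow(out))) {
      bs <- tryCatch(beta_se_from_or_ci(orv[i], lo[i], hi[i], level = level),
                     error = function(e) NULL)
      if (is.null(bs)) conv_reason[i] <- "invalid_or_ci" else {
        out$beta[i] <- bs[["beta"]]
        out$se[i] <- bs[["se"]]
      }
    }
  }
  reasons <- validate_sumstats(out)
  reasons <- ifelse(nchar(conv_reason),
                    ifelse(nchar(reasons), paste0(conv_reason, ";", reasons),
                           conv_reason),
                    reasons)
  bad <- nchar(reasons) > 0
  rejected <- cbind(raw[bad, , drop = FALSE], reason = reasons[bad])
  if (any(bad)) {
    warning(sprintf("%d row(s) failed validation and were set aside (see attr(x, 'rejected'))",
                    sum(bad)), call. = FALSE)
  }
  out <- out[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  class(out) <- c("kc_sumstats", "data.frame")
  out
}

#' Write GWAS summary statistics
#'
#' Writes the `BETA`/`SE` form of the summary-statistics dialect at full
#' double precision, so `read_sumstats(write_sumstats(x))` is lossless.
#'
#' @param x data frame with columns `chrom, pos, id, ea, oa, beta, se, p`
#'   and optionally `eaf`.
#' @param path output path.
#' @param extra optional data frame of extra columns (e.g. heterogeneity
#'   statistics) appended after the standard columns.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(x, path, extra = NULL) {
  out <- data.frame(
    CHR = x$chrom, POS = x$pos, ID = x$id, EA = x$ea, OA = x$oa,
    BETA = .fmt_num(x$beta), SE = .fmt_num(x$se), P = .fmt_num(x$p),
    EAF = .fmt_num(if (is.null(x$eaf)) rep(NA_real_, nrow(x)) else x$eaf),
    stringsAsFactors = FALSE, check.names = FALSE
  )
  if (!is.null(extra)) out <- cbind(out, extra)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a genotype dataset
#'
#' In-memory container for a dosage matrix with variant metadata and
#' optional phenotype/covariates.  Dosages are effect-allele counts in
#' \[0, 2\] (fractional imputed values allowed); missing dosages are kept
#' as `NA` with the per-variant missing fraction recorded, and are
#' mean-imputed only where a complete matrix is required (PCA, association,
#' scoring).
#'
#' @param dosages numeric matrix, samples x variants.
#' @param variants data frame with columns `chrom, pos, id, ea, oa`.
#' @param sample_ids character vector; defaults to rownames or S1..Sn.
#' @param phenotype optional binary vector (0 = control, 1 = case).
#' @param covariates optional numeric matrix (samples x covariates).
#' @return object of class `kc_genotypes`.
#' @export
genotype_dataset <- function(dosages, variants, sample_ids = NULL,
                             phenotype = NULL, covariates = NULL) {
  dosages <- as.matrix(dosages)
  if (nrow(variants) != ncol(dosages)) {
    stop("variants table and dosage matrix dimensions disagree", call. = FALSE)
  }
  if (is.null(sample_ids)) {
    sample_ids <- rownames(dosages)
    if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(dosages)))
  }
  if (length(sample_ids) != nrow(dosages)) {
    stop("sample_ids length and dosage matrix dimensions disagree", call. = FALSE)
  }
  rng <- range(dosages, na.rm = TRUE)
  if (rng[1] < -1e-9 || rng[2] > 2 + 1e-9) {
    stop("dosages must lie within [0, 2]", call. = FALSE)
  }
  if (!is.null(phenotype)) {
    if (length(phenotype) != nrow(dosages)) {
      stop("phenotype length and dosage matrix dimensions disagree", call. = FALSE)
    }
    if (!all(phenotype %in% c(0, 1, NA))) {
      stop("phenotype must be binary 0/1", call. = FALSE)
    }
  }
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != nrow(dosages)) {
      stop("covariate rows and dosage matrix dimensions disagree", call. = FALSE)
    }
  }
  rownames(dosages) <- sample_ids
  colnames(dosages) <- variants$id
  structure(list(
    dosages = dosages,
    variants = as.data.frame(variants, stringsAsFactors = FALSE),
    sample_ids = sample_ids,
    phenotype = phenotype,
    covariates = covariates,
    missing_rate = colMeans(is.na(dosages))
  ), class = "kc_genotypes")
}

#' @export
print.kc_genotypes <- function(x, ...) {
  cat(sprintf("<kc_genotypes> %d samples x %d variants", length(x$sample_ids),
              nrow(x$variants)))
  if (!is.null(x$phenotype)) {
    cat(sprintf("; %d cases / %d controls", sum(x$phenotype == 1, na.rm = TRUE),
                sum(x$phenotype == 0, na.rm = TRUE)))
  }
  cat("\n")
  invisible(x)
}

# mean-impute missing dosages per variant (common GWAS practice)
impute_mean <- function(dosages) {
  nas <- which(colSums(is.na(dosages)) > 0)
  for (j in nas) {
    v <- dosages[, j]
    m <- mean(v, na.rm = TRUE)
    if (is.nan(m)) m <- 0
    v[is.na(v)] <- m
    dosages[, j] <- v
  }
  dosages
}

#' Read genotypes from VCF or dosage TSV
#'
#' The VCF reader (a v4.2 subset via \pkg{vcfR}) uses the `DS` FORMAT field
#' when present, otherwise counts ALT alleles from diploid `GT` calls.
#' Multi-allelic records and non-diploid genotypes are rejected.  The
#' dosage TSV layout is one row per variant with columns
#' `CHR POS ID EA OA` followed by one column per sample holding
#' effect-allele dosages.
#'
#' @param path input file.
#' @param format `"vcf"` or `"dosage_tsv"`.
#' @return [genotype_dataset()] without phenotype/covariates.
#' @export
read_genotypes <- function(path, format = c("vcf", "dosage_tsv")) {
  format <- match.arg(format)
  if (format == "dosage_tsv") {
    raw <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
    .stop_missing_cols(names(raw), c("CHR", "POS", "ID", "EA", "OA"),
                       "dosage table")
    meta_cols <- c("CHR", "POS", "ID", "EA", "OA")
    samples <- setdiff(names(raw), meta_cols)
    if (!length(samples)) stop("dosage table has no sample columns", call. = FALSE)
    dos <- t(as.matrix(raw[, samples, drop = FALSE]))
    storage.mode(dos) <- "double"
    variants <- data.frame(chrom = as.character(raw$CHR), pos = as.integer(raw$POS),
                           id = as.character(raw$ID), ea = as.character(raw$EA),
                           oa = as.character(raw$OA), stringsAsFactors = FALSE)
    return(genotype_dataset(dos, variants, sample_ids = samples))
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix
  alt <- fix[, "ALT"]
  if (any(grepl(",", alt))) {
    stop("multi-allelic record(s) are not supported: ",
         paste(utils::head(fix[grepl(",", alt), "ID"]), collapse = ", "),
         call. = FALSE)
  }
  ids <- fix[, "ID"]
  noid <- is.na(ids) | ids == "."
  ids[noid] <- paste0(fix[noid, "CHROM"], ":", fix[noid, "POS"])
  variants <- data.frame(chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
                         id = ids, ea = fix[, "ALT"], oa = fix[, "REF"],
                         stringsAsFactors = FALSE)
  fmt_keys <- unique(unlist(strsplit(vcf@gt[, "FORMAT"], ":")))
  if ("DS" %in% fmt_keys) {
    ds <- vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE)
  } else if ("GT" %in% fmt_keys) {
    gt <- vcfR::extract.gt(vcf, element = "GT")
    parse_gt <- function(g) {
      if (is.na(g) || g %in% c(".", "./.", ".|.")) return(NA_real_)
      alleles <- strsplit(g, "[/|]")[[1]]
      if (length(alleles) != 2) stop("non-diploid genotype: ", g, call. = FALSE)
      if (any(alleles == ".")) return(NA_real_)
      sum(alleles == "1")
    }
    ds <- apply(gt, c(1, 2), parse_gt)
  } else {
    stop("VCF has neither GT nor DS per-sample fields", call. = FALSE)
  }
  genotype_dataset(t(ds), variants, sample_ids = colnames(ds))
}

#' Read a phenotype table
#'
#' TSV with columns `SAMPLE` and `PHENO` (0 = control, 1 = case).
#'
#' @param path input file.
#' @return named numeric vector of 0/1, names = sample IDs.
#' @export
read_phenotypes <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE)
  .stop_missing_cols(names(raw), c("SAMPLE", "PHENO"), "phenotype table")
  ph <- as.numeric(raw$PHENO)
  if (!all(ph %in% c(0, 1, NA))) stop("PHENO must be binary 0/1", call. = FALSE)
  stats::setNames(ph, raw$SAMPLE)
}

#' Read a covariate table
#'
#' TSV with a `SAMPLE` column followed by numeric covariate columns
#' (e.g. principal components).
#'
#' @param path input file.
#' @return numeric matrix with sample IDs as rownames.
#' @export
read_covariates <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE)
  .stop_missing_cols(names(raw), "SAMPLE", "covariate table")
  m <- as.matrix(raw[, setdiff(names(raw), "SAMPLE"), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- raw$SAMPLE
  m
}

#' Read a variant/gene annotation table
#'
#' TSV with columns `ID GENE IS_CODING CONSEQUENCE CADD PLI NCRVIS RDB EQTL
#' CI_MAPPED PROTEIN_CODING`, one row per (variant, gene) pair.  The
#' RegulomeDB category must be one of "1".."7" (sub-categories such as
#' "2b" are accepted and mapped by their leading digit) or NA; CADD must be
#' non-negative and pLI within \[0, 1\].
#'
#' @param path input file.
#' @return validated data frame of class `kc_annotation`.
#' @export
read_annotation_table <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  need <- c("ID", "GENE", "IS_CODING", "CONSEQUENCE", "CADD", "PLI", "NCRVIS",
            "RDB", "EQTL", "CI_MAPPED", "PROTEIN_CODING")
  .stop_missing_cols(names(raw), need, "annotation table")
  out <- data.frame(
    id = as.character(raw$ID), gene = as.character(raw$GENE),
    is_coding = as.logical(raw$IS_CODING),
    consequence = as.character(raw$CONSEQUENCE),
    cadd = as.numeric(raw$CADD), pli = as.numeric(raw$PLI),
    ncrvis = as.numeric(raw$NCRVIS), rdb = as.character(raw$RDB),
    eqtl = as.logical(raw$EQTL), ci_mapped = as.logical(raw$CI_MAPPED),
    protein_coding = as.logical(raw$PROTEIN_CODING),
    stringsAsFactors = FALSE
  )
  bad_cons <- !is.na(out$consequence) & !(out$consequence %in% .VALID_CONSEQUENCE)
  if (any(bad_cons)) {
    stop("annotation table: invalid consequence value(s): ",
         paste(unique(out$consequence[bad_cons]), collapse = ", "), call. = FALSE)
  }
  rdb_digit <- substr(out$rdb, 1, 1)
  bad_rdb <- !is.na(out$rdb) & !(rdb_digit %in% .VALID_RDB)
  if (any(bad_rdb)) {
    stop("annotation table: RDB category outside 1-7: ",
         paste(unique(out$rdb[bad_rdb]), collapse = ", "), call. = FALSE)
  }
  if (any(!is.na(out$cadd) & out$cadd < 0)) {
    stop("annotation table: CADD must be >= 0", call. = FALSE)
  }
  if (any(!is.na(out$pli) & (out$pli < 0 | out$pli > 1))) {
    stop("annotation table: pLI must lie in [0, 1]", call. = FALSE)
  }
  class(out) <- c("kc_annotation", "data.frame")
  out
}

#' Write an annotation table
#' @param x annotation data frame as returned by [read_annotation_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotation_table <- function(x, path) {
  out <- data.frame(ID = x$id, GENE = x$gene, IS_CODING = x$is_coding,
                    CONSEQUENCE = x$consequence, CADD = .fmt_num(x$cadd),
                    PLI = .fmt_num(x$pli), NCRVIS = .fmt_num(x$ncrvis),
                    RDB = x$rdb, EQTL = x$eqtl, CI_MAPPED = x$ci_mapped,
                    PROTEIN_CODING = x$protein_coding, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a drug-target table
#'
#' TSV with columns `DRUG STATUS TARGET ACTION`; `STATUS` must be one of
#' approved/investigational/withdrawn/experimental, and drug and target
#' must be non-empty.
#'
#' @param path input file.
#' @return data frame of class `kc_drugs` with columns
#'   `drug, status, target, action`.
#' @export
read_drug_table <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  .stop_missing_cols(names(raw), c("DRUG", "STATUS", "TARGET", "ACTION"),
                     "drug table")
  out <- data.frame(drug = as.character(raw$DRUG),
                    status = tolower(as.character(raw$STATUS)),
                    target = as.character(raw$TARGET),
                    action = as.character(raw$ACTION),
                    stringsAsFactors = FALSE)
  if (any(is.na(out$drug) | out$drug == "") || any(is.na(out$target) | out$target == "")) {
    stop("drug table: DRUG and TARGET must be non-empty", call. = FALSE)
  }
  bad <- !(out$status %in% .VALID_STATUS)
  if (any(bad)) {
    stop("drug table: invalid STATUS value(s): ",
         paste(unique(out$status[bad]), collapse = ", "), call. = FALSE)
  }
  class(out) <- c("kc_drugs", "data.frame")
  out
}

#' Write a drug-target table
#' @param x drug data frame as returned by [read_drug_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_drug_table <- function(x, path) {
  out <- data.frame(DRUG = x$drug, STATUS = x$status, TARGET = x$target,
                    ACTION = x$action, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an LD (r-squared) matrix
#'
#' TSV with variant IDs as both the first column and the header; values are
#' squared allelic correlations.  The matrix must be symmetric with a unit
#' diagonal within `tol`.
#'
#' @param path input file.
#' @param tol tolerance for symmetry/diagonal validation.
#' @return symmetric numeric matrix with variant IDs as dimnames.
#' @export
read_ld_matrix <- function(path, tol = 1e-9) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  ids <- as.character(raw[[1]])
  m <- as.matrix(raw[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (!identical(colnames(m), ids)) {
    stop("LD matrix row and column labels disagree", call. = FALSE)
  }
  validate_ld_matrix(m, tol = tol)
}

#' Validate an LD matrix
#' @param m square numeric matrix with matching dimnames.
#' @param tol tolerance for symmetry and unit-diagonal checks.
#' @return `m` invisibly unchanged (classed), or an error.
#' @export
validate_ld_matrix <- function(m, tol = 1e-9) {
  if (nrow(m) != ncol(m)) stop("LD matrix must be square", call. = FALSE)
  if (max(abs(m - t(m))) > tol) {
    stop("LD matrix asymmetric beyond tolerance ", tol, call. = FALSE)
  }
  if (max(abs(diag(m) - 1)) > tol) {
    stop("LD matrix diagonal differs from 1 beyond tolerance ", tol, call. = FALSE)
  }
  m
}

#' Write an LD matrix
#' @param m symmetric numeric matrix with variant-ID dimnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ld_matrix <- function(m, path) {
  df <- data.frame(ID = rownames(m),
                   apply(m, 2, function(col) .fmt_num(col)),
                   stringsAsFactors = FALSE, check.names = FALSE)
  names(df) <- c("ID", colnames(m))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a genotype dataset as a dosage TSV
#' @param ds [genotype_dataset()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dosage_tsv <- function(ds, path) {
  dos <- t(ds$dosages)
  df <- data.frame(CHR = ds$variants$chrom, POS = ds$variants$pos,
                   ID = ds$variants$id, EA = ds$variants$ea,
                   OA = ds$variants$oa, stringsAsFactors = FALSE,
                   check.names = FALSE)
  dosdf <- as.data.frame(dos, stringsAsFactors = FALSE)
  names(dosdf) <- ds$sample_ids
  utils::write.table(cbind(df, dosdf), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
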