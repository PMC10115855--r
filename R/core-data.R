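# Shared data model: expression matrices (plain numeric matrix, genes in
# rows, rownames = gene ids, colnames = sample ids), drug-response tables
# (data.frame sample_id / ic50 / auc) and sample annotations.

#' Validate an expression matrix
#'
#' Expression data are represented as a plain numeric matrix with genes
#' in rows (`rownames` are gene identifiers) and samples in columns
#' (`colnames` are sample identifiers), on a log2 scale.
#'
#' @param m numeric matrix, genes x samples.
#' @param require_unique_genes logical; when `TRUE` (default) duplicated
#'   gene identifiers are an error (see [collapse_duplicate_genes()]).
#' @return `m`, invisibly, after validation.
#' @export
validate_expression_matrix <- function(m, require_unique_genes = TRUE) {
  if (!is.matrix(m) || !is.numeric(m))
    stop("expression data must be a numeric matrix")
  if (nrow(m) < 2L || ncol(m) < 2L)
    stop("expression matrix needs at least 2 genes and 2 samples")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("expression matrix must carry gene rownames and sample colnames")
  if (anyDuplicated(colnames(m)))
    stop("duplicated sample identifiers: ",
         paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "))
  if (require_unique_genes && anyDuplicated(rownames(m)))
    stop("duplicated gene identifiers (collapse_duplicate_genes() first): ",
         paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "))
  if (!all(is.finite(m))) {
    bad <- which(!is.finite(m), arr.ind = TRUE)[1L, ]
    stop("non-finite expression value at gene '", rownames(m)[bad[1L]],
         "', sample '", colnames(m)[bad[2L]], "'")
  }
  invisible(m)
}

#' Read an expression matrix from delimited text
#'
#' Reads a TSV/CSV file with gene identifiers in the first column and a
#' header row of sample identifiers (the default `genes_in_rows`
#' dialect), or the transpose.  Values must parse as finite numbers;
#' duplicate gene rows are kept as-is and can be collapsed afterwards
#' with [collapse_duplicate_genes()].
#'
#' @param path path to a delimited text file; `.csv` files are read
#'   comma-separated, anything else tab-separated unless `sep` is given.
#' @param dialect `"genes_in_rows"` (default) or `"genes_in_cols"`.
#' @param sep field separator override.
#' @return numeric matrix, genes x samples.
#' @export
read_expression_matrix <- function(path,
                                   dialect = c("genes_in_rows", "genes_in_cols"),
                                   sep = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (nrow(df) == 0L || ncol(df) < 2L) stop("empty or malformed expression file: ", path)
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  suppressWarnings(storage.mode(m) <- "double")
  rownames(m) <- ids
  if (dialect == "genes_in_cols") m <- t(m)
  if (anyNA(m) || !all(is.finite(m))) {
    bad <- which(!is.finite(m), arr.ind = TRUE)[1L, ]
    stop("non-numeric or missing value at gene '", rownames(m)[bad[1L]],
         "', sample '", colnames(m)[bad[2L]], "' in ", path)
  }
  validate_expression_matrix(m, require_unique_genes = FALSE)
  m
}

#' Write an expression matrix as delimited text
#'
#' Inverse of [read_expression_matrix()]; values are written with 12
#' significant digits so that read-write round trips are lossless at
#' that precision.
#'
#' @param m numeric matrix, genes x samples.
#' @param path output path; `.csv` selects comma separation.
#' @param sep field separator override.
#' @param gene_col header for the gene identifier column.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(m, path, sep = NULL, gene_col = "gene_id") {
  validate_expression_matrix(m, require_unique_genes = FALSE)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- data.frame(gene = rownames(m),
                   signif(m, 12L),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1L] <- gene_col
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Average rows that share a gene identifier
#'
#' Repeated identifiers (for example multiple array probes mapped to one
#' symbol) are replaced by the arithmetic mean of their rows.  Row order
#' follows the first occurrence of each identifier.  Idempotent.
#'
#' @param m numeric matrix, genes x samples, possibly with duplicated
#'   rownames.
#' @return matrix with unique rownames.
#' @export
collapse_duplicate_genes <- function(m) {
  validate_expression_matrix(m, require_unique_genes = FALSE)
  ids <- rownames(m)
  if (!anyDuplicated(ids)) return(m)
  first <- !duplicated(ids)
  out <- rowsum(m, group = ids, reorder = FALSE) /
    as.vector(table(factor(ids, levels = unique(ids))))
  out[match(ids[first], rownames(out)), , drop = FALSE]
}

#' Z-score each gene across samples
#'
#' Centers and scales every row to mean 0 and standard deviation 1
#' (sample SD, divisor n - 1).  Constant genes are an error; drop them
#' first or pass them through [variance_filter()].
#'
#' @param m numeric matrix, genes x samples.
#' @return matrix of the same shape with standardized rows.
#' @export
zscore_by_gene <- function(m) {
  validate_expression_matrix(m)
  mu <- rowMeans(m)
  s <- row_sds(m)
  if (any(s == 0)) {
    stop("constant gene(s), cannot z-score: ",
         paste(head(rownames(m)[s == 0], 10L), collapse = ", "))
  }
  (m - mu) / s
}

# Row variances and standard deviations (divisor n - 1), vectorized.
row_vars <- function(m) {
  pmax(rowSums((m - rowMeans(m))^2), 0) / (ncol(m) - 1L)
}
row_sds <- function(m) sqrt(row_vars(m))

#' Read a drug-response table
#'
#' Expects delimited text with columns `sample_id`, `ic50` (log2 uM; the
#' column may also be named `ic50_log2uM`) and optionally `auc`.
#'
#' @param path path to a TSV/CSV file.
#' @return data.frame with columns `sample_id`, `ic50` and optionally
#'   `auc`.
#' @export
read_drug_response <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- read.delim(path, sep = sep, header = TRUE, stringsAsFactors = FALSE)
  if ("ic50_log2uM" %in% names(df) && !"ic50" %in% names(df))
    names(df)[names(df) == "ic50_log2uM"] <- "ic50"
  validate_drug_response(df)
}

#' Validate a drug-response table
#'
#' @param df data.frame with columns `sample_id`, `ic50` and optionally
#'   `auc` (in \[0, 1\]).
#' @return the validated data.frame with `sample_id` as character.
#' @export
validate_drug_response <- function(df) {
  if (!all(c("sample_id", "ic50") %in% names(df)))
    stop("drug response table needs columns 'sample_id' and 'ic50'")
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id))
    stop("duplicated sample_id in drug response table")
  if (!is.numeric(df$ic50) || !all(is.finite(df$ic50)))
    stop("every sample needs a finite ic50")
  if (!is.null(df$auc)) {
    ok <- is.finite(df$auc) & df$auc >= 0 & df$auc <= 1
    if (!all(ok | is.na(df$auc))) stop("auc values must lie in [0, 1]")
  }
  df
}

#' Read sample annotations
#'
#' Delimited text with columns `sample_id`, `disease_site` and
#' optionally `treated`, `time_months`, `event`, followed by one
#' logical/0-1 column per mutation gene.
#'
#' @param path path to a TSV/CSV file.
#' @param mutation_cols character vector naming the mutation columns;
#'   when `NULL`, all columns after the known ones are taken as
#'   mutations.
#' @return data.frame of annotations; mutation columns are logical.
#' @export
read_sample_annotations <- function(path, mutation_cols = NULL) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- read.delim(path, sep = sep, header = TRUE, stringsAsFactors = FALSE)
  known <- c("sample_id", "disease_site", "treated", "time_months", "event")
  if (is.null(mutation_cols)) mutation_cols <- setdiff(names(df), known)
  for (cl in intersect(c("treated", "event", mutation_cols), names(df)))
    df[[cl]] <- as.logical(df[[cl]])
  validate_sample_annotations(df, mutation_cols)
}

validate_sample_annotations <- function(df, mutation_cols = character()) {
  if (!"sample_id" %in% names(df)) stop("annotations need a sample_id column")
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) stop("duplicated sample_id in annotations")
  if (xor(is.null(df$time_months), is.null(df$event)))
    stop("survival time and event must be supplied together")
  if (!is.null(df$time_months)) {
    ok <- is.na(df$time_months) | df$time_months > 0
    if (!all(ok)) stop("survival times must be positive")
  }
  for (cl in mutation_cols)
    if (!is.logical(df[[cl]])) stop("mutation column '", cl, "' must be logical")
  df
}

#' Pipeline configuration
#'
#' Bundles the tunable parameters of the extraction pipeline with their
#' defaults: five folds; extreme-responder fraction 0.2; unadjusted-p /
#' FDR cutoff 0.20; log2 fold-change cutoff 0.5 (moderated-t branch
#' only); 10000 SAM permutations; 1000 minP bootstrap iterations;
#' affinity binarization at the top 5 percent; connectivity cut at the
#' top 20 percent; consensus membership in at least 3 of the folds.
#'
#' @param n_folds integer, number of data partitions.
#' @param extreme_fraction fraction of samples in each extreme-responder
#'   group, in (0, 0.5].
#' @param fdr_cutoff significance cutoff shared by the three tests.
#' @param lfc_cutoff log2 fold-change cutoff (moderated t only).
#' @param n_perm_sam permutations for the SAM null.
#' @param n_boot_minp bootstrap iterations for the minP null.
#' @param affinity_top_fraction pooled top fraction kept when binarizing
#'   affinities.
#' @param connectivity_top_fraction top fraction of connectivity scores
#'   (over all genes) defining connectivity genes.
#' @param consensus_min_folds minimum number of folds a gene must appear
#'   in to enter the consensus signature.
#' @param n_null number of random signatures for null distributions.
#' @param rng_seed base seed for all stochastic steps.
#' @return a list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(n_folds = 5L,
                            extreme_fraction = 0.2,
                            fdr_cutoff = 0.20,
                            lfc_cutoff = 0.5,
                            n_perm_sam = 10000L,
                            n_boot_minp = 1000L,
                            affinity_top_fraction = 0.05,
                            connectivity_top_fraction = 0.20,
                            consensus_min_folds = 3L,
                            n_null = 1000L,
                            rng_seed = 1L) {
  cfg <- list(n_folds = as.integer(n_folds),
              extreme_fraction = extreme_fraction,
              fdr_cutoff = fdr_cutoff,
              lfc_cutoff = lfc_cutoff,
              n_perm_sam = as.integer(n_perm_sam),
              n_boot_minp = as.integer(n_boot_minp),
              affinity_top_fraction = affinity_top_fraction,
              connectivity_top_fraction = connectivity_top_fraction,
              consensus_min_folds = as.integer(consensus_min_folds),
              n_null = as.integer(n_null),
              rng_seed = as.integer(rng_seed))
  class(cfg) <- "pipeline_config"
  validate_pipeline_config(cfg)
}

validate_pipeline_config <- function(cfg) {
  stopifnot(cfg$n_folds >= 2L,
            cfg$consensus_min_folds >= 1L,
            cfg$consensus_min_folds <= cfg$n_folds)
  frac <- c(extreme_fraction = cfg$extreme_fraction,
            affinity_top_fraction = cfg$affinity_top_fraction,
            connectivity_top_fraction = cfg$connectivity_top_fraction)
  if (any(frac <= 0 | frac >= 1))
    stop("fractions must lie in (0, 1): ",
         paste(names(frac)[frac <= 0 | frac >= 1], collapse = ", "))
  if (cfg$extreme_fraction > 0.5) stop("extreme_fraction must be <= 0.5")
  if (cfg$fdr_cutoff <= 0 || cfg$fdr_cutoff > 1) stop("fdr_cutoff must be in (0, 1]")
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' The YAML keys mirror the [pipeline_config()] arguments; missing keys
#' take their defaults, unknown keys are an error.
#'
#' @param path path to a YAML file.
#' @return a `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  extra <- setdiff(names(vals), known)
  if (length(extra)) stop("unknown config keys: ", paste(extra, collapse = ", "))
  do.call(pipeline_config, vals)
}
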