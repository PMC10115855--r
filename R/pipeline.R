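# End-to-end signature extraction: fold-wise tri-method DE consensus on
# the cell line panel, connectivity filtering on the clinical cohort,
# cross-fold consensus.

#' Derive a consensus drug-response signature
#'
#' Runs the full extraction pipeline: the panel samples are split into
#' `n_folds` folds; for each fold, the retained samples' extreme
#' responders (lowest / highest `extreme_fraction` of IC50) are
#' compared with the moderated t-test, the SAM permutation test and
#' the bootstrap minP test; the intersection of the three up-in-
#' sensitive significant sets forms the fold's seed genes; seeds are
#' filtered by co-expression connectivity in the clinical cohort; and
#' genes present in at least `consensus_min_folds` of the per-fold
#' connectivity sets form the consensus signature.
#'
#' @param expr panel expression matrix (genes x lines, log2).
#' @param resp drug-response data.frame covering the panel samples.
#' @param clinical clinical-cohort expression matrix sharing the gene
#'   universe.
#' @param config a [pipeline_config()].
#' @param verbose print per-fold progress.
#' @return list of class `"signature_derivation"` with `signature` (a
#'   `"consensus_signature"`), `folds`, `seed_sets`, `connectivity`
#'   (per-fold `"connectivity_result"`s) and `config`.
#' @export
derive_signature <- function(expr, resp, clinical,
                             config = pipeline_config(),
                             verbose = FALSE) {
  validate_expression_matrix(expr)
  validate_expression_matrix(clinical)
  resp <- validate_drug_response(resp)
  config <- validate_pipeline_config(config)
  samples <- intersect(colnames(expr), resp$sample_id)
  if (length(samples) < config$n_folds * 2L)
    stop("too few samples with both expression and response")
  folds <- split_folds(samples, config$n_folds, seed = config$rng_seed)

  seed_sets <- vector("list", config$n_folds)
  connectivity <- vector("list", config$n_folds)
  for (k in seq_len(config$n_folds)) {
    retained <- folds$retained_per_fold[[k]]
    grp <- select_extreme_responders(
      resp[resp$sample_id %in% retained, , drop = FALSE],
      fraction = config$extreme_fraction)
    mk <- expr[, retained, drop = FALSE]
    res <- list(
      moderated_t_test(mk, grp$sensitive, grp$resistant,
                       lfc_cutoff = config$lfc_cutoff,
                       p_cutoff = config$fdr_cutoff),
      sam_test(mk, grp$sensitive, grp$resistant,
               n_perm = config$n_perm_sam, fdr_cutoff = config$fdr_cutoff,
               seed = config$rng_seed + k),
      minp_test(mk, grp$sensitive, grp$resistant,
                n_boot = config$n_boot_minp,
                adj_p_cutoff = config$fdr_cutoff,
                seed = config$rng_seed + k))
    seed_sets[[k]] <- suppressWarnings(derive_seed_genes(res, fold = k))
    if (verbose)
      message("fold ", k, ": ",
              paste(names(seed_sets[[k]]$per_method_counts),
                    seed_sets[[k]]$per_method_counts,
                    sep = "=", collapse = ", "),
              " -> ", length(seed_sets[[k]]$genes), " seed genes")
    seeds_k <- intersect(seed_sets[[k]]$genes, rownames(clinical))
    if (length(seeds_k)) {
      aff <- compute_affinity_matrix(clinical, seeds_k)
      aff <- binarize_affinity(aff, config$affinity_top_fraction)
      con <- compute_connectivity_scores(aff)
      connectivity[[k]] <- extract_connectivity_genes(
        con, seeds_k, config$connectivity_top_fraction)
    } else {
      connectivity[[k]] <- structure(
        list(connectivity_score = numeric(), threshold_value = NA_real_,
             connectivity_genes = character()),
        class = "connectivity_result")
    }
    if (verbose)
      message("fold ", k, ": ",
              length(connectivity[[k]]$connectivity_genes),
              " connectivity genes")
  }
  sig <- suppressWarnings(
    consensus_signature(connectivity, min_folds = config$consensus_min_folds))
  structure(list(signature = sig, folds = folds, seed_sets = seed_sets,
                 connectivity = connectivity, config = config),
            class = "signature_derivation")
}

#' @export
print.signature_derivation <- function(x, ...) {
  cat("Signature derivation over", x$config$n_folds, "folds\n")
  for (k in seq_along(x$seed_sets))
    cat("  fold", k, ":", length(x$seed_sets[[k]]$genes), "seeds ->",
        length(x$connectivity[[k]]$connectivity_genes), "connectivity genes\n")
  print(x$signature)
  invisible(x)
}

#' Precision and recall of a signature against a known gene set
#'
#' @param signature character vector (or `"consensus_signature"`).
#' @param truth character vector of true program genes.
#' @return named numeric vector with `precision`, `recall`, `jaccard`.
#' @export
signature_recovery <- function(signature, truth) {
  genes <- if (inherits(signature, "consensus_signature")) signature$genes
  else as.character(signature)
  tp <- length(intersect(genes, truth))
  c(precision = if (length(genes)) tp / length(genes) else NA_real_,
    recall = if (length(truth)) tp / length(truth) else NA_real_,
    jaccard = tp / length(union(genes, truth)))
}

#' Published 19-gene cisplatin sensitivity signature
#'
#' Convenience accessor for the packaged gene list of a published
#' pan-cancer cisplatin sensitivity signature (19 HGNC symbols derived
#' from an epithelial cell line panel), useful as a realistic signature
#' length and symbol set for scoring and translation examples.
#'
#' @return character vector of 19 HGNC gene symbols.
#' @export
cisplatin_signature_genes <- function() {
  path <- system.file("extdata", "cisplatin_signature_19genes.txt",
                      package = "consig", mustWork = TRUE)
  readLines(path)
}
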