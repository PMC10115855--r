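# Seed-gene co-expression on a clinical cohort: Spearman affinity
# scores, global top-fraction binarization, connectivity scores, and
# the per-fold / cross-fold signature assembly.

#' Spearman affinity of every seed gene to every gene
#'
#' Pairwise Spearman correlation (average-rank ties) between each seed
#' gene and every gene in the clinical cohort, computed across
#' samples.  The self-pair of each seed is recorded as missing, as are
#' pairs involving constant genes.
#'
#' @param clinical expression matrix (genes x samples) of the clinical
#'   cohort; at least 10 samples.
#' @param seeds character vector of seed genes, all present in
#'   `clinical`.
#' @return list of class `"affinity_matrix"` with `seed_ids`,
#'   `gene_ids`, `values` (seeds x genes Spearman matrix, `NA` on
#'   self-pairs) and `binarized` (`NULL` until [binarize_affinity()]).
#' @export
compute_affinity_matrix <- function(clinical, seeds) {
  validate_expression_matrix(clinical)
  seeds <- unique(as.character(seeds))
  if (ncol(clinical) < 10L) stop("need at least 10 clinical samples")
  missing <- setdiff(seeds, rownames(clinical))
  if (length(missing))
    stop("seed gene(s) absent from the clinical cohort: ",
         paste(missing, collapse = ", "))
  const <- row_sds(clinical) == 0
  if (any(const))
    warning("constant gene(s) in cohort; affinities recorded as missing: ",
            paste(head(rownames(clinical)[const], 10L), collapse = ", "))
  rk <- t(apply(clinical, 1L, rank))          # average-rank ties
  vals <- suppressWarnings(
    cor(t(rk[seeds, , drop = FALSE]), t(rk)))  # Pearson on ranks = Spearman
  vals[, const] <- NA_real_
  vals[cbind(seq_along(seeds), match(seeds, colnames(vals)))] <- NA_real_
  if (any(rownames(clinical)[const] %in% seeds))
    vals[rownames(clinical)[const][rownames(clinical)[const] %in% seeds], ] <- NA_real_
  structure(list(seed_ids = seeds, gene_ids = rownames(clinical),
                 values = vals, binarized = NULL),
            class = "affinity_matrix")
}

#' Binarize affinity scores at a pooled top fraction
#'
#' The threshold is the `(1 - top_fraction)` type-7 quantile of all
#' non-missing signed affinity values pooled across the whole matrix;
#' entries strictly above it become 1, everything else (including
#' ties with the threshold) becomes 0.  Signed values are used, so only
#' positive co-expression can survive a small `top_fraction`.
#'
#' @param a an `"affinity_matrix"`.
#' @param top_fraction fraction of entries kept (default 0.05).
#' @return the affinity matrix with its `binarized` field populated.
#' @export
binarize_affinity <- function(a, top_fraction = 0.05) {
  stopifnot(inherits(a, "affinity_matrix"))
  if (top_fraction <= 0 || top_fraction >= 1) stop("top_fraction must be in (0, 1)")
  v <- a$values[!is.na(a$values)]
  if (!length(v)) stop("all affinity values are missing")
  thr <- quantile(v, 1 - top_fraction, type = 7, names = FALSE)
  b <- (a$values > thr) * 1
  if (sum(b, na.rm = TRUE) == 0)
    warning("no affinity exceeds the threshold strictly (tied values?)")
  a$binarized <- b
  a$threshold <- thr
  a
}

#' Connectivity scores from a binarized affinity matrix
#'
#' A gene's connectivity score is the mean of its binarized affinities
#' over seed genes, excluding missing self-pairs from the denominator.
#'
#' @param a an `"affinity_matrix"` with `binarized` populated.
#' @return list of class `"connectivity_result"` with
#'   `connectivity_score` (named numeric over all genes),
#'   `threshold_value` (`NA` until [extract_connectivity_genes()]) and
#'   `connectivity_genes` (empty until then).
#' @export
compute_connectivity_scores <- function(a) {
  stopifnot(inherits(a, "affinity_matrix"))
  if (is.null(a$binarized)) stop("binarize_affinity() first")
  score <- colMeans(a$binarized, na.rm = TRUE)
  score[is.nan(score)] <- 0    # genes with no usable seed partner
  structure(list(connectivity_score = score,
                 threshold_value = NA_real_,
                 connectivity_genes = character()),
            class = "connectivity_result")
}

#' Connectivity genes: seeds in the top fraction of connectivity
#'
#' The threshold is the `(1 - top_fraction)` type-7 quantile of
#' connectivity scores over ALL genes; the connectivity genes are the
#' seeds whose score lies strictly above it.
#'
#' @param con a `"connectivity_result"`.
#' @param seeds character vector of this fold's seed genes.
#' @param top_fraction fraction defining the cut (default 0.20).
#' @return the `"connectivity_result"` with `threshold_value` and
#'   `connectivity_genes` filled in.
#' @export
extract_connectivity_genes <- function(con, seeds, top_fraction = 0.20) {
  stopifnot(inherits(con, "connectivity_result"))
  if (!length(seeds)) {
    warning("empty seed set; no connectivity genes")
    con$connectivity_genes <- character()
    return(con)
  }
  score <- con$connectivity_score
  thr <- quantile(score, 1 - top_fraction, type = 7, names = FALSE)
  keep <- names(score)[score > thr]
  con$threshold_value <- thr
  con$connectivity_genes <- sort(intersect(as.character(seeds), keep))
  con
}

#' Cross-fold consensus signature
#'
#' Genes present in at least `min_folds` of the per-fold connectivity
#' gene sets, ordered by descending fold-membership count and then
#' lexicographically.
#'
#' @param per_fold list of `"connectivity_result"` objects (or plain
#'   character vectors of per-fold genes).
#' @param min_folds minimum number of folds (default 3).
#' @return list of class `"consensus_signature"` with `genes`,
#'   `fold_membership` (named list of fold indices) and `min_folds`.
#' @export
consensus_signature <- function(per_fold, min_folds = 3L) {
  sets <- lapply(per_fold, function(x)
    if (inherits(x, "connectivity_result")) x$connectivity_genes else as.character(x))
  if (min_folds > length(sets))
    stop("min_folds exceeds the number of fold results")
  all_genes <- sort(unique(unlist(sets)))
  membership <- lapply(all_genes, function(g)
    which(vapply(sets, function(s) g %in% s, logical(1))))
  names(membership) <- all_genes
  counts <- lengths(membership)
  keep <- counts >= min_folds
  if (!any(keep)) warning("no gene reaches the consensus threshold")
  genes <- all_genes[keep][order(-counts[keep], all_genes[keep])]
  structure(list(genes = genes,
                 fold_membership = membership[genes],
                 min_folds = as.integer(min_folds)),
            class = "consensus_signature")
}

#' @export
print.consensus_signature <- function(x, ...) {
  cat("Consensus signature:", length(x$genes), "gene(s), present in >=",
      x$min_folds, "fold(s)\n")
  if (length(x$genes)) {
    counts <- lengths(x$fold_membership)
    cat(paste0(x$genes, " (", counts, ")", collapse = ", "), "\n")
  }
  invisible(x)
}
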