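# Fold construction and extreme-responder selection.

#' Partition samples into folds
#'
#' Seeded uniform random partition into `n_folds` folds whose sizes
#' differ by at most one.  The pipeline retains, for fold k, every
#' sample NOT assigned to fold k.
#'
#' @param samples character vector of sample identifiers.
#' @param n_folds number of folds (>= 2).
#' @param seed RNG seed.
#' @return list with `fold_assignments` (named integer vector) and
#'   `retained_per_fold` (list of character vectors).
#' @export
split_folds <- function(samples, n_folds, seed = 1L) {
  n <- length(samples)
  if (n_folds < 2L) stop("n_folds must be >= 2")
  if (n_folds > n) stop("more folds than samples")
  if (anyDuplicated(samples)) stop("duplicated sample identifiers")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  fold <- setNames(sample(rep_len(seq_len(n_folds), n)), samples)
  retained <- lapply(seq_len(n_folds), function(k) samples[fold != k])
  list(fold_assignments = fold, retained_per_fold = retained)
}

#' Select extreme responders by IC50
#'
#' The `floor(fraction * n)` samples with the lowest IC50 form the
#' sensitive group and the same number with the highest IC50 the
#' resistant group.  Samples are ordered by IC50 with ties broken by
#' sample identifier (ascending); the sensitive group takes the head of
#' that ordering and the resistant group its tail, which keeps the two
#' groups disjoint even when a tie block straddles a boundary.
#'
#' @param resp drug-response data.frame (`sample_id`, `ic50`).
#' @param fraction group fraction in (0, 0.5].
#' @return list with character vectors `sensitive` and `resistant`.
#' @export
select_extreme_responders <- function(resp, fraction = 0.2) {
  resp <- validate_drug_response(resp)
  if (fraction <= 0 || fraction > 0.5) stop("fraction must be in (0, 0.5]")
  n <- nrow(resp)
  k <- floor(fraction * n)
  if (k < 2L) stop("fraction * n must be at least 2 per group")
  ord <- order(resp$ic50, resp$sample_id)
  list(sensitive = resp$sample_id[ord[seq_len(k)]],
       resistant = resp$sample_id[ord[seq.int(n - k + 1L, n)]])
}
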