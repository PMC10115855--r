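# Single-step minP multiplicity adjustment with a null-enforcing
# bootstrap: genes are mean-centred within each group, bootstrap
# resamples are drawn from the pooled centred columns, and the adjusted
# p-value of a gene is the fraction of iterations in which the most
# extreme statistic anywhere on the array beats that gene's observed
# statistic.

#' Bootstrap single-step minP test between sensitive and resistant groups
#'
#' Raw p-values come from the pooled-variance two-sample t-test.  The
#' null distribution is built from `n_boot` bootstrap resamples of the
#' per-gene mean-centred data (centring within each group enforces the
#' complete null).  Because every gene shares the same degrees of
#' freedom, the minimum raw p-value over genes in an iteration is
#' attained by the maximum absolute t-statistic, so the single-step
#' minP adjusted p-value is the fraction of iterations whose maximal
#' `|t|` exceeds the gene's observed `|t|`; it is clipped below by the
#' raw p-value, which the exact adjustment can never undercut.
#' Significance requires `adj_p <= adj_p_cutoff` and a positive log2
#' fold change.
#'
#' @inheritParams moderated_t_test
#' @param n_boot bootstrap iterations (default 1000).
#' @param adj_p_cutoff adjusted-p cutoff (default 0.20).
#' @param seed RNG seed.
#' @return data.frame as in [moderated_t_test()] with `method =
#'   "minp"`, `stat` the pooled t-statistic and `q_or_adj` the
#'   single-step minP adjusted p-value.
#' @export
minp_test <- function(m, sensitive, resistant,
                      n_boot = 1000L, adj_p_cutoff = 0.20, seed = 1L) {
  if (n_boot < 100L) warning("n_boot < 100: bootstrap null will be coarse")
  gs <- de_group_stats(m, sensitive, resistant)
  n1 <- gs$n1; n2 <- gs$n2; n <- n1 + n2; df <- n - 2L
  se <- sqrt(gs$sp2 * (1 / n1 + 1 / n2))
  t_obs <- ifelse(se > 0, gs$lfc / se, 0)
  p_raw <- 2 * pt(-abs(t_obs), df = df)

  # null-enforcing centring, then pooled bootstrap via multinomial counts
  xc <- cbind(m[, sensitive, drop = FALSE] - gs$m1,
              m[, resistant, drop = FALSE] - gs$m2)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  C1 <- stats::rmultinom(n_boot, n1, rep(1 / n, n))
  C2 <- stats::rmultinom(n_boot, n2, rep(1 / n, n))
  S1 <- xc %*% C1; Q1 <- (xc^2) %*% C1
  S2 <- xc %*% C2; Q2 <- (xc^2) %*% C2
  m1 <- S1 / n1; m2 <- S2 / n2
  ss <- pmax(Q1 - n1 * m1^2, 0) + pmax(Q2 - n2 * m2^2, 0)
  se_b <- sqrt(ss / df * (1 / n1 + 1 / n2))
  t_b <- (m1 - m2) / se_b
  t_b[!is.finite(t_b)] <- 0
  max_abs <- apply(abs(t_b), 2L, max)

  adj <- vapply(abs(t_obs), function(t0) mean(max_abs >= t0), numeric(1))
  adj <- pmax(adj, p_raw)

  res <- data.frame(gene_id = gs$genes,
                    mean_sensitive = gs$m1, mean_resistant = gs$m2,
                    lfc = gs$lfc, stat = t_obs, p_raw = p_raw,
                    q_or_adj = pmin(adj, 1), method = "minp",
                    stringsAsFactors = FALSE)
  res$significant <- res$q_or_adj <= adj_p_cutoff & res$lfc > 0
  res
}

#' Intersect the three methods' significant up-regulated genes
#'
#' Seed genes for a fold are the genes that every supplied
#' differential-expression result calls significantly up-regulated in
#' the sensitive state.
#'
#' @param results list of data.frames as returned by
#'   [moderated_t_test()], [sam_test()] and [minp_test()], computed on
#'   the same gene universe.
#' @param fold integer fold label carried through for provenance.
#' @return list of class `"seed_gene_set"` with elements `fold`,
#'   `genes` (character) and `per_method_counts` (named integer).
#' @export
derive_seed_genes <- function(results, fold = NA_integer_) {
  stopifnot(is.list(results), length(results) >= 2L)
  universes <- lapply(results, function(r) sort(r$gene_id))
  for (i in seq_along(universes)[-1L])
    if (!identical(universes[[1L]], universes[[i]]))
      stop("differential-expression results cover different gene universes")
  sig_sets <- lapply(results, function(r) r$gene_id[r$significant])
  counts <- vapply(sig_sets, length, integer(1))
  names(counts) <- vapply(results, function(r) r$method[1L], character(1))
  genes <- Reduce(intersect, sig_sets)
  if (!length(genes))
    warning("empty seed gene set", if (!is.na(fold)) paste0(" for fold ", fold))
  structure(list(fold = fold, genes = sort(genes),
                 per_method_counts = counts),
            class = "seed_gene_set")
}
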