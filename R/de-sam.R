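# SAM-style permutation test.  Tusher d-statistic with a fudge factor
# s0 chosen to minimise the coefficient of variation of d across
# windows of the per-gene standard errors, a label-permutation null
# (full enumeration when feasible), and per-gene q-values from the
# median false-call count.

#' SAM permutation test between sensitive and resistant groups
#'
#' The per-gene statistic is `d = (mean_s - mean_r) / (s + s0)`, where
#' `s` is the pooled two-sample standard error and the fudge factor
#' `s0` is the percentile of the `s` distribution that minimises the
#' coefficient of variation of the median absolute deviation of `d`
#' across `s`-quantile windows.  The null is built from label
#' permutations of the pooled extreme samples (exhaustive enumeration
#' whenever the number of distinct label splits does not exceed
#' `n_perm`).  Per-gene q-values use the median false-call estimate
#' over permutations with a quartile-based estimate of the true-null
#' proportion.  Significance requires `q <= fdr_cutoff` and `d > 0`.
#'
#' @inheritParams moderated_t_test
#' @param n_perm number of label permutations (default 10000).
#' @param fdr_cutoff q-value cutoff (default 0.20).
#' @param seed RNG seed for the permutation draw.
#' @param s0 optional fudge-factor override (`0` makes the ranking of
#'   `d` coincide with the ordinary t ranking).
#' @param return_null logical; keep the permutation d matrix (genes x
#'   permutations) in the `"null_d"` attribute.
#' @return data.frame as in [moderated_t_test()] with `method = "sam"`,
#'   `stat` the d-statistic and `q_or_adj` the q-value.  Attributes:
#'   `"s0"`, `"pi0"`, `"exhaustive"`, and optionally `"null_d"`.
#' @export
sam_test <- function(m, sensitive, resistant,
                     n_perm = 10000L, fdr_cutoff = 0.20, seed = 1L,
                     s0 = NULL, return_null = FALSE) {
  if (n_perm < 100L) warning("n_perm < 100: permutation null will be coarse")
  gs <- de_group_stats(m, sensitive, resistant)
  n1 <- gs$n1; n2 <- gs$n2; n <- n1 + n2
  se <- sqrt(gs$sp2 * (1 / n1 + 1 / n2))
  if (is.null(s0)) s0 <- sam_fudge_factor(gs$lfc, se)
  d_obs <- gs$lfc / (se + s0)

  x <- m[, c(sensitive, resistant), drop = FALSE]
  perm <- sam_permutations(n, n1, n_perm, seed)
  null_d <- sam_null_d(x, perm, n1, n2, s0)
  counts <- sam_null_counts(d_obs, null_d)
  q <- sam_qvalues(d_obs, counts, length(null_d))
  p_raw <- sam_perm_p(d_obs, counts, length(null_d))

  res <- data.frame(gene_id = gs$genes,
                    mean_sensitive = gs$m1, mean_resistant = gs$m2,
                    lfc = gs$lfc, stat = d_obs,
                    p_raw = p_raw,
                    q_or_adj = q, method = "sam",
                    stringsAsFactors = FALSE)
  res$significant <- res$q_or_adj <= fdr_cutoff & res$stat > 0
  attr(res, "s0") <- s0
  attr(res, "pi0") <- attr(q, "pi0")
  attr(res, "exhaustive") <- attr(perm, "exhaustive")
  if (return_null) attr(res, "null_d") <- null_d
  res
}

# Tusher fudge factor: candidate s0 = alpha-quantiles of se for
# alpha in 0, 0.05, ..., 1; pick the alpha minimising the coefficient
# of variation of mad(d) across (up to) 100 se-quantile windows.
sam_fudge_factor <- function(lfc, se, alphas = seq(0, 1, by = 0.05)) {
  n_bins <- max(2L, min(100L, floor(length(se) / 5)))
  bin <- cut(rank(se, ties.method = "first"), breaks = n_bins, labels = FALSE)
  cand <- quantile(se, alphas, type = 7, names = FALSE)
  cv <- vapply(cand, function(a) {
    d <- lfc / (se + a)
    mads <- tapply(d, bin, mad)
    m <- mean(mads)
    if (!is.finite(m) || m == 0) Inf else sd(mads) / m
  }, numeric(1))
  cand[which.min(cv)]
}

# Label permutations as a 0/1 membership matrix (n x B) for the
# "sensitive" group.  Exhaustive when choose(n, n1) <= n_perm.
sam_permutations <- function(n, n1, n_perm, seed) {
  exhaustive <- choose(n, n1) <= n_perm
  if (exhaustive) {
    idx <- combn(n, n1)
    B <- ncol(idx)
    M <- matrix(0, n, B)
    M[cbind(as.vector(idx), rep(seq_len(B), each = n1))] <- 1
  } else {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(seed)
    M <- vapply(seq_len(n_perm), function(b) {
      z <- numeric(n); z[sample.int(n, n1)] <- 1; z
    }, numeric(n))
  }
  attr(M, "exhaustive") <- exhaustive
  M
}

# Null d-statistics for every permutation (genes x B): one matrix
# product with the membership matrix; the within-group sum of squares
# comes from the permutation-invariant per-gene totals.
sam_null_d <- function(x, M, n1, n2, s0) {
  n <- n1 + n2
  tot <- rowSums(x); tot2 <- rowSums(x^2)
  m1 <- (x %*% M) / n1
  m2 <- (tot - n1 * m1) / n2
  ss <- pmax(tot2 - n1 * m1^2 - n2 * m2^2, 0)
  (m1 - m2) / (sqrt(ss * ((1 / n1 + 1 / n2) / (n - 2L))) + s0)
}

# Exceedance counts of the permutation null at every observed d: the
# per-permutation counts feed the median false-call estimate, their
# pooled sums the permutation p-values.  Each permutation column is
# histogrammed over the sorted observed values (no per-column sort).
sam_null_counts <- function(d_obs, null_d) {
  G <- length(d_obs)
  B <- ncol(null_d)
  ts <- sort(d_obs, method = "quick")
  cnt_ge <- matrix(0L, G, B)   # #{null d >= ts_g} per permutation
  cnt_le <- matrix(0L, G, B)
  for (b in seq_len(B)) {
    x <- null_d[, b]
    i1 <- findInterval(x, ts)                     # #{ts <= x}
    cnt_ge[, b] <- rev(cumsum(rev(tabulate(i1, nbins = G))))
    i2 <- findInterval(x, ts, left.open = TRUE)   # #{ts < x}
    cnt_le[, b] <- cumsum(tabulate(i2 + 1L, nbins = G))
  }
  pos <- rank(d_obs, ties.method = "first")       # gene -> its threshold
  list(false_up = row_medians_int(cnt_ge)[pos],
       false_dn = row_medians_int(cnt_le)[pos],
       pooled_ge = rowSums(cnt_ge)[pos],
       pooled_le = rowSums(cnt_le)[pos])
}

# Two-sided permutation p: twice the smaller pooled tail fraction.
sam_perm_p <- function(d_obs, counts, n_null) {
  p <- 2 * pmin(counts$pooled_ge, counts$pooled_le) / n_null
  pmin(1, pmax(p, 1 / n_null))
}

# q-values: for a positive d, the false-call count is the median over
# permutations of #{null d >= d}; called = #{observed d >= d}; q =
# pi0 * false / called, with pi0 from the quartile rule (fraction of
# observed d inside the null interquartile range, via the pooled null
# ECDF), capped at 1 and made monotone in |d| within each tail.
sam_qvalues <- function(d_obs, counts, n_null) {
  G <- length(d_obs)
  Fg <- counts$pooled_le / n_null
  pi0 <- min(1, sum(Fg >= 0.25 & Fg <= 0.75) / (0.5 * G))
  false_up <- counts$false_up
  false_dn <- counts$false_dn

  ord_up <- rank(-d_obs, ties.method = "max")   # #{d >= d_g}
  ord_dn <- rank(d_obs, ties.method = "max")    # #{d <= d_g}
  q <- ifelse(d_obs >= 0,
              pi0 * false_up / ord_up,
              pi0 * false_dn / ord_dn)
  q <- pmin(q, 1)
  # monotone: q must not decrease as |d| shrinks, within each tail
  pos <- which(d_obs >= 0)
  q[pos] <- monotone_q(d_obs[pos], q[pos])
  neg <- which(d_obs < 0)
  q[neg] <- monotone_q(-d_obs[neg], q[neg])
  attr(q, "pi0") <- pi0
  q
}

# Row medians of a large integer matrix (radix sort per row on the
# transposed copy for contiguous access).
row_medians_int <- function(M) {
  Mt <- t(M)
  B <- nrow(Mt)
  h <- B %/% 2L
  odd <- B %% 2L == 1L
  vapply(seq_len(ncol(Mt)), function(j) {
    x <- sort.int(Mt[, j], method = "radix")
    if (odd) as.numeric(x[h + 1L]) else (x[h] + x[h + 1L]) / 2
  }, numeric(1))
}

monotone_q <- function(stat, q) {
  ord <- order(stat, decreasing = TRUE)
  q[ord] <- cummax(q[ord])
  q
}
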