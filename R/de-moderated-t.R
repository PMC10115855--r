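# Empirical-Bayes moderated two-group t-test.  Per-gene pooled-variance
# linear model with the residual variances shrunk towards a common (or
# trend) prior estimated by method of moments on log s^2.

#' Moderated t-test between sensitive and resistant groups
#'
#' Per gene, a pooled-variance two-group comparison with empirical-Bayes
#' variance moderation: the prior degrees of freedom `d0` and prior
#' variance `s0^2` are estimated by the method of moments applied to
#' the log residual variances, the posterior variance is
#' `(d0 s0^2 + d s^2) / (d0 + d)`, and the moderated t-statistic is
#' referred to a Student t distribution on `d0 + d` degrees of freedom.
#' Significance requires an unadjusted p-value below `p_cutoff` AND a
#' log2 fold change (sensitive minus resistant) of at least
#' `lfc_cutoff` (so only genes up-regulated in the sensitive state
#' qualify).
#'
#' @param m log2 expression matrix (genes x samples).
#' @param sensitive,resistant disjoint character vectors of sample ids,
#'   each with at least 3 samples.
#' @param lfc_cutoff log2 fold-change cutoff (default 0.5).
#' @param p_cutoff unadjusted p-value cutoff (default 0.20).
#' @param prior_df override for the prior degrees of freedom `d0`;
#'   `NULL` (default) estimates it, `0` reduces the test to the
#'   classical pooled two-sample t-test, `Inf` fixes every posterior
#'   variance at the prior.
#' @param trend logical; when `TRUE`, the prior variance follows a
#'   lowess trend (span 0.5) of the log variances on average log
#'   expression instead of a single constant.
#' @return data.frame with one row per gene: `gene_id`,
#'   `mean_sensitive`, `mean_resistant`, `lfc`, `stat`, `p_raw`,
#'   `q_or_adj` (equal to `p_raw`; no multiplicity adjustment),
#'   `method`, `significant`.
#' @export
moderated_t_test <- function(m, sensitive, resistant,
                             lfc_cutoff = 0.5, p_cutoff = 0.20,
                             prior_df = NULL, trend = FALSE) {
  gs <- de_group_stats(m, sensitive, resistant)
  d <- gs$n1 + gs$n2 - 2L
  s2 <- gs$sp2
  ok <- s2 > 0
  if (!any(ok)) stop("all genes are constant within groups")
  z <- ifelse(ok, log(s2), NA_real_)
  e <- z - digamma(d / 2) + log(d / 2)
  if (trend) {
    amean <- rowMeans(m[gs$genes, c(sensitive, resistant), drop = FALSE])
    fit <- lowess(amean[ok], e[ok], f = 0.5)
    e0 <- approx(fit$x, fit$y, xout = amean, rule = 2L)$y
  } else {
    e0 <- rep(mean(e[ok]), length(e))
  }
  if (is.null(prior_df)) {
    evar <- var(e[ok] - e0[ok]) - trigamma(d / 2)
    d0 <- if (is.na(evar) || evar <= 0) Inf else 2 * trigamma_inverse(evar)
  } else {
    d0 <- prior_df
  }
  s0sq <- if (is.infinite(d0) || d0 == 0) exp(e0) else
    exp(e0 + digamma(d0 / 2) - log(d0 / 2))
  s2_shrunk <- s2
  s2_shrunk[!ok] <- 0   # constant genes: fully shrunk to the prior
  post_var <- if (d0 == 0) s2_shrunk else if (is.infinite(d0)) s0sq else
    (d0 * s0sq + d * s2_shrunk) / (d0 + d)
  se <- sqrt(post_var * (1 / gs$n1 + 1 / gs$n2))
  stat <- ifelse(se > 0, gs$lfc / se, ifelse(gs$lfc == 0, 0, Inf * sign(gs$lfc)))
  p <- 2 * pt(-abs(stat), df = d0 + d)   # pt() handles df = Inf (normal limit)
  res <- data.frame(gene_id = gs$genes,
                    mean_sensitive = gs$m1, mean_resistant = gs$m2,
                    lfc = gs$lfc, stat = stat, p_raw = p, q_or_adj = p,
                    method = "moderated_t",
                    stringsAsFactors = FALSE)
  res$significant <- res$p_raw < p_cutoff & res$lfc >= lfc_cutoff & res$lfc > 0
  attr(res, "prior_df") <- d0
  attr(res, "prior_var") <- s0sq
  res
}

# Shared per-gene two-group summaries: means, lfc, pooled variance.
de_group_stats <- function(m, sensitive, resistant) {
  validate_expression_matrix(m)
  sensitive <- as.character(sensitive); resistant <- as.character(resistant)
  if (length(intersect(sensitive, resistant)))
    stop("sensitive and resistant groups overlap")
  missing <- setdiff(c(sensitive, resistant), colnames(m))
  if (length(missing))
    stop("samples absent from expression matrix: ",
         paste(head(missing, 5L), collapse = ", "))
  n1 <- length(sensitive); n2 <- length(resistant)
  if (n1 < 3L || n2 < 3L) stop("each group needs at least 3 samples")
  x1 <- m[, sensitive, drop = FALSE]; x2 <- m[, resistant, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  ss1 <- rowSums((x1 - m1)^2); ss2 <- rowSums((x2 - m2)^2)
  sp2 <- (ss1 + ss2) / (n1 + n2 - 2L)
  list(genes = rownames(m), n1 = n1, n2 = n2, m1 = m1, m2 = m2,
       lfc = m1 - m2, sp2 = sp2)
}

# Solve trigamma(x) = y by Newton iteration.
trigamma_inverse <- function(y) {
  if (y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:75) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (abs(dif) < 1e-10 * x) break
  }
  x
}
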