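# Signature scoring (median per-gene z-score), positive shifting for
# log-scale display, and the quality-control metric battery with its
# radar-area summary.

#' Signature score per sample
#'
#' The score of a sample is the median, over the signature genes, of
#' the per-gene z-scored expression (each gene standardised across the
#' samples of the dataset at hand).  Constant genes are excluded before
#' z-scoring with a warning.
#'
#' @param m expression matrix (genes x samples).
#' @param genes character vector of signature genes.
#' @param drop_missing when `TRUE` (default) genes absent from `m` are
#'   dropped with a warning; otherwise they are an error.
#' @return named numeric vector of scores (one per sample).
#' @export
signature_score <- function(m, genes, drop_missing = TRUE) {
  validate_expression_matrix(m)
  genes <- unique(as.character(genes))
  absent <- setdiff(genes, rownames(m))
  if (length(absent)) {
    if (!drop_missing)
      stop("signature gene(s) absent from matrix: ", paste(absent, collapse = ", "))
    warning("dropping ", length(absent), " signature gene(s) absent from matrix: ",
            paste(head(absent, 10L), collapse = ", "))
    genes <- setdiff(genes, absent)
  }
  if (!length(genes))
    stop("no signature gene overlaps the expression matrix")
  sub <- m[genes, , drop = FALSE]
  const <- row_sds(sub) == 0
  if (any(const)) {
    warning("excluding constant signature gene(s): ",
            paste(rownames(sub)[const], collapse = ", "))
    sub <- sub[!const, , drop = FALSE]
    if (!nrow(sub)) stop("all overlapping signature genes are constant")
  }
  z <- (sub - rowMeans(sub)) / row_sds(sub)
  apply(z, 2L, median)
}

#' Shift scores to a positive range
#'
#' Adds `|min(score)| + 1` to every score.  When the minimum is at or
#' below zero this maps the minimum to exactly 1, which permits
#' plotting on a log axis; for an all-positive minimum the formula is
#' applied verbatim (the minimum then lands above 1).
#'
#' @param score named numeric vector of signature scores.
#' @return named numeric vector of shifted scores.
#' @export
shift_scores_positive <- function(score) {
  if (!all(is.finite(score))) stop("scores must be finite")
  score + abs(min(score)) + 1
}

#' Quality-control metrics for a signature in a dataset
#'
#' Computes the metric battery used to compare candidate signatures:
#' mean pairwise Spearman correlation among signature genes
#' (`intra_sig_correlation`); Spearman correlation between per-sample
#' mean and median signature expression (`rho_mean_median`); Spearman
#' correlation between the per-sample mean and the first principal
#' component of the signature submatrix, sign-aligned to the mean
#' (`rho_mean_pc1`); the standard deviation (`score_sd`) and
#' coefficient of variation (`score_cv`, computed on positively
#' shifted scores) of the signature score; the proportion of signature
#' genes among the top 10/25/50 percent most variable genes genome-wide
#' (`prop_top_var`); and the skewness of the score distribution
#' (`skewness`).
#'
#' @param m expression matrix (genes x samples), at least 10 samples.
#' @param genes signature gene set (at least 2 present in `m`).
#' @return list of class `"qc_report"`.
#' @export
qc_metrics <- function(m, genes) {
  validate_expression_matrix(m)
  if (ncol(m) < 10L) stop("need at least 10 samples for QC metrics")
  genes <- intersect(unique(as.character(genes)), rownames(m))
  if (length(genes) < 2L) stop("need at least 2 signature genes present in the matrix")
  sub <- m[genes, , drop = FALSE]
  keep <- row_sds(sub) > 0
  sub <- sub[keep, , drop = FALSE]
  if (nrow(sub) < 2L) stop("fewer than 2 non-constant signature genes")

  cors <- cor(t(sub), method = "spearman")
  intra <- mean(cors[upper.tri(cors)])

  z <- (sub - rowMeans(sub)) / row_sds(sub)
  mean_expr <- colMeans(z)
  med_expr <- apply(z, 2L, median)
  rho_mm <- suppressWarnings(cor(mean_expr, med_expr, method = "spearman"))

  pc1 <- stats::prcomp(t(z), center = TRUE, scale. = FALSE)$x[, 1L]
  if (cor(pc1, mean_expr) < 0) pc1 <- -pc1
  rho_pc1 <- suppressWarnings(cor(mean_expr, pc1, method = "spearman"))

  score <- med_expr
  shifted <- shift_scores_positive(score)
  vr <- row_sds(m)^2
  top_prop <- vapply(c(`10` = 0.10, `25` = 0.25, `50` = 0.50), function(f) {
    thr <- quantile(vr, 1 - f, type = 7, names = FALSE)
    mean(vr[rownames(sub)] >= thr)
  }, numeric(1))

  structure(list(intra_sig_correlation = intra,
                 rho_mean_median = rho_mm,
                 rho_mean_pc1 = rho_pc1,
                 score_sd = sd(score),
                 score_cv = sd(shifted) / mean(shifted),
                 prop_top_var = top_prop,
                 skewness = skewness(score),
                 n_genes_used = nrow(sub)),
            class = "qc_report")
}

# Moment skewness (biased, as commonly reported for signature scores).
skewness <- function(x) {
  x <- x - mean(x)
  n <- length(x)
  (sum(x^3) / n) / (sum(x^2) / n)^1.5
}

#' Radar-area summary of normalized QC metrics
#'
#' Places `K >= 3` metrics, already normalized to \[0, 1\], on a radar
#' plot at angles `2 pi k / K` and returns the polygon area divided by
#' the area of the full regular polygon (all radii 1).  Invariant to
#' cyclic rotation of the metric order.
#'
#' @param metrics named numeric vector in \[0, 1\].
#' @param metric_order optional character vector giving the axis order
#'   (defaults to `names(metrics)`).
#' @return number in \[0, 1\].
#' @export
qc_area_score <- function(metrics, metric_order = names(metrics)) {
  r <- metrics[metric_order]
  if (length(r) < 3L) stop("need at least 3 metrics for a radar area")
  if (any(!is.finite(r)) || any(r < -1e-12) || any(r > 1 + 1e-12))
    stop("metrics must be normalized to [0, 1]")
  r <- pmin(pmax(as.numeric(r), 0), 1)
  sum(r * c(r[-1L], r[1L])) / length(r)
}

#' Normalize QC reports for radar comparison
#'
#' Maps each report's metrics to \[0, 1\]: correlations are clipped
#' below at 0; proportions pass through; `score_sd` and `score_cv`
#' (unbounded) are min-max scaled across the set of reports being
#' compared; skewness enters as `1 / (1 + |skewness|)` so that a
#' symmetric score distribution scores highest.  Returns one normalized
#' metric vector per report plus its radar-area summary.
#'
#' @param reports named list of `"qc_report"` objects.
#' @return data.frame, one row per report, with the normalized metrics
#'   and an `area_score` column.
#' @export
qc_compare <- function(reports) {
  stopifnot(length(reports) >= 1L, all(vapply(reports, inherits, logical(1), "qc_report")))
  sds <- vapply(reports, `[[`, numeric(1), "score_sd")
  cvs <- vapply(reports, `[[`, numeric(1), "score_cv")
  minmax <- function(x) if (diff(range(x)) == 0) rep(1, length(x)) else
    (x - min(x)) / diff(range(x))
  sds_n <- minmax(sds); cvs_n <- minmax(cvs)
  rows <- lapply(seq_along(reports), function(i) {
    r <- reports[[i]]
    v <- c(intra_sig_correlation = max(r$intra_sig_correlation, 0),
           rho_mean_median = max(r$rho_mean_median, 0),
           rho_mean_pc1 = max(r$rho_mean_pc1, 0),
           score_sd = sds_n[i], score_cv = cvs_n[i],
           prop_top_10 = r$prop_top_var[["10"]],
           prop_top_25 = r$prop_top_var[["25"]],
           prop_top_50 = r$prop_top_var[["50"]],
           symmetry = 1 / (1 + abs(r$skewness)))
    c(v, area_score = qc_area_score(v))
  })
  out <- as.data.frame(do.call(rbind, rows))
  rownames(out) <- names(reports)
  out
}
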