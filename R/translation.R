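# Clinical translation: disease-site ranking and concordance, mutation
# association, and the Cox panel-model workflow (variance filter,
# univariate screen, multivariate training, linear predictor, risk
# grouping by fixed or optimal cutpoints, KM comparison).

#' Rank disease sites by median shifted signature score
#'
#' Sites with fewer than `min_n` samples are dropped; the remaining
#' sites are ranked by the median of positively shifted scores (rank 1
#' = highest median), ties broken by site name.
#'
#' @param score named numeric vector of signature scores.
#' @param ann annotation data.frame with `sample_id` and
#'   `disease_site`.
#' @param min_n minimum samples per site (default 25 for clinical
#'   cohorts; use 0 for cell line panels).
#' @return data.frame with columns `site`, `n`, `median_score`,
#'   `rank`.
#' @export
rank_disease_sites <- function(score, ann, min_n = 25L) {
  ann <- validate_sample_annotations(ann)
  if (is.null(ann$disease_site)) stop("annotations need a disease_site column")
  ids <- intersect(names(score), ann$sample_id)
  if (!length(ids)) stop("no scored sample has an annotation")
  shifted <- shift_scores_positive(score[ids])
  site <- ann$disease_site[match(ids, ann$sample_id)]
  med <- tapply(shifted, site, median)
  n <- as.integer(table(site)[names(med)])
  keep <- n >= min_n
  if (!any(keep)) stop("no disease site reaches min_n = ", min_n)
  out <- data.frame(site = names(med)[keep], n = n[keep],
                    median_score = as.numeric(med[keep]),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$median_score, out$site), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Spearman concordance between two site rankings
#'
#' @param a,b data.frames from [rank_disease_sites()]; at least 3
#'   shared sites required.
#' @return list with `rho`, `p` (asymptotic) and `shared_sites`.
#' @export
rank_concordance <- function(a, b) {
  shared <- intersect(a$site, b$site)
  if (length(shared) < 3L) stop("need at least 3 shared sites")
  ra <- a$rank[match(shared, a$site)]
  rb <- b$rank[match(shared, b$site)]
  ct <- suppressWarnings(cor.test(ra, rb, method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value, shared_sites = shared)
}

#' Association between mutation status and signature score
#'
#' Samples are split into high/low halves at the median score (strictly
#' above the median = high).  For each gene, a 2x2 Pearson chi-square
#' test with continuity correction compares mutation presence between
#' the halves; genes mutated in none or all samples are untestable and
#' excluded from the Bonferroni correction factor.
#'
#' @param score named numeric vector of signature scores (>= 20
#'   samples).
#' @param ann annotation data.frame with logical mutation columns.
#' @param genes character vector naming the mutation columns to test.
#' @return data.frame with `gene`, `chi_square`, `p_raw`,
#'   `p_bonferroni` and `testable`.
#' @export
mutation_association <- function(score, ann, genes) {
  ann <- validate_sample_annotations(ann, mutation_cols = genes)
  ids <- intersect(names(score), ann$sample_id)
  if (length(ids) < 20L) stop("need at least 20 annotated, scored samples")
  high <- score[ids] > median(score[ids])
  rows <- lapply(genes, function(g) {
    mut <- ann[[g]][match(ids, ann$sample_id)]
    if (anyNA(mut)) stop("missing mutation calls for gene ", g)
    if (all(mut) || !any(mut))
      return(data.frame(gene = g, chi_square = NA_real_, p_raw = NA_real_,
                        testable = FALSE, stringsAsFactors = FALSE))
    ct <- suppressWarnings(chisq.test(table(high, mut), correct = TRUE))
    data.frame(gene = g, chi_square = unname(ct$statistic),
               p_raw = ct$p.value, testable = TRUE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  k <- sum(out$testable)
  out$p_bonferroni <- ifelse(out$testable, pmin(1, out$p_raw * k), NA_real_)
  out
}

#' Filter genes by expression variance
#'
#' Retains the genes whose sample variance (divisor n - 1) is at least
#' `threshold`; genes with variance strictly below it are removed.
#'
#' @param m expression matrix.
#' @param genes candidate gene set (subset of `rownames(m)`).
#' @param threshold variance threshold (default 0.2).
#' @return character vector of retained genes.
#' @export
variance_filter <- function(m, genes, threshold = 0.2) {
  validate_expression_matrix(m)
  genes <- unique(as.character(genes))
  missing <- setdiff(genes, rownames(m))
  if (length(missing))
    stop("gene(s) absent from matrix: ", paste(missing, collapse = ", "))
  v <- row_vars(m[genes, , drop = FALSE])
  out <- genes[v >= threshold]
  if (!length(out))
    stop("no gene passes the variance filter; review the threshold")
  out
}

# Assemble a survival data.frame (time, event) for a set of samples.
surv_frame <- function(ann, samples) {
  ann <- validate_sample_annotations(ann)
  if (is.null(ann$time_months) || is.null(ann$event))
    stop("annotations need time_months and event columns")
  i <- match(samples, ann$sample_id)
  if (anyNA(i)) stop("samples absent from annotations")
  data.frame(time = ann$time_months[i], event = as.integer(ann$event[i]),
             row.names = samples)
}

#' Univariate Cox screen of signature genes
#'
#' Fits a single-covariate proportional-hazards model (Efron ties) per
#' gene and retains the genes whose fitted coefficient is at most
#' `coef_threshold` (the default, 0.5, is a permissive magnitude rule
#' keeping protective and mildly hazardous genes alike).
#' `mode = "protective"` keeps only genes with a negative coefficient
#' (increased expression, improved survival).
#'
#' @param m expression matrix of the training cohort.
#' @param ann annotations with `time_months` and `event`; at least 10
#'   events required.
#' @param genes candidate genes.
#' @param coef_threshold coefficient ceiling (default 0.5).
#' @param mode `"verbatim"` (coefficient <= threshold) or
#'   `"protective"` (coefficient < 0).
#' @return character vector of retained genes, with the fitted
#'   coefficients as the `"coefficients"` attribute.
#' @export
univariate_cox_screen <- function(m, ann, genes, coef_threshold = 0.5,
                                  mode = c("verbatim", "protective")) {
  mode <- match.arg(mode)
  validate_expression_matrix(m)
  genes <- intersect(unique(as.character(genes)), rownames(m))
  sf <- surv_frame(ann, colnames(m))
  if (sum(sf$event) < 10L) stop("need at least 10 events for the screen")
  coefs <- vapply(genes, function(g) {
    fit <- tryCatch(
      survival::coxph(survival::Surv(sf$time, sf$event) ~ x,
                      data = data.frame(x = m[g, ]), ties = "efron"),
      warning = function(w) NULL, error = function(e) NULL)
    if (is.null(fit) || !is.finite(coef(fit)[1L])) NA_real_ else
      unname(coef(fit)[1L])
  }, numeric(1))
  if (anyNA(coefs))
    warning("dropping non-converging gene(s): ",
            paste(genes[is.na(coefs)], collapse = ", "))
  keep <- !is.na(coefs) &
    (if (mode == "protective") coefs < 0 else coefs <= coef_threshold)
  if (!any(keep)) stop("no gene retained by the univariate screen")
  structure(genes[keep], coefficients = coefs[keep])
}

#' Train a multivariate Cox panel model
#'
#' Joint proportional-hazards fit (Efron ties) over the screened genes.
#'
#' @param m expression matrix of the training cohort.
#' @param ann annotations with survival columns.
#' @param genes screened genes.
#' @param cohort_id label stored with the model.
#' @return list of class `"cox_panel_model"` with `genes`,
#'   `coefficients`, `se` and `cohort_id`.
#' @export
multivariate_cox_train <- function(m, ann, genes, cohort_id = "train") {
  validate_expression_matrix(m)
  genes <- unique(as.character(genes))
  if (!all(genes %in% rownames(m))) stop("model genes absent from matrix")
  sf <- surv_frame(ann, colnames(m))
  if (length(genes) >= sum(sf$event))
    warning("more genes than events; the fit may be unstable")
  X <- as.data.frame(t(m[genes, , drop = FALSE]))
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(sf$time, sf$event) ~ ., data = X,
                    ties = "efron"),
    warning = function(w) {
      if (grepl("converge|infinite|singular", conditionMessage(w)))
        stop("multivariate Cox fit degenerate: ", conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  b <- coef(fit)
  if (any(!is.finite(b))) stop("multivariate Cox fit produced non-finite coefficients")
  structure(list(genes = genes, coefficients = setNames(unname(b), genes),
                 se = setNames(sqrt(diag(fit$var)), genes),
                 cohort_id = cohort_id),
            class = "cox_panel_model")
}

#' Linear predictor (risk score) of a Cox panel model
#'
#' `eta_j = sum_g beta_g x_gj`; higher values mean higher predicted
#' hazard ("high risk").
#'
#' @param model a `"cox_panel_model"`.
#' @param m expression matrix of the cohort to score (duplicate gene
#'   rows collapsed beforehand).
#' @return named numeric vector of risk scores.
#' @export
linear_predictor <- function(model, m) {
  stopifnot(inherits(model, "cox_panel_model"))
  validate_expression_matrix(m)
  missing <- setdiff(model$genes, rownames(m))
  if (length(missing))
    stop("model gene(s) absent from matrix: ", paste(missing, collapse = ", "))
  drop(crossprod(m[model$genes, , drop = FALSE], model$coefficients))[colnames(m)]
}

#' Optimal log-rank cutpoints on a risk score
#'
#' Exhaustive search over midpoints between consecutive sorted unique
#' risk scores (single cut) or ordered midpoint pairs (double cut),
#' keeping only splits where every group has at least `min_group`
#' samples, and maximising the log-rank chi-square across the
#' resulting k+1 groups.  Objective ties are broken by the lowest
#' cutpoint(s).
#'
#' @param risk named numeric risk scores.
#' @param ann annotations with survival columns.
#' @param k number of cutpoints, 1 or 2.
#' @param min_group minimum group size (default 4).
#' @return list of class `"cutpoint_result"` with `cutpoints`,
#'   `group_sizes`, `chi_square`, `p` and `groups` (named factor).
#' @export
optimal_cutpoints <- function(risk, ann, k = 1L, min_group = 4L) {
  stopifnot(k %in% c(1L, 2L))
  n <- length(risk)
  if (n < (k + 1L) * min_group)
    stop("need at least ", (k + 1L) * min_group, " samples for k = ", k)
  sf <- surv_frame(ann, names(risk))
  s <- sort(unique(risk))
  if (length(s) < 2L) stop("constant risk scores; no feasible cutpoint")
  mids <- (s[-1L] + s[-length(s)]) / 2

  eval_split <- function(cuts) {
    grp <- cut(risk, breaks = c(-Inf, cuts, Inf), labels = FALSE)
    sizes <- tabulate(grp, nbins = length(cuts) + 1L)
    if (any(sizes < min_group)) return(NULL)
    sd <- survival::survdiff(survival::Surv(sf$time, sf$event) ~ grp)
    list(chisq = sd$chisq, sizes = sizes)
  }

  best <- NULL
  if (k == 1L) {
    for (c1 in mids) {
      r <- eval_split(c1)
      if (!is.null(r) && (is.null(best) || r$chisq > best$chisq + 1e-12))
        best <- c(r, list(cuts = c1))
    }
  } else {
    nm <- length(mids)
    for (i in seq_len(nm - 1L)) for (j in seq.int(i + 1L, nm)) {
      r <- eval_split(c(mids[i], mids[j]))
      if (!is.null(r) && (is.null(best) || r$chisq > best$chisq + 1e-12))
        best <- c(r, list(cuts = c(mids[i], mids[j])))
    }
  }
  if (is.null(best)) stop("no feasible cutpoint satisfies the group-size constraint")
  df <- k
  grp <- cut(risk, breaks = c(-Inf, best$cuts, Inf),
             labels = c("low", if (k == 2L) "middle", "high"))
  names(grp) <- names(risk)
  structure(list(cutpoints = best$cuts, group_sizes = best$sizes,
                 chi_square = best$chisq,
                 p = pchisq(best$chisq, df = df, lower.tail = FALSE),
                 groups = grp),
            class = "cutpoint_result")
}

#' Fixed risk-group splits (median or tertiles)
#'
#' @param risk named numeric risk scores.
#' @param method `"median"` (two groups) or `"tertile"` (three).
#' @return named factor of group labels (`low` < (`middle`) < `high`).
#' @export
risk_groups <- function(risk, method = c("median", "tertile")) {
  method <- match.arg(method)
  if (method == "median") {
    cuts <- median(risk)
    labs <- c("low", "high")
  } else {
    cuts <- quantile(risk, c(1 / 3, 2 / 3), type = 7, names = FALSE)
    labs <- c("low", "middle", "high")
  }
  grp <- cut(risk, breaks = c(-Inf, cuts, Inf), labels = labs)
  names(grp) <- names(risk)
  grp
}

#' Kaplan-Meier comparison of risk groups
#'
#' Standard KM curves with right censoring per group, plus the
#' log-rank test across groups.
#'
#' @param groups named factor of group labels.
#' @param ann annotations with survival columns.
#' @return list with `curves` (data.frame: group, time, surv, n_risk),
#'   `chi_square`, `df`, `p`.
#' @export
km_compare <- function(groups, ann) {
  if (is.null(names(groups))) stop("groups must be named by sample id")
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2L) stop("need at least 2 non-empty groups")
  sf <- surv_frame(ann, names(groups))
  fit <- survival::survfit(survival::Surv(sf$time, sf$event) ~ groups)
  strata <- rep(names(fit$strata), fit$strata)
  curves <- data.frame(group = sub("^groups=", "", strata),
                       time = fit$time, surv = fit$surv,
                       n_risk = fit$n.risk, stringsAsFactors = FALSE)
  sd <- survival::survdiff(survival::Surv(sf$time, sf$event) ~ groups)
  df <- nlevels(groups) - 1L
  list(curves = curves, chi_square = sd$chisq, df = df,
       p = pchisq(sd$chisq, df = df, lower.tail = FALSE))
}
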