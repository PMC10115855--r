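# Cell line persistence curves: Kaplan-Meier estimates that use IC50 in
# lieu of survival time (a line "persists" at concentrations below its
# IC50; every observation is an event), plus log-rank comparison,
# Cox hazard ratios, and the random-signature null engine.

#' Cell line persistence curve
#'
#' Kaplan-Meier estimate over IC50 with every observation an event;
#' with no censoring the curve equals one minus the empirical CDF of
#' IC50.  The median persistence is the smallest IC50 at which the
#' curve drops to 0.5 or below.
#'
#' @param resp drug-response data.frame (`sample_id`, `ic50`).
#' @param cohort character vector of sample ids (subset of `resp`).
#' @param label cohort label carried into the result.
#' @return list of class `"persistence_curve"` with `event_times`
#'   (sorted unique IC50), `survival_prob`, `n_at_risk`, `median` and
#'   `cohort_label`.
#' @export
persistence_curve <- function(resp, cohort, label = "cohort") {
  resp <- validate_drug_response(resp)
  cohort <- as.character(cohort)
  if (!length(cohort)) stop("empty cohort")
  missing <- setdiff(cohort, resp$sample_id)
  if (length(missing))
    stop("cohort samples absent from response table: ",
         paste(head(missing, 5L), collapse = ", "))
  ic50 <- resp$ic50[match(cohort, resp$sample_id)]
  fit <- survival::survfit(survival::Surv(ic50, rep(1L, length(ic50))) ~ 1)
  med <- fit$time[which(fit$surv <= 0.5)[1L]]
  structure(list(event_times = fit$time, survival_prob = fit$surv,
                 n_at_risk = fit$n.risk, median = med,
                 cohort_label = label, n = length(ic50)),
            class = "persistence_curve")
}

#' Log-rank test between two persistence cohorts
#'
#' Standard two-group log-rank statistic over the pooled IC50 "event"
#' times (hypergeometric variance for ties), with the p-value from a
#' chi-square distribution on one degree of freedom.
#'
#' @param resp drug-response data.frame.
#' @param cohort_a,cohort_b disjoint non-empty character vectors of
#'   sample ids.
#' @return list with `chi_square`, `df` and `p`.
#' @export
logrank_test <- function(resp, cohort_a, cohort_b) {
  resp <- validate_drug_response(resp)
  cohort_a <- as.character(cohort_a); cohort_b <- as.character(cohort_b)
  if (!length(cohort_a) || !length(cohort_b)) stop("cohorts must be non-empty")
  if (length(intersect(cohort_a, cohort_b))) stop("cohorts must be disjoint")
  ids <- c(cohort_a, cohort_b)
  ic50 <- resp$ic50[match(ids, resp$sample_id)]
  if (anyNA(ic50)) stop("cohort samples absent from response table")
  grp <- rep(c("a", "b"), c(length(cohort_a), length(cohort_b)))
  sd <- survival::survdiff(survival::Surv(ic50, rep(1L, length(ic50))) ~ grp)
  df <- length(sd$n) - 1L
  list(chi_square = sd$chisq, df = df,
       p = pchisq(sd$chisq, df = df, lower.tail = FALSE))
}

#' Hazard ratio between high- and low-score cohorts
#'
#' Proportional-hazards fit (Efron ties) with a single indicator for
#' the high-score cohort, IC50 as the time scale and every observation
#' an event.  A hazard ratio above 1 means the high-score lines reach
#' their IC50 at lower concentrations, i.e. are more sensitive.
#'
#' @param resp drug-response data.frame.
#' @param cohort_high,cohort_low disjoint character vectors of sample
#'   ids, each with at least 5 samples.
#' @return the hazard ratio (numeric scalar) with the fitted
#'   coefficient and its standard error as attributes.
#' @export
cohort_hazard_ratio <- function(resp, cohort_high, cohort_low) {
  resp <- validate_drug_response(resp)
  cohort_high <- as.character(cohort_high); cohort_low <- as.character(cohort_low)
  if (length(cohort_high) < 5L || length(cohort_low) < 5L)
    stop("each cohort needs at least 5 samples")
  if (length(intersect(cohort_high, cohort_low))) stop("cohorts must be disjoint")
  ids <- c(cohort_high, cohort_low)
  ic50 <- resp$ic50[match(ids, resp$sample_id)]
  if (anyNA(ic50)) stop("cohort samples absent from response table")
  high <- rep(c(1L, 0L), c(length(cohort_high), length(cohort_low)))
  note <- NULL
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(ic50, rep(1L, length(ic50))) ~ high,
                    ties = "efron"),
    warning = function(w) {
      note <<- conditionMessage(w)
      invokeRestart("muffleWarning")
    })
  b <- unname(coef(fit))
  if (!is.finite(b) || abs(b) > 15)
    stop("hazard-ratio fit degenerate (complete separation?): ",
         if (is.null(note)) "" else note)
  structure(exp(b), coef = b, se = sqrt(unname(fit$var[1L, 1L])),
            note = note)
}

#' Draw random signatures from a gene universe
#'
#' `n` signatures, each a uniform without-replacement sample of
#' `length` genes; deterministic given `seed`.
#'
#' @param universe character vector of gene ids.
#' @param length signature length.
#' @param n number of signatures.
#' @param seed RNG seed.
#' @return list of character vectors.
#' @export
sample_null_signatures <- function(universe, length, n, seed = 1L) {
  universe <- as.character(universe)
  if (length > base::length(universe)) stop("signature longer than the universe")
  if (n < 1L) stop("n must be >= 1")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  lapply(seq_len(n), function(i) sample(universe, length))
}

#' Evaluate a signature against a random-signature null distribution
#'
#' Applies `metric_fn` to every null signature and to the observed
#' signature.  Evaluations returning `NA`/`NaN` (degenerate models,
#' e.g. constant predictions) are dropped and counted.  The percentile
#' of the observed value uses strict "less than", so null ties count
#' against the observed signature.
#'
#' @param metric_fn function taking a character vector of genes and
#'   returning a single number (or `NA` when degenerate).
#' @param nulls list of character vectors (see
#'   [sample_null_signatures()]).
#' @param observed_signature character vector of genes.
#' @return list of class `"null_distribution"` with `values`,
#'   `n_requested`, `n_degenerate`, `observed` and
#'   `percentile_of_observed` (in \[0, 100\]).
#' @export
build_null_distribution <- function(metric_fn, nulls, observed_signature) {
  vals <- vapply(nulls, function(g) {
    v <- tryCatch(metric_fn(g), error = function(e) NA_real_)
    if (is.null(v) || !is.finite(v)) NA_real_ else as.numeric(v)
  }, numeric(1))
  n_requested <- length(vals)
  keep <- is.finite(vals)
  if (!any(keep)) stop("all null evaluations were degenerate")
  vals <- vals[keep]
  obs <- metric_fn(observed_signature)
  if (!is.finite(obs)) stop("observed signature evaluation is degenerate")
  structure(list(values = vals,
                 n_requested = n_requested,
                 n_degenerate = n_requested - length(vals),
                 observed = as.numeric(obs),
                 percentile_of_observed = 100 * mean(vals < obs)),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat("Null distribution:", length(x$values), "values (",
      x$n_degenerate, "degenerate dropped )\n")
  cat("observed =", signif(x$observed, 4L),
      "-> percentile", round(x$percentile_of_observed, 1L), "\n")
  invisible(x)
}
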