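# IC50 prediction suite: continuous (Spearman rho) and binary (ROC AUC)
# outcomes from either the signature score (single covariate) or
# per-gene expression, with outer 5-fold CV and best-of-folds
# reporting.  Penalized models tune lambda by inner 10-fold CV; SVMs
# tune cost/gamma(/degree) by grid search; random forests grow 500
# trees.

#' Specify a prediction model
#'
#' @param input_kind `"score"` (the signature score as single
#'   covariate) or `"per_gene"` (z-scored expression of each signature
#'   gene).
#' @param outcome `"continuous_ic50"` or `"binary_ic50"` (above /
#'   below the group median).
#' @param method one of `"linear"`, `"logistic"`, `"elastic_net"`,
#'   `"l1"`, `"l2"`, `"svm_linear"`, `"svm_poly"`, `"random_forest"`.
#'   Penalized, SVM and random-forest methods require per-gene input;
#'   `"linear"` requires a continuous outcome and `"logistic"`,
#'   SVMs and random forests a binary one.
#' @param subset `"all"` samples or `"quintiles"` (top and bottom
#'   quintile of signature score).
#' @param n_folds_outer outer CV folds (default 5).
#' @param n_folds_inner inner tuning folds (default 10).
#' @param svm_cost,svm_gamma,svm_degree SVM tuning grids.
#' @param n_trees random-forest size (default 500).
#' @param seed RNG seed for fold assignment and stochastic learners.
#' @return list of class `"model_spec"`.
#' @export
model_spec <- function(input_kind = c("score", "per_gene"),
                       outcome = c("continuous_ic50", "binary_ic50"),
                       method = c("linear", "logistic", "elastic_net", "l1",
                                  "l2", "svm_linear", "svm_poly",
                                  "random_forest"),
                       subset = c("all", "quintiles"),
                       n_folds_outer = 5L, n_folds_inner = 10L,
                       svm_cost = 10^(-3:3), svm_gamma = 10^(-3:3),
                       svm_degree = 3:5, n_trees = 500L,
                       seed = 1L) {
  spec <- list(input_kind = match.arg(input_kind),
               outcome = match.arg(outcome),
               method = match.arg(method),
               subset = match.arg(subset),
               n_folds_outer = as.integer(n_folds_outer),
               n_folds_inner = as.integer(n_folds_inner),
               svm_cost = svm_cost, svm_gamma = svm_gamma,
               svm_degree = as.integer(svm_degree),
               n_trees = as.integer(n_trees), seed = as.integer(seed))
  penalized <- c("elastic_net", "l1", "l2")
  ml <- c("svm_linear", "svm_poly", "random_forest")
  if (spec$method == "linear" && spec$outcome != "continuous_ic50")
    stop("linear regression predicts the continuous outcome")
  if (spec$method %in% c("logistic", ml) && spec$outcome != "binary_ic50")
    stop(spec$method, " predicts the binary outcome")
  if (spec$method %in% c(penalized, ml) && spec$input_kind != "per_gene")
    stop(spec$method, " uses per-gene expression input")
  class(spec) <- "model_spec"
  spec
}

#' Binary IC50 outcome (above the group median)
#'
#' Labels a sample 1 when its IC50 is strictly above the median of the
#' included group; samples at exactly the median are labelled 0.
#'
#' @param resp drug-response data.frame.
#' @param samples character vector of included sample ids (default:
#'   all).
#' @return named integer vector of 0/1 labels.
#' @export
make_binary_outcome <- function(resp, samples = resp$sample_id) {
  resp <- validate_drug_response(resp)
  samples <- as.character(samples)
  if (length(samples) < 4L) stop("need at least 4 samples")
  ic50 <- resp$ic50[match(samples, resp$sample_id)]
  if (anyNA(ic50)) stop("samples absent from response table")
  if (diff(range(ic50)) == 0) stop("all IC50 values identical; no median split")
  setNames(as.integer(ic50 > median(ic50)), samples)
}

#' Top- and bottom-quintile samples by signature score
#'
#' Union of the `floor(n/5)` lowest-score and `floor(n/5)`
#' highest-score samples; ties are broken by sample id (the low tail
#' keeps the lexicographically smallest ids, the high tail the
#' largest, so the two tails never overlap).
#'
#' @param score named numeric vector of signature scores (>= 10
#'   samples).
#' @return character vector of sample ids.
#' @export
quintile_subset <- function(score) {
  n <- length(score)
  if (n < 10L) stop("need at least 10 samples for quintile subsetting")
  if (is.null(names(score))) stop("scores must be named by sample id")
  if (diff(range(score)) == 0)
    warning("constant scores; quintile selection is lexicographic only")
  k <- floor(n / 5)
  ord <- order(score, names(score))
  c(names(score)[ord[seq_len(k)]], names(score)[ord[seq.int(n - k + 1L, n)]])
}

#' Fit a prediction model with outer cross-validation
#'
#' Runs the model described by `spec` under outer
#' `n_folds_outer`-fold cross-validation (80/20 at the default).
#' Score-input models use the signature score computed on the full
#' included set as the single covariate; per-gene models use the
#' expression of each signature gene, z-scored with means/SDs fitted
#' on the training fold only.  The per-fold metric is the Spearman
#' correlation between predicted and observed IC50 (continuous
#' outcome) or the ROC AUC (binary outcome) on the held-out fold;
#' `best_metric` is the maximum across folds (mean and SD are also
#' reported).
#'
#' @param spec a [model_spec()].
#' @param m expression matrix (genes x samples).
#' @param resp drug-response data.frame covering the samples of `m`.
#' @param genes signature gene set.
#' @return list of class `"model_result"` with `per_fold_metric`,
#'   `best_metric`, `mean_metric`, `sd_metric`, `metric_name`,
#'   `n_train`, `n_test`, `samples_used` and `spec`.
#' @export
fit_predict_cv <- function(spec, m, resp, genes) {
  stopifnot(inherits(spec, "model_spec"))
  validate_expression_matrix(m)
  resp <- validate_drug_response(resp)
  genes <- intersect(unique(as.character(genes)), rownames(m))
  if (!length(genes)) stop("no signature gene present in the matrix")
  samples <- intersect(colnames(m), resp$sample_id)
  score <- signature_score(m[, samples, drop = FALSE], genes)
  if (spec$subset == "quintiles") samples <- quintile_subset(score)

  ic50 <- setNames(resp$ic50[match(samples, resp$sample_id)], samples)
  y <- if (spec$outcome == "binary_ic50") make_binary_outcome(resp, samples) else ic50
  X <- if (spec$input_kind == "score")
    matrix(score[samples], ncol = 1L, dimnames = list(samples, "score"))
  else t(m[genes, samples, drop = FALSE])

  folds <- split_folds(samples, spec$n_folds_outer, seed = spec$seed)
  metric_name <- if (spec$outcome == "binary_ic50") "auc" else "spearman_rho"
  per_fold <- rep(NA_real_, spec$n_folds_outer)
  n_train <- n_test <- integer(spec$n_folds_outer)
  for (k in seq_len(spec$n_folds_outer)) {
    train <- folds$retained_per_fold[[k]]
    test <- setdiff(samples, train)
    n_train[k] <- length(train); n_test[k] <- length(test)
    if (spec$outcome == "binary_ic50" &&
        (length(unique(y[train])) < 2L || length(unique(y[test])) < 2L)) {
      warning("fold ", k, " degenerate (single class); skipped")
      next
    }
    # per-feature standardization fitted on the training fold
    mu <- colMeans(X[train, , drop = FALSE])
    sg <- apply(X[train, , drop = FALSE], 2L, sd)
    sg[sg == 0] <- 1
    Xtr <- sweep(sweep(X[train, , drop = FALSE], 2L, mu), 2L, sg, "/")
    Xte <- sweep(sweep(X[test, , drop = FALSE], 2L, mu), 2L, sg, "/")
    pred <- fit_one_model(spec, Xtr, y[train], Xte)
    per_fold[k] <- if (metric_name == "auc") {
      roc_auc(y[test], pred)
    } else if (sd(pred) == 0 || sd(y[test]) == 0) NA_real_ else
      suppressWarnings(cor(pred, y[test], method = "spearman"))
  }
  if (all(is.na(per_fold))) stop("all outer folds degenerate")
  structure(list(per_fold_metric = per_fold,
                 best_metric = max(per_fold, na.rm = TRUE),
                 mean_metric = mean(per_fold, na.rm = TRUE),
                 sd_metric = sd(per_fold[!is.na(per_fold)]),
                 metric_name = metric_name,
                 n_train = n_train, n_test = n_test,
                 samples_used = samples, spec = spec),
            class = "model_result")
}

# Train on (Xtr, ytr), return a numeric prediction (or decision score,
# for classifiers) for Xte.
fit_one_model <- function(spec, Xtr, ytr, Xte) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(spec$seed + 17L)
  switch(spec$method,
    linear = {
      df <- data.frame(y = ytr, Xtr)
      unname(predict(lm(y ~ ., data = df), newdata = data.frame(Xte)))
    },
    logistic = {
      df <- data.frame(y = ytr, Xtr)
      unname(predict(glm(y ~ ., data = df, family = binomial()),
                     newdata = data.frame(Xte), type = "link"))
    },
    elastic_net = glmnet_predict(Xtr, ytr, Xte, alpha = 0.5, spec),
    l1 = glmnet_predict(Xtr, ytr, Xte, alpha = 1, spec),
    l2 = glmnet_predict(Xtr, ytr, Xte, alpha = 0, spec),
    svm_linear = svm_predict(Xtr, ytr, Xte, kernel = "linear", spec),
    svm_poly = svm_predict(Xtr, ytr, Xte, kernel = "polynomial", spec),
    random_forest = {
      fit <- randomForest::randomForest(
        x = Xtr, y = factor(ytr, levels = c(0, 1)), ntree = spec$n_trees)
      unname(predict(fit, Xte, type = "prob")[, "1"])
    })
}

glmnet_predict <- function(Xtr, ytr, Xte, alpha, spec) {
  family <- if (spec$outcome == "binary_ic50") "binomial" else "gaussian"
  type_meas <- if (family == "binomial") "class" else "mse"
  cv <- glmnet::cv.glmnet(Xtr, ytr, alpha = alpha, family = family,
                          nfolds = spec$n_folds_inner,
                          type.measure = type_meas)
  as.numeric(predict(cv, Xte, s = "lambda.min", type = "link"))
}

svm_predict <- function(Xtr, ytr, Xte, kernel, spec) {
  ranges <- list(cost = spec$svm_cost, gamma = spec$svm_gamma)
  if (kernel == "polynomial") ranges$degree <- spec$svm_degree
  tn <- e1071::tune(e1071::svm, train.x = Xtr,
                    train.y = factor(ytr, levels = c(0, 1)),
                    kernel = kernel, ranges = ranges,
                    tunecontrol = e1071::tune.control(
                      cross = min(spec$n_folds_inner, nrow(Xtr))))
  fit <- tn$best.model
  as.numeric(attr(predict(fit, Xte, decision.values = TRUE),
                  "decision.values"))
}

# Rank-based ROC AUC with orientation fixed so that higher predictor
# values indicate the positive class.
roc_auc <- function(truth, score) {
  r <- pROC::roc(response = truth, predictor = as.numeric(score),
                 levels = c(0, 1), direction = "<", quiet = TRUE)
  as.numeric(pROC::auc(r))
}

#' Run the full model suite
#'
#' Convenience wrapper fitting the standard battery of model
#' specifications (score-input simple regression plus per-gene
#' penalized, SVM and random-forest models, each on all samples and on
#' the score quintiles).
#'
#' @param m expression matrix.
#' @param resp drug-response data.frame.
#' @param genes signature gene set.
#' @param methods subset of methods to run (default: all).
#' @param seed RNG seed shared by all specs.
#' @param ... passed to [model_spec()] (e.g. reduced SVM grids).
#' @return data.frame with one row per spec: input, outcome, method,
#'   subset, metric, best, mean, sd.
#' @export
run_model_suite <- function(m, resp, genes,
                            methods = c("linear", "elastic_net", "l1", "l2",
                                        "logistic", "svm_linear", "svm_poly",
                                        "random_forest"),
                            seed = 1L, ...) {
  specs <- list()
  for (meth in methods) {
    input <- if (meth %in% c("linear", "logistic")) "score" else "per_gene"
    outcome <- if (meth == "linear") "continuous_ic50" else
      if (meth %in% c("elastic_net", "l1", "l2")) "continuous_ic50" else "binary_ic50"
    for (sub in c("all", "quintiles"))
      specs[[length(specs) + 1L]] <-
        model_spec(input_kind = input, outcome = outcome, method = meth,
                   subset = sub, seed = seed, ...)
    if (meth %in% c("elastic_net", "l1", "l2"))   # binary variants too
      for (sub in c("all", "quintiles"))
        specs[[length(specs) + 1L]] <-
          model_spec(input_kind = "per_gene", outcome = "binary_ic50",
                     method = meth, subset = sub, seed = seed, ...)
  }
  rows <- lapply(specs, function(sp) {
    res <- fit_predict_cv(sp, m, resp, genes)
    data.frame(input = sp$input_kind, outcome = sp$outcome,
               method = sp$method, subset = sp$subset,
               metric = res$metric_name, best = res$best_metric,
               mean = res$mean_metric, sd = res$sd_metric,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
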