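# Synthetic study generator.  A latent per-line sensitivity u drives both
# a planted "sensitivity program" (a co-expressed gene block whose
# expression rises with u) and IC50 (which falls with u), so that higher
# program expression marks the drug-sensitive state.  A companion
# clinical cohort shares the program's co-expression structure, and its
# treated arm carries a survival benefit that scales with signature
# score.

#' Synthetic study configuration
#'
#' Parameters of the synthetic cell line panel and clinical cohort.
#' Defaults describe the study conditions used throughout the test
#' suite: a 250-line, 2000-gene panel with a 25-gene sensitivity
#' program whose loading is 2 expression SD units per latent unit.
#'
#' @param n_lines number of cell lines in the panel.
#' @param n_genes total genes in the universe.
#' @param n_program_genes size of the planted sensitivity program.
#' @param program_effect loading (expression SD units) of program genes
#'   on the latent sensitivity.
#' @param ic50_noise_sd SD of the IC50 measurement noise (log2 uM).
#' @param n_blocks number of background co-expression blocks.
#' @param block_rho pairwise correlation within a background block.
#' @param n_clinical number of clinical samples.
#' @param n_sites number of disease sites.
#' @param site_shift_sd SD of the per-site global expression shift.
#' @param surv_baseline_hazard baseline event hazard (per month).
#' @param surv_effect log-hazard decrease per unit signature score in
#'   the treated arm.
#' @param censor_rate probability that a record is censored.
#' @param mutation_rate background mutation probability per gene.
#' @param n_mutation_genes number of mutation-call genes in the
#'   annotations (the first one is a score-linked positive control).
#' @param seed RNG seed; the gene universe, block structure and program
#'   membership are derived deterministically from it.
#' @return a list of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_lines = 250L,
                             n_genes = 2000L,
                             n_program_genes = 25L,
                             program_effect = 2,
                             ic50_noise_sd = 0.5,
                             n_blocks = 10L,
                             block_rho = 0.5,
                             n_clinical = 300L,
                             n_sites = 6L,
                             site_shift_sd = 0.3,
                             surv_baseline_hazard = 0.05,
                             surv_effect = 1,
                             censor_rate = 0.3,
                             mutation_rate = 0.2,
                             n_mutation_genes = 12L,
                             seed = 1L) {
  cfg <- list(n_lines = as.integer(n_lines), n_genes = as.integer(n_genes),
              n_program_genes = as.integer(n_program_genes),
              program_effect = program_effect, ic50_noise_sd = ic50_noise_sd,
              n_blocks = as.integer(n_blocks), block_rho = block_rho,
              n_clinical = as.integer(n_clinical), n_sites = as.integer(n_sites),
              site_shift_sd = site_shift_sd,
              surv_baseline_hazard = surv_baseline_hazard,
              surv_effect = surv_effect, censor_rate = censor_rate,
              mutation_rate = mutation_rate,
              n_mutation_genes = as.integer(n_mutation_genes),
              seed = as.integer(seed))
  class(cfg) <- "synthetic_config"
  validate_synthetic_config(cfg)
}

validate_synthetic_config <- function(cfg) {
  stopifnot(cfg$n_program_genes < cfg$n_genes,
            cfg$n_program_genes >= 0L,
            cfg$n_lines >= 4L, cfg$n_genes >= 10L,
            cfg$block_rho >= 0, cfg$block_rho < 1,
              cfg$censor_rate >= 0, cfg$censor_rate < 1,
            cfg$mutation_rate > 0, cfg$mutation_rate < 1,
            cfg$surv_baseline_hazard > 0,
            cfg$ic50_noise_sd >= 0, cfg$site_shift_sd >= 0)
  cfg
}

# Shared structural layer (gene universe, program membership, block
# assignment, per-gene baselines, per-site shifts), deterministic in
# cfg$seed so the panel and the cohort agree on it.
synth_structure <- function(cfg) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)
  gene_ids <- sprintf("g%04d", seq_len(cfg$n_genes))
  program <- sort(sample(gene_ids, cfg$n_program_genes))
  background <- setdiff(gene_ids, program)
  block <- setNames(rep_len(seq_len(cfg$n_blocks), length(background)),
                    sample(background))
  baseline <- setNames(rnorm(cfg$n_genes, mean = 7, sd = 1), gene_ids)
  sites <- sprintf("site_%02d", seq_len(cfg$n_sites))
  site_shift <- setNames(rnorm(cfg$n_sites, 0, cfg$site_shift_sd), sites)
  list(gene_ids = gene_ids, program = program, block = block,
       baseline = baseline, sites = sites, site_shift = site_shift)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

# Draw a genes x samples expression matrix given latent score `lat`
# (length = samples) and the structural layer.
synth_expression <- function(cfg, st, lat, site) {
  n <- length(lat)
  m <- matrix(rnorm(cfg$n_genes * n), cfg$n_genes, n,
              dimnames = list(st$gene_ids, names(lat)))
  # program genes load on the latent sensitivity
  if (length(st$program))
    m[st$program, ] <- cfg$program_effect * rep(lat, each = length(st$program)) +
      m[st$program, , drop = FALSE]
  # background blocks are equicorrelated (single factor per block)
  f <- matrix(rnorm(cfg$n_blocks * n), cfg$n_blocks, n)
  bg <- names(st$block)
  if (length(bg)) {
    rho <- cfg$block_rho
    m[bg, ] <- sqrt(rho) * f[st$block, , drop = FALSE] +
      sqrt(1 - rho) * m[bg, , drop = FALSE]
  }
  m <- m + st$baseline[rownames(m)]
  m <- m + rep(st$site_shift[site], each = nrow(m))
  m
}

synth_mutations <- function(cfg, lat) {
  n <- length(lat)
  genes <- sprintf("mut%02d", seq_len(cfg$n_mutation_genes))
  mut <- matrix(rbinom(cfg$n_mutation_genes * n, 1L, cfg$mutation_rate) == 1L,
                nrow = n, ncol = cfg$n_mutation_genes, byrow = TRUE,
                dimnames = list(names(lat), genes))
  # the first mutation gene is a positive control tied to the latent score
  mut[, 1L] <- runif(n) < plogis(qlogis(cfg$mutation_rate) + 1.5 * lat)
  as.data.frame(mut)
}

#' Simulate a cell line panel with a planted sensitivity program
#'
#' Each line draws a latent sensitivity `u ~ N(0, 1)`.  IC50 (log2 uM)
#' is `4 - 2 u + noise`, so high-`u` lines are sensitive; program genes
#' load positively on `u`, so high program expression marks the
#' sensitive state.  Background genes fall into equicorrelated blocks
#' independent of `u`.
#'
#' @param cfg a [synthetic_config()].
#' @return list with `expr` (genes x lines matrix), `response`
#'   (drug-response data.frame with `sample_id`, `ic50`, `auc`),
#'   `annotations` (data.frame with `sample_id`, `disease_site`),
#'   `program_genes` (character, ground truth) and `latent` (named
#'   numeric `u`).
#' @export
simulate_cellline_panel <- function(cfg = synthetic_config()) {
  validate_synthetic_config(cfg)
  st <- synth_structure(cfg)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed + 1000L)
  ids <- sprintf("line_%03d", seq_len(cfg$n_lines))
  u <- setNames(rnorm(cfg$n_lines), ids)
  site <- sample(st$sites, cfg$n_lines, replace = TRUE)
  ic50 <- 4 - 2 * u + rnorm(cfg$n_lines, 0, cfg$ic50_noise_sd)
  # AUC: monotone-decreasing transform of sensitivity, in [0, 1]
  auc <- plogis((ic50 - 4) / 2 + rnorm(cfg$n_lines, 0, 0.15))
  expr <- synth_expression(cfg, st, u, site)
  list(expr = expr,
       response = data.frame(sample_id = ids, ic50 = ic50, auc = auc,
                             stringsAsFactors = FALSE),
       annotations = data.frame(sample_id = ids, disease_site = site,
                                stringsAsFactors = FALSE),
       program_genes = st$program,
       latent = u)
}

#' Simulate a clinical cohort sharing the panel's co-expression program
#'
#' Clinical samples draw a latent `v ~ N(0, 1)`; the supplied program
#' genes load on `v` with the panel's loading, so they are mutually
#' co-expressed in the cohort.  Half the patients are flagged treated;
#' treated patients' event times are exponential with hazard
#' `h0 * exp(-surv_effect * score)` where `score` is the median
#' z-scored program-gene expression, while untreated hazards ignore the
#' score.  Censoring is independent at rate `censor_rate`.  Mutation
#' calls are Bernoulli, except the first mutation gene, whose
#' probability increases with `v` (positive control).
#'
#' @param cfg a [synthetic_config()].
#' @param program_genes character vector of program genes (defaults to
#'   the configuration's own planted program); must be non-empty and a
#'   subset of the gene universe.
#' @param cohort_seed optional separate seed for the cohort draw; the
#'   gene universe, program and block structure still come from
#'   `cfg$seed`, so two calls with different `cohort_seed` values give
#'   independent cohorts over the same genes (e.g. a training and a
#'   testing cohort).
#' @return list with `expr`, `annotations` (including `treated`,
#'   `time_months`, `event`, `disease_site` and mutation columns),
#'   `latent` (`v`) and `score` (the true signature score used for the
#'   hazard).
#' @export
simulate_clinical_cohort <- function(cfg = synthetic_config(),
                                     program_genes = NULL,
                                     cohort_seed = NULL) {
  validate_synthetic_config(cfg)
  st <- synth_structure(cfg)
  if (is.null(program_genes)) program_genes <- st$program
  if (!length(program_genes)) stop("program gene set must be non-empty")
  if (!all(program_genes %in% st$gene_ids))
    stop("program genes outside the simulated gene universe: ",
         paste(setdiff(program_genes, st$gene_ids), collapse = ", "))
  st$program <- program_genes
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(if (is.null(cohort_seed)) cfg$seed + 2000L else as.integer(cohort_seed))
  ids <- sprintf("pt_%04d", seq_len(cfg$n_clinical))
  v <- setNames(rnorm(cfg$n_clinical), ids)
  site <- sample(st$sites, cfg$n_clinical, replace = TRUE)
  expr <- synth_expression(cfg, st, v, site)
  score <- apply(zscore_by_gene(expr)[program_genes, , drop = FALSE], 2L, median)
  treated <- runif(cfg$n_clinical) < 0.5
  haz <- ifelse(treated,
                cfg$surv_baseline_hazard * exp(-cfg$surv_effect * score),
                cfg$surv_baseline_hazard)
  t_event <- rexp(cfg$n_clinical, rate = haz)
  censored <- runif(cfg$n_clinical) < cfg$censor_rate
  time <- ifelse(censored, runif(cfg$n_clinical, 0, t_event), t_event)
  ann <- data.frame(sample_id = ids, disease_site = site, treated = treated,
                    time_months = time, event = !censored,
                    stringsAsFactors = FALSE)
  ann <- cbind(ann, synth_mutations(cfg, v))
  list(expr = expr, annotations = ann, latent = v, score = score)
}
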