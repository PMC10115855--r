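make_surv_ann <- function(ids, time, event, site = "x") {
  data.frame(sample_id = ids, disease_site = site, time_months = time,
             event = event, stringsAsFactors = FALSE)
}

test_that("disease sites are ranked by median shifted score with a size filter", {
  ann <- data.frame(sample_id = sprintf("p%02d", 1:12),
                    disease_site = rep(c("lung", "skin", "rare"), c(6, 5, 1)),
                    stringsAsFactors = FALSE)
  sc <- setNames(c(rep(5, 6), rep(3, 5), 100), ann$sample_id)
  rk <- rank_disease_sites(sc, ann, min_n = 2)
  expect_identical(rk$site, c("lung", "skin"))   # rare: n = 1 < 2, dropped
  expect_identical(rk$rank, 1:2)

  rk5 <- rank_disease_sites(sc, ann, min_n = 5)
  expect_identical(rk5$site, c("lung", "skin"))
  expect_error(rank_disease_sites(sc, ann, min_n = 7), "min_n")
})

test_that("planted site shifts are recovered in rank order", {
  cfg <- small_config(seed = 81, n_clinical = 400L, site_shift_sd = 1)
  cl <- simulate_clinical_cohort(cfg)
  sc <- signature_score(cl$expr, simulate_cellline_panel(cfg)$program_genes)
  rk <- rank_disease_sites(sc, cl$annotations, min_n = 10)
  shifts <- consig:::synth_structure(cfg)$site_shift
  planted <- rank(-shifts[rk$site])
  expect_gt(cor(rk$rank, planted, method = "spearman"), 0.7)
  # every clearly separated pair of sites (shift gap > 1 SD of the
  # per-gene noise) is ordered correctly
  for (i in seq_len(nrow(rk) - 1)) for (j in seq.int(i + 1, nrow(rk))) {
    gap <- shifts[rk$site[i]] - shifts[rk$site[j]]
    if (abs(gap) > 1) expect_gt(gap, 0)  # rank i above j implies larger shift
  }
})

test_that("rank concordance matches brute-force Spearman on shared sites", {
  a <- data.frame(site = letters[1:8], rank = 1:8, stringsAsFactors = FALSE)
  b <- a
  expect_equal(rank_concordance(a, b)$rho, 1)
  brev <- data.frame(site = letters[1:8], rank = 8:1, stringsAsFactors = FALSE)
  expect_equal(rank_concordance(a, brev)$rho, -1)

  set.seed(81)
  bshuf <- data.frame(site = letters[1:8], rank = sample(8),
                      stringsAsFactors = FALSE)
  got <- rank_concordance(a, bshuf)
  expect_equal(got$rho, cor(1:8, bshuf$rank, method = "spearman"))
  expect_error(rank_concordance(a[1:2, ], b), "shared")
})

test_that("mutation association is calibrated, powered, and hand-checkable", {
  set.seed(82)
  n <- 200
  ids <- sprintf("p%03d", 1:n)
  sc <- setNames(rnorm(n), ids)

  # perfect association: mutation = indicator(score > median)
  ann1 <- data.frame(sample_id = ids,
                     mutA = sc > median(sc),
                     stringsAsFactors = FALSE)
  out1 <- mutation_association(sc, ann1, "mutA")
  expect_lt(out1$p_raw, 1e-10)

  # hand-computed 2x2 with continuity correction: 20/80 vs 50/50 mutated
  mut <- c(rep(c(TRUE, FALSE), c(20, 80)), rep(c(TRUE, FALSE), c(50, 50)))
  sc2 <- setNames(c(seq_len(100), 101:200), ids)  # low half then high half
  ann2 <- data.frame(sample_id = ids, mutB = mut, stringsAsFactors = FALSE)
  out2 <- mutation_association(sc2, ann2, "mutB")
  hand <- chisq.test(table(sc2 > median(sc2), mut), correct = TRUE)
  expect_equal(out2$chi_square, unname(hand$statistic))
  expect_equal(out2$p_raw, hand$p.value)

  # untestable genes are excluded from the Bonferroni factor
  ann3 <- data.frame(sample_id = ids, mutB = mut,
                     all_mut = TRUE, none_mut = FALSE,
                     stringsAsFactors = FALSE)
  out3 <- mutation_association(sc2, ann3, c("mutB", "all_mut", "none_mut"))
  expect_identical(out3$testable, c(TRUE, FALSE, FALSE))
  expect_equal(out3$p_bonferroni[1], out3$p_raw[1])  # factor 1, not 3

  # null calibration: independent mutations give uniform p-values
  pvals <- vapply(1:200, function(i) {
    set.seed(400 + i)
    annN <- data.frame(sample_id = ids, mutN = runif(n) < 0.3,
                       stringsAsFactors = FALSE)
    scN <- setNames(rnorm(n), ids)
    mutation_association(scN, annN, "mutN")$p_raw
  }, numeric(1))
  # continuity-corrected chi-square p-values are discrete and
  # conservative; require no excess of small p rather than exact
  # uniformity
  expect_lt(mean(pvals < 0.05), 0.08)
  expect_gt(median(pvals), 0.3)
})

test_that("the variance filter removes strictly sub-threshold genes only", {
  set.seed(83)
  m <- rbind(lowvar = rnorm(40, sd = sqrt(0.1)),
             atvar = rnorm(40),
             highvar = rnorm(40, sd = 2))
  m["lowvar", ] <- scale(m["lowvar", ])[, 1] * sqrt(0.1)
  colnames(m) <- sprintf("s%02d", 1:40)
  got <- variance_filter(m, rownames(m), threshold = 0.2)
  expect_setequal(got, c("atvar", "highvar"))
  # a variance exactly at the threshold is retained (removal is strict "<")
  thr_at <- consig:::row_vars(m["atvar", , drop = FALSE])[[1]]
  expect_true("atvar" %in% variance_filter(m, rownames(m), thr_at))

  big <- toy_matrix(19, 30, seed = 84, sd = 0.6)
  expect_setequal(variance_filter(big, rownames(big), 0.2),
                  rownames(big)[apply(big, 1, var) >= 0.2])
})

test_that("the univariate screen keeps protective genes and drops strongly
           hazardous ones", {
  set.seed(85)
  n <- 120
  ids <- sprintf("p%03d", 1:n)
  protective <- rnorm(n)
  hazardous <- rnorm(n)
  noise <- rnorm(n)
  haz <- 0.05 * exp(-1 * protective + 1.2 * hazardous)
  time <- rexp(n, haz)
  m <- rbind(prot = protective, hzrd = hazardous, noise = noise)
  colnames(m) <- ids
  ann <- make_surv_ann(ids, time, TRUE)
  kept <- univariate_cox_screen(m, ann, rownames(m), coef_threshold = 0.5)
  expect_true("prot" %in% kept)
  expect_true("noise" %in% kept)        # near-zero coefficient passes <= 0.5
  expect_false("hzrd" %in% kept)        # coefficient near 1.2 is excluded
  expect_lt(attr(kept, "coefficients")["prot"], 0)

  kept_p <- univariate_cox_screen(m, ann, rownames(m), mode = "protective")
  expect_true("prot" %in% kept_p)
  expect_false("hzrd" %in% kept_p)
})

test_that("multivariate training reduces to univariate for one gene and
           rejects collinearity", {
  set.seed(86)
  n <- 80
  ids <- sprintf("p%03d", 1:n)
  x <- rnorm(n)
  time <- rexp(n, 0.05 * exp(-x))
  m <- rbind(g1 = x, g2 = rnorm(n))
  colnames(m) <- ids
  ann <- make_surv_ann(ids, time, TRUE)

  uni <- survival::coxph(survival::Surv(time, rep(1, n)) ~ x, ties = "efron")
  multi <- multivariate_cox_train(m, ann, "g1")
  expect_equal(unname(multi$coefficients["g1"]), unname(coef(uni)),
               tolerance = 1e-8)

  mc <- rbind(a = x, b = x, filler = rnorm(n))   # perfectly collinear pair
  colnames(mc) <- ids
  expect_error(multivariate_cox_train(mc, ann, c("a", "b")),
               "degenerate|non-finite")
})

test_that("the linear predictor is the coefficient dot product", {
  m <- toy_matrix(5, 6, seed = 87)
  model <- structure(list(genes = rownames(m)[1:3],
                          coefficients = setNames(c(0.5, -1, 2), rownames(m)[1:3]),
                          se = setNames(rep(0.1, 3), rownames(m)[1:3]),
                          cohort_id = "t"),
                     class = "cox_panel_model")
  eta <- linear_predictor(model, m)
  hand <- 0.5 * m[1, ] - 1 * m[2, ] + 2 * m[3, ]
  expect_equal(eta, hand)

  model0 <- model; model0$coefficients[] <- 0
  expect_equal(unname(linear_predictor(model0, m)), rep(0, 6))

  model1 <- model; model1$genes <- rownames(m)[1]
  model1$coefficients <- setNames(1, rownames(m)[1])
  expect_equal(linear_predictor(model1, m), m[1, ])

  modelx <- model; modelx$genes <- c(model$genes, "ghost")
  expect_error(linear_predictor(modelx, m), "ghost")
})

test_that("optimal cutpoints equal exhaustive brute force under the
           group-size constraint", {
  set.seed(88)
  # two well-separated risk clusters, n = 12
  risk <- setNames(c(rnorm(6, 0), rnorm(6, 10)), sprintf("p%02d", 1:12))
  time <- c(rexp(6, 0.02), rexp(6, 0.4))
  ann <- make_surv_ann(names(risk), time, TRUE)
  got <- optimal_cutpoints(risk, ann, k = 1, min_group = 4)

  # brute force over every midpoint
  s <- sort(unique(risk)); mids <- (s[-1] + s[-length(s)]) / 2
  brute <- sapply(mids, function(cp) {
    g <- risk > cp
    if (min(table(g)) < 4) return(NA_real_)
    survival::survdiff(survival::Surv(time, rep(1, 12)) ~ g)$chisq
  })
  expect_equal(got$chi_square, max(brute, na.rm = TRUE), tolerance = 1e-10)

  # n = 8, min_group 4: exactly one feasible split
  risk8 <- setNames(1:8, sprintf("q%d", 1:8))
  ann8 <- make_surv_ann(names(risk8), rexp(8, 0.1), TRUE)
  got8 <- optimal_cutpoints(risk8, ann8, k = 1, min_group = 4)
  expect_identical(got8$group_sizes, c(4L, 4L))
  expect_gt(got8$cutpoints, 4); expect_lt(got8$cutpoints, 5)

  # k = 2 needs at least 12 samples at min_group 4
  risk11 <- setNames(1:11, sprintf("r%02d", 1:11))
  ann11 <- make_surv_ann(names(risk11), rexp(11, 0.1), TRUE)
  expect_error(optimal_cutpoints(risk11, ann11, k = 2, min_group = 4),
               "at least 12")

  # the optimum dominates the median split by construction
  med_groups <- risk_groups(risk, "median")
  med_chi <- km_compare(med_groups, ann)$chi_square
  expect_gte(got$chi_square, med_chi - 1e-12)
})

test_that("two-cutpoint search equals the exhaustive pair scan", {
  set.seed(89)
  n <- 15
  risk <- setNames(sort(rnorm(n)), sprintf("p%02d", 1:n))
  time <- rexp(n, 0.05 * exp(seq(-1, 1, length.out = n)))
  ann <- make_surv_ann(names(risk), time, TRUE)
  got <- optimal_cutpoints(risk, ann, k = 2, min_group = 4)

  s <- sort(unique(risk)); mids <- (s[-1] + s[-length(s)]) / 2
  best <- -Inf
  for (i in seq_along(mids)) for (j in seq_along(mids)) {
    if (j <= i) next
    g <- cut(risk, c(-Inf, mids[i], mids[j], Inf))
    if (min(table(g)) < 4) next
    chi <- survival::survdiff(survival::Surv(time, rep(1, n)) ~ g)$chisq
    best <- max(best, chi)
  }
  expect_equal(got$chi_square, best, tolerance = 1e-10)
  expect_identical(length(got$cutpoints), 2L)
  expect_true(all(got$group_sizes >= 4))
})

test_that("KM comparison separates planted treated-arm risk and not noise", {
  # identical groups: chi-square 0
  ids <- sprintf("p%02d", 1:20)
  time <- rep(rexp(10, 0.1), 2)
  ann <- make_surv_ann(ids, time, TRUE)
  grp <- setNames(factor(rep(c("a", "b"), each = 10)), ids)
  # groups a and b contain identical survival data
  out <- km_compare(grp, ann)
  expect_lt(out$chi_square, 1e-10)

  # an all-censored group yields a flat curve
  ann2 <- make_surv_ann(ids, time, rep(c(FALSE, TRUE), each = 10))
  out2 <- km_compare(grp, ann2)
  expect_true(all(out2$curves$surv[out2$curves$group == "a"] == 1))
})
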