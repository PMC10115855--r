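test_that("folds partition samples into near-equal parts", {
  ids <- sprintf("c%03d", 1:429)
  fp <- split_folds(ids, 5, seed = 2)
  sizes <- table(fp$fold_assignments)
  expect_true(all(sizes %in% c(85L, 86L)))
  expect_true(all(lengths(fp$retained_per_fold) %in% c(343L, 344L)))
  expect_setequal(names(fp$fold_assignments), ids)

  fp10 <- split_folds(sprintf("x%02d", 1:10), 5, seed = 1)
  expect_true(all(table(fp10$fold_assignments) == 2L))
  expect_true(all(lengths(fp10$retained_per_fold) == 8L))

  expect_identical(split_folds(ids, 5, seed = 7), split_folds(ids, 5, seed = 7))
  expect_error(split_folds(sprintf("x%d", 1:3), 5), "more folds")
})

test_that("extreme responders are the IC50 tails with stable tie handling", {
  resp <- toy_response(1:10)
  grp <- select_extreme_responders(resp, 0.2)
  expect_identical(grp$sensitive, resp$sample_id[1:2])
  expect_identical(grp$resistant, resp$sample_id[9:10])

  resp343 <- toy_response(rnorm(343), ids = sprintf("c%03d", 1:343))
  g343 <- select_extreme_responders(resp343, 0.2)
  expect_length(g343$sensitive, 68L)
  expect_length(g343$resistant, 68L)
  expect_length(intersect(g343$sensitive, g343$resistant), 0L)

  # boundary ties: selection equals a stable sort by (ic50, sample_id)
  resp_t <- toy_response(c(1, 2, 2, 2, 3, 4, 5, 6, 7, 8),
                         ids = sprintf("s%02d", 10:1))
  gt <- select_extreme_responders(resp_t, 0.2)
  ord <- order(resp_t$ic50, resp_t$sample_id)
  expect_identical(gt$sensitive, resp_t$sample_id[ord[1:2]])
  expect_identical(gt$resistant, resp_t$sample_id[ord[9:10]])
  expect_error(select_extreme_responders(toy_response(1:5), 0.2), "at least 2")
})

test_that("moderated t with zero prior df reduces to the classical pooled t", {
  m <- toy_matrix(120, 14, seed = 21)
  sens <- colnames(m)[1:7]; res <- colnames(m)[8:14]
  r0 <- moderated_t_test(m, sens, res, prior_df = 0)
  for (g in rownames(m)[c(1, 40, 120)]) {
    tt <- t.test(m[g, sens], m[g, res], var.equal = TRUE)
    expect_equal(r0$stat[r0$gene_id == g], unname(tt$statistic), tolerance = 1e-8)
    expect_equal(r0$p_raw[r0$gene_id == g], tt$p.value, tolerance = 1e-8)
  }
})

test_that("moderated t matches the reference empirical-Bayes implementation", {
  skip_if_not_installed("limma")
  set.seed(31)
  G <- 250; n1 <- 6; n2 <- 6
  sdg <- sqrt(1 / rgamma(G, shape = 3, rate = 3))
  m <- matrix(rnorm(G * (n1 + n2), sd = rep(sdg, n1 + n2)), G,
              dimnames = list(sprintf("g%03d", 1:G), sprintf("s%02d", 1:12)))
  sens <- colnames(m)[1:n1]; res <- colnames(m)[(n1 + 1):(n1 + n2)]
  mine <- moderated_t_test(m, sens, res)
  fit <- limma::eBayes(limma::lmFit(m, cbind(1, rep(c(1, 0), c(n1, n2)))),
                       trend = FALSE)
  expect_equal(unname(attr(mine, "prior_df")), fit$df.prior, tolerance = 1e-8)
  expect_equal(unname(mine$stat), unname(fit$t[, 2]), tolerance = 1e-8)
  expect_equal(unname(mine$p_raw), unname(fit$p.value[, 2]), tolerance = 1e-8)
})

test_that("the fold-change gate excludes small effects regardless of p", {
  set.seed(5)
  n1 <- n2 <- 30
  m <- rbind(small = c(rnorm(n1, 0.4, 0.05), rnorm(n2, 0, 0.05)),
             filler = rnorm(n1 + n2),
             filler2 = rnorm(n1 + n2))
  colnames(m) <- sprintf("s%02d", 1:(n1 + n2))
  r <- moderated_t_test(m, colnames(m)[1:n1], colnames(m)[(n1 + 1):(n1 + n2)])
  row <- r[r$gene_id == "small", ]
  expect_lt(row$p_raw, 0.001)       # strong evidence ...
  expect_lt(row$lfc, 0.5)           # ... but below the fold-change cutoff
  expect_false(row$significant)

  # identical groups: lfc exactly 0, never significant
  half <- toy_matrix(10, 5, seed = 2)
  m2 <- cbind(half, half)
  colnames(m2) <- sprintf("s%02d", 1:10)
  r2 <- moderated_t_test(m2, colnames(m2)[1:5], colnames(m2)[6:10])
  expect_true(all(r2$lfc == 0))
  expect_false(any(r2$significant))
})

test_that("SAM enumerates all label splits when feasible and matches brute force", {
  m <- toy_matrix(40, 8, seed = 2)
  sens <- colnames(m)[1:4]; res <- colnames(m)[5:8]
  r <- sam_test(m, sens, res, n_perm = 10000, return_null = TRUE)
  nd <- attr(r, "null_d")
  expect_true(attr(r, "exhaustive"))
  expect_identical(ncol(nd), 70L)

  s0 <- attr(r, "s0")
  cmb <- combn(8, 4)
  oracle <- sapply(seq_len(ncol(cmb)), function(b) {
    i1 <- cmb[, b]; i2 <- setdiff(1:8, i1)
    apply(m, 1, function(x) {
      m1 <- mean(x[i1]); m2 <- mean(x[i2])
      sp <- sqrt((sum((x[i1] - m1)^2) + sum((x[i2] - m2)^2)) / 6 * 0.5)
      (m1 - m2) / (sp + s0)
    })
  })
  expect_equal(nd, oracle, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("with s0 = 0 the d-statistic ranks genes like the ordinary t", {
  m <- toy_matrix(60, 12, seed = 3)
  sens <- colnames(m)[1:6]; res <- colnames(m)[7:12]
  r <- sam_test(m, sens, res, n_perm = 300, s0 = 0, seed = 4)
  tstat <- apply(m, 1, function(x)
    t.test(x[sens], x[res], var.equal = TRUE)$statistic)
  expect_identical(order(r$stat), order(unname(tstat)))
  # determinism given seed
  r2 <- sam_test(m, sens, res, n_perm = 300, s0 = 0, seed = 4)
  expect_identical(r, r2)
})

test_that("minP adjusted p dominates raw p and responds to real signal", {
  # monotone conservativeness across many random fixtures
  for (i in 1:25) {
    m <- toy_matrix(15, 12, seed = 100 + i)
    r <- minp_test(m, colnames(m)[1:6], colnames(m)[7:12],
                   n_boot = 150, seed = i)
    expect_true(all(r$q_or_adj >= r$p_raw - 1e-12))
    expect_true(all(r$q_or_adj <= 1 & r$p_raw <= 1))
  }
  # a strong planted effect survives the adjustment
  m <- toy_matrix(50, 16, seed = 6)
  m[1, 1:8] <- m[1, 1:8] + 4
  r <- minp_test(m, colnames(m)[1:8], colnames(m)[9:16], n_boot = 500, seed = 1)
  expect_true(r$significant[r$gene_id == "g001"])
  expect_false(any(r$significant[-1]))
  expect_warning(minp_test(m, colnames(m)[1:8], colnames(m)[9:16], n_boot = 50),
                 "coarse")
})

test_that("relabelling the groups negates the directional statistics", {
  m <- toy_matrix(40, 12, seed = 12)
  m[1:5, 1:6] <- m[1:5, 1:6] + 2
  a <- colnames(m)[1:6]; b <- colnames(m)[7:12]
  fwd <- moderated_t_test(m, a, b)
  rev_ <- moderated_t_test(m, b, a)
  expect_equal(fwd$lfc, -rev_$lfc)
  expect_equal(fwd$stat, -rev_$stat)
  expect_length(intersect(fwd$gene_id[fwd$significant],
                          rev_$gene_id[rev_$significant]), 0L)
})

test_that("seed genes are the three-way intersection of up-regulated calls", {
  mk <- function(sig, method) data.frame(
    gene_id = c("A", "B", "C", "D"), mean_sensitive = 0, mean_resistant = 0,
    lfc = 1, stat = 1, p_raw = 0.5, q_or_adj = 0.5, method = method,
    significant = c("A", "B", "C", "D") %in% sig, stringsAsFactors = FALSE)
  res <- list(mk(c("A", "B", "C"), "moderated_t"),
              mk(c("B", "C", "D"), "sam"),
              mk(c("C", "B"), "minp"))
  seeds <- derive_seed_genes(res, fold = 1)
  expect_identical(seeds$genes, c("B", "C"))
  expect_identical(unname(seeds$per_method_counts), c(3L, 3L, 2L))

  expect_warning(derive_seed_genes(list(mk(character(), "moderated_t"),
                                        mk("A", "sam"), mk("A", "minp"))),
                 "empty")
  bad <- mk("A", "sam"); bad$gene_id <- c("A", "B", "C", "E")
  expect_error(derive_seed_genes(list(res[[1]], bad)), "universes")
})

test_that("pure-noise panels yield at most a trickle of seed genes", {
  n_seeds <- vapply(1:8, function(i) {
    m <- toy_matrix(150, 20, seed = 300 + i)
    sens <- colnames(m)[1:10]; res <- colnames(m)[11:20]
    out <- list(moderated_t_test(m, sens, res),
                sam_test(m, sens, res, n_perm = 300, seed = i),
                minp_test(m, sens, res, n_boot = 200, seed = i))
    length(suppressWarnings(derive_seed_genes(out))$genes)
  }, numeric(1))
  expect_lte(mean(n_seeds), 0.05 * 150)
})
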