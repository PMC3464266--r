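# GRASS machinery: the penalized fit, gene norms, the permutation null and
# the two-stage pathway p-value.

test_that("gene norms and the pathway statistic are Euclidean norms", {
  cf <- c(0.5, 3, 4, 1, 2, 2)   # intercept + 5 coefficients
  bi <- list(g1 = 1:2, g2 = 3:5)
  gn <- gene_norms(cf, bi)
  expect_equal(unname(gn), c(5, 3))
  expect_equal(gene_norms(c(1, 0, 0), list(g = 1:2))[["g"]], 0)
  set.seed(701)
  v <- rnorm(7)
  expect_equal(gene_norms(c(0, v), list(g = 1:7))[["g"]], sqrt(sum(v^2)))
  expect_equal(pathway_statistic(c(3, 4)), 5)
  expect_equal(pathway_statistic(rep(0, 4)), 0)
  expect_equal(pathway_statistic(v), sqrt(sum(v^2)))
  expect_error(pathway_statistic(numeric(0)), "no gene")
  expect_error(gene_norms(c(1, 2), list(g = integer(0))))
})

test_that("permutation p-value follows the (1+count)/(1+B) estimator", {
  expect_equal(pathway_pvalue(10, rep(1, 99)), 1 / 100)
  expect_equal(pathway_pvalue(0.5, rep(1, 99)), 1)
  expect_equal(pathway_pvalue(1, c(0.5, 1, 2)), (1 + 2) / 4)
})

test_that("an overwhelming penalty shrinks all coefficients to zero", {
  set.seed(702)
  X <- scale(matrix(rnorm(200 * 6), 200))
  y <- rbinom(200, 1, 0.5)
  cfg <- grass_config(penalty_grid = c(1e9, 1e8), seed = 3)
  fit <- fit_penalized_logistic(X, y, cfg)
  expect_lt(max(abs(fit$coefficients[-1])), 1e-6)
  expect_equal(unname(stats::plogis(fit$coefficients[1])), mean(y),
               tolerance = 1e-6)
})

test_that("zero penalty reproduces the unpenalized IRLS fit", {
  set.seed(703)
  X <- scale(matrix(rnorm(300 * 4), 300))
  colnames(X) <- paste0("e", 1:4)
  y <- rbinom(300, 1, stats::plogis(0.4 * X[, 1]))
  cfg <- grass_config(penalty_grid = c(0), seed = 5)
  fit <- fit_penalized_logistic(X, y, cfg)
  ml <- glm(y ~ X, family = binomial())
  expect_equal(unname(fit$coefficients), unname(coef(ml)), tolerance = 1e-6)
})

test_that("under an independent phenotype the CV deviance is flat-ish and
          coefficients stay small", {
  set.seed(704)
  X <- scale(matrix(rnorm(300 * 10), 300))
  y <- rbinom(300, 1, 0.5)
  cfg <- grass_config(seed = 7)
  fit <- fit_penalized_logistic(X, y, cfg)
  expect_lt(max(abs(fit$coefficients[-1])), 0.3)
  expect_lt(diff(range(fit$cv_deviance)) / min(fit$cv_deviance), 0.15)
})

test_that("the permutation engine matches a literal loop-based reference", {
  set.seed(705)
  n <- 120
  X <- scale(matrix(rnorm(n * 5), n))
  colnames(X) <- paste0("e", 1:5)
  y <- rbinom(n, 1, 0.5)
  gene_sizes <- c(g1 = 2L, g2 = 3L)
  cfg <- grass_config(penalty_grid = c(20, 1), cv_folds = 3L, seed = 11)
  gm <- permutation_null(X, y, cfg, B = 100, gene_sizes)
  # reproduce folds and permutation stream, then fit with the Newton oracle
  setup <- pathgwas:::with_seed(11, {
    folds <- pathgwas:::make_folds(n, 3L)
    perms <- pathgwas:::make_perms(n, 100)
    list(folds = folds, perms = perms)
  })
  ref <- oracle_grass_permutations(X, y, gene_sizes, c(20, 1), setup$folds,
                                   setup$perms)
  expect_equal(unname(gm[, ]), ref, tolerance = 1e-6)
  # determinism: same seed reproduces mu and sigma exactly
  gm2 <- permutation_null(X, y, cfg, B = 100, gene_sizes)
  expect_identical(colMeans(gm), colMeans(gm2))
  expect_identical(apply(gm, 2, sd), apply(gm2, 2, sd))
})

test_that("observed gene norms sit inside the exchangeable-null permutation
          distribution", {
  set.seed(706)
  ranks <- replicate(12, {
    n <- 150
    X <- scale(matrix(rnorm(n * 4), n))
    y <- rbinom(n, 1, 0.5)
    cfg <- grass_config(seed = sample.int(1e6, 1))
    folds <- pathgwas:::with_seed(cfg$seed, pathgwas:::make_folds(n, 5L))
    obs <- fit_penalized_logistic(X, y, cfg, fold_ids = folds)
    gm <- permutation_null(X, y, cfg, B = 100, c(g = 4L))
    mean(gm[, 1] <= gene_norms(obs$coefficients, list(g = 1:4))[[1]])
  })
  # ranks should look uniform: none of mean/extremes pathological
  expect_gt(mean(ranks), 0.2)
  expect_lt(mean(ranks), 0.8)
})

test_that("run_grass escalates significant pathways and reports Bonferroni", {
  ds <- null_dataset(707, n = 150, n_genes = 24, pw = c(12L, 12L))
  gm <- map_snps_to_genes(ds$snp_meta, ds$gene_regions)
  pw <- filter_pathways(ds$pathways, gm)
  blocks <- build_eigensnp_blocks(ds, gm)
  cfg <- grass_config(stage1_B = 100L, stage2_B = 200L,
                      escalation_threshold = 0.3, seed = 13)
  res <- run_grass(ds, pw, blocks, cfg)
  expect_identical(nrow(res), 2L)
  expect_true(all(res$B_used %in% c(100L, 200L)))
  expect_identical(res$escalated, res$B_used == 200L)
  expect_equal(attr(res, "bonferroni"), signif(0.05 / 2, 2))
  expect_true(all(res$p_value > 0 & res$p_value <= 1))
  expect_true(!is.unsorted(res$p_value))
  # full determinism of the pathway test
  res2 <- run_grass(ds, pw, blocks, cfg)
  expect_identical(res, res2)
})

test_that("frozen-tuning mode runs and stays close to full re-selection", {
  set.seed(708)
  n <- 150
  X <- scale(matrix(rnorm(n * 4), n))
  y <- rbinom(n, 1, 0.5)
  cfgA <- grass_config(seed = 5)
  cfgB <- grass_config(seed = 5, freeze_tuning = TRUE)
  gmA <- permutation_null(X, y, cfgA, B = 100, c(g = 4L))
  gmB <- permutation_null(X, y, cfgB, B = 100, c(g = 4L))
  expect_identical(dim(gmA), dim(gmB))
  expect_gt(cor(gmA[, 1], gmB[, 1]), 0.5)
})
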