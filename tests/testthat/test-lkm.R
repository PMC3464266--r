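# Logistic kernel machine: null model, score statistic, and the
# mixture-of-chi-squares p-value machinery.

test_that("null model satisfies the score equations", {
  set.seed(801)
  y <- rbinom(200, 1, 0.4)
  nf0 <- fit_null_logistic(y, NULL)
  expect_equal(unique(round(nf0$mu0, 12)), round(mean(y), 12))
  cov <- data.frame(age_group = factor(sample(paste0("a", 1:5), 200, TRUE)),
                    sex = rbinom(200, 1, 0.5), x = rnorm(200))
  nf <- fit_null_logistic(y, cov)
  expect_lt(max(abs(crossprod(nf$X, y - nf$mu0))), 1e-8)
  expect_true(all(nf$mu0 > 0 & nf$mu0 < 1))
  # balanced null: covariate coefficients within sampling error of zero
  sf <- summary(glm(y ~ ., data = cbind(data.frame(y = y), cov),
                    family = binomial()))$coefficients
  expect_lt(max(abs(sf[-1, "z value"])), 4)
  # rank-deficient design: duplicated column dropped with warning
  cov2 <- cbind(cov, x_dup = cov$x)
  expect_warning(nf2 <- fit_null_logistic(y, cov2), "rank-deficient")
  expect_false("x_dup" %in% colnames(nf2$X))
})

test_that("score statistic equals the algebraic identity", {
  set.seed(802)
  n <- 150
  G <- simulate_gene_block(n, 4, 0.3, 0.4)
  y <- rbinom(n, 1, 0.5)
  mu0 <- rep(mean(y), n)
  Q <- score_statistic(y, mu0, G)
  Gc <- scale(apply(G, 2, function(c) ifelse(is.na(c), mean(c, na.rm = TRUE), c)),
              scale = FALSE)
  r <- y - mu0
  expect_equal(Q, sum((t(Gc) %*% r)^2) / 2, tolerance = 1e-10)
  expect_equal(Q, (t(r) %*% (Gc %*% t(Gc)) %*% r)[1] / 2, tolerance = 1e-8)
  # y = mu0 exactly: zero residuals
  expect_equal(score_statistic(mu0, mu0, G), 0)
  expect_error(score_statistic(y, mu0, G[, 0, drop = FALSE]), "empty gene")
})

test_that("single-SNP genes match the 1-df scaled chi-square closed form", {
  set.seed(803)
  for (i in 1:5) {
    n <- 300
    G <- simulate_gene_block(n, 1, runif(1, 0.1, 0.5), 0)
    y <- rbinom(n, 1, 0.5)
    nf <- fit_null_logistic(y, data.frame(x = rnorm(n)))
    Q <- score_statistic(y, nf$mu0, G)
    pv <- null_pvalue(Q, G, nf, method = "davies")
    # closed form: Q / lambda1 ~ chi2_1
    Gc <- scale(G, scale = FALSE)
    v <- nf$mu0 * (1 - nf$mu0)
    VX <- nf$X * v
    W <- Gc - nf$X %*% solve(crossprod(nf$X, VX), crossprod(VX, Gc))
    lam1 <- sum(v * W^2) / 2
    expect_equal(pv$p_value, pchisq(Q / lam1, 1, lower.tail = FALSE),
                 tolerance = 1e-6)
  }
})

test_that("Q = 0 gives p = 1 and Davies agrees with equal-weight closed form", {
  nf <- list(mu0 = rep(0.5, 10), X = matrix(1, 10, 1), y = rep(0:1, 5))
  G <- matrix(rbinom(30, 2, 0.3), 10)
  expect_equal(null_pvalue(0, G, nf)$p_value, 1)
  # two equal eigenvalues: exact survival exp(-q / (2 lambda))
  expect_lt(abs(pathgwas:::imhof_pvalue(50, c(2.5, 2.5)) -
                  exp(-50 / (2 * 2.5))), 1e-8)
})

test_that("Davies and Satterthwaite agree when eigenvalues are balanced", {
  set.seed(804)
  for (i in 1:10) {
    lam <- runif(6, 0.5, 1.5)        # top eigenvalue well under 60% of total
    q <- sum(lam) * runif(1, 0.5, 3)
    pd <- pathgwas:::imhof_pvalue(q, lam)
    ps <- pathgwas:::satterthwaite_pvalue(q, lam)
    if (pd > 1e-4) expect_lt(abs(pd - ps) / pd, 0.10)
  }
})

test_that("Davies p-values track the residual-permutation oracle", {
  set.seed(805)
  n <- 400
  cov <- data.frame(age_group = factor(sample(paste0("a", 1:5), n, TRUE)),
                    sex = rbinom(n, 1, 0.5))
  y <- rbinom(n, 1, 0.5)
  nf <- fit_null_logistic(y, cov)
  for (i in 1:5) {
    G <- simulate_gene_block(n, 5, runif(1, 0.15, 0.45), 0.5)
    Q <- score_statistic(y, nf$mu0, G)
    pd <- null_pvalue(Q, G, nf, method = "davies")$p_value
    B <- 4000
    pp <- lkm_permutation_pvalue(Q, G, y, nf$mu0, B = B, perm_seed = i)
    se <- sqrt(pp * (1 - pp) / B)
    expect_lt(abs(pd - pp), 4 * se + 0.005)
  }
})

test_that("Q is invariant to covariate location shifts", {
  set.seed(806)
  n <- 200
  cov <- data.frame(x = rnorm(n), z = rnorm(n))
  y <- rbinom(n, 1, 0.5)
  G <- simulate_gene_block(n, 3, 0.3, 0.3)
  nf1 <- fit_null_logistic(y, cov)
  cov2 <- cov; cov2$x <- cov2$x + 100
  nf2 <- fit_null_logistic(y, cov2)
  Q1 <- score_statistic(y, nf1$mu0, G)
  Q2 <- score_statistic(y, nf2$mu0, G)
  expect_equal(Q1, Q2, tolerance = 1e-6)
  p1 <- null_pvalue(Q1, G, nf1)$p_value
  p2 <- null_pvalue(Q2, G, nf2)$p_value
  expect_equal(p1, p2, tolerance = 1e-6)
})

test_that("run_lkm reports per-gene results and the Bonferroni threshold", {
  ds <- null_dataset(807, n = 200, n_genes = 15, pw = 15L)
  gm <- map_snps_to_genes(ds$snp_meta, ds$gene_regions)
  res <- run_lkm(ds, gm)
  expect_identical(nrow(res), length(gm))
  expect_true(all(res$p_value > 0 & res$p_value <= 1))
  expect_equal(attr(res, "bonferroni"), signif(0.05 / length(gm), 3))
  expect_true(all(res$method %in% c("davies", "satterthwaite")))
  expect_gt(mean(res$method == "davies"), 0.8)
  expect_identical(res$major_gene, res$p_value < 0.001)
})

test_that("null LKM p-values are roughly uniform", {
  set.seed(808)
  n <- 300
  y <- rbinom(n, 1, 0.5)
  cov <- data.frame(sex = rbinom(n, 1, 0.5))
  nf <- fit_null_logistic(y, cov)
  ps <- vapply(1:150, function(i) {
    G <- simulate_gene_block(n, sample(1:5, 1), runif(1, 0.1, 0.5), 0.5)
    Q <- score_statistic(y, nf$mu0, G)
    null_pvalue(Q, G, nf)$p_value
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})
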