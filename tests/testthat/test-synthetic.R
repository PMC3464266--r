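# Synthetic GWAS generator: marginal calibration, LD control, disease model,
# determinism and bookkeeping.

test_that("gene-block marginals hit the target allele frequency and HWE", {
  set.seed(301)
  d <- simulate_gene_block(20000, 4, 0.3, 0)
  expect_true(all(abs(colMeans(d) / 2 - 0.3) < 0.01))
  expect_true(abs(cor(d[, 1], d[, 2])) < 0.03)
  # single SNP: genotype counts consistent with HWE at the target maf
  d1 <- simulate_gene_block(20000, 1, 0.2, 0)
  counts <- tabulate(d1[, 1] + 1L, 3)
  expect_gt(hwe_exact_test(counts[1], counts[2], counts[3]), 1e-4)
  expect_true(abs(counts[2] / 20000 - 2 * 0.2 * 0.8) < 0.02)
})

test_that("AR(1) latent correlation orders the dosage LD", {
  set.seed(302)
  d9 <- simulate_gene_block(20000, 2, 0.3, 0.9)
  set.seed(302)
  d0 <- simulate_gene_block(20000, 2, 0.3, 0.0)
  expect_gt(cor(d9[, 1], d9[, 2]), cor(d0[, 1], d0[, 2]))
  expect_gt(cor(d9[, 1], d9[, 2]), 0.5)
})

test_that("marginal HWE holds across many simulated SNPs", {
  # exact-test p-values approximately uniform over independent SNPs
  set.seed(303)
  d <- simulate_gene_block(2000, 500, runif(500, 0.1, 0.5), 0)
  ps <- apply(d, 2, function(x)
    hwe_exact_test(sum(x == 0), sum(x == 1), sum(x == 2)))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("phenotype model matches its closed-form prevalence and effect", {
  set.seed(304)
  D <- matrix(0L, 50000, 1, dimnames = list(NULL, "s1"))
  y <- simulate_phenotype(D, alpha0 = -2)
  p <- stats::plogis(-2)
  expect_lt(abs(mean(y) - p), 3 * sqrt(p * (1 - p) / 50000))
  y0 <- simulate_phenotype(D, alpha0 = 0)
  expect_lt(abs(mean(y0) - 0.5), 3 * sqrt(0.25 / 50000))
  # per-allele odds ratio recovered by a logistic-regression oracle
  g <- simulate_gene_block(50000, 1, 0.3, 0)
  colnames(g) <- "s1"
  y1 <- simulate_phenotype(g, c(s1 = 0.5), alpha0 = -1)
  fit <- glm(y1 ~ g[, 1], family = binomial())
  expect_lt(abs(coef(fit)[2] - 0.5), 3 * summary(fit)$coefficients[2, 2])
  expect_error(simulate_phenotype(D, c(nope = 1)), "unknown causal SNP")
})

test_that("generate_dataset is deterministic and injects what it says", {
  cfg <- synthetic_config(n_cases = 80, n_controls = 80, n_genes = 12,
                          pathway_sizes = c(6L, 6L), missing_rate = 0.05,
                          hwe_violation_snps = 3L, seed = 11)
  a <- generate_dataset(cfg)
  b <- generate_dataset(cfg)
  expect_identical(a, b)
  expect_lt(abs(mean(is.na(a$dosages)) - 0.05), 0.005)
  expect_length(a$truth$hwe_violation_snps, 3L)
  # positions strictly increasing, dosage domain respected
  expect_true(all(diff(a$snp_meta$pos) > 0))
  expect_true(all(is.na(a$dosages) | a$dosages %in% 0:2))
  # a degenerate SNPs-per-gene range is honored exactly
  d4 <- generate_dataset(synthetic_config(
    n_cases = 20, n_controls = 20, n_genes = 10,
    snps_per_gene = c(4L, 4L), pathway_sizes = 10L, seed = 3))
  expect_identical(as.integer(table(d4$snp_meta$gene)), rep(4L, 10))
})

test_that("causal truth bookkeeping stays inside the causal pathway", {
  cfg <- synthetic_config(
    n_cases = 60, n_controls = 60, n_genes = 20, pathway_sizes = c(10L, 10L),
    causal_pathways = list(pw1 = list(n_causal = 10, beta = 0.3)), seed = 4)
  ds <- generate_dataset(cfg)
  expect_length(ds$truth$causal_snps, 10L)
  genes <- ds$snp_meta$gene[match(ds$truth$causal_snps, ds$snp_meta$snp_id)]
  expect_true(all(genes %in% ds$pathways$pw1))
})

test_that("exchangeable subpopulations show no mean dosage difference", {
  cfg <- synthetic_config(n_cases = 300, n_controls = 300, n_genes = 10,
                          pathway_sizes = 10L, structure_fst = 0,
                          subpop_fractions = c(0.5, 0.5), seed = 21)
  ds <- generate_dataset(cfg)
  sp <- ds$truth$ancestry
  dm <- colMeans(ds$dosages[sp == 1, , drop = FALSE]) -
    colMeans(ds$dosages[sp == 2, , drop = FALSE])
  t_stats <- dm / apply(ds$dosages, 2, function(x)
    sqrt(var(x[sp == 1]) / sum(sp == 1) + var(x[sp == 2]) / sum(sp == 2)))
  expect_lt(mean(abs(t_stats) > 2.6), 0.1)
})

test_that("an unreachable case target reports the achievable prevalence", {
  cfg <- synthetic_config(n_cases = 500, n_controls = 10, n_genes = 4,
                          pathway_sizes = 4L, baseline_alpha0 = -6,
                          pool_multiplier = 2, seed = 2)
  expect_error(generate_dataset(cfg), "achievable prevalence")
})

test_that("config validation rejects out-of-range parameters", {
  expect_error(synthetic_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(synthetic_config(ld_rho = 1), "ld_rho")
  expect_error(synthetic_config(subpop_fractions = c(0.6, 0.6)), "sum to 1")
  expect_error(synthetic_config(pathway_sizes = rep(30L, 2), n_genes = 40),
               "exceeds n_genes")
})
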