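# SNP-level QC: additive recoding, exact HWE test, the joint filters, trend
# statistics, inflation factors, LD pruning and Q-Q data.

test_that("additive recoding counts minor-allele copies", {
  ped <- rbind(c("A", "A", "A", "G", "C", "C"),
               c("A", "A", "A", "A", "C", "C"),
               c("A", "A", "A", "G", "C", "C"))
  enc <- encode_additive(ped, c("s1", "s2", "s3"))
  expect_identical(enc$dosages[, "s1"], c(0L, 0L, 0L))    # monomorphic
  expect_identical(enc$minor[2], "G")                     # G rarer (2 of 6)
  expect_identical(enc$dosages[, "s2"], c(1L, 0L, 1L))
  # tie at maf 0.5: lexicographic order picks the minor allele
  tie <- rbind(c("G", "A"), c("A", "G"))
  et <- encode_additive(tie, "s1")
  expect_identical(et$minor, "A")
  expect_identical(et$dosages[, "s1"], c(1L, 1L))
  tri <- rbind(c("A", "C"), c("G", "G"))
  expect_error(encode_additive(tri, "bad1"), "triallelic SNP: bad1")
})

test_that("exact HWE test matches the enumeration oracle exactly", {
  expect_identical(hwe_exact_test(25, 50, 25), 1)
  cases <- list(c(50, 0, 50), c(0, 100, 0), c(30, 40, 30), c(88, 10, 2),
                c(1, 1, 1), c(0, 3, 97))
  for (cs in cases)
    expect_equal(hwe_exact_test(cs[1], cs[2], cs[3]),
                 oracle_hwe_exact(cs[1], cs[2], cs[3]), tolerance = 1e-12)
  expect_error(hwe_exact_test(0, 0, 0), "zero")
})

test_that("exact HWE test equals brute force for all configurations n <= 30", {
  # exhaustive sweep over every genotype configuration up to n = 30
  for (n in c(2, 5, 11, 30)) {
    for (n_bb in 0:floor(n / 2)) {
      for (n_ab in 0:(n - 2 * n_bb)) {
        n_aa <- n - n_bb - n_ab
        if (n_aa < n_bb) next
        expect_equal(hwe_exact_test(n_aa, n_ab, n_bb),
                     oracle_hwe_exact(n_aa, n_ab, n_bb),
                     tolerance = 1e-12)
      }
    }
  }
  # spot checks at larger n up to 200
  set.seed(401)
  for (i in 1:25) {
    n <- sample(31:200, 1)
    n_bb <- sample(0:floor(n / 3), 1)
    n_ab <- sample(0:(n - 2 * n_bb), 1)
    expect_equal(hwe_exact_test(n - n_bb - n_ab, n_ab, n_bb),
                 oracle_hwe_exact(n - n_bb - n_ab, n_ab, n_bb),
                 tolerance = 1e-12)
  }
})

test_that("QC filters exclude exactly the constructed violations", {
  n <- 400
  set.seed(402)
  ok <- function() simulate_gene_block(n, 1, 0.3, 0)[, 1]
  d <- cbind(clean = ok(), lowcall = ok(), rare = rbinom(n, 2, 0.01),
             hwe_bad = c(rep(0L, 200), rep(2L, 200)), desert = ok())
  d[1:12, "lowcall"] <- NA           # call rate 0.97 < 0.98
  meta <- data.frame(snp_id = colnames(d), chrom = "1",
                     pos = c(1000L, 1100L, 1200L, 1300L, 90000L),
                     allele1 = "A", allele2 = "B", gene = NA)
  regions <- data.frame(chrom = "1", start = 500L, end = 2000L, gene = "G1")
  ds <- structure(list(dosages = d, snp_meta = meta,
                       phenotype = rep(0:1, n / 2)),
                  class = "genotype_dataset")
  res <- apply_qc(ds, regions)
  expect_identical(res$qc$excluded,
                   c(FALSE, TRUE, TRUE, TRUE, TRUE))
  expect_identical(res$qc$exclusion_reasons[2], "CALL_RATE")
  expect_identical(res$qc$exclusion_reasons[3], "MAF")
  expect_identical(res$qc$exclusion_reasons[4], "HWE")
  expect_identical(res$qc$exclusion_reasons[5], "GENE_DESERT")
  expect_identical(colnames(res$dataset$dosages), "clean")
  # boundary: call rate exactly 0.98 is retained (strict inequality)
  d2 <- cbind(boundary = ok())
  d2[1:8, 1] <- NA                   # exactly 0.98
  ds2 <- structure(list(dosages = d2, snp_meta = meta[1, ],
                        phenotype = ds$phenotype),
                   class = "genotype_dataset")
  expect_false(apply_qc(ds2, regions)$qc$excluded)
  # vacuous thresholds exclude nothing
  res3 <- apply_qc(ds, regions, thresholds = list(call_rate = 0, maf = 0,
                                                  hwe_p = 0,
                                                  desert_window = Inf))
  expect_identical(sum(res3$qc$excluded), 0L)
})

test_that("trend statistic equals N r^2 and the stats oracle", {
  set.seed(403)
  for (i in 1:10) {
    g <- rbinom(120, 2, 0.3)
    y <- rbinom(120, 1, 0.5)
    ca <- cochran_armitage_trend(g, y)
    expect_equal(ca, 120 * cor(g, y)^2, tolerance = 1e-12)
    tab <- table(factor(y, 0:1), factor(g, 0:2))
    pt <- stats::prop.trend.test(tab[2, ], colSums(tab), 0:2)
    expect_equal(ca, unname(pt$statistic), tolerance = 1e-9)
  }
  expect_identical(cochran_armitage_trend(rep(1L, 50), rbinom(50, 1, 0.5)), 0)
  # perfect separation: statistic equals N
  expect_equal(cochran_armitage_trend(c(rep(2, 30), rep(0, 30)),
                                      c(rep(1, 30), rep(0, 30))), 60)
})

test_that("inflation factor follows the lambda-1000 rescaling formula", {
  med <- qchisq(0.5, 1)
  r <- inflation_factor(c(med), 500, 500)
  expect_equal(r$lambda_raw, 1)
  expect_equal(r$lambda_1000, 1)
  # direct substitution: lambda 1.10 at 4000/4000 rescales to 1.025
  chi <- c(med * 1.10)
  r2 <- inflation_factor(chi, 4000, 4000)
  expect_equal(r2$lambda_1000, 1.025, tolerance = 1e-12)
  expect_error(inflation_factor(1, 0, 100), "positive")
  # affine contraction toward 1 for cohorts of 1000+
  set.seed(404)
  for (i in 1:20) {
    lam <- runif(1, 0.8, 1.6)
    rr <- inflation_factor(med * lam, sample(1000:5000, 1),
                           sample(1000:5000, 1))
    expect_lte(abs(rr$lambda_1000 - 1), abs(rr$lambda_raw - 1) + 1e-12)
  }
})

test_that("null trend statistics are calibrated (lambda near 1)", {
  set.seed(405)
  n <- 300
  m <- 10000   # enough SNPs that the median's sampling error is ~0.01
  d <- simulate_gene_block(n, m, runif(m, 0.1, 0.5), 0)
  y <- rep(0:1, n / 2)
  chi <- apply(d, 2, cochran_armitage_trend, phenotype = y)
  r <- inflation_factor(chi, n / 2, n / 2)
  expect_gt(r$lambda_raw, 0.95)
  expect_lt(r$lambda_raw, 1.05)
  pfrac <- mean(pchisq(chi, 1, lower.tail = FALSE) < 0.05)
  expect_lt(abs(pfrac - 0.05), 2.6 * sqrt(0.05 * 0.95 / m))
})

test_that("LD pruning keeps one of each correlated pair", {
  set.seed(406)
  x <- simulate_gene_block(500, 1, 0.3, 0)
  d <- cbind(a = x[, 1], b = x[, 1], c = rbinom(500, 2, 0.3))
  expect_identical(ld_prune(d, 0.5), c("a", "c"))
  # independent SNPs survive a high threshold
  ind <- simulate_gene_block(500, 20, 0.3, 0)
  colnames(ind) <- paste0("s", 1:20)
  expect_identical(ld_prune(ind, 0.99), colnames(ind))
  # tight threshold on a high-LD block keeps the first SNP only
  blk <- simulate_gene_block(500, 5, 0.3, 0.9)
  colnames(blk) <- paste0("b", 1:5)
  kept <- ld_prune(blk, 0.004)
  expect_identical(kept[1], "b1")
  expect_false("b2" %in% kept)
  expect_identical(ld_prune(d[, 0, drop = FALSE], 0.5), character(0))
})

test_that("Q-Q data uses chi-square-1 plotting positions", {
  q1 <- qq_points(c(5))
  expect_equal(q1$expected, qchisq(0.5, 1))
  set.seed(407)
  obs <- rchisq(10000, 1)
  qq <- qq_points(obs)
  expect_identical(qq$observed, sort(obs))
  expect_true(all(diff(qq$expected) > 0))
  ks <- suppressWarnings(stats::ks.test(obs, "pchisq", df = 1))
  expect_gt(ks$p.value, 0.01)
  expect_lt(max(abs(qq$observed - qq$expected)[qq$expected < 6]), 1)
})
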