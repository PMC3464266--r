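# Synthetic case-control GWAS generator.
#
# Genotypes follow a Gaussian-copula haplotype model: each subject carries two
# independent latent haplotypes per gene; a haplotype is an AR(1) multivariate
# normal vector thresholded at the quantile of each SNP's allele frequency.
# Marginally every SNP is therefore in exact Hardy-Weinberg proportions at its
# target frequency, while the AR(1) parameter controls within-gene LD
# independently of the allele frequencies.

#' Configuration for the synthetic GWAS generator
#'
#' The defaults emulate the design of a two-cohort pancreatic-cancer style
#' case-control GWAS at desk scale: a few hundred subjects, genes of 1-60
#' SNPs with within-gene LD, pathways of tens of genes, an additive logistic
#' disease model on selected causal SNPs, and categorical covariates.
#'
#' @param n_cases,n_controls target sample sizes after retrospective sampling.
#' @param n_genes number of genes.
#' @param snps_per_gene integer range (length-2) of SNPs per gene.
#' @param maf_range interval of minor allele frequencies, within (0, 0.5].
#' @param ld_rho AR(1) latent correlation between adjacent SNPs, in [0, 1).
#' @param pathway_sizes integer vector of gene counts per pathway; must sum
#'   to at most `n_genes`. Genes are assigned to pathways consecutively.
#' @param causal_pathways named list: pathway id -> list(n_causal, beta).
#'   Causal SNPs are drawn uniformly from the pathway's genes and act
#'   additively on the log-odds scale with effect `beta` per allele.
#' @param baseline_alpha0 log-odds intercept of the disease model.
#' @param covariate_effects named list of log-odds effects: `age_group`
#'   (length-5 vector), `sex` (scalar), `study` (vector, one per study).
#' @param n_studies number of study labels.
#' @param structure_fst Balding-Nichols differentiation between
#'   subpopulations, in [0, 1). 0 disables structure.
#' @param subpop_fractions proportions of subjects per subpopulation;
#'   must sum to 1.
#' @param ancestry_effects log-odds offset added to the disease model per
#'   subpopulation (recycled); nonzero values make ancestry a confounder,
#'   the scenario population-structure adjustment exists for.
#' @param missing_rate fraction of dosages set missing completely at random.
#' @param hwe_violation_snps number of SNP columns replaced by
#'   heterozygote-depleted genotypes.
#' @param pool_multiplier subject-pool size as a multiple of
#'   `n_cases + n_controls` for retrospective sampling.
#' @param seed integer seed; the whole dataset is reproducible from it.
#' @return an object of class `synthetic_config` (a validated list).
#' @export
synthetic_config <- function(n_cases = 200, n_controls = 200,
                             n_genes = 40,
                             snps_per_gene = c(3L, 6L),
                             maf_range = c(0.1, 0.4),
                             ld_rho = 0.5,
                             pathway_sizes = rep(10L, 4L),
                             causal_pathways = list(),
                             baseline_alpha0 = -1,
                             covariate_effects = list(),
                             n_studies = 2L,
                             structure_fst = 0,
                             subpop_fractions = 1,
                             ancestry_effects = 0,
                             missing_rate = 0,
                             hwe_violation_snps = 0L,
                             pool_multiplier = 20,
                             seed = 1L) {
  cfg <- list(n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
              n_genes = as.integer(n_genes),
              snps_per_gene = as.integer(snps_per_gene),
              maf_range = maf_range, ld_rho = ld_rho,
              pathway_sizes = as.integer(pathway_sizes),
              causal_pathways = causal_pathways,
              baseline_alpha0 = baseline_alpha0,
              covariate_effects = covariate_effects,
              n_studies = as.integer(n_studies),
              structure_fst = structure_fst,
              subpop_fractions = subpop_fractions,
              ancestry_effects = ancestry_effects,
              missing_rate = missing_rate,
              hwe_violation_snps = as.integer(hwe_violation_snps),
              pool_multiplier = pool_multiplier,
              seed = as.integer(seed))
  stopifnot(cfg$n_cases > 0, cfg$n_controls > 0, cfg$n_genes > 0,
            length(cfg$snps_per_gene) == 2L, all(cfg$snps_per_gene >= 1L),
            cfg$snps_per_gene[1] <= cfg$snps_per_gene[2])
  if (cfg$maf_range[1] <= 0 || cfg$maf_range[2] > 0.5)
    stop("maf_range must lie within (0, 0.5]")
  if (cfg$ld_rho < 0 || cfg$ld_rho >= 1) stop("ld_rho must be in [0, 1)")
  if (abs(sum(cfg$subpop_fractions) - 1) > 1e-8)
    stop("subpop_fractions must sum to 1")
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1)
    stop("missing_rate must be in [0, 1)")
  if (sum(cfg$pathway_sizes) > cfg$n_genes)
    stop("pathway_sizes sum exceeds n_genes")
  for (pw in names(cfg$causal_pathways))
    if (!pw %in% paste0("pw", seq_along(cfg$pathway_sizes)))
      stop("unknown causal pathway id: ", pw)
  class(cfg) <- "synthetic_config"
  cfg
}

#' Simulate one gene's dosage block under the Gaussian-copula LD model
#'
#' Each dosage is the sum of two independent latent haplotypes; a haplotype is
#' an AR(1) standard-normal vector with lag-one correlation `rho`, thresholded
#' at `qnorm(maf)` per SNP. Marginal genotype frequencies are exact
#' Hardy-Weinberg proportions at `maf`; adjacent-SNP dosage correlation grows
#' with `rho`.
#'
#' @param n_subjects number of subjects.
#' @param n_snps number of SNPs; `maf` is recycled to this length.
#' @param maf per-SNP allele frequencies in (0, 0.5].
#' @param rho AR(1) latent correlation in [0, 1).
#' @param subpop optional integer vector (length `n_subjects`) of
#'   subpopulation labels, used with `subpop_freqs`.
#' @param subpop_freqs optional matrix (subpopulations x SNPs) of
#'   per-subpopulation allele frequencies overriding `maf`.
#' @return integer dosage matrix (subjects x SNPs) with entries in 0:2.
#' @export
simulate_gene_block <- function(n_subjects, n_snps, maf, rho,
                                subpop = NULL, subpop_freqs = NULL) {
  if (n_snps < 1) stop("n_snps must be positive")
  if (rho < 0 || rho >= 1) stop("rho must be in [0, 1)")
  maf <- rep_len(maf, n_snps)
  if (is.null(subpop_freqs) && (any(maf <= 0) || any(maf > 0.5)))
    stop("maf must lie in (0, 0.5]")
  haplo <- function() {
    z <- matrix(rnorm(n_subjects * n_snps), n_subjects, n_snps)
    if (rho > 0 && n_snps > 1) {
      s <- sqrt(1 - rho^2)
      for (j in 2:n_snps) z[, j] <- rho * z[, j - 1] + s * z[, j]
    }
    z
  }
  thr <- if (is.null(subpop_freqs)) {
    matrix(qnorm(maf), n_subjects, n_snps, byrow = TRUE)
  } else {
    stopifnot(!is.null(subpop), nrow(subpop_freqs) >= max(subpop))
    qnorm(subpop_freqs)[subpop, , drop = FALSE]
  }
  d <- (haplo() < thr) + (haplo() < thr)
  storage.mode(d) <- "integer"
  d
}

#' Simulate binary disease status under an additive logistic model
#'
#' P(case) = logistic(alpha0 + sum(beta * dosage) + covariate terms), sampled
#' independently per subject.
#'
#' @param dosages dosage matrix with named columns (SNP ids).
#' @param causal_map named numeric vector: SNP id -> log-odds per allele.
#' @param covariates optional data frame of covariates.
#' @param alpha0 log-odds intercept (scalar, or one value per subject).
#' @param covariate_effects named list of effects; for a factor column a
#'   vector of per-level effects (first level is reference 0 if one short),
#'   for a numeric column a scalar.
#' @return integer vector of 0/1 phenotypes (1 = case).
#' @export
simulate_phenotype <- function(dosages, causal_map = numeric(0),
                               covariates = NULL, alpha0 = -1,
                               covariate_effects = list()) {
  eta <- rep_len(as.numeric(alpha0), nrow(dosages))
  if (length(causal_map)) {
    miss <- setdiff(names(causal_map), colnames(dosages))
    if (length(miss)) stop("unknown causal SNP id: ", paste(miss, collapse = ", "))
    eta <- eta + dosages[, names(causal_map), drop = FALSE] %*% causal_map
  }
  for (nm in names(covariate_effects)) {
    if (is.null(covariates) || !nm %in% names(covariates))
      stop("covariate not found: ", nm)
    x <- covariates[[nm]]
    ef <- covariate_effects[[nm]]
    if (is.factor(x) || is.character(x)) {
      f <- as.factor(x)
      if (length(ef) == nlevels(f) - 1L) ef <- c(0, ef)
      stopifnot(length(ef) == nlevels(f))
      eta <- eta + ef[as.integer(f)]
    } else {
      eta <- eta + ef * x
    }
  }
  p <- 1 / (1 + exp(-as.numeric(eta)))
  as.integer(runif(length(p)) < p)
}

#' Generate a complete synthetic case-control GWAS dataset
#'
#' Simulates a subject pool of `pool_multiplier * (n_cases + n_controls)`
#' subjects, assigns disease status under the additive logistic model, then
#' samples exactly the target numbers of cases and controls (retrospective
#' design). Genes get consecutive non-overlapping coordinate intervals on one
#' chromosome with SNP positions inside them; pathways are consecutive blocks
#' of genes. Missingness is injected completely at random, and a chosen
#' number of SNP columns are replaced by heterozygote-depleted genotypes
#' (half of the heterozygotes moved to homozygotes, split evenly) to create
#' detectable Hardy-Weinberg violations.
#'
#' @param config a [synthetic_config()].
#' @return an object of class `genotype_dataset`: a list with `dosages`
#'   (integer matrix, `NA` = missing), `snp_meta` (snp_id, chrom, pos,
#'   allele1, allele2, gene), `phenotype` (1 = case), `covariates`,
#'   `gene_regions` (0-based half-open BED-style intervals), `pathways`
#'   (named list of gene symbols), and `truth` (causal SNPs and betas,
#'   causal pathways, ancestry labels).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, generate_dataset_impl(config))
}

generate_dataset_impl <- function(cfg) {
  n_target <- cfg$n_cases + cfg$n_controls
  n_pool <- ceiling(cfg$pool_multiplier * n_target)
  n_sub <- length(cfg$subpop_fractions)

  ## gene layout: 50 kb genes every 120 kb on chromosome 1 (gaps exceed the
  ## 2 x 20 kb mapping window, so gene windows never overlap)
  gene_len <- 50000L; gene_gap <- 120000L
  genes <- sprintf("GENE%03d", seq_len(cfg$n_genes))
  g_start <- (seq_len(cfg$n_genes) - 1L) * gene_gap + 100000L
  gene_regions <- data.frame(chrom = "1", start = g_start,
                             end = g_start + gene_len, gene = genes,
                             stringsAsFactors = FALSE)

  snp_range <- seq(cfg$snps_per_gene[1], cfg$snps_per_gene[2])
  n_snps_gene <- snp_range[sample.int(length(snp_range), cfg$n_genes,
                                      replace = TRUE)]
  subpop <- sample.int(n_sub, n_pool, replace = TRUE,
                       prob = cfg$subpop_fractions)

  blocks <- vector("list", cfg$n_genes)
  meta <- vector("list", cfg$n_genes)
  for (g in seq_len(cfg$n_genes)) {
    m <- n_snps_gene[g]
    maf <- runif(m, cfg$maf_range[1], cfg$maf_range[2])
    sp_freq <- NULL
    if (cfg$structure_fst > 0 && n_sub > 1) {
      fst <- cfg$structure_fst
      a <- maf * (1 - fst) / fst
      b <- (1 - maf) * (1 - fst) / fst
      sp_freq <- matrix(0, n_sub, m)
      for (k in seq_len(n_sub))
        sp_freq[k, ] <- pmin(pmax(rbeta(m, a, b), 0.01), 0.99)
    }
    blocks[[g]] <- simulate_gene_block(n_pool, m, maf, cfg$ld_rho,
                                       subpop = subpop,
                                       subpop_freqs = sp_freq)
    pos <- sort(sample.int(gene_len - 2L, m)) + g_start[g] + 1L
    meta[[g]] <- data.frame(
      snp_id = sprintf("rs%03d_%02d", g, seq_len(m)),
      chrom = "1", pos = pos, allele1 = "A", allele2 = "B",
      gene = genes[g], stringsAsFactors = FALSE)
    colnames(blocks[[g]]) <- meta[[g]]$snp_id
  }
  dosages <- do.call(cbind, blocks)
  snp_meta <- do.call(rbind, meta)

  ## pathways: consecutive blocks of genes
  pw_ids <- paste0("pw", seq_along(cfg$pathway_sizes))
  stops <- cumsum(cfg$pathway_sizes)
  starts <- c(1L, head(stops, -1L) + 1L)
  pathways <- mapply(function(s, e) genes[s:e], starts, stops,
                     SIMPLIFY = FALSE)
  names(pathways) <- pw_ids

  ## causal SNPs inside the designated pathways
  causal_map <- numeric(0)
  for (pw in names(cfg$causal_pathways)) {
    spec <- cfg$causal_pathways[[pw]]
    cand <- snp_meta$snp_id[snp_meta$gene %in% pathways[[pw]]]
    if (spec$n_causal > length(cand))
      stop("pathway ", pw, " has fewer SNPs than requested causal count")
    picked <- sample(cand, spec$n_causal)
    causal_map[picked] <- spec$beta
  }

  ## covariates for the pool
  covariates <- data.frame(
    age_group = factor(sample(paste0("age", 1:5), n_pool, replace = TRUE)),
    sex = sample(0:1, n_pool, replace = TRUE),
    study = factor(sample(paste0("study", seq_len(cfg$n_studies)), n_pool,
                          replace = TRUE)))

  alpha0 <- cfg$baseline_alpha0 +
    rep_len(cfg$ancestry_effects, n_sub)[subpop]
  y <- simulate_phenotype(dosages, causal_map, covariates,
                          alpha0, cfg$covariate_effects)

  idx_case <- which(y == 1L); idx_ctrl <- which(y == 0L)
  if (length(idx_case) < cfg$n_cases || length(idx_ctrl) < cfg$n_controls)
    stop(sprintf(
      "subject pool exhausted: achievable prevalence %.3f yielded %d cases / %d controls (need %d / %d)",
      mean(y), length(idx_case), length(idx_ctrl), cfg$n_cases, cfg$n_controls))
  keep <- c(sample(idx_case, cfg$n_cases), sample(idx_ctrl, cfg$n_controls))
  dosages <- dosages[keep, , drop = FALSE]
  covariates <- droplevels(covariates[keep, , drop = FALSE])
  y <- y[keep]
  subpop <- subpop[keep]
  rownames(dosages) <- sprintf("S%05d", seq_along(keep))
  rownames(covariates) <- rownames(dosages)

  ## Hardy-Weinberg violation: deplete heterozygotes in chosen columns
  hwe_viol <- character(0)
  if (cfg$hwe_violation_snps > 0) {
    hwe_viol <- sample(colnames(dosages),
                       min(cfg$hwe_violation_snps, ncol(dosages)))
    for (s in hwe_viol) {
      het <- which(dosages[, s] == 1L)
      mv <- sample(het, floor(length(het) / 2))
      half <- seq_along(mv) <= length(mv) / 2
      dosages[mv[half], s] <- 0L
      dosages[mv[!half], s] <- 2L
    }
  }

  if (cfg$missing_rate > 0) {
    miss <- runif(length(dosages)) < cfg$missing_rate
    dosages[miss] <- NA_integer_
  }

  structure(list(
    dosages = dosages, snp_meta = snp_meta, phenotype = y,
    covariates = covariates, gene_regions = gene_regions,
    pathways = pathways,
    truth = list(causal_snps = names(causal_map), causal_beta = causal_map,
                 causal_pathways = names(cfg$causal_pathways),
                 ancestry = subpop, hwe_violation_snps = hwe_viol),
    config = cfg), class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat(sprintf("genotype_dataset: %d subjects (%d cases), %d SNPs in %d genes, %d pathways\n",
              nrow(x$dosages), sum(x$phenotype), ncol(x$dosages),
              length(unique(x$snp_meta$gene)), length(x$pathways)))
  invisible(x)
}

#' Write a small named synthetic dataset to disk for tests and examples
#'
#' Profiles: `"null"` (no causal SNPs), `"causal"` (one causal pathway with
#' 10 causal SNPs at beta 0.3), `"structured"` (two subpopulations at
#' Fst 0.05, no causal SNPs).
#'
#' @param profile one of `"null"`, `"causal"`, `"structured"`.
#' @param seed integer seed.
#' @param dir output directory (created if needed).
#' @return invisibly, the `genotype_dataset`; side effect: PLINK .ped/.map,
#'   gene BED, pathway GMT, covariate TSV and truth JSON under `dir`.
#' @export
make_fixture <- function(profile = c("null", "causal", "structured"),
                         seed = 1L, dir = tempfile("fixture")) {
  profile <- match.arg(profile)
  base <- list(n_cases = 100, n_controls = 100, n_genes = 24,
               snps_per_gene = c(2L, 4L), pathway_sizes = rep(12L, 2L),
               missing_rate = 0.01, seed = seed)
  cfg <- switch(profile,
    null = do.call(synthetic_config, base),
    causal = do.call(synthetic_config, c(base, list(
      causal_pathways = list(pw1 = list(n_causal = 10, beta = 0.3))))),
    structured = do.call(synthetic_config, c(base, list(
      structure_fst = 0.05, subpop_fractions = c(0.5, 0.5)))))
  ds <- generate_dataset(cfg)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_dataset(ds, dir, prefix = profile)
  invisible(ds)
}
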