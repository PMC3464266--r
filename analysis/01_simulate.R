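#!/usr/bin/env Rscript
# Stage 1: simulate the study data.
#
# Generates a desk-scale case-control GWAS with the structure the analysis
# assumes: 400 subjects, 200 genes in 20 pathways of 10 genes, strong
# within-gene LD (so eigenSNP compression has something to compress), a
# single causal pathway (pw1: 10 causal SNPs at log-OR 0.3), 1% missingness
# and 5 heterozygote-depleted SNPs, plus age/sex/study covariates.
# Everything downstream reads the plain-text files this writes.

library(pathgwas)

seed <- 2026L
dir.create("results", showWarnings = FALSE)

cfg <- synthetic_config(
  n_cases = 200, n_controls = 200,
  n_genes = 200, snps_per_gene = c(4L, 10L), ld_rho = 0.9,
  pathway_sizes = rep(10L, 20),
  causal_pathways = list(pw1 = list(n_causal = 10, beta = 0.3)),
  missing_rate = 0.01, hwe_violation_snps = 5L,
  seed = seed)
ds <- generate_dataset(cfg)
write_dataset(ds, "results/dataset", prefix = "study")

cat("Simulated", nrow(ds$dosages), "subjects x", ncol(ds$dosages), "SNPs;",
    length(ds$pathways), "pathways;",
    length(ds$truth$causal_snps), "causal SNPs in pw1.\n")
cat("Files under results/dataset/: PLINK .ped/.map, gene BED, pathway GMT,",
    "covariate TSV, truth JSON.\n")
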