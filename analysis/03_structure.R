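#!/usr/bin/env Rscript
# Stage 3: population-structure principal components.
#
# LD-prunes the QC'd SNPs to a near-independent panel, computes
# EIGENSTRAT-style principal components and appends pc1..pc5 to the
# covariate table used by the gene-level kernel test.

library(pathgwas)

ds <- read_plink("results/dataset/study_qc")
ds$gene_regions <- read_bed("results/dataset/study_qc_genes.bed")
cv <- read_covariates("results/dataset/study_covariates.tsv")
ds$covariates <- cv[match(rownames(ds$dosages), rownames(cv)), , drop = FALSE]

ds <- add_structure_pcs(ds, k = 5)
pca <- attr(ds, "pca")
cat("PC panel:", nrow(pca$snp_loadings), "SNPs; top eigenvalues:",
    paste(signif(pca$eigenvalues, 3), collapse = " "), "\n")

out <- cbind(subject_id = rownames(ds$dosages), ds$covariates)
write.table(out, "results/covariates_with_pcs.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("Wrote results/covariates_with_pcs.tsv\n")
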