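#!/usr/bin/env Rscript
# Stage 8: functional enrichment of the top gene list.
#
# Takes the genes below the LKM p < 0.01 cutoff, scores every pathway term
# by the EASE-modified one-tailed Fisher exact test against the background
# of all tested genes, and groups similar terms by kappa clustering; each
# cluster is summarized by the mean -log10 of its members' p-values.

library(pathgwas)

lkm <- read.table("results/lkm_results.tsv", header = TRUE, sep = "\t")
terms <- read_gmt("results/dataset/study_qc_pathways.gmt")
mapping <- read.table("results/mapping.tsv", header = TRUE, sep = "\t")

hits <- lkm$gene[lkm$p_value < 0.01]
cat(length(hits), "genes below p = 0.01 enter the enrichment analysis\n")
enr <- run_enrichment(hits, terms, universe = unique(mapping$gene))

tab <- do.call(rbind, lapply(enr$clusters, function(cl) {
  m <- enr$terms[match(cl$term_ids, enr$terms$term_id), ]
  data.frame(cluster = cl$cluster_id,
             enrichment_score = round(cl$enrichment_score, 2),
             term = m$term_id, n_genes = m$k, p_value = m$ease_p)
}))
if (is.null(tab)) tab <- data.frame()
write.table(tab, "results/enrichment_clusters.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
print(head(tab, 10))
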