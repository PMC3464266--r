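# SNP-to-gene mapping (+/- 20 kb windows), pathway size filtering, and
# per-gene eigenSNP compression.

#' Map SNPs to gene regions with a flanking window
#'
#' A SNP is assigned to a gene iff its 0-based position lies in
#' `[start - window, end + window)` — inclusive lower bound, exclusive upper
#' (BED convention). `snp_meta` positions are 1-based (PLINK .map
#' convention) and converted internally. A SNP may map to several
#' overlapping genes.
#'
#' @param snp_meta data frame with columns snp_id, chrom, pos (1-based).
#' @param regions data frame with chrom, start, end (0-based half-open),
#'   gene.
#' @param window flanking window in bp (default 20000).
#' @param warn_empty warn about genes with zero mapped SNPs (dropped).
#' @return named list: gene symbol -> character vector of SNP ids.
#' @export
map_snps_to_genes <- function(snp_meta, regions, window = 20000,
                              warn_empty = TRUE) {
  stopifnot(window >= 0, all(regions$start < regions$end))
  pos0 <- snp_meta$pos - 1L
  out <- lapply(seq_len(nrow(regions)), function(i) {
    hit <- snp_meta$chrom == regions$chrom[i] &
      pos0 >= regions$start[i] - window &
      pos0 < regions$end[i] + window
    snp_meta$snp_id[hit]
  })
  names(out) <- regions$gene
  empty <- lengths(out) == 0
  if (any(empty) && warn_empty)
    warning(sum(empty), " gene(s) with no mapped SNPs dropped: ",
            paste(utils::head(names(out)[empty], 5), collapse = ", "))
  out[!empty]
}

#' Filter pathways by the number of genes with mapped SNPs
#'
#' A pathway is retained iff its count of member genes having at least one
#' mapped SNP lies in `[min_genes, max_genes]` (inclusive).
#'
#' @param pathways named list: pathway id -> gene symbols.
#' @param gene_map mapping from [map_snps_to_genes()].
#' @param min_genes,max_genes inclusive bounds (defaults 10 and 500).
#' @return retained pathways (named list, members restricted to mapped
#'   genes); excluded pathways recorded in attribute `"excluded"` with
#'   reasons `TOO_FEW`, `TOO_MANY` or `NO_GENES`.
#' @export
filter_pathways <- function(pathways, gene_map, min_genes = 10L,
                            max_genes = 500L) {
  mapped <- lapply(pathways, function(g) intersect(g, names(gene_map)))
  n <- lengths(mapped)
  reason <- ifelse(n == 0, "NO_GENES",
                   ifelse(n < min_genes, "TOO_FEW",
                          ifelse(n > max_genes, "TOO_MANY", "")))
  keep <- reason == ""
  out <- mapped[keep]
  attr(out, "excluded") <- data.frame(pathway = names(pathways)[!keep],
                                      n_genes = n[!keep],
                                      reason = reason[!keep],
                                      row.names = NULL)
  out
}

#' Compress a gene's SNPs into eigenSNPs by PCA
#'
#' Missing dosages are mean-imputed per SNP; columns are centered and (by
#' default) scaled to unit variance; PCA retains the smallest number of
#' components whose cumulative explained variance reaches
#' `variance_threshold`. Retained score columns are rescaled to unit sample
#' variance. Constant columns are dropped before the PCA; an all-constant
#' block yields zero eigenSNPs and is flagged.
#'
#' @param gene_dosages dosage matrix (subjects x SNPs of one gene).
#' @param variance_threshold cumulative explained-variance target
#'   (default 0.95).
#' @param scale. standardize SNP columns before PCA (correlation-matrix PCA,
#'   the default) or only center them.
#' @return an `eigen_snp_block`: list with `n_snps`, `n_eigensnps`, `scores`
#'   (subjects x eigenSNPs, unit variance), `loadings`,
#'   `variance_fractions`, `cumulative_variance`, `degenerate` flag.
#' @export
compute_eigensnps <- function(gene_dosages, variance_threshold = 0.95,
                              scale. = TRUE) {
  stopifnot(ncol(gene_dosages) >= 1)
  x <- apply(gene_dosages, 2, function(col) {
    mu <- mean(col, na.rm = TRUE)
    if (is.nan(mu)) mu <- 0
    col[is.na(col)] <- mu
    col
  })
  sds <- apply(x, 2, sd)
  keep <- sds > 1e-12
  if (!any(keep)) {
    return(structure(list(n_snps = ncol(gene_dosages), n_eigensnps = 0L,
                          scores = matrix(0, nrow(gene_dosages), 0),
                          loadings = matrix(0, ncol(gene_dosages), 0),
                          variance_fractions = numeric(0),
                          cumulative_variance = 0, degenerate = TRUE),
                     class = "eigen_snp_block"))
  }
  pc <- prcomp(x[, keep, drop = FALSE], center = TRUE, scale. = scale.)
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  pos <- pc$sdev > pc$sdev[1] * 1e-8     # numerically nonzero components
  k <- min(which(cumsum(vf) >= variance_threshold - 1e-12))
  k <- min(k, sum(pos))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  scores <- sweep(scores, 2, apply(scores, 2, sd), `/`)
  colnames(scores) <- paste0("eig", seq_len(k))
  structure(list(n_snps = ncol(gene_dosages), n_eigensnps = k,
                 scores = scores,
                 loadings = pc$rotation[, seq_len(k), drop = FALSE],
                 variance_fractions = vf[seq_len(k)],
                 cumulative_variance = sum(vf[seq_len(k)]),
                 degenerate = FALSE),
            class = "eigen_snp_block")
}

#' Build eigenSNP blocks for every mapped gene
#'
#' @param dataset a `genotype_dataset`.
#' @param gene_map mapping from [map_snps_to_genes()].
#' @param variance_threshold passed to [compute_eigensnps()].
#' @return named list of `eigen_snp_block`s (degenerate genes dropped with a
#'   warning).
#' @export
build_eigensnp_blocks <- function(dataset, gene_map,
                                  variance_threshold = 0.95) {
  blocks <- lapply(gene_map, function(snps)
    compute_eigensnps(dataset$dosages[, snps, drop = FALSE],
                      variance_threshold))
  bad <- vapply(blocks, `[[`, logical(1), "degenerate")
  if (any(bad))
    warning("dropping ", sum(bad), " all-constant gene block(s): ",
            paste(names(blocks)[bad], collapse = ", "))
  blocks[!bad]
}
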