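# EIGENSTRAT-style principal components for population-structure adjustment.

#' Standardize a dosage matrix the EIGENSTRAT way
#'
#' Per SNP: missing entries are replaced by the SNP mean, the column is
#' centered at `2*p` and divided by `sqrt(2*p*(1-p))` where `p` is the sample
#' allele frequency. Monomorphic columns become all zeros.
#'
#' @param dosages dosage matrix (subjects x SNPs), NA = missing.
#' @return numeric standardized matrix of the same shape.
#' @export
standardize_genotypes <- function(dosages) {
  stopifnot(nrow(dosages) >= 2)
  x <- apply(dosages, 2, function(col) {
    mu <- mean(col, na.rm = TRUE)
    if (is.nan(mu)) mu <- 0
    col[is.na(col)] <- mu
    p <- mu / 2
    s <- sqrt(2 * p * (1 - p))
    if (s < 1e-12) rep(0, length(col)) else (col - mu) / s
  })
  dimnames(x) <- dimnames(dosages)
  x
}

#' Top principal components of a standardized genotype matrix
#'
#' Scores are projections of subjects onto the top-k right singular
#' directions of the subjects x SNPs matrix. Sign convention: each loading
#' vector has a positive sum (flipped otherwise) so results are reproducible
#' across platforms.
#'
#' @param standardized matrix from [standardize_genotypes()].
#' @param k number of components (default 5, matching the five covariate PCs
#'   used downstream).
#' @return list with `scores` (subjects x k), `eigenvalues` (descending;
#'   singular values squared over subjects - 1), `snp_loadings`, `k`.
#' @export
top_principal_components <- function(standardized, k = 5L) {
  stopifnot(k >= 1, k <= min(dim(standardized)))
  sv <- svd(standardized, nu = k, nv = k)
  ev <- sv$d^2 / (nrow(standardized) - 1)
  rank <- sum(sv$d > sv$d[1] * 1e-10)
  if (k > rank) {
    warning("requested ", k, " components but rank is ", rank,
            "; returning ", rank)
    k <- rank
  }
  flip <- ifelse(colSums(sv$v[, seq_len(k), drop = FALSE]) < 0, -1, 1)
  scores <- sweep(sv$u[, seq_len(k), drop = FALSE] %*%
                    diag(sv$d[seq_len(k)], k), 2, flip, `*`)
  loadings <- sweep(sv$v[, seq_len(k), drop = FALSE], 2, flip, `*`)
  dimnames(scores) <- list(rownames(standardized), paste0("pc", seq_len(k)))
  rownames(loadings) <- colnames(standardized)
  list(scores = scores, eigenvalues = ev[seq_len(k)],
       snp_loadings = loadings, k = k)
}

#' Compute structure PCs and merge them into the covariate table
#'
#' Convenience wrapper used by the pipeline: LD-prunes the SNP set down to a
#' near-independent panel, standardizes, extracts `k` PCs and appends them
#' as covariate columns `pc1..pck`.
#'
#' The default pruning threshold is `max(0.004, 20/n)`: 0.004 is the
#' conventional structure-panel cutoff for biobank-scale cohorts, but the
#' squared correlation between truly independent SNPs has sampling scale
#' `1/n`, so at small `n` a fixed 0.004 would prune on noise and starve the
#' panel; the `20/n` floor keeps the false-pruning probability per pair
#' below 1e-5 while still removing real LD.
#'
#' @param dataset a `genotype_dataset`.
#' @param k number of PCs (default 5).
#' @param r2_threshold LD-pruning threshold; `NA` for the adaptive default,
#'   `NULL` skips pruning.
#' @return the dataset with `covariates` extended and the `pca` result
#'   attached as attribute `"pca"`.
#' @export
add_structure_pcs <- function(dataset, k = 5L, r2_threshold = NA) {
  d <- dataset$dosages
  if (!is.null(r2_threshold)) {
    if (is.na(r2_threshold)) r2_threshold <- max(0.004, 20 / nrow(d))
    keep <- ld_prune(d, r2_threshold, dataset$snp_meta)
    if (length(keep) >= k) d <- d[, keep, drop = FALSE]
  }
  pca <- top_principal_components(standardize_genotypes(d), k)
  cov <- dataset$covariates
  cov <- cov[, !grepl("^pc[0-9]+$", names(cov)), drop = FALSE]
  dataset$covariates <- cbind(cov, as.data.frame(pca$scores))
  attr(dataset, "pca") <- pca
  dataset
}
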