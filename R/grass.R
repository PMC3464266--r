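# GRASS pathway association test: ridge-penalized logistic regression on a
# pathway's eigenSNPs, permutation-standardized gene-level statistics, the
# pathway statistic S = sqrt(sum of squared standardized gene statistics),
# and a two-stage permutation p-value.

#' Configuration for the GRASS pathway test
#'
#' @param penalty_grid ridge tuning values, log-spaced; sorted descending
#'   internally so cross-validation ties resolve toward the stronger penalty.
#' @param cv_folds number of cross-validation folds (default 5).
#' @param stage1_B stage-1 permutation count (default 5000; desk-scale runs
#'   typically use a few hundred).
#' @param stage2_B stage-2 permutation count for escalated pathways
#'   (default 50000).
#' @param escalation_threshold stage-1 p-value at or below which a pathway is
#'   re-tested at `stage2_B` (default 0.00025).
#' @param permutation_stratified_by optional covariate name; permutations
#'   shuffle phenotypes within its levels.
#' @param freeze_tuning if `TRUE`, the penalty selected on the observed data
#'   is reused for every permutation instead of re-selected. Faster, but the
#'   permutation null then conditions on an observed-data quantity, which
#'   slightly breaks exchangeability; off by default.
#' @param seed integer seed driving folds and permutation streams.
#' @return a `grass_config` list.
#' @export
grass_config <- function(penalty_grid = exp(seq(log(200), log(0.05),
                                                length.out = 6)),
                         cv_folds = 5L, stage1_B = 5000L, stage2_B = 50000L,
                         escalation_threshold = 0.00025,
                         permutation_stratified_by = NULL,
                         freeze_tuning = FALSE, seed = 1L) {
  stopifnot(stage2_B > stage1_B, escalation_threshold > 0,
            escalation_threshold < 1, cv_folds >= 2,
            all(penalty_grid >= 0))
  structure(list(penalty_grid = sort(penalty_grid, decreasing = TRUE),
                 cv_folds = as.integer(cv_folds),
                 stage1_B = as.integer(stage1_B),
                 stage2_B = as.integer(stage2_B),
                 escalation_threshold = escalation_threshold,
                 permutation_stratified_by = permutation_stratified_by,
                 freeze_tuning = isTRUE(freeze_tuning),
                 seed = as.integer(seed)),
            class = "grass_config")
}

make_folds <- function(n, k) sample(rep_len(seq_len(k) - 1L, n))

make_perms <- function(n, B, strata = NULL) {
  perm <- matrix(0L, n, B)
  for (b in seq_len(B)) {
    if (is.null(strata)) {
      perm[, b] <- sample.int(n)
    } else {
      idx <- seq_len(n)
      for (lev in unique(strata)) {
        w <- which(strata == lev)
        idx[w] <- w[sample.int(length(w))]
      }
      perm[, b] <- idx
    }
  }
  perm - 1L  # 0-based for the C++ engine
}

#' Ridge-penalized logistic regression over a pathway's eigenSNPs
#'
#' Fits all of the pathway's eigenSNPs jointly with an L2 penalty on the
#' non-intercept coefficients; the tuning value is selected from
#' `config$penalty_grid` by minimizing k-fold cross-validated binomial
#' deviance under a deterministic, seed-fixed fold assignment.
#'
#' @param eigensnps numeric matrix (subjects x eigenSNPs), unit-variance
#'   columns.
#' @param phenotype binary vector (1 = case); both classes must be present.
#' @param config a [grass_config()].
#' @param fold_ids optional 0-based fold assignment; by default drawn from
#'   `config$seed`.
#' @return list with `coefficients` (intercept first), `lambda` (selected
#'   tuning value), `cv_deviance` (per grid value), `fold_ids`.
#' @export
fit_penalized_logistic <- function(eigensnps, phenotype, config,
                                   fold_ids = NULL) {
  stopifnot(length(unique(phenotype)) == 2)
  if (is.null(fold_ids))
    fold_ids <- with_seed(config$seed,
                          make_folds(nrow(eigensnps), config$cv_folds))
  fit <- cpp_cv_ridge_fit(eigensnps, as.numeric(phenotype),
                          config$penalty_grid, as.integer(fold_ids))
  if (fit$n_nonconverged > 0)
    stop("ridge fit failed to converge at lambda = ",
         signif(config$penalty_grid[fit$lambda_index], 4))
  cf <- as.numeric(fit$beta)
  names(cf) <- c("(intercept)", colnames(eigensnps))
  list(coefficients = cf, lambda = config$penalty_grid[fit$lambda_index],
       cv_deviance = as.numeric(fit$cv_deviance), fold_ids = fold_ids)
}

#' Per-gene coefficient norms
#'
#' `gamma_g = sqrt(sum over the gene's eigenSNP coefficients squared)`.
#'
#' @param coefficients coefficient vector including the intercept first.
#' @param block_index named list: gene -> positions within the non-intercept
#'   coefficients.
#' @return named numeric vector of gene norms.
#' @export
gene_norms <- function(coefficients, block_index) {
  stopifnot(all(lengths(block_index) > 0))
  beta <- coefficients[-1]
  vapply(block_index, function(ix) sqrt(sum(beta[ix]^2)), numeric(1))
}

#' Permutation null distribution of the gene norms
#'
#' For each permutation the phenotype labels are shuffled (optionally within
#' strata) and the full penalized fit — including tuning selection — is
#' re-run; the per-gene coefficient norms are recorded. Fold assignment is
#' fixed across permutations.
#'
#' @param eigensnps subjects x eigenSNPs matrix.
#' @param phenotype binary vector.
#' @param config a [grass_config()].
#' @param B number of permutations (>= 100).
#' @param gene_sizes integer vector of eigenSNP counts per gene, in column
#'   order.
#' @param strata optional stratification labels for the permutations.
#' @param perm_seed seed for the permutation stream (default `config$seed`).
#' @return matrix (B x genes) of permutation gene norms; attribute
#'   `"lambda_index"` records the tuning chosen per permutation.
#' @export
permutation_null <- function(eigensnps, phenotype, config, B, gene_sizes,
                             strata = NULL, perm_seed = config$seed) {
  stopifnot(B >= 100)
  n <- nrow(eigensnps)
  setup <- with_seed(perm_seed, list(folds = make_folds(n, config$cv_folds),
                                     perms = make_perms(n, B, strata)))
  grid <- config$penalty_grid
  if (config$freeze_tuning) {
    obs <- fit_penalized_logistic(eigensnps, phenotype, config,
                                  fold_ids = setup$folds)
    grid <- obs$lambda
  }
  res <- cpp_grass_permutations(eigensnps, as.numeric(phenotype),
                                as.integer(gene_sizes), setup$perms, grid,
                                as.integer(setup$folds))
  if (res$n_nonconverged > 0)
    warning(res$n_nonconverged, " non-converged permutation fit(s)")
  gm <- res$gamma
  colnames(gm) <- names(gene_sizes)
  attr(gm, "lambda_index") <- as.integer(res$lambda_index)
  attr(gm, "fold_ids") <- setup$folds
  gm
}

#' Pathway statistic from standardized gene statistics
#'
#' `S = sqrt(sum of t_g^2)`.
#'
#' @param gene_stats data frame with a `t` column, or a numeric vector of
#'   standardized gene statistics.
#' @return the pathway statistic S.
#' @export
pathway_statistic <- function(gene_stats) {
  t <- if (is.data.frame(gene_stats)) gene_stats$t else gene_stats
  if (!length(t)) stop("no gene statistics")
  sqrt(sum(t^2))
}

#' Permutation p-value for a pathway statistic
#'
#' `p = (1 + #\{S_b >= S_observed\}) / (1 + B)`, so p is never 0 and the
#' test is valid by construction.
#'
#' @param S_observed observed pathway statistic.
#' @param S_permuted vector of permutation statistics.
#' @return p-value in (0, 1].
#' @export
pathway_pvalue <- function(S_observed, S_permuted) {
  stopifnot(length(S_permuted) >= 1)
  (1 + sum(S_permuted >= S_observed)) / (1 + length(S_permuted))
}

# Full single-pathway GRASS test at B permutations.
grass_one <- function(X, gene_sizes, phenotype, config, B, strata,
                      fold_seed, perm_seed) {
  folds <- with_seed(fold_seed, make_folds(nrow(X), config$cv_folds))
  obs <- fit_penalized_logistic(X, phenotype, config, fold_ids = folds)
  ends <- cumsum(gene_sizes); starts <- c(1L, head(ends, -1L) + 1L)
  block_index <- mapply(function(s, e) s:e, starts, ends, SIMPLIFY = FALSE)
  names(block_index) <- names(gene_sizes)
  gamma_obs <- gene_norms(obs$coefficients, block_index)
  gm <- permutation_null(X, phenotype, config, B, gene_sizes,
                         strata = strata, perm_seed = perm_seed)
  mu <- colMeans(gm)
  sigma <- apply(gm, 2, sd)
  std <- function(g) ifelse(sigma > 0, (g - mu) / sigma, 0)
  t_obs <- std(gamma_obs)
  S_obs <- pathway_statistic(t_obs)
  S_perm <- apply(gm, 1, function(g) pathway_statistic(std(g)))
  list(S = S_obs, p_value = pathway_pvalue(S_obs, S_perm), B_used = B,
       gene_stats = data.frame(gene = names(gene_sizes), gamma = gamma_obs,
                               mu = mu, sigma = sigma, t = t_obs,
                               row.names = NULL),
       lambda = obs$lambda, S_perm = S_perm)
}

#' Run the GRASS test over all retained pathways
#'
#' Stage 1 tests every pathway at `stage1_B` permutations; pathways with a
#' stage-1 p-value at or below `escalation_threshold` are re-tested at
#' `stage2_B` with a fresh permutation stream (stage-2 results replace
#' stage 1). The Bonferroni threshold 0.05 / (pathways tested) is attached.
#'
#' @param dataset a `genotype_dataset` (supplies the phenotype and, for
#'   stratified permutations, the covariates).
#' @param pathways named list: pathway id -> gene symbols (already filtered).
#' @param blocks named list of `eigen_snp_block`s from
#'   [build_eigensnp_blocks()].
#' @param config a [grass_config()].
#' @return data frame sorted by p-value: pathway, n_genes, n_snps,
#'   n_eigensnps, S, p_value, B_used, escalated; per-pathway gene statistics
#'   in attribute `"gene_stats"`, Bonferroni threshold in attribute
#'   `"bonferroni"`.
#' @export
run_grass <- function(dataset, pathways, blocks, config = grass_config()) {
  strata <- NULL
  if (!is.null(config$permutation_stratified_by))
    strata <- dataset$covariates[[config$permutation_stratified_by]]
  y <- dataset$phenotype
  res <- vector("list", length(pathways))
  for (i in seq_along(pathways)) {
    pw <- names(pathways)[i]
    genes <- intersect(pathways[[pw]], names(blocks))
    bl <- blocks[genes]
    X <- do.call(cbind, lapply(bl, `[[`, "scores"))
    gene_sizes <- vapply(bl, `[[`, integer(1), "n_eigensnps")
    fold_seed <- stage_seed(config$seed, paste0("folds_", pw))
    r <- grass_one(X, gene_sizes, y, config, config$stage1_B, strata,
                   fold_seed, stage_seed(config$seed, paste0("perm1_", pw)))
    escalated <- r$p_value <= config$escalation_threshold
    if (escalated)
      r <- grass_one(X, gene_sizes, y, config, config$stage2_B, strata,
                     fold_seed, stage_seed(config$seed, paste0("perm2_", pw)))
    res[[i]] <- list(row = data.frame(
      pathway = pw, n_genes = length(genes),
      n_snps = sum(vapply(bl, `[[`, integer(1), "n_snps")),
      n_eigensnps = sum(gene_sizes), S = r$S, p_value = r$p_value,
      B_used = r$B_used, escalated = escalated, stringsAsFactors = FALSE),
      gene_stats = r$gene_stats)
  }
  out <- do.call(rbind, lapply(res, `[[`, "row"))
  gene_stats <- lapply(res, `[[`, "gene_stats")
  names(gene_stats) <- out$pathway
  ord <- order(out$p_value)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "gene_stats") <- gene_stats
  attr(out, "bonferroni") <- signif(0.05 / nrow(out), 2)
  out
}
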