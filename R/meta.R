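# Two-cohort replication: stratified random splitting, Stouffer z-score
# combination of p-values, and the replication report.

#' Stouffer z-score combination of two p-values
#'
#' One-sided combination: `z_i = qnorm(1 - p_i)`,
#' `z_meta = (z1 + z2) / sqrt(2)` (equal weights),
#' `p_meta = 1 - pnorm(z_meta)`. Inputs of exactly 0 or 1 are clamped — to
#' `[1/(2*B_used), 1 - 1/(2*B_used)]` when a permutation count is supplied,
#' else to `[1e-15, 1 - 1e-15]` — with a warning.
#'
#' @param p1,p2 cohort p-values in (0, 1).
#' @param B_used optional permutation count behind the p-values, used for
#'   clamping degenerate inputs.
#' @param weights optional cohort weights (e.g. sqrt of sample sizes);
#'   default equal. `z_meta = sum(w z) / sqrt(sum(w^2))`.
#' @return data frame row: p1, p2, z1, z2, z_meta, p_meta.
#' @export
stouffer_combine <- function(p1, p2, B_used = NULL, weights = c(1, 1)) {
  clamp <- function(p) {
    if (p < 0 || p > 1) stop("p-values must lie in [0, 1]")
    lo <- if (!is.null(B_used)) 1 / (2 * B_used) else 1e-15
    if (p == 0 || p == 1) {
      warning("degenerate p-value ", p, " clamped")
      p <- min(max(p, lo), 1 - lo)
    }
    p
  }
  p1 <- clamp(p1); p2 <- clamp(p2)
  z <- qnorm(1 - c(p1, p2))
  z_meta <- sum(weights * z) / sqrt(sum(weights^2))
  data.frame(p1 = p1, p2 = p2, z1 = z[1], z2 = z[2], z_meta = z_meta,
             p_meta = pnorm(z_meta, lower.tail = FALSE))
}

#' Randomly split a dataset into two halves, stratified by case status
#'
#' Each half preserves the case fraction within one subject; reproducible
#' from `seed`.
#'
#' @param dataset a `genotype_dataset`.
#' @param seed integer seed.
#' @return list of two `genotype_dataset`s.
#' @export
random_split <- function(dataset, seed = 1L) {
  y <- dataset$phenotype
  if (sum(y == 1) < 2 || sum(y == 0) < 2)
    stop("need at least 2 cases and 2 controls to split")
  pick <- with_seed(seed, {
    half <- function(idx) sample(idx, floor(length(idx) / 2))
    c(half(which(y == 1)), half(which(y == 0)))
  })
  subset_ds <- function(ix) {
    out <- dataset
    out$dosages <- dataset$dosages[ix, , drop = FALSE]
    out$phenotype <- dataset$phenotype[ix]
    out$covariates <- droplevels(dataset$covariates[ix, , drop = FALSE])
    if (!is.null(out$truth)) out$truth$ancestry <- dataset$truth$ancestry[ix]
    out
  }
  list(subset_ds(sort(pick)),
       subset_ds(setdiff(seq_along(y), pick)))
}

#' Combine two cohort result tables into a replication report
#'
#' Joins the tables on the unit id (pathway or gene), applies
#' [stouffer_combine()] row-wise, and flags meta p-values significant after
#' Bonferroni correction at `0.05 / n_tests`. Ids present in only one table
#' are listed in a warning and excluded.
#'
#' @param results_a,results_b data frames with an id column (first column or
#'   `pathway`/`gene`) and a `p_value` column.
#' @param n_tests number of tests behind the Bonferroni flag (default: the
#'   number of matched units).
#' @return data frame: unit_id, p1, p2, z1, z2, z_meta, p_meta,
#'   significant_after_bonferroni.
#' @export
replicate_report <- function(results_a, results_b, n_tests = NULL) {
  idcol <- function(x) {
    nm <- intersect(c("pathway", "gene", "unit_id"), names(x))
    if (length(nm)) x[[nm[1]]] else x[[1]]
  }
  ida <- idcol(results_a); idb <- idcol(results_b)
  common <- intersect(ida, idb)
  mis <- union(setdiff(ida, idb), setdiff(idb, ida))
  if (length(mis))
    warning("unmatched unit id(s) excluded: ", paste(mis, collapse = ", "))
  if (is.null(n_tests)) n_tests <- length(common)
  rows <- lapply(common, function(id) {
    r <- stouffer_combine(results_a$p_value[match(id, ida)],
                          results_b$p_value[match(id, idb)])
    cbind(data.frame(unit_id = id, stringsAsFactors = FALSE), r)
  })
  out <- do.call(rbind, rows)
  out$significant_after_bonferroni <- out$p_meta < 0.05 / n_tests
  out[order(out$p_meta), , drop = FALSE]
}
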