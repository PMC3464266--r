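# DAVID-style functional enrichment: EASE-modified one-tailed Fisher exact
# p-values, Cohen's-kappa term similarity, greedy term clustering, and the
# cluster enrichment score (mean -log10 p of member terms).

#' EASE-modified one-tailed Fisher exact p-value
#'
#' Hypergeometric upper tail with the observed overlap reduced by one (the
#' EASE penalization): `p = P(X >= k - 1)` for an overlap of `k` genes
#' between a list of `n` and a term of `m` genes in a background of `N`;
#' `k <= 1` gives 1. Always at least the classical Fisher upper-tail p.
#'
#' @param k overlap count (list genes in the term).
#' @param n gene-list size.
#' @param m term size in the background.
#' @param N background size.
#' @return p-value in (0, 1].
#' @export
ease_fisher <- function(k, n, m, N) {
  if (k > min(n, m) || n > N || m > N || k < 0)
    stop("inconsistent counts: need k <= min(n, m) and n, m <= N")
  if (k <= 1) return(1)
  # P(X >= k - 1), X ~ Hypergeometric(N, m, n)
  phyper(k - 2, m, N - m, n, lower.tail = FALSE)
}

#' Cohen's kappa between two gene sets over a universe
#'
#' Chance-corrected agreement of the two binary membership vectors.
#'
#' @param term_a,term_b character vectors of gene symbols.
#' @param universe character vector; the comparison universe.
#' @return kappa in [-1, 1] (1 when both memberships are identical).
#' @export
kappa_similarity <- function(term_a, term_b, universe) {
  stopifnot(length(universe) > 0)
  a <- universe %in% term_a
  b <- universe %in% term_b
  po <- mean(a == b)
  pe <- mean(a) * mean(b) + mean(!a) * mean(!b)
  if (abs(1 - pe) < 1e-12) return(if (po == 1) 1 else 0)
  (po - pe) / (1 - pe)
}

#' Greedy kappa clustering of enrichment terms
#'
#' Repeatedly seeds a cluster at the unclustered term with the most partners
#' at kappa >= `kappa_threshold` and groups it with those partners; ties are
#' broken by term order; remaining terms become singleton clusters. A
#' deterministic, documented stand-in for fuzzy annotation clustering.
#'
#' @param results data frame of enrichment results with columns `term_id`
#'   and `ease_p`.
#' @param term_genes named list: term_id -> gene symbols.
#' @param universe comparison universe for [kappa_similarity()].
#' @param kappa_threshold clustering threshold (default 0.5).
#' @return list of clusters; each is a list with `cluster_id`, `term_ids`,
#'   `enrichment_score` (mean -log10 ease_p of members).
#' @export
cluster_terms <- function(results, term_genes, universe,
                          kappa_threshold = 0.5) {
  ids <- results$term_id
  stopifnot(length(ids) >= 1, all(ids %in% names(term_genes)))
  n <- length(ids)
  kap <- diag(1, n)
  if (n > 1) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      kap[i, j] <- kap[j, i] <-
        kappa_similarity(term_genes[[ids[i]]], term_genes[[ids[j]]], universe)
    }
  }
  linked <- kap >= kappa_threshold
  diag(linked) <- FALSE
  unused <- rep(TRUE, n)
  clusters <- list()
  repeat {
    deg <- colSums(linked[unused, , drop = FALSE]) * unused
    if (!any(deg > 0 & unused)) break
    seed <- which.max(ifelse(unused, deg, -1))  # ties -> first term
    members <- sort(unique(c(seed, which(linked[seed, ] & unused))))
    unused[members] <- FALSE
    clusters[[length(clusters) + 1L]] <- members
  }
  for (s in which(unused)) clusters[[length(clusters) + 1L]] <- s
  lapply(seq_along(clusters), function(ci) {
    ix <- clusters[[ci]]
    list(cluster_id = ci, term_ids = ids[ix],
         enrichment_score = enrichment_score(results$ease_p[ix]))
  })
}

#' Cluster enrichment score
#'
#' Mean of `-log10(p)` over member terms, i.e. `-log10` of the geometric
#' mean of the member p-values.
#'
#' @param ease_p vector of member term p-values (must be > 0).
#' @return the enrichment score (not rounded; round to 2 decimals for
#'   reporting).
#' @export
enrichment_score <- function(ease_p) {
  stopifnot(length(ease_p) >= 1, all(ease_p > 0))
  mean(-log10(ease_p))
}

#' Over-representation analysis of a gene list against annotation terms
#'
#' Computes the EASE p-value of every term with at least one overlapping
#' gene and clusters the significant terms by kappa similarity.
#'
#' @param gene_list character vector (e.g. genes below a p-value cutoff).
#' @param terms named list: term_id -> gene symbols (e.g. from
#'   [read_gmt()]).
#' @param universe background gene universe (default: union of all term
#'   genes); the conventional choice is all genes tested.
#' @param kappa_threshold clustering threshold.
#' @param max_p keep terms with ease_p below this for clustering
#'   (default 1 = all).
#' @return list with `terms` (data frame: term_id, k, n, m, N, ease_p) and
#'   `clusters` (from [cluster_terms()], sorted by score).
#' @export
run_enrichment <- function(gene_list, terms, universe = NULL,
                           kappa_threshold = 0.5, max_p = 1) {
  if (is.null(universe)) universe <- unique(unlist(terms, use.names = FALSE))
  gene_list <- intersect(unique(gene_list), universe)
  N <- length(universe); n <- length(gene_list)
  rows <- lapply(names(terms), function(tid) {
    tg <- intersect(terms[[tid]], universe)
    k <- length(intersect(gene_list, tg))
    if (k == 0) return(NULL)
    data.frame(term_id = tid, k = k, n = n, m = length(tg), N = N,
               ease_p = ease_fisher(k, n, length(tg), N),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res))
    return(list(terms = data.frame(), clusters = list()))
  res <- res[order(res$ease_p), , drop = FALSE]
  rownames(res) <- NULL
  keep <- res[res$ease_p <= max_p, , drop = FALSE]
  cl <- if (nrow(keep)) {
    cluster_terms(keep, terms, universe, kappa_threshold)
  } else list()
  cl <- cl[order(-vapply(cl, `[[`, numeric(1), "enrichment_score"))]
  list(terms = res, clusters = cl)
}
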