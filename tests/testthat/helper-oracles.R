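# Independent reference implementations used as oracles. These deliberately
# use different algorithms from the package code paths they check.

# Exact HWE test via the heterozygote-count recurrence (Wigginton-style),
# independent of the log-factorial closed form in the package.
oracle_hwe_exact <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  n_rare <- 2 * min(n_aa, n_bb) + n_ab
  # work with the rarer allele; symmetric in the two choices
  n_r <- 2 * n_bb + n_ab
  if (n_r > n) n_r <- 2 * n - n_r
  hets <- seq(n_r %% 2, n_r, by = 2)
  hets <- hets[(n_r - hets) / 2 + (2 * n - n_r - hets) / 2 + hets == n]
  probs <- numeric(length(hets))
  mid <- which.min(abs(hets - n_r * (2 * n - n_r) / (2 * n)))
  probs[mid] <- 1
  h <- hets[mid]
  if (mid < length(hets)) {
    for (i in mid:(length(hets) - 1)) {
      h <- hets[i]
      rare_hom <- (n_r - h) / 2; com_hom <- n - h - rare_hom
      probs[i + 1] <- probs[i] * 4 * rare_hom * com_hom /
        ((h + 2) * (h + 1))
    }
  }
  if (mid > 1) {
    for (i in mid:2) {
      h <- hets[i]
      rare_hom <- (n_r - h) / 2; com_hom <- n - h - rare_hom
      probs[i - 1] <- probs[i] * h * (h - 1) /
        (4 * (rare_hom + 1) * (com_hom + 1))
    }
  }
  probs <- probs / sum(probs)
  obs_het <- n_ab
  sum(probs[probs <= probs[match(obs_het, hets)] * (1 + 1e-12)])
}

# High-precision ridge logistic IRLS (Newton) reference.
oracle_ridge_fit <- function(X, y, lambda, tol = 1e-12) {
  Xa <- cbind(1, X)
  p1 <- ncol(Xa)
  Dg <- c(0, rep(1, p1 - 1))
  beta <- rep(0, p1)
  for (it in 1:200) {
    eta <- as.numeric(Xa %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(Xa, Xa * w) + diag(lambda * Dg, p1)
    g <- crossprod(Xa, y - mu) - lambda * Dg * beta
    d <- solve(H, g)
    beta <- beta + as.numeric(d)
    if (max(abs(d)) < tol) break
  }
  beta
}

oracle_deviance <- function(X, y, beta) {
  eta <- as.numeric(cbind(1, X) %*% beta)
  2 * sum(log1p(exp(-abs(eta))) + pmax(eta, 0) - y * eta)
}

# Literal loop-based reference for the GRASS permutation null: same fold
# assignment and permutation stream, fits by the Newton oracle above.
oracle_grass_permutations <- function(X, y, gene_sizes, lambdas, fold_ids,
                                      perms) {
  lambdas <- sort(lambdas, decreasing = TRUE)
  cv_select <- function(yy) {
    dev <- numeric(length(lambdas))
    for (k in sort(unique(fold_ids))) {
      tr <- fold_ids != k
      for (l in seq_along(lambdas)) {
        b <- oracle_ridge_fit(X[tr, , drop = FALSE], yy[tr], lambdas[l])
        dev[l] <- dev[l] + oracle_deviance(X[!tr, , drop = FALSE], yy[!tr], b)
      }
    }
    which.min(dev)
  }
  ends <- cumsum(gene_sizes); starts <- c(1, head(ends, -1) + 1)
  gam <- function(beta) {
    b <- beta[-1]
    mapply(function(s, e) sqrt(sum(b[s:e]^2)), starts, ends)
  }
  B <- ncol(perms)
  out <- matrix(0, B, length(gene_sizes))
  for (bi in seq_len(B)) {
    yy <- y[perms[, bi] + 1]
    l <- cv_select(yy)
    out[bi, ] <- gam(oracle_ridge_fit(X, yy, lambdas[l]))
  }
  out
}

# Brute-force SNP-in-window check (quadratic in SNPs x genes).
oracle_snp_gene_map <- function(snp_meta, regions, window) {
  out <- list()
  for (i in seq_len(nrow(regions))) {
    hits <- character(0)
    for (j in seq_len(nrow(snp_meta))) {
      p0 <- snp_meta$pos[j] - 1
      if (snp_meta$chrom[j] == regions$chrom[i] &&
          p0 >= regions$start[i] - window && p0 < regions$end[i] + window)
        hits <- c(hits, snp_meta$snp_id[j])
    }
    if (length(hits)) out[[regions$gene[i]]] <- hits
  }
  out
}

# Hypergeometric point-mass enumeration for the EASE upper tail.
oracle_ease <- function(k, n, m, N) {
  if (k <= 1) return(1)
  js <- (k - 1):min(n, m)
  sum(exp(lchoose(m, js) + lchoose(N - m, n - js) - lchoose(N, n)))
}

# Small synthetic dataset builders with fixed study conditions.
null_dataset <- function(seed, n = 200, n_genes = 20, pw = c(10L, 10L),
                         ...) {
  generate_dataset(synthetic_config(
    n_cases = n / 2, n_controls = n / 2, n_genes = n_genes,
    pathway_sizes = pw, seed = seed, ...))
}
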