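# SNP-level quality control: additive recoding, exact Hardy-Weinberg test,
# call-rate/MAF/HWE/gene-desert filters, Cochran-Armitage trend statistics,
# genomic inflation (lambda and lambda-1000), Q-Q data and LD pruning.

#' Additive recoding of PLINK-style allele pairs
#'
#' The minor allele is the one with the lower sample frequency (computed on
#' non-missing genotypes); ties are broken by lexicographic allele order (the
#' alphabetically first allele is taken as minor). Dosage counts copies of
#' the minor allele: 0 homozygote common, 1 heterozygote, 2 homozygote rare.
#'
#' @param ped_alleles character matrix (subjects x 2*SNPs) of single alleles,
#'   "0" meaning missing, or (subjects x SNPs) of "A B" pairs.
#' @param snp_ids SNP identifiers, one per SNP.
#' @return list with `dosages` (integer matrix, NA missing), `minor`,
#'   `major` (allele labels per SNP).
#' @export
encode_additive <- function(ped_alleles, snp_ids) {
  if (ncol(ped_alleles) == length(snp_ids)) {
    sp <- strsplit(as.character(ped_alleles), " ", fixed = TRUE)
    a1 <- matrix(vapply(sp, `[[`, character(1), 1), nrow(ped_alleles))
    a2 <- matrix(vapply(sp, `[[`, character(1), 2), nrow(ped_alleles))
  } else {
    stopifnot(ncol(ped_alleles) == 2 * length(snp_ids))
    a1 <- ped_alleles[, seq(1, ncol(ped_alleles), 2), drop = FALSE]
    a2 <- ped_alleles[, seq(2, ncol(ped_alleles), 2), drop = FALSE]
  }
  n_snp <- length(snp_ids)
  d <- matrix(NA_integer_, nrow(a1), n_snp,
              dimnames = list(rownames(ped_alleles), snp_ids))
  minor <- major <- character(n_snp)
  for (j in seq_len(n_snp)) {
    al <- c(a1[, j], a2[, j])
    obs <- al[al != "0"]
    lev <- sort(unique(obs))
    if (length(lev) > 2)
      stop("triallelic SNP: ", snp_ids[j], " (alleles ",
           paste(lev, collapse = "/"), ")")
    if (length(lev) == 0) { minor[j] <- major[j] <- NA_character_; next }
    if (length(lev) == 1) lev <- c(lev, lev)
    f1 <- mean(obs == lev[1])
    ## strictly rarer allele is minor; tie -> lexicographically first (lev[1])
    mi <- if (f1 <= 0.5) lev[1] else lev[2]
    ma <- setdiff(lev, mi)[1]
    if (is.na(ma)) ma <- mi  # monomorphic
    minor[j] <- mi; major[j] <- ma
    ok <- a1[, j] != "0" & a2[, j] != "0"
    d[ok, j] <- (a1[ok, j] == mi) + (a2[ok, j] == mi)
    if (mi == ma) d[ok, j] <- 0L  # monomorphic: dosage 0 by convention
  }
  list(dosages = d, minor = minor, major = major)
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact test conditioning on the allele counts: the p-value is the
#' sum of probabilities of all heterozygote-count configurations no more
#' probable than the observed one. Probabilities are computed from the
#' hypergeometric-type closed form via log-factorials.
#'
#' @param n_hom_common,n_het,n_hom_rare genotype counts.
#' @return exact two-sided p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_hom_common, n_het, n_hom_rare) {
  stopifnot(n_hom_common >= 0, n_het >= 0, n_hom_rare >= 0)
  n <- n_hom_common + n_het + n_hom_rare
  if (n == 0) stop("all genotype counts are zero")
  n_rare <- 2 * n_hom_rare + n_het           # rare-allele count
  hets <- seq(n_rare %% 2, min(n_rare, 2 * n - n_rare), by = 2)
  ## log P(het = h | n, n_rare) up to a constant
  logp <- lgamma(n + 1) - lgamma((n_rare - hets) / 2 + 1) - lgamma(hets + 1) -
    lgamma(n - (n_rare + hets) / 2 + 1) + hets * log(2)
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  obs <- match(n_het, hets)
  min(1, sum(pr[pr <= pr[obs] * (1 + 1e-12)]))
}

#' Apply SNP-level QC filters
#'
#' A SNP is excluded iff call rate < `call_rate` (strict), MAF < `maf`
#' (strict), exact HWE p < `hwe_p` (strict), or it lies farther than
#' `desert_window` bp from every gene interval (gene desert). All filters
#' are evaluated on the pre-filter data; a SNP may carry several reasons.
#' Call rate, MAF and the HWE test use non-missing genotypes of all subjects.
#'
#' @param dataset a `genotype_dataset`.
#' @param gene_regions data frame (chrom, start, end, gene), 0-based
#'   half-open; `NULL` disables the gene-desert filter.
#' @param thresholds list with elements `call_rate` (default 0.98), `maf`
#'   (0.05), `hwe_p` (0.001), `desert_window` (20000 bp).
#' @return list with `dataset` (filtered), `qc` (one row per SNP: call_rate,
#'   maf, hwe_p, gene_desert, excluded, exclusion_reasons), and `summary`
#'   (counts per reason; reasons overlap).
#' @export
apply_qc <- function(dataset, gene_regions = dataset$gene_regions,
                     thresholds = list()) {
  th <- utils::modifyList(list(call_rate = 0.98, maf = 0.05, hwe_p = 0.001,
                               desert_window = 20000), thresholds)
  d <- dataset$dosages
  m <- dataset$snp_meta
  n <- nrow(d)
  call_rate <- colMeans(!is.na(d))
  af <- colMeans(d, na.rm = TRUE) / 2
  af[is.nan(af)] <- 0
  maf <- pmin(af, 1 - af)
  hwe_p <- vapply(seq_len(ncol(d)), function(j) {
    x <- d[, j]; x <- x[!is.na(x)]
    if (!length(x)) return(1)
    hwe_exact_test(sum(x == 0L), sum(x == 1L), sum(x == 2L))
  }, numeric(1))

  desert <- rep(FALSE, ncol(d))
  if (!is.null(gene_regions)) {
    gm <- map_snps_to_genes(m, gene_regions, window = th$desert_window,
                            warn_empty = FALSE)
    desert <- !(m$snp_id %in% unlist(gm, use.names = FALSE))
  } else if (is.finite(th$desert_window)) {
    stop("gene_regions required for the gene-desert filter")
  }

  reasons <- mapply(function(cr, mf, hw, de) {
    r <- c(if (cr < th$call_rate) "CALL_RATE", if (mf < th$maf) "MAF",
           if (hw < th$hwe_p) "HWE", if (de) "GENE_DESERT")
    paste(r, collapse = ";")
  }, call_rate, maf, hwe_p, desert)
  excluded <- nzchar(reasons)

  qc <- data.frame(snp_id = m$snp_id, call_rate = call_rate, maf = maf,
                   hwe_p = hwe_p, gene_desert = desert, excluded = excluded,
                   exclusion_reasons = reasons, stringsAsFactors = FALSE,
                   row.names = NULL)
  keep <- !excluded
  out <- dataset
  out$dosages <- d[, keep, drop = FALSE]
  out$snp_meta <- m[keep, , drop = FALSE]
  summary <- list(
    n_snps = ncol(d), n_excluded = sum(excluded), n_retained = sum(keep),
    by_reason = c(CALL_RATE = sum(grepl("CALL_RATE", reasons)),
                  MAF = sum(grepl("\\bMAF\\b", reasons)),
                  HWE = sum(grepl("\\bHWE\\b", reasons)),
                  GENE_DESERT = sum(grepl("GENE_DESERT", reasons))))
  list(dataset = out, qc = qc, summary = summary)
}

#' Cochran-Armitage trend chi-square statistic (1 df)
#'
#' Linear-trend score test with scores (0, 1, 2); equals `N * r^2` where `r`
#' is the sample correlation between dosage and phenotype. Missing dosages
#' are dropped pairwise. A constant dosage (or phenotype) gives 0.
#'
#' @param dosages dosage vector in 0/1/2 (NA allowed).
#' @param phenotype binary vector (1 = case).
#' @return the 1-df chi-square trend statistic.
#' @export
cochran_armitage_trend <- function(dosages, phenotype) {
  ok <- !is.na(dosages) & !is.na(phenotype)
  s <- as.numeric(dosages[ok]); y <- as.numeric(phenotype[ok])
  n <- length(s)
  if (n == 0) return(0)
  vs <- sum(s^2) - sum(s)^2 / n
  vy <- sum(y^2) - sum(y)^2 / n
  if (vs <= 0 || vy <= 0) return(0)
  u <- sum(s * y) - sum(s) * sum(y) / n
  n * u^2 / (vs * vy)
}

#' Genomic inflation factor, rescaled to 1,000 cases and 1,000 controls
#'
#' `lambda_raw` is the median of the 1-df chi-square statistics divided by
#' 0.4549364 (the chi-square-1 median). The excess is rescaled to a
#' 1,000/1,000 design:
#' `lambda_1000 = 1 + (lambda_raw - 1) * (1/n_cases + 1/n_controls) / (2/1000)`.
#'
#' @param chi2_values vector of 1-df association statistics.
#' @param n_cases,n_controls sample sizes behind the statistics.
#' @return list with `lambda_raw`, `lambda_1000`, `n_cases`, `n_controls`,
#'   `chi2_values`.
#' @export
inflation_factor <- function(chi2_values, n_cases, n_controls) {
  stopifnot(length(chi2_values) > 0)
  if (n_cases <= 0 || n_controls <= 0)
    stop("n_cases and n_controls must be positive")
  lambda_raw <- median(chi2_values) / qchisq(0.5, 1)
  lambda_1000 <- 1 + (lambda_raw - 1) *
    (1 / n_cases + 1 / n_controls) / (1 / 1000 + 1 / 1000)
  list(lambda_raw = lambda_raw, lambda_1000 = lambda_1000,
       n_cases = n_cases, n_controls = n_controls,
       chi2_values = chi2_values)
}

#' Greedy LD pruning by squared correlation
#'
#' SNPs are scanned in position order within each chromosome; a SNP is kept
#' iff its squared Pearson correlation with every previously kept SNP on the
#' same chromosome is below `r2_threshold`. Missing dosages are mean-imputed
#' for the correlation; SNPs with zero variance are skipped.
#'
#' @param dosages dosage matrix (subjects x SNPs).
#' @param r2_threshold squared-correlation cutoff in (0, 1].
#' @param snp_meta optional SNP table (snp_id, chrom, pos) giving scan order;
#'   by default columns are scanned left to right on one chromosome.
#' @return character vector of retained SNP ids.
#' @export
ld_prune <- function(dosages, r2_threshold, snp_meta = NULL) {
  stopifnot(r2_threshold > 0, r2_threshold <= 1)
  if (ncol(dosages) == 0) return(character(0))
  ids <- colnames(dosages)
  if (is.null(snp_meta)) {
    snp_meta <- data.frame(snp_id = ids, chrom = "1", pos = seq_along(ids))
  }
  snp_meta <- snp_meta[match(ids, snp_meta$snp_id), ]
  ## mean-imputed standardized copy so correlations reduce to cross products
  n <- nrow(dosages)
  std <- apply(dosages, 2, function(col) {
    mu <- mean(col, na.rm = TRUE)
    if (is.nan(mu)) mu <- 0
    col[is.na(col)] <- mu
    col <- col - mean(col)
    s <- sqrt(sum(col^2))
    if (s < 1e-12) rep(NA_real_, n) else col / s
  })
  kept <- character(0)
  for (ch in unique(snp_meta$chrom)) {
    ord <- ids[snp_meta$chrom == ch][order(snp_meta$pos[snp_meta$chrom == ch])]
    kept_mat <- matrix(0, n, 0)
    kept_ch <- character(0)
    for (s in ord) {
      x <- std[, s]
      if (anyNA(x)) next                       # monomorphic
      if (ncol(kept_mat) > 0 &&
          max(crossprod(kept_mat, x)^2) >= r2_threshold) next
      kept_mat <- cbind(kept_mat, x)
      kept_ch <- c(kept_ch, s)
    }
    kept <- c(kept, kept_ch)
  }
  kept
}

#' Q-Q data for 1-df chi-square statistics
#'
#' Observed statistics sorted ascending against chi-square-1 quantiles at
#' probabilities `(i - 0.5) / m`.
#'
#' @param chi2_values vector of statistics.
#' @return data frame with columns `expected`, `observed`.
#' @export
qq_points <- function(chi2_values) {
  stopifnot(length(chi2_values) > 0)
  m <- length(chi2_values)
  data.frame(expected = qchisq((seq_len(m) - 0.5) / m, 1),
             observed = sort(chi2_values))
}
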