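# Readers and writers for the plain-text formats the pipeline exchanges:
# PLINK .ped/.map, a TSV dosage dialect, BED gene regions (0-based half-open),
# GMT gene sets, covariate TSV, and truth/manifest JSON.

#' Write a genotype_dataset to disk
#'
#' Emits `<prefix>.ped` / `<prefix>.map` (PLINK text; .map columns chrom,
#' snp id, genetic distance 0, bp position; .ped phenotype coded 1 = control,
#' 2 = case; missing genotype "0 0"), `<prefix>_genes.bed` (0-based
#' half-open), `<prefix>_pathways.gmt`, `<prefix>_covariates.tsv` and
#' `<prefix>_truth.json`.
#'
#' @param dataset a `genotype_dataset`.
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @return invisibly, the vector of file paths written.
#' @export
write_dataset <- function(dataset, dir, prefix = "synthetic") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(ext) file.path(dir, paste0(prefix, ext))

  m <- dataset$snp_meta
  write.table(data.frame(m$chrom, m$snp_id, 0L, m$pos),
              p(".map"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)

  d <- dataset$dosages
  code <- function(dos, a1, a2) {
    out <- rep("0 0", length(dos))
    out[!is.na(dos) & dos == 0L] <- paste(a1, a1)
    out[!is.na(dos) & dos == 1L] <- paste(a1, a2)
    out[!is.na(dos) & dos == 2L] <- paste(a2, a2)
    out
  }
  geno <- vapply(seq_len(ncol(d)),
                 function(j) code(d[, j], m$allele1[j], m$allele2[j]),
                 character(nrow(d)))
  ped <- cbind("FAM1", rownames(d), "0", "0",
               as.character(dataset$covariates$sex + 1L),
               as.character(dataset$phenotype + 1L), geno)
  write.table(ped, p(".ped"), sep = " ", quote = FALSE,
              row.names = FALSE, col.names = FALSE)

  g <- dataset$gene_regions
  write.table(data.frame(g$chrom, g$start, g$end, g$gene),
              p("_genes.bed"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)

  gmt <- vapply(names(dataset$pathways), function(pw)
    paste(c(pw, paste0(pw, " synthetic pathway"), dataset$pathways[[pw]]),
          collapse = "\t"), character(1))
  writeLines(gmt, p("_pathways.gmt"))

  cov <- cbind(subject_id = rownames(d), dataset$covariates)
  write.table(cov, p("_covariates.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  jsonlite::write_json(
    list(causal_snps = dataset$truth$causal_snps %||% character(0),
         causal_beta = as.list(dataset$truth$causal_beta %||% numeric(0)),
         causal_pathways = dataset$truth$causal_pathways %||% character(0),
         ancestry = dataset$truth$ancestry %||% integer(0),
         hwe_violation_snps = dataset$truth$hwe_violation_snps %||%
           character(0),
         seed = dataset$config$seed %||% NA_integer_),
    p("_truth.json"), auto_unbox = FALSE, digits = NA)

  invisible(c(p(".ped"), p(".map"), p("_genes.bed"), p("_pathways.gmt"),
              p("_covariates.tsv"), p("_truth.json")))
}

#' Read PLINK text genotypes (.ped/.map) into a genotype_dataset
#'
#' Genotypes are recoded additively with [encode_additive()]: dosage counts
#' copies of the minor allele (by sample frequency; lexicographic tie-break).
#' Positions in .map are 1-based and kept as such in `snp_meta`.
#'
#' @param prefix path prefix (reads `<prefix>.ped` and `<prefix>.map`).
#' @return a `genotype_dataset` (without pathway/gene-region slots).
#' @export
read_plink <- function(prefix) {
  map <- read.table(paste0(prefix, ".map"), header = FALSE,
                    col.names = c("chrom", "snp_id", "cm", "pos"),
                    colClasses = c("character", "character", "numeric",
                                   "integer"))
  ped <- read.table(paste0(prefix, ".ped"), header = FALSE,
                    colClasses = "character")
  n_snp <- nrow(map)
  if (ncol(ped) != 6 + 2 * n_snp)
    stop("ped/map mismatch: expected ", 6 + 2 * n_snp, " columns, got ",
         ncol(ped))
  alle <- as.matrix(ped[, -(1:6), drop = FALSE])
  enc <- encode_additive(alle, map$snp_id)
  meta <- data.frame(snp_id = map$snp_id, chrom = map$chrom, pos = map$pos,
                     allele1 = enc$major, allele2 = enc$minor,
                     gene = NA_character_, stringsAsFactors = FALSE)
  d <- enc$dosages
  rownames(d) <- ped[[2]]
  structure(list(dosages = d, snp_meta = meta,
                 phenotype = as.integer(ped[[6]]) - 1L,
                 covariates = data.frame(sex = as.integer(ped[[5]]) - 1L),
                 gene_regions = NULL, pathways = NULL, truth = NULL,
                 config = NULL),
            class = "genotype_dataset")
}

#' Read a TSV dosage table (subjects x SNPs, header of SNP ids, NA missing)
#'
#' @param path file path; first column must be subject ids.
#' @return integer dosage matrix with dimnames.
#' @export
read_dosage_tsv <- function(path) {
  x <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  d <- as.matrix(x[, -1, drop = FALSE])
  if (!all(is.na(d) | d %in% 0:2)) stop("dosage entries must be 0/1/2 or NA")
  storage.mode(d) <- "integer"
  rownames(d) <- x[[1]]
  d
}

#' Read gene regions from BED (0-based, half-open)
#' @param path BED file with columns chrom, start, end, gene symbol.
#' @return data frame with columns chrom, start, end, gene.
#' @export
read_bed <- function(path) {
  x <- read.table(path, header = FALSE, sep = "\t",
                  colClasses = c("character", "integer", "integer",
                                 "character"))
  names(x) <- c("chrom", "start", "end", "gene")
  if (any(x$start >= x$end)) stop("malformed BED: start must be < end")
  x
}

#' Read gene sets from GMT (name, description, member gene symbols)
#' @param path GMT file path.
#' @return named list of character vectors of gene symbols; descriptions in
#'   attribute `"description"`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3
  if (any(bad)) stop("malformed GMT line(s): ", which(bad)[1])
  sets <- lapply(parts, function(x) x[-(1:2)])
  names(sets) <- vapply(parts, `[[`, character(1), 1)
  attr(sets, "description") <- vapply(parts, `[[`, character(1), 2)
  sets
}

#' Read a covariate TSV (header row, first column subject id)
#' @param path file path.
#' @return data frame with subject ids as row names; character columns
#'   become factors.
#' @export
read_covariates <- function(path) {
  x <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = TRUE)
  rownames(x) <- as.character(x[[1]])
  x[[1]] <- NULL
  x
}
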