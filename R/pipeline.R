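# End-to-end orchestration: generate/read -> QC -> structure PCs -> SNP/gene/
# pathway mapping -> GRASS -> LKM -> split + meta -> enrichment, with stage
# logging and a reproducibility manifest. Each stage draws its randomness
# from a substream of the global seed (see stage_seed()) so stages can be
# re-run in isolation.

#' Run the full pathway-GWAS pipeline on a dataset
#'
#' Stages: SNP-level QC, structure PCs merged into the covariates, SNP-to-
#' gene mapping and pathway filtering, eigenSNP compression, the GRASS
#' pathway test, the per-gene LKM test, a stratified random split with
#' Stouffer meta-analysis of the two halves' GRASS results, and functional
#' enrichment of the top LKM genes against the pathway collection. Writes
#' qc_report.tsv, pca_covariates.tsv, mapping.tsv, grass_results.tsv,
#' lkm_results.tsv, meta_report.tsv, enrichment_clusters.tsv, run_log.txt
#' and manifest.json under `out_dir`.
#'
#' @param dataset a `genotype_dataset`, or a path prefix to PLINK .ped/.map
#'   files (then `gene_bed` and `pathway_gmt` must be given).
#' @param out_dir output directory (created).
#' @param seed global integer seed.
#' @param gene_bed,pathway_gmt,covariates_tsv optional file paths overriding
#'   the dataset's own slots.
#' @param qc_thresholds passed to [apply_qc()].
#' @param grass config overrides for [grass_config()] (list).
#' @param lkm_major_p LKM flagging threshold (default 0.001).
#' @param enrichment_p LKM p-value cutoff defining the enrichment gene list
#'   (default 0.01).
#' @param n_pcs number of structure PCs (default 5).
#' @param meta_mode `"random_split"` (default) splits the dataset in two and
#'   meta-analyzes the halves; `"none"` skips the stage.
#' @return invisibly, a list with every stage's in-memory result and the
#'   manifest.
#' @export
run_full_pipeline <- function(dataset, out_dir, seed = 1L,
                              gene_bed = NULL, pathway_gmt = NULL,
                              covariates_tsv = NULL,
                              qc_thresholds = list(), grass = list(),
                              lkm_major_p = 0.001, enrichment_p = 0.01,
                              n_pcs = 5L, meta_mode = "random_split") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run_log.txt")
  cat("", file = log_path)
  logmsg <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    cat(line, "\n", file = log_path, append = TRUE, sep = "")
  }
  stage <- function(name, expr) {
    logmsg("stage ", name, " start")
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e) {
      cat("FAILED", file = file.path(out_dir, "FAILED"))
      stop("stage ", name, " failed: ", conditionMessage(e), call. = FALSE)
    })
    logmsg("stage ", name, sprintf(" done (%.1fs)",
                                   as.numeric(Sys.time() - t0, units = "secs")))
    out
  }
  tsv <- function(x, name) write.table(x, file.path(out_dir, name),
                                       sep = "\t", quote = FALSE,
                                       row.names = FALSE)

  if (is.character(dataset)) {
    dataset <- stage("read", {
      ds <- read_plink(dataset)
      ds$gene_regions <- read_bed(gene_bed)
      ds$pathways <- read_gmt(pathway_gmt)
      if (!is.null(covariates_tsv)) {
        cv <- read_covariates(covariates_tsv)
        ds$covariates <- cv[match(rownames(ds$dosages), rownames(cv)), ,
                            drop = FALSE]
      }
      ds
    })
  }
  if (!is.null(gene_bed) && is.null(dataset$gene_regions))
    dataset$gene_regions <- read_bed(gene_bed)
  if (!is.null(pathway_gmt) && is.null(dataset$pathways))
    dataset$pathways <- read_gmt(pathway_gmt)

  qc <- stage("qc", apply_qc(dataset, thresholds = qc_thresholds))
  tsv(qc$qc, "qc_report.tsv")
  jsonlite::write_json(qc$summary, file.path(out_dir, "qc_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  ds <- qc$dataset

  ds <- stage("pca", with_seed(stage_seed(seed, "pca"),
                               add_structure_pcs(ds, k = n_pcs)))
  tsv(cbind(subject_id = rownames(ds$dosages), ds$covariates),
      "pca_covariates.tsv")

  mapres <- stage("map", {
    gm <- map_snps_to_genes(ds$snp_meta, ds$gene_regions)
    pw <- filter_pathways(ds$pathways, gm)
    blocks <- build_eigensnp_blocks(ds, gm)
    list(gene_map = gm, pathways = pw, blocks = blocks)
  })
  map_tab <- do.call(rbind, lapply(names(mapres$pathways), function(p)
    data.frame(pathway = p, gene = mapres$pathways[[p]],
               n_snps = vapply(mapres$pathways[[p]], function(g)
                 mapres$blocks[[g]]$n_snps, integer(1)),
               n_eigensnps = vapply(mapres$pathways[[p]], function(g)
                 mapres$blocks[[g]]$n_eigensnps, integer(1)))))
  tsv(map_tab, "mapping.tsv")

  gcfg <- do.call(grass_config,
                  utils::modifyList(list(stage1_B = 200L, stage2_B = 1000L,
                                         seed = stage_seed(seed, "grass")),
                                    grass))
  grass_res <- stage("grass", run_grass(ds, mapres$pathways, mapres$blocks,
                                        gcfg))
  tsv(grass_res, "grass_results.tsv")

  lkm_res <- stage("lkm", run_lkm(ds, mapres$gene_map,
                                  major_gene_p = lkm_major_p))
  tsv(lkm_res, "lkm_results.tsv")

  meta_res <- NULL
  if (identical(meta_mode, "random_split")) {
    meta_res <- stage("meta", {
      halves <- random_split(ds, seed = stage_seed(seed, "split"))
      res <- lapply(seq_along(halves), function(i) {
        h <- halves[[i]]
        cfg <- do.call(grass_config, utils::modifyList(
          list(stage1_B = 200L, stage2_B = 1000L,
               seed = stage_seed(seed, paste0("grass_half", i))), grass))
        blocks <- build_eigensnp_blocks(h, mapres$gene_map)
        run_grass(h, mapres$pathways, blocks, cfg)
      })
      replicate_report(res[[1]], res[[2]])
    })
    tsv(meta_res, "meta_report.tsv")
  }

  enr <- stage("enrich", {
    top <- lkm_res$gene[lkm_res$p_value < enrichment_p]
    run_enrichment(top, mapres$pathways,
                   universe = names(mapres$gene_map))
  })
  enr_tab <- if (length(enr$clusters)) {
    do.call(rbind, lapply(enr$clusters, function(cl) {
      m <- enr$terms[match(cl$term_ids, enr$terms$term_id), ]
      data.frame(cluster = cl$cluster_id,
                 enrichment_score = round(cl$enrichment_score, 2),
                 term = m$term_id, n_genes = m$k, p_value = m$ease_p)
    }))
  } else {
    data.frame(cluster = integer(0), enrichment_score = numeric(0),
               term = character(0), n_genes = integer(0),
               p_value = numeric(0))
  }
  tsv(enr_tab, "enrichment_clusters.tsv")

  manifest <- list(
    seed = seed, n_subjects = nrow(ds$dosages), n_cases = sum(ds$phenotype),
    n_snps_pre_qc = qc$summary$n_snps, n_snps_post_qc = qc$summary$n_retained,
    n_pathways = nrow(grass_res), n_genes = nrow(lkm_res),
    grass_bonferroni = attr(grass_res, "bonferroni"),
    lkm_bonferroni = attr(lkm_res, "bonferroni"),
    rows = list(qc = nrow(qc$qc), mapping = nrow(map_tab),
                grass = nrow(grass_res), lkm = nrow(lkm_res),
                meta = if (is.null(meta_res)) 0L else nrow(meta_res),
                enrichment = nrow(enr_tab)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  logmsg("pipeline complete")
  invisible(list(dataset = ds, qc = qc, map = mapres, grass = grass_res,
                 lkm = lkm_res, meta = meta_res, enrichment = enr,
                 manifest = manifest))
}
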