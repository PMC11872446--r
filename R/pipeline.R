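# Orchestration: a single YAML config drives the three analysis stages
# (pairwise overlap, per-locus colocalization, pseudobulk DE), each writing
# TSV reports plus a machine-readable run manifest.

#' Read and validate a pipeline configuration
#'
#' The YAML file holds input paths, column-dialect mappings, thresholds and
#' seeds.  Defaults are filled for every threshold the analyses use:
#' p_threshold 5e-8, proxy_r2 0.50, clump_r2 0.4, share_r2 0.4, half_width
#' 500000, priors p1 = p2 = 1e-4 and p12 = 1e-5, prior effect sds 0.15 /
#' 0.2, DE filters (min_cells_per_cluster 10, min_counts_per_cell 500,
#' min_count 5), seed 1.
#'
#' @param path YAML file path.
#' @return A `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  pipeline_config(cfg)
}

#' @rdname read_pipeline_config
#' @param cfg named list of configuration values.
#' @export
pipeline_config <- function(cfg = list()) {
  defaults <- list(p_threshold = GWS_P_THRESHOLD, proxy_r2 = LD_PROXY_R2,
                   clump_r2 = 0.4, share_r2 = 0.4, half_width = 500000L,
                   p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                   prior_sd_quantitative = PRIOR_SD_QUANTITATIVE,
                   prior_sd_case_control = PRIOR_SD_CASE_CONTROL,
                   min_cells_per_cluster = 10, min_counts_per_cell = 500,
                   min_count = 5, me = NULL, seed = 1L)
  for (nm in names(defaults))
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  stopifnot(cfg$p_threshold > 0, cfg$p_threshold <= 1,
            cfg$proxy_r2 >= 0, cfg$proxy_r2 <= 1,
            cfg$clump_r2 >= 0, cfg$clump_r2 <= 1,
            cfg$half_width > 0, cfg$p12 <= min(cfg$p1, cfg$p2))
  structure(cfg, class = "pipeline_config")
}

#' @keywords internal
.write_manifest <- function(outdir, cfg, stage, outputs, row_counts) {
  manifest <- list(
    stage = stage,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package_version = as.character(utils::packageVersion("pleiocoloc")),
    config = unclass(cfg)[!vapply(unclass(cfg), is.null, logical(1))],
    seed = cfg$seed,
    outputs = outputs,
    row_counts = row_counts)
  yaml::write_yaml(manifest, file.path(outdir, paste0(stage, "_manifest.yaml")))
}

#' Run the pairwise trait-overlap stage
#'
#' Reads two summary-statistics files and a dosage panel named in the
#' config (`trait1`, `trait2`, `panel_dosages`, `panel_variants`, `me`),
#' clumps, matches and tests enrichment, and writes `overlap_report.tsv`
#' (columns n1_pcut, n2_pcut, Nshare_all, N_expected, fold, p, p_adj) plus
#' a manifest under `outdir`.
#'
#' @param config a `pipeline_config` (or path to one).
#' @param outdir output directory.
#' @return the report data.frame, invisibly.
#' @export
run_overlap <- function(config, outdir) {
  cfg <- if (is.character(config)) read_pipeline_config(config) else config
  for (key in c("trait1", "trait2", "panel_dosages", "panel_variants", "me"))
    if (is.null(cfg[[key]])) stop("config key '", key, "' is required")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  t1 <- read_sumstats(cfg$trait1)
  t2 <- read_sumstats(cfg$trait2)
  panel <- read_panel_tsv(cfg$panel_dosages, cfg$panel_variants)
  res <- trait_pair_overlap(t1, t2, panel, me = cfg$me,
                            p_threshold = cfg$p_threshold,
                            clump_r2 = cfg$clump_r2,
                            share_r2 = cfg$share_r2)
  report <- res$report
  report$p_adj <- if (is.na(report$p)) NA_real_ else bh_adjust(report$p)
  out <- file.path(outdir, "overlap_report.tsv")
  utils::write.table(report, out, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  .write_manifest(outdir, cfg, "overlap", out, nrow(report))
  invisible(report)
}

#' Run the per-locus colocalization stage
#'
#' For each locus in the config's `loci` list (each with chrom, pos and
#' optional half_width), restricts both traits to the window and computes
#' PP0-PP4, the PP4/PP3 ratio and the interpretation label; writes
#' `coloc_report.tsv` plus a manifest.
#'
#' @inheritParams run_overlap
#' @return the report data.frame, invisibly.
#' @export
run_coloc <- function(config, outdir) {
  cfg <- if (is.character(config)) read_pipeline_config(config) else config
  for (key in c("trait1", "trait2", "loci"))
    if (is.null(cfg[[key]])) stop("config key '", key, "' is required")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  t1 <- read_sumstats(cfg$trait1)
  t2 <- read_sumstats(cfg$trait2)
  priors <- coloc_priors(cfg$p1, cfg$p2, cfg$p12)
  rows <- lapply(cfg$loci, function(loc) {
    hw <- if (is.null(loc$half_width)) cfg$half_width else loc$half_width
    w <- locus_window(loc$chrom, loc$pos, hw)
    res <- coloc_region(t1, t2, w, priors)
    if (is.null(res))
      return(data.frame(chrom = w$chrom, pos = w$pos, status = "empty",
                        n_snps = 0L, pp0 = NA_real_, pp1 = NA_real_,
                        pp2 = NA_real_, pp3 = NA_real_, pp4 = NA_real_,
                        pp4_pp3 = NA_real_, label = NA_character_))
    data.frame(chrom = w$chrom, pos = w$pos, status = "ok",
               n_snps = res$n_snps, pp0 = res$pp0, pp1 = res$pp1,
               pp2 = res$pp2, pp3 = res$pp3, pp4 = res$pp4,
               pp4_pp3 = res$pp4_pp3, label = res$label)
  })
  report <- do.call(rbind, rows)
  out <- file.path(outdir, "coloc_report.tsv")
  utils::write.table(report, out, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  .write_manifest(outdir, cfg, "coloc", out, nrow(report))
  invisible(report)
}

#' Run the pseudobulk differential-expression stage
#'
#' Reads the single-cell dataset named in the config (`sc_mtx`, `sc_genes`,
#' `sc_barcodes`, `sc_meta`), filters cells and clusters, writes per-donor
#' cell-type proportions and per-cell-type NB Wald DE tables plus a
#' manifest.
#'
#' @inheritParams run_overlap
#' @return list with proportions and de data.frames, invisibly.
#' @export
run_de <- function(config, outdir) {
  cfg <- if (is.character(config)) read_pipeline_config(config) else config
  for (key in c("sc_mtx", "sc_genes", "sc_barcodes", "sc_meta"))
    if (is.null(cfg[[key]])) stop("config key '", key, "' is required")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  m <- read_sc_counts(cfg$sc_mtx, cfg$sc_genes, cfg$sc_barcodes, cfg$sc_meta)
  m <- filter_cells_clusters(m, cfg$min_cells_per_cluster,
                             cfg$min_counts_per_cell)
  props <- celltype_proportions(m)
  pb <- pseudobulk(m)
  de <- nb_wald_de(pb)
  prop_path <- file.path(outdir, "celltype_proportions.tsv")
  utils::write.table(props, prop_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  de_paths <- character(0)
  for (ct in unique(de$cell_type)) {
    pth <- file.path(outdir, paste0("de_", gsub("[^A-Za-z0-9_.-]", "_", ct),
                                    ".tsv"))
    utils::write.table(de[de$cell_type == ct, , drop = FALSE], pth,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    de_paths <- c(de_paths, pth)
  }
  .write_manifest(outdir, cfg, "de", c(prop_path, de_paths),
                  c(nrow(props), nrow(de)))
  invisible(list(proportions = props, de = de))
}
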