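# Single-cell filtering, pseudobulk aggregation, median-of-ratios
# normalization, and per-cell-type negative-binomial Wald differential
# expression between disease and control.
#
# The DE machinery is deliberately minimal: median-of-ratios size factors,
# per-gene method-of-moments dispersion (no shrinkage across genes), and a
# fixed-dispersion NB log-linear Wald test.  There is no fold-change
# shrinkage and no outlier handling, so per-gene p-values will differ from
# full DESeq2-style pipelines on real data; the intended use is calibrated
# testing on pseudobulked replicates.

#' Cell-level count container
#'
#' @param counts cell x gene matrix (dense or dgCMatrix) of non-negative
#'   integer counts.
#' @param cell_meta data.frame with one row per cell: barcode, donor_id,
#'   cell_type, condition ("disease" or "control").
#' @param gene_ids character vector, one per column.
#' @return A `cell_counts` list.
#' @export
cell_counts <- function(counts, cell_meta, gene_ids = colnames(counts)) {
  if (nrow(counts) != nrow(cell_meta))
    stop("cell_meta rows must align with count rows")
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(ncol(counts)))
  if (length(gene_ids) != ncol(counts))
    stop("gene_ids must match count columns")
  stopifnot(all(cell_meta$condition %in% c("disease", "control")))
  if (any(counts < 0)) stop("counts must be non-negative")
  colnames(counts) <- gene_ids
  structure(list(counts = counts, cell_meta = as.data.frame(cell_meta),
                 gene_ids = gene_ids),
            class = "cell_counts")
}

#' @export
print.cell_counts <- function(x, ...) {
  cat("cell_counts:", nrow(x$counts), "cells x", ncol(x$counts), "genes;",
      length(unique(x$cell_meta$donor_id)), "donors,",
      length(unique(x$cell_meta$cell_type)), "cell types\n")
  invisible(x)
}

#' Filter cells and cell-type clusters
#'
#' Removes cells with fewer than `min_counts_per_cell` total counts first,
#' then drops entire cell-type clusters left with fewer than
#' `min_cells_per_cluster` cells.  Both thresholds are inclusive keeps
#' (a 500-count cell and a 10-cell cluster survive).
#'
#' @param m a [cell_counts()].
#' @param min_cells_per_cluster minimum surviving cells per cell type
#'   (default 10).
#' @param min_counts_per_cell minimum total counts per cell (default 500).
#' @return filtered `cell_counts`.
#' @export
filter_cells_clusters <- function(m, min_cells_per_cluster = 10,
                                  min_counts_per_cell = 500) {
  tot <- Matrix::rowSums(m$counts)
  keep <- tot >= min_counts_per_cell
  if (sum(!keep) > 0)
    message(sum(!keep), " cell(s) below ", min_counts_per_cell,
            " total counts removed")
  meta <- m$cell_meta[keep, , drop = FALSE]
  counts <- m$counts[keep, , drop = FALSE]
  ct_n <- table(meta$cell_type)
  bad_ct <- names(ct_n)[ct_n < min_cells_per_cluster]
  if (length(bad_ct) > 0) {
    message("cluster(s) dropped for < ", min_cells_per_cluster, " cells: ",
            paste(bad_ct, collapse = ", "))
    keep2 <- !(meta$cell_type %in% bad_ct)
    meta <- meta[keep2, , drop = FALSE]
    counts <- counts[keep2, , drop = FALSE]
  }
  if (nrow(counts) == 0) stop("all cells removed by filtering")
  rownames(meta) <- NULL
  cell_counts(counts, meta, m$gene_ids)
}

#' Per-donor cell-type proportions
#'
#' @param m a [cell_counts()].
#' @return data.frame (donor_id, condition, cell_type, n_cells, fraction);
#'   fractions sum to 1 within each donor.
#' @export
celltype_proportions <- function(m) {
  meta <- m$cell_meta
  if (nrow(meta) == 0) stop("no cells")
  agg <- stats::aggregate(list(n_cells = rep(1L, nrow(meta))),
                          by = list(donor_id = meta$donor_id,
                                    condition = meta$condition,
                                    cell_type = meta$cell_type),
                          FUN = sum)
  tot <- stats::ave(agg$n_cells, agg$donor_id, FUN = sum)
  agg$fraction <- agg$n_cells / tot
  agg[order(agg$donor_id, agg$cell_type), , drop = FALSE]
}

#' Pseudobulk aggregation by donor and cell type
#'
#' Sums gene counts over the cells in each (donor, cell type) group.
#'
#' @param m a [cell_counts()].
#' @return A `pseudobulk_matrix` list: counts ((donor, cell type) x gene
#'   matrix) and group_meta (donor_id, cell_type, condition, n_cells).
#' @export
pseudobulk <- function(m) {
  meta <- m$cell_meta
  grp <- paste(meta$donor_id, meta$cell_type, sep = "||")
  grp_f <- factor(grp, levels = unique(grp))
  # indicator (group x cell) %*% counts sums cells within group
  ind <- Matrix::sparseMatrix(i = as.integer(grp_f), j = seq_along(grp),
                              x = 1, dims = c(nlevels(grp_f), length(grp)))
  agg <- as.matrix(ind %*% m$counts)
  first <- !duplicated(grp_f)
  group_meta <- data.frame(donor_id = meta$donor_id[first],
                           cell_type = meta$cell_type[first],
                           condition = meta$condition[first],
                           n_cells = as.integer(table(grp_f)[levels(grp_f)]),
                           stringsAsFactors = FALSE)
  rownames(agg) <- paste(group_meta$donor_id, group_meta$cell_type,
                         sep = "||")
  colnames(agg) <- m$gene_ids
  structure(list(counts = agg, group_meta = group_meta),
            class = "pseudobulk_matrix")
}

#' Median-of-ratios size factors
#'
#' Per-sample factor = median over reference genes of
#' count / geometric-mean-across-samples.  Reference genes are those with
#' nonzero counts in all samples; when none exists, genes nonzero in at
#' least 90 percent of samples are used, with geometric means over nonzero
#' entries only (warned).
#'
#' @param counts sample x gene matrix of counts.
#' @return numeric vector of size factors, one per sample (row).
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2) stop("at least 2 samples required")
  all_nz <- colSums(counts > 0) == nrow(counts)
  if (any(all_nz)) {
    ref <- counts[, all_nz, drop = FALSE]
    log_gm <- colMeans(log(ref))
    sf <- apply(ref, 1, function(row) exp(stats::median(log(row) - log_gm)))
  } else {
    frac_nz <- colSums(counts > 0) / nrow(counts)
    use <- frac_nz >= 0.9
    if (!any(use)) stop("no gene expressed in >= 90% of samples")
    warning("no gene expressed in all samples; ",
            "using genes nonzero in >= 90% of samples", call. = FALSE)
    ref <- counts[, use, drop = FALSE]
    log_gm <- apply(ref, 2, function(col) mean(log(col[col > 0])))
    sf <- apply(ref, 1, function(row) {
      lr <- log(row) - log_gm
      exp(stats::median(lr[is.finite(lr)]))
    })
  }
  unname(sf)
}

#' Filter and normalize a bulk count matrix
#'
#' Genes whose maximum count across samples is below `min_count` are
#' removed; remaining counts are divided by median-of-ratios size factors.
#'
#' @param counts gene x sample matrix of integer counts.
#' @param min_count minimum max-across-samples count to keep a gene
#'   (default 5).
#' @param filter_stat "max" (default) or "sum": statistic compared against
#'   `min_count`.
#' @return normalized gene x sample matrix.
#' @export
bulk_normalize <- function(counts, min_count = 5,
                           filter_stat = c("max", "sum")) {
  filter_stat <- match.arg(filter_stat)
  counts <- as.matrix(counts)
  stat <- if (filter_stat == "max") apply(counts, 1, max)
  else rowSums(counts)
  keep <- stat >= min_count
  if (!any(keep)) stop("no genes pass the count filter")
  if (sum(!keep) > 0)
    message(sum(!keep), " gene(s) removed by the count filter")
  kept <- counts[keep, , drop = FALSE]
  sf <- size_factors(t(kept))
  sweep(kept, 2, sf, "/")
}

#' @keywords internal
.moments_dispersion <- function(norm_counts, floor = 1e-8) {
  # per-gene NB dispersion alpha from Var = mu + alpha mu^2 on normalized
  # counts pooled across conditions
  m <- colMeans(norm_counts)
  v <- apply(norm_counts, 2, stats::var)
  pmax((v - m) / m^2, floor)
}

#' @keywords internal
.nb_wald_one <- function(y, x, sf, alpha) {
  # fixed-dispersion NB GLM log mu = log sf + b0 + b1 x; Wald on b1
  fit <- tryCatch(
    suppressWarnings(stats::glm(
      y ~ x + offset(log(sf)),
      family = MASS::negative.binomial(theta = 1 / alpha))),
    error = function(e) NULL)
  if (is.null(fit)) return(c(NA_real_, NA_real_))
  sm <- tryCatch(summary(fit)$coefficients, error = function(e) NULL)
  if (is.null(sm) || !"x" %in% rownames(sm)) return(c(NA_real_, NA_real_))
  # dispersion is fixed, so use the asymptotic (dispersion = 1) covariance
  se <- sqrt(diag(stats::vcov(fit, dispersion = 1)))["x"]
  c(unname(stats::coef(fit)["x"]), unname(se))
}

#' Per-cell-type negative-binomial Wald differential expression
#'
#' For each cell type with at least `min_donors` donors per condition, fits
#' per gene the NB log-linear model
#' `log mu = log(size factor) + b0 + b1 * I(disease)` with per-gene
#' method-of-moments dispersion (floor 1e-8), and reports the Wald z
#' statistic `b1/se`, two-sided normal p, and BH-adjusted p within the cell
#' type.  Genes with all-zero counts in the cell type are excluded.
#'
#' @param pb a [pseudobulk()] result.
#' @param cell_type cell type to test; NULL tests every eligible cell type.
#' @param min_donors minimum donors per condition (default 2); cell types
#'   below it are skipped with a message.
#' @return data.frame with columns gene, cell_type, base_mean, log2fc, se,
#'   wald, p, p_adj, stars.
#' @export
nb_wald_de <- function(pb, cell_type = NULL, min_donors = 2) {
  cts <- if (is.null(cell_type)) unique(pb$group_meta$cell_type)
  else cell_type
  out <- NULL
  for (ct in cts) {
    rows <- pb$group_meta$cell_type == ct
    meta <- pb$group_meta[rows, , drop = FALSE]
    n_dis <- length(unique(meta$donor_id[meta$condition == "disease"]))
    n_con <- length(unique(meta$donor_id[meta$condition == "control"]))
    if (n_dis < min_donors || n_con < min_donors) {
      message("cell type '", ct, "' skipped: ", n_dis, " disease / ",
              n_con, " control donors (need >= ", min_donors, ")")
      next
    }
    counts <- pb$counts[rows, , drop = FALSE]
    expressed <- colSums(counts) > 0
    counts <- counts[, expressed, drop = FALSE]
    if (ncol(counts) == 0) next
    sf <- size_factors(counts)
    norm <- sweep(counts, 1, sf, "/")
    alpha <- .moments_dispersion(norm)
    x <- as.numeric(meta$condition == "disease")
    est <- vapply(seq_len(ncol(counts)), function(j)
      .nb_wald_one(counts[, j], x, sf, alpha[j]), numeric(2))
    b1 <- est[1, ]; se <- est[2, ]
    wald <- b1 / se
    p <- 2 * stats::pnorm(-abs(wald))
    p <- pmin(pmax(p, .Machine$double.xmin), 1)
    p_adj <- rep(NA_real_, length(p))
    ok <- !is.na(p)
    p_adj[ok] <- stats::p.adjust(p[ok], method = "BH")
    res <- data.frame(gene = colnames(counts), cell_type = ct,
                      base_mean = colMeans(norm),
                      log2fc = b1 / log(2), se = se / log(2),
                      wald = wald, p = p, p_adj = p_adj,
                      stars = de_stars(p_adj),
                      row.names = NULL, stringsAsFactors = FALSE)
    out <- rbind(out, res)
  }
  if (is.null(out))
    out <- data.frame(gene = character(), cell_type = character(),
                      base_mean = numeric(), log2fc = numeric(),
                      se = numeric(), wald = numeric(), p = numeric(),
                      p_adj = numeric(), stars = character())
  out
}

#' Significance stars for adjusted p-values
#'
#' `*` for p_adj < 0.05, `**` for < 0.001, `***` for < 0.0001.
#'
#' @param p_adj numeric vector of BH-adjusted p-values.
#' @return character vector of star annotations ("" when not significant).
#' @export
de_stars <- function(p_adj) {
  out <- rep("", length(p_adj))
  out[!is.na(p_adj) & p_adj < 0.05] <- "*"
  out[!is.na(p_adj) & p_adj < 0.001] <- "**"
  out[!is.na(p_adj) & p_adj < 0.0001] <- "***"
  out
}

#' Read single-cell counts from MatrixMarket triplet files
#'
#' @param mtx_path MatrixMarket file, cells x genes or genes x cells
#'   (transposed automatically using the barcode count).
#' @param genes_path,barcodes_path one-identifier-per-line text files.
#' @param meta_path cell-metadata TSV with columns barcode, donor_id,
#'   cell_type, condition.
#' @return A [cell_counts()].
#' @export
read_sc_counts <- function(mtx_path, genes_path, barcodes_path, meta_path) {
  mm <- Matrix::readMM(mtx_path)
  genes <- readLines(genes_path)
  barcodes <- readLines(barcodes_path)
  if (nrow(mm) == length(genes) && ncol(mm) == length(barcodes)) {
    mm <- Matrix::t(mm)
  } else if (!(nrow(mm) == length(barcodes) && ncol(mm) == length(genes))) {
    stop("matrix dimensions match neither genes x cells nor cells x genes")
  }
  meta <- utils::read.table(meta_path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  idx <- match(barcodes, meta$barcode)
  if (anyNA(idx)) stop("metadata missing for some barcodes")
  cell_counts(methods::as(mm, "CsparseMatrix"), meta[idx, , drop = FALSE],
              genes)
}

#' Write single-cell counts as MatrixMarket triplet plus sidecars
#' @param m a [cell_counts()].
#' @param dir output directory (created if needed); writes counts.mtx,
#'   genes.txt, barcodes.txt, cell_meta.tsv.
#' @export
write_sc_counts <- function(m, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(methods::as(Matrix::Matrix(m$counts, sparse = TRUE),
                              "generalMatrix"),
                  file.path(dir, "counts.mtx"))
  writeLines(m$gene_ids, file.path(dir, "genes.txt"))
  writeLines(as.character(m$cell_meta$barcode),
             file.path(dir, "barcodes.txt"))
  utils::write.table(m$cell_meta, file.path(dir, "cell_meta.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
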