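# Genotype reference panel: allele frequencies, pairwise LD r-squared, and
# proxy search.  The panel stands in for an external LD service: a sample x
# variant matrix of unphased allele dosages in {0, 1, 2} with missing values
# allowed, plus a variant table (chrom, pos, alleles, rsid).

# LD bands used when reporting proxies: r^2 > 0.50 qualifies a variant as an
# LD proxy; 0.80 and 0.90 mark strong and very strong LD.
#' @export
LD_PROXY_R2 <- 0.50
#' @export
LD_STRONG_R2 <- 0.80
#' @export
LD_VERY_STRONG_R2 <- 0.90

#' Construct a genotype panel
#'
#' @param dosages numeric matrix, samples in rows and variants in columns;
#'   entries in \{0, 1, 2\} or NA.
#' @param variants data.frame with columns rsid, chrom, pos (one row per
#'   column of `dosages`).
#' @param sample_ids optional character vector of row identifiers.
#' @return A `genotype_panel` list with elements dosages, variants,
#'   sample_ids.
#' @export
genotype_panel <- function(dosages, variants, sample_ids = NULL) {
  dosages <- as.matrix(dosages)
  if (ncol(dosages) != nrow(variants))
    stop("dosage columns must match variant rows")
  vals <- dosages[!is.na(dosages)]
  if (length(vals) && !all(vals %in% c(0, 1, 2)))
    stop("dosages must be 0, 1, 2 or NA")
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(dosages)))
  variants$chrom <- .norm_chrom(variants$chrom)
  variants$pos <- as.integer(variants$pos)
  if (is.null(variants$rsid)) variants$rsid <- paste0("v", seq_len(nrow(variants)))
  colnames(dosages) <- variants$rsid
  rownames(dosages) <- sample_ids
  structure(list(dosages = dosages, variants = variants,
                 sample_ids = sample_ids),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("genotype_panel:", nrow(x$dosages), "samples x",
      ncol(x$dosages), "variants\n")
  invisible(x)
}

#' @keywords internal
.panel_index <- function(panel, variant) {
  v <- panel$variants
  if (is.character(variant) && length(variant) == 1) {
    i <- match(variant, v$rsid)
  } else if (is.list(variant)) {
    i <- which(v$chrom == .norm_chrom(variant$chrom) & v$pos == variant$pos)[1]
  } else {
    i <- as.integer(variant)
  }
  if (is.na(i) || i < 1 || i > ncol(panel$dosages))
    stop("variant not found in panel")
  i
}

#' Per-variant allele frequencies
#'
#' Alternate-allele frequency is `mean(dosage)/2` over non-missing samples;
#' MAF is `min(freq, 1 - freq)`.  Variants with all dosages missing get NA
#' and are flagged, as are monomorphic variants.
#'
#' @param panel a [genotype_panel()].
#' @return data.frame with columns rsid, chrom, pos, n_called, freq, maf,
#'   monomorphic.
#' @export
allele_freqs <- function(panel) {
  d <- panel$dosages
  if (ncol(d) == 0) stop("empty panel")
  n_called <- colSums(!is.na(d))
  freq <- colMeans(d, na.rm = TRUE) / 2
  freq[n_called == 0] <- NA_real_
  maf <- pmin(freq, 1 - freq)
  data.frame(rsid = panel$variants$rsid, chrom = panel$variants$chrom,
             pos = panel$variants$pos, n_called = n_called,
             freq = freq, maf = maf,
             monomorphic = !is.na(freq) & (freq == 0 | freq == 1),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Pairwise LD between two variants
#'
#' r-squared is the squared Pearson correlation of unphased dosage vectors
#' over pairwise-complete samples (composite LD).  Invariant under allele
#' recoding g -> 2 - g of either variant and symmetric in its arguments.
#'
#' @param panel a [genotype_panel()].
#' @param a,b variant identifiers: rsid, list(chrom=, pos=) or column index.
#' @return list with variant_a, variant_b, r2, n_samples.
#' @export
ld_r2 <- function(panel, a, b) {
  ia <- .panel_index(panel, a); ib <- .panel_index(panel, b)
  ga <- panel$dosages[, ia]; gb <- panel$dosages[, ib]
  ok <- !is.na(ga) & !is.na(gb)
  if (sum(ok) < 2) stop("fewer than 2 complete sample pairs")
  ga <- ga[ok]; gb <- gb[ok]
  if (stats::var(ga) == 0 || stats::var(gb) == 0)
    stop("variant monomorphic in complete subset; LD undefined")
  r <- stats::cor(ga, gb)
  list(variant_a = panel$variants$rsid[ia], variant_b = panel$variants$rsid[ib],
       r2 = r * r, n_samples = sum(ok))
}

#' @keywords internal
.ld_r2_vector <- function(panel, i, idx) {
  # r2 of variant i against each column in idx, pairwise-complete; NA where
  # undefined.  Used by proxy search and clumping.
  gi <- panel$dosages[, i]
  vapply(idx, function(j) {
    gj <- panel$dosages[, j]
    ok <- !is.na(gi) & !is.na(gj)
    if (sum(ok) < 2) return(NA_real_)
    x <- gi[ok]; y <- gj[ok]
    if (stats::var(x) == 0 || stats::var(y) == 0) return(NA_real_)
    stats::cor(x, y)^2
  }, numeric(1))
}

#' Find LD proxies for a query variant
#'
#' Returns variants within `window` whose r-squared with the query is at
#' least `r2_min` (the query itself is excluded), sorted by descending r2;
#' ties are broken by genomic distance to the query, then by position.
#'
#' @param panel a [genotype_panel()].
#' @param query variant identifier.
#' @param r2_min minimum r-squared (default the proxy band, 0.50).
#' @param window optional [locus_window()]; defaults to a 1 Mb window
#'   centered on the query.
#' @return data.frame with columns rsid, chrom, pos, r2, distance.
#' @export
find_proxies <- function(panel, query, r2_min = LD_PROXY_R2, window = NULL) {
  iq <- .panel_index(panel, query)
  v <- panel$variants
  if (is.null(window))
    window <- locus_window(v$chrom[iq], v$pos[iq])
  gq <- panel$dosages[, iq]
  if (stats::var(gq, na.rm = TRUE) %in% c(0, NA))
    stop("query variant monomorphic; LD undefined")
  in_win <- which(v$chrom == window$chrom &
                    abs(v$pos - window$pos) <= window$half_width)
  in_win <- setdiff(in_win, iq)
  if (length(in_win) == 0)
    return(data.frame(rsid = character(), chrom = character(),
                      pos = integer(), r2 = numeric(), distance = integer()))
  r2 <- .ld_r2_vector(panel, iq, in_win)
  # tolerance absorbs float error in cor() (e.g. duplicate columns at
  # r2_min = 1)
  keep <- !is.na(r2) & r2 >= r2_min - 1e-12
  out <- data.frame(rsid = v$rsid[in_win], chrom = v$chrom[in_win],
                    pos = v$pos[in_win], r2 = r2,
                    distance = abs(v$pos[in_win] - v$pos[iq]),
                    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  out <- out[order(-out$r2, out$distance, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a genotype panel from a dosage TSV plus variant sidecar
#'
#' The dosage file is samples x variants with a header of variant ids and a
#' first column of sample ids; the sidecar maps ids to coordinates.
#'
#' @param dosage_path TSV of dosages.
#' @param variants_path TSV with columns rsid, chrom, pos.
#' @return A [genotype_panel()].
#' @export
read_panel_tsv <- function(dosage_path, variants_path) {
  d <- utils::read.table(dosage_path, header = TRUE, sep = "\t",
                         row.names = 1, check.names = FALSE)
  v <- utils::read.table(variants_path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  v <- v[match(colnames(d), v$rsid), , drop = FALSE]
  if (anyNA(v$rsid)) stop("variant sidecar missing ids present in dosage file")
  genotype_panel(as.matrix(d), v, sample_ids = rownames(d))
}

#' Write a genotype panel to dosage + variant TSVs
#' @param panel a [genotype_panel()].
#' @param dosage_path,variants_path output paths.
#' @export
write_panel_tsv <- function(panel, dosage_path, variants_path) {
  d <- data.frame(sample_id = panel$sample_ids, panel$dosages,
                  check.names = FALSE)
  utils::write.table(d, dosage_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(panel$variants[c("rsid", "chrom", "pos")],
                     variants_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(dosage_path)
}

#' Read a genotype panel from a VCF
#'
#' Converts the GT field to allele dosage; multi-allelic records are skipped
#' with a message.  Requires the vcfR package.
#'
#' @param path VCF path (optionally gzipped).
#' @return A [genotype_panel()].
#' @export
read_panel_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF panels requires the vcfR package")
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT)
  if (any(multi)) {
    message(sum(multi), " multi-allelic record(s) skipped")
    vcf <- vcf[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  alt_count <- function(g) {
    if (is.na(g)) return(NA_real_)
    alleles <- strsplit(g, "[/|]")[[1]]
    if (any(alleles == ".")) return(NA_real_)
    sum(alleles != "0")
  }
  # samples x variants
  dos <- apply(gt, 1, function(row) vapply(row, alt_count, numeric(1)))
  if (is.null(dim(dos))) dos <- matrix(dos, nrow = ncol(gt))
  variants <- data.frame(
    rsid = ifelse(is.na(fix$ID) | fix$ID == ".",
                  paste0(fix$CHROM, ":", fix$POS), fix$ID),
    chrom = fix$CHROM, pos = as.integer(fix$POS), stringsAsFactors = FALSE)
  genotype_panel(dos, variants, sample_ids = colnames(gt))
}
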