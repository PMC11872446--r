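# Summary-statistics tables: reading, validation, harmonization, windowing.
#
# A sumstat_table is a data.frame with one row per variant and the columns
#   rsid, chrom, pos, effect_allele, other_allele, beta, se, p, n, maf
# plus attributes trait_type ("quantitative" or "case-control"),
# case_fraction, trait_label and context_label.  Positions are 1-based;
# chromosome labels are stored without a "chr" prefix.

#' Default logical-to-file column mapping for summary statistics
#'
#' Maps the logical column names used throughout the package to the headers
#' found in a summary-statistics file.  Override any entry to match your
#' file's dialect.
#'
#' @return Named character vector (logical name -> file header).
#' @export
sumstats_dialect <- function() {
  c(rsid = "rsid", chrom = "chrom", pos = "pos",
    effect_allele = "effect_allele", other_allele = "other_allele",
    beta = "beta", se = "se", p = "p", n = "n", maf = "maf")
}

#' @keywords internal
.norm_chrom <- function(x) sub("^[Cc][Hh][Rr]", "", as.character(x))

# Smallest p-value retained before log-scale transforms; values below are
# clipped (with a warning at the transform site) to avoid infinite z-scores.
P_CLIP_MIN <- 1e-300

#' Construct a validated summary-statistics table
#'
#' Validates records, normalizes chromosome labels, drops rows that fail
#' validation (with a message giving the count), and orders rows by
#' (chrom, pos).  A row is valid when it has a usable position, two distinct
#' alleles, and at least one of \{(beta, se), p\}; p must lie in (0, 1],
#' se must be positive when present, and maf in (0, 0.5] when present.
#'
#' @param df data.frame with (a subset of) the logical columns of
#'   [sumstats_dialect()].
#' @param trait_type "quantitative" or "case-control".
#' @param case_fraction proportion of cases in (0,1); required for
#'   case-control tables.
#' @param trait_label,context_label free-text labels (context = tissue, cell
#'   type or disease state).
#' @return A `sumstat_table` data.frame.
#' @export
sumstat_table <- function(df, trait_type = c("quantitative", "case-control"),
                          case_fraction = NULL, trait_label = "trait",
                          context_label = "") {
  trait_type <- match.arg(trait_type)
  if (trait_type == "case-control") {
    if (is.null(case_fraction) || !is.finite(case_fraction) ||
        case_fraction <= 0 || case_fraction >= 1)
      stop("case-control tables require case_fraction in (0,1)")
  }
  cols <- names(sumstats_dialect())
  for (cc in cols) if (is.null(df[[cc]])) df[[cc]] <- NA
  df <- df[cols]
  df$chrom <- .norm_chrom(df$chrom)
  df$pos <- suppressWarnings(as.integer(df$pos))
  df$rsid <- as.character(df$rsid)
  for (cc in c("beta", "se", "p", "maf")) {
    df[[cc]] <- suppressWarnings(as.numeric(df[[cc]]))
  }
  df$n <- suppressWarnings(as.numeric(df$n))
  df$effect_allele <- toupper(as.character(df$effect_allele))
  df$other_allele <- toupper(as.character(df$other_allele))

  ok <- !is.na(df$chrom) & nzchar(df$chrom) &
    !is.na(df$pos) & df$pos >= 1L &
    !is.na(df$effect_allele) & !is.na(df$other_allele) &
    nzchar(df$effect_allele) & nzchar(df$other_allele) &
    df$effect_allele != df$other_allele
  has_bse <- !is.na(df$beta) & !is.na(df$se) & df$se > 0
  has_p <- !is.na(df$p) & df$p > 0 & df$p <= 1
  ok <- ok & (has_bse | has_p)
  ok <- ok & (is.na(df$maf) | (df$maf > 0 & df$maf <= 0.5))
  ok <- ok & (is.na(df$n) | df$n > 0)
  ok[is.na(ok)] <- FALSE
  n_drop <- sum(!ok)
  if (n_drop > 0) message(n_drop, " record(s) failed validation and were dropped")
  df <- df[ok, , drop = FALSE]
  if (nrow(df) == 0) stop("no valid summary-statistic records")

  key <- paste(df$chrom, df$pos, pmin(df$effect_allele, df$other_allele),
               pmax(df$effect_allele, df$other_allele))
  if (anyDuplicated(key)) {
    message(sum(duplicated(key)), " duplicate variant(s) dropped (first kept)")
    df <- df[!duplicated(key), , drop = FALSE]
  }
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("sumstat_table", "data.frame"),
            trait_type = trait_type, case_fraction = case_fraction,
            trait_label = trait_label, context_label = context_label)
}

#' Read a summary-statistics file
#'
#' Reads a tab- or comma-delimited text file (gzip transparently supported),
#' renames columns according to `dialect`, and validates via
#' [sumstat_table()].  An optional two-column coordinate map (`old_pos`,
#' `new_pos`, applied per chromosome via `chrom`) can translate positions
#' between builds at read time.
#'
#' @param path file path.
#' @param dialect named character vector mapping logical names to file
#'   headers; see [sumstats_dialect()].
#' @param coord_map optional data.frame with columns chrom, old_pos, new_pos;
#'   unmapped positions are dropped with a message.
#' @inheritParams sumstat_table
#' @return A `sumstat_table`.
#' @export
read_sumstats <- function(path, dialect = sumstats_dialect(),
                          trait_type = "quantitative", case_fraction = NULL,
                          trait_label = basename(path), context_label = "",
                          coord_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 0) stop("empty summary-statistics file: ", path)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, comment.char = "",
                          check.names = FALSE)
  if (nrow(df) == 0) stop("empty summary-statistics file: ", path)
  required <- c("chrom", "pos", "effect_allele", "other_allele")
  for (logical_name in names(dialect)) {
    header <- dialect[[logical_name]]
    if (header %in% names(df)) {
      names(df)[names(df) == header] <- logical_name
    } else if (logical_name %in% required) {
      stop("required column '", header, "' (", logical_name,
           ") missing from ", path)
    }
  }
  if (!is.null(coord_map)) {
    cm_key <- paste(.norm_chrom(coord_map$chrom), coord_map$old_pos)
    idx <- match(paste(.norm_chrom(df$chrom), df$pos), cm_key)
    n_un <- sum(is.na(idx))
    if (n_un > 0) message(n_un, " variant(s) without coordinate mapping dropped")
    df <- df[!is.na(idx), , drop = FALSE]
    df$pos <- coord_map$new_pos[idx[!is.na(idx)]]
  }
  sumstat_table(df, trait_type = trait_type, case_fraction = case_fraction,
                trait_label = trait_label, context_label = context_label)
}

#' Write a summary-statistics table as TSV
#'
#' Fixed column order, floats rendered with 6 significant digits.
#'
#' @param t a `sumstat_table`.
#' @param path output path.
#' @export
write_sumstats <- function(t, path) {
  out <- as.data.frame(t)
  for (cc in c("beta", "se", "p", "maf"))
    out[[cc]] <- signif(out[[cc]], 6)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Locus window around a variant
#'
#' A closed interval `[pos - half_width, pos + half_width]` on one
#' chromosome.  The default half-width of 500 kb gives the 1 Mb total window
#' used when filtering SNPs around a variant of interest.
#'
#' @param chrom chromosome label.
#' @param pos 1-based center position.
#' @param half_width window half-width in bases (> 0).
#' @return A `locus_window` list.
#' @export
locus_window <- function(chrom, pos, half_width = 500000L) {
  stopifnot(half_width > 0, pos >= 1)
  structure(list(chrom = .norm_chrom(chrom), pos = as.integer(pos),
                 half_width = as.integer(half_width)),
            class = "locus_window")
}

#' Restrict a table to a locus window
#'
#' Keeps records on the window's chromosome with
#' `|pos - center| <= half_width` (closed interval), ordered by position.
#' An empty result is allowed.
#'
#' @param t a `sumstat_table`.
#' @param w a [locus_window()].
#' @return A `sumstat_table` (possibly with zero rows).
#' @export
extract_window <- function(t, w) {
  stopifnot(inherits(w, "locus_window"))
  keep <- t$chrom == w$chrom & abs(t$pos - w$pos) <= w$half_width
  out <- t[keep, , drop = FALSE]
  out <- out[order(out$pos), , drop = FALSE]
  rownames(out) <- NULL
  attributes_to_keep <- attributes(t)[c("trait_type", "case_fraction",
                                        "trait_label", "context_label")]
  attributes(out)[names(attributes_to_keep)] <- attributes_to_keep
  class(out) <- class(t)
  out
}

#' @keywords internal
.is_palindromic <- function(ea, oa) {
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  !is.na(comp[ea]) & !is.na(comp[oa]) & comp[ea] == oa
}

#' Harmonize two summary-statistics tables onto shared variants
#'
#' Matches variants on (chrom, pos, unordered allele set).  When the effect
#' and other alleles are swapped between the tables, the second table's beta
#' sign is flipped so both effects refer to the same allele.  Variants whose
#' allele sets do not match are dropped with a message.  Palindromic (A/T,
#' C/G) variants are retained with a warning by default because downstream
#' p-value-based analyses are direction-blind; `strict = TRUE` drops them.
#'
#' @param a,b `sumstat_table`s.
#' @param strict drop palindromic variants instead of warning.
#' @return data.frame with columns chrom, pos, effect_allele, other_allele,
#'   rsid and per-trait suffixed columns (beta_a, se_a, p_a, n_a, maf_a and
#'   the `_b` counterparts).  Zero rows signal an empty overlap.
#' @export
harmonize_pair <- function(a, b, strict = FALSE) {
  key <- function(t) paste(t$chrom, t$pos,
                           pmin(t$effect_allele, t$other_allele),
                           pmax(t$effect_allele, t$other_allele))
  ka <- key(a); kb <- key(b)
  # positional matches whose allele sets differ are dropped with a message
  pos_a <- paste(a$chrom, a$pos); pos_b <- paste(b$chrom, b$pos)
  n_allele_mismatch <- length(intersect(pos_a, pos_b)) -
    length(intersect(ka, kb))
  if (n_allele_mismatch > 0)
    message(n_allele_mismatch,
            " shared position(s) dropped for mismatched allele sets")
  ia <- match(kb, ka)
  keep <- !is.na(ia)
  if (!any(keep)) {
    out <- data.frame(chrom = character(), pos = integer(),
                      effect_allele = character(), other_allele = character(),
                      rsid = character(),
                      beta_a = numeric(), se_a = numeric(), p_a = numeric(),
                      n_a = numeric(), maf_a = numeric(),
                      beta_b = numeric(), se_b = numeric(), p_b = numeric(),
                      n_b = numeric(), maf_b = numeric())
    return(out)
  }
  bb <- b[keep, , drop = FALSE]
  aa <- a[ia[keep], , drop = FALSE]
  flipped <- aa$effect_allele == bb$other_allele &
    aa$other_allele == bb$effect_allele
  beta_b <- ifelse(flipped, -bb$beta, bb$beta)
  pal <- .is_palindromic(aa$effect_allele, aa$other_allele)
  if (any(pal)) {
    if (strict) {
      message(sum(pal), " palindromic variant(s) dropped (strict mode)")
    } else {
      warning(sum(pal), " palindromic (A/T or C/G) variant(s) retained; ",
              "strand flips cannot be resolved for these", call. = FALSE)
    }
  }
  out <- data.frame(chrom = aa$chrom, pos = aa$pos,
                    effect_allele = aa$effect_allele,
                    other_allele = aa$other_allele,
                    rsid = ifelse(is.na(aa$rsid), bb$rsid, aa$rsid),
                    beta_a = aa$beta, se_a = aa$se, p_a = aa$p,
                    n_a = aa$n, maf_a = aa$maf,
                    beta_b = beta_b, se_b = bb$se, p_b = bb$p,
                    n_b = bb$n, maf_b = bb$maf,
                    stringsAsFactors = FALSE)
  if (strict) out <- out[!pal, , drop = FALSE]
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}
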