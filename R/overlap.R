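# Cross-phenotype overlap of independent genome-wide-significant loci:
# greedy LD clumping to lead SNPs, matching of leads between two traits via
# panel r-squared, and enrichment arithmetic (expected shared count, fold
# enrichment, one-sided Fisher exact p over the effective-SNP universe,
# Benjamini-Hochberg adjustment across trait pairs).

#' Genome-wide significance threshold
#' @export
GWS_P_THRESHOLD <- 5e-8

#' Greedy LD clumping of significant variants to independent leads
#'
#' Repeatedly takes the smallest-p remaining significant variant as a lead
#' and removes all remaining significant variants with panel r-squared at or
#' above `clump_r2` to it.  Ties on p are broken by (chrom, pos).  Variants
#' not covered by the panel are treated as independent leads (with a
#' message).
#'
#' @param t a `sumstat_table` with p-values.
#' @param panel a [genotype_panel()].
#' @param p_threshold significance cutoff (default genome-wide, 5e-8).
#' @param clump_r2 r-squared at or above which two hits are collapsed.
#' @return A `lead_snp_set`: data.frame (rsid, chrom, pos, p) with
#'   attributes trait_label, p_threshold, clump_r2.
#' @export
clump_hits <- function(t, panel, p_threshold = GWS_P_THRESHOLD,
                       clump_r2 = 0.4) {
  sig <- t[!is.na(t$p) & t$p <= p_threshold, , drop = FALSE]
  lab <- attr(t, "trait_label")
  empty <- data.frame(rsid = character(), chrom = character(),
                      pos = integer(), p = numeric())
  if (nrow(sig) == 0)
    return(structure(empty, class = c("lead_snp_set", "data.frame"),
                     trait_label = lab, p_threshold = p_threshold,
                     clump_r2 = clump_r2))
  sig <- sig[order(sig$p, sig$chrom, sig$pos), , drop = FALSE]
  pk <- paste(panel$variants$chrom, panel$variants$pos)
  idx_panel <- match(paste(sig$chrom, sig$pos), pk)
  if (anyNA(idx_panel))
    message(sum(is.na(idx_panel)),
            " significant variant(s) absent from panel; treated as independent")
  remaining <- seq_len(nrow(sig))
  leads <- integer(0)
  while (length(remaining) > 0) {
    lead <- remaining[1]
    leads <- c(leads, lead)
    remaining <- remaining[-1]
    if (length(remaining) == 0) break
    if (is.na(idx_panel[lead])) next
    cov <- remaining[!is.na(idx_panel[remaining])]
    if (length(cov) > 0) {
      r2 <- .ld_r2_vector(panel, idx_panel[lead], idx_panel[cov])
      drop <- cov[!is.na(r2) & r2 >= clump_r2]
      remaining <- setdiff(remaining, drop)
    }
  }
  out <- sig[leads, c("rsid", "chrom", "pos", "p"), drop = FALSE]
  out <- out[order(out$p, out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("lead_snp_set", "data.frame"),
            trait_label = lab, p_threshold = p_threshold,
            clump_r2 = clump_r2)
}

#' Shared lead pairs between two traits
#'
#' A pair (va, vb) is shared when the leads are the same variant or their
#' panel r-squared is at least `share_r2`.  Matching is greedy one-to-one by
#' descending r-squared, so each lead participates in at most one pair.
#'
#' @param a,b `lead_snp_set`s from [clump_hits()].
#' @param panel a [genotype_panel()].
#' @param share_r2 r-squared at or above which two leads count as shared.
#' @return data.frame with columns rsid_a, rsid_b, r2.
#' @export
count_shared <- function(a, b, panel, share_r2 = 0.4) {
  empty <- data.frame(rsid_a = character(), rsid_b = character(),
                      r2 = numeric())
  if (nrow(a) == 0 || nrow(b) == 0) return(empty)
  pk <- paste(panel$variants$chrom, panel$variants$pos)
  ia <- match(paste(a$chrom, a$pos), pk)
  ib <- match(paste(b$chrom, b$pos), pk)
  cand <- NULL
  for (i in seq_len(nrow(a))) {
    same <- which(b$chrom == a$chrom[i] & b$pos == a$pos[i])
    r2 <- rep(NA_real_, nrow(b))
    if (!is.na(ia[i])) {
      cov <- which(!is.na(ib))
      if (length(cov) > 0) r2[cov] <- .ld_r2_vector(panel, ia[i], ib[cov])
    }
    r2[same] <- 1
    hit <- which(!is.na(r2) & r2 >= share_r2)
    if (length(hit) > 0)
      cand <- rbind(cand, data.frame(i = i, j = hit, r2 = r2[hit]))
  }
  if (is.null(cand)) return(empty)
  cand <- cand[order(-cand$r2, cand$i, cand$j), , drop = FALSE]
  used_a <- logical(nrow(a)); used_b <- logical(nrow(b))
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    if (!used_a[cand$i[k]] && !used_b[cand$j[k]]) {
      keep[k] <- TRUE
      used_a[cand$i[k]] <- TRUE
      used_b[cand$j[k]] <- TRUE
    }
  }
  cand <- cand[keep, , drop = FALSE]
  data.frame(rsid_a = a$rsid[cand$i], rsid_b = b$rsid[cand$j],
             r2 = cand$r2, row.names = NULL, stringsAsFactors = FALSE)
}

#' Overlap enrichment between two lead sets
#'
#' Expected shared count is `n1 * n2 / me`, where `me` is the effective
#' number of independent SNPs for the LD population; fold enrichment is
#' `n_share / expected`.  Significance is a one-sided Fisher exact test
#' (alternative = enrichment) on the 2x2 table
#' `[n_share, n1 - n_share; n2 - n_share, me - n1 - n2 + n_share]`.
#'
#' @param n1,n2 independent lead counts for traits 1 and 2.
#' @param n_share shared lead count.
#' @param me effective number of independent SNPs in the LD population
#'   (configuration input, population specific).
#' @return An `overlap_result` list: n1, n2, n_share, me, expected, fold, p.
#' @export
overlap_enrichment <- function(n1, n2, n_share, me) {
  stopifnot(n1 > 0, n2 > 0, n_share >= 0)
  if (n_share > min(n1, n2)) stop("n_share exceeds min(n1, n2)")
  if (me < n1 + n2 - n_share) stop("me too small for the given counts")
  me <- round(me)
  expected <- n1 * n2 / me
  fold <- n_share / expected
  tab <- matrix(c(n_share, n1 - n_share,
                  n2 - n_share, me - n1 - n2 + n_share), nrow = 2)
  p <- stats::fisher.test(tab, alternative = "greater")$p.value
  structure(list(n1 = n1, n2 = n2, n_share = n_share, me = me,
                 expected = expected, fold = fold, p = p),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf(
    "overlap: n1=%d n2=%d shared=%d (expected %.4g, fold %.4g, p=%.3g)\n",
    x$n1, x$n2, x$n_share, x$expected, x$fold, x$p))
  invisible(x)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH with monotonicity enforcement, order-preserving; a thin
#' wrapper over [stats::p.adjust()].
#'
#' @param pvals numeric vector of p-values in (0, 1].
#' @return adjusted p-values, same order as input.
#' @export
bh_adjust <- function(pvals) {
  stopifnot(all(pvals > 0 & pvals <= 1))
  stats::p.adjust(pvals, method = "BH")
}

#' Pairwise overlap analysis of two traits
#'
#' Convenience pipeline: clump each trait's hits to independent leads, match
#' leads via the panel, and compute enrichment.  Columns mirror the
#' cross-phenotype report format (n1_pcut, n2_pcut, Nshare_all, N_expected,
#' fold, p).
#'
#' @inheritParams clump_hits
#' @param t1,t2 `sumstat_table`s for the two traits.
#' @param me effective number of independent SNPs (see
#'   [overlap_enrichment()]).
#' @param share_r2 see [count_shared()].
#' @return list with elements leads1, leads2, shared (data.frame) and
#'   report (one-row data.frame).
#' @export
trait_pair_overlap <- function(t1, t2, panel, me,
                               p_threshold = GWS_P_THRESHOLD,
                               clump_r2 = 0.4, share_r2 = 0.4) {
  l1 <- clump_hits(t1, panel, p_threshold, clump_r2)
  l2 <- clump_hits(t2, panel, p_threshold, clump_r2)
  shared <- count_shared(l1, l2, panel, share_r2)
  if (nrow(l1) == 0 || nrow(l2) == 0) {
    report <- data.frame(trait1 = attr(t1, "trait_label"),
                         trait2 = attr(t2, "trait_label"),
                         n1_pcut = nrow(l1), n2_pcut = nrow(l2),
                         Nshare_all = nrow(shared), N_expected = NA_real_,
                         fold = NA_real_, p = NA_real_)
    return(list(leads1 = l1, leads2 = l2, shared = shared, report = report))
  }
  enr <- overlap_enrichment(nrow(l1), nrow(l2), nrow(shared), me)
  report <- data.frame(trait1 = attr(t1, "trait_label"),
                       trait2 = attr(t2, "trait_label"),
                       n1_pcut = enr$n1, n2_pcut = enr$n2,
                       Nshare_all = enr$n_share, N_expected = enr$expected,
                       fold = enr$fold, p = enr$p)
  list(leads1 = l1, leads2 = l2, shared = shared, report = report)
}
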