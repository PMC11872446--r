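# Candidate causal-gene nomination from QTL catalogs via LD proxies, plus
# the small per-gene statistics used on genotype-stratified molecular data.

#' Nominate candidate eGenes for a query variant via LD proxies
#'
#' Scans a QTL catalog for conditionally independent entries whose variant
#' equals the query or has panel r-squared at least `r2_min` with it, and
#' emits one candidate per (feature, context), keeping the maximum-r2 proxy
#' on duplicates, sorted by descending r2.
#'
#' @param query variant identifier resolvable in the panel (rsid,
#'   list(chrom=, pos=) or column index).
#' @param catalog data.frame with columns rsid, chrom, pos, feature,
#'   context, p and conditionally_independent (logical); optional beta.
#' @param panel a [genotype_panel()].
#' @param r2_min LD proxy threshold (default 0.50).
#' @return data.frame with columns feature, context, proxy_rsid, r2,
#'   source_p.
#' @export
nominate_egenes <- function(query, catalog, panel, r2_min = LD_PROXY_R2) {
  iq <- .panel_index(panel, query)
  v <- panel$variants
  gq <- panel$dosages[, iq]
  if (isTRUE(stats::var(gq, na.rm = TRUE) == 0))
    stop("query variant monomorphic; LD undefined")
  cat_ok <- catalog[isTRUE_vec(catalog$conditionally_independent), ,
                    drop = FALSE]
  empty <- data.frame(feature = character(), context = character(),
                      proxy_rsid = character(), r2 = numeric(),
                      source_p = numeric())
  if (nrow(cat_ok) == 0) return(empty)
  cat_idx <- match(paste(.norm_chrom(cat_ok$chrom), cat_ok$pos),
                   paste(v$chrom, v$pos))
  r2 <- rep(NA_real_, nrow(cat_ok))
  self <- !is.na(cat_idx) & cat_idx == iq
  r2[self] <- 1
  cov <- which(!is.na(cat_idx) & !self)
  if (length(cov) > 0) r2[cov] <- .ld_r2_vector(panel, iq, cat_idx[cov])
  keep <- !is.na(r2) & r2 >= r2_min
  if (!any(keep)) return(empty)
  out <- data.frame(feature = cat_ok$feature[keep],
                    context = cat_ok$context[keep],
                    proxy_rsid = cat_ok$rsid[keep],
                    r2 = r2[keep], source_p = cat_ok$p[keep],
                    stringsAsFactors = FALSE)
  # one candidate per (feature, context): keep the max-r2 proxy
  out <- out[order(-out$r2, out$proxy_rsid), , drop = FALSE]
  out <- out[!duplicated(paste(out$feature, out$context)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @keywords internal
isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' Linear regression of a measurement on genotype dosage
#'
#' Ordinary least squares of `value` on allele count; the two-sided p-value
#' comes from the slope t-statistic on n - 2 degrees of freedom.  Used for
#' genotype-stratified expression or methylation (the regression-slope
#' annotation on genotype boxplots).
#'
#' @param dosage per-sample allele counts in \{0, 1, 2\}.
#' @param value per-sample measurements.
#' @return list with slope, intercept, se, t, p, n.
#' @export
genotype_regression <- function(dosage, value) {
  ok <- !is.na(dosage) & !is.na(value)
  x <- dosage[ok]; y <- value[ok]
  n <- length(x)
  if (n < 3) stop("at least 3 complete samples required")
  if (length(unique(x)) < 2) stop("constant dosage; regression degenerate")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)$coefficients
  list(slope = unname(sm["x", "Estimate"]),
       intercept = unname(sm["(Intercept)", "Estimate"]),
       se = unname(sm["x", "Std. Error"]),
       t = unname(sm["x", "t value"]),
       p = unname(sm["x", "Pr(>|t|)"]),
       n = n)
}

#' Unpaired two-sample t-test
#'
#' Student's equal-variance test by default (Welch via `welch = TRUE`),
#' two-sided.
#'
#' @param a,b numeric vectors (each of length >= 2).
#' @return list with t, df, p, mean_a, mean_b.
#' @export
unpaired_ttest <- function(a, b, welch = FALSE) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 values")
  tt <- tryCatch(stats::t.test(a, b, var.equal = !welch),
                 error = function(e) NULL)
  if (is.null(tt)) {
    # both groups essentially constant: apply the formula directly, which
    # yields t = 0 (equal means) or infinite t (different means)
    na <- length(a); nb <- length(b)
    sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) /
      (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    diff <- mean(a) - mean(b)
    t <- if (se == 0 && diff == 0) 0 else diff / se
    df <- na + nb - 2
    p <- 2 * stats::pt(-abs(t), df)
    return(list(t = t, df = df, p = p, mean_a = mean(a), mean_b = mean(b)))
  }
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_a = mean(a), mean_b = mean(b))
}
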