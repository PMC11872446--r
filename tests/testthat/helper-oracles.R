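# Independent oracles used across the suite.  Each one computes the target
# quantity by a route that shares no code with the implementation.

# Explicit enumeration of causal configurations for the five-hypothesis
# posterior: works on linear-scale Bayes factors with plain sums/products.
oracle_coloc_posteriors <- function(l1, l2, p1, p2, p12) {
  bf1 <- exp(l1); bf2 <- exp(l2)
  n <- length(bf1)
  w0 <- 1
  w1 <- p1 * sum(bf1)
  w2 <- p2 * sum(bf2)
  w3 <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j)
    w3 <- w3 + p1 * p2 * bf1[i] * bf2[j]
  w4 <- p12 * sum(bf1 * bf2)
  w <- c(w0, w1, w2, w3, w4)
  w / sum(w)
}

# Upper tail of the hypergeometric by explicit term-by-term summation.
oracle_hyper_tail <- function(n_share, n1, n2, me) {
  ks <- n_share:min(n1, n2)
  terms <- exp(lchoose(n1, ks) + lchoose(me - n1, n2 - ks) - lchoose(me, n2))
  sum(terms)
}

# Closed-form simple linear regression (textbook formulas).
oracle_ols <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  resid <- y - intercept - slope * x
  se <- sqrt(sum(resid^2) / (n - 2) / sxx)
  t <- slope / se
  list(slope = slope, intercept = intercept, se = se, t = t,
       p = 2 * pt(-abs(t), n - 2))
}

# Normal-prior Bayes factor by numerical integration of the marginal
# likelihood against the N(0, w) effect prior.
oracle_labf_quadrature <- function(beta, se, w) {
  marg <- integrate(function(b) dnorm(beta, b, se) * dnorm(b, 0, sqrt(w)),
                    -Inf, Inf, rel.tol = 1e-12)$value
  log(marg / dnorm(beta, 0, se))
}

# Brute-force r2: squared Pearson correlation computed from raw sums.
oracle_r2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- (n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2)
  num^2 / den
}

# Median-of-ratios by direct transcription of the definition; reference
# genes are those nonzero in every sample.  Fixtures use an odd reference
# count so the sample median is a single ratio and the linear-scale median
# here equals the log-scale median of the implementation.
oracle_size_factors <- function(counts) {
  ref <- counts[, colSums(counts > 0) == nrow(counts), drop = FALSE]
  gm <- apply(ref, 2, function(g) exp(mean(log(g))))
  apply(ref, 1, function(row) median(row / gm))
}

# Small deterministic dosage panel used by several fixtures.
make_test_panel <- function(dosages, chrom = "1", start = 100000L,
                            spacing = 1000L) {
  dosages <- as.matrix(dosages)
  variants <- data.frame(
    rsid = paste0("rs", seq_len(ncol(dosages))),
    chrom = chrom,
    pos = start + (seq_len(ncol(dosages)) - 1L) * spacing)
  genotype_panel(dosages, variants)
}

make_sumstat_df <- function(chrom, pos, p, beta = NA, se = NA,
                            n = 1000, maf = 0.2,
                            ea = "A", oa = "G", rsid = NULL) {
  k <- length(pos)
  data.frame(rsid = if (is.null(rsid)) paste0("rs", seq_len(k)) else rsid,
             chrom = chrom, pos = pos, effect_allele = ea, other_allele = oa,
             beta = beta, se = se, p = p, n = n, maf = maf,
             stringsAsFactors = FALSE)
}
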