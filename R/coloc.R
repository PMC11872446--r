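# Bayesian colocalization of two association signals at one locus.
#
# Per-SNP evidence is a Wakefield-style approximate Bayes factor under a
# normal prior N(0, W) on the effect size: with V = se^2, z = beta/se and
# r = W/(W + V),
#
#     log ABF = 0.5 * (log(1 - r) + r * z^2).
#
# When only (p, MAF, N) are available, z is the two-sided normal quantile
# and V is approximated from the variance of the genotype:
# V = 1/(2 N f (1-f)) for a quantitative trait and
# V = 1/(2 N f (1-f) s (1-s)) for a case-control trait with case fraction s.
#
# The five hypotheses at a locus (no association; trait 1 only; trait 2
# only; two distinct causal variants; one shared causal variant) get
# posterior probabilities PP0-PP4 by summing per-SNP ABFs over causal
# configurations under per-SNP priors p1, p2, p12.  All sums are done in
# log space.

# Prior effect-size standard deviations (sd; W = sd^2).  sdY is taken as 1
# for quantitative traits since p-value inputs cannot estimate it.
#' @export
PRIOR_SD_QUANTITATIVE <- 0.15
#' @export
PRIOR_SD_CASE_CONTROL <- 0.2

#' Colocalization priors
#'
#' Per-SNP prior probabilities: `p1` for association with trait 1 only,
#' `p2` with trait 2 only, `p12` with both.  Defaults are the standard
#' p1 = p2 = 1e-4, p12 = 1e-5.
#'
#' @param p1,p2,p12 priors in (0, 1) with p12 <= min(p1, p2).
#' @return A `coloc_priors` list.
#' @export
coloc_priors <- function(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) {
  stopifnot(p1 > 0, p2 > 0, p12 > 0, p1 < 1, p2 < 1,
            p12 <= p1, p12 <= p2)
  structure(list(p1 = p1, p2 = p2, p12 = p12), class = "coloc_priors")
}

#' Log approximate Bayes factor from an effect estimate
#'
#' @param beta effect size.
#' @param se its standard error (> 0).
#' @param w prior effect-size variance (sd^2, > 0).
#' @return natural-log ABF (vectorized).
#' @export
labf_from_beta_se <- function(beta, se, w) {
  if (any(se <= 0)) stop("se must be positive")
  if (any(w <= 0)) stop("prior variance w must be positive")
  v <- se^2
  z2 <- (beta / se)^2
  r <- w / (w + v)
  0.5 * (log1p(-r) + r * z2)
}

#' Log approximate Bayes factor from (p, MAF, N)
#'
#' The direction-blind route used when effect estimates are unavailable:
#' z is recovered from the two-sided p-value and the sampling variance V is
#' approximated from allele frequency and sample size.  p-values below
#' 1e-300 are clipped there with a warning.
#'
#' @param p two-sided p-value in (0, 1].
#' @param maf minor allele frequency in (0, 0.5].
#' @param n sample size (>= 2).
#' @param trait_type "quantitative" or "case-control".
#' @param case_fraction case fraction s in (0,1), required for case-control.
#' @param w prior effect-size variance; default sd^2 with sd 0.15
#'   (quantitative) or 0.2 (case-control).
#' @return natural-log ABF (vectorized).
#' @export
labf_from_p <- function(p, maf, n,
                        trait_type = c("quantitative", "case-control"),
                        case_fraction = NULL, w = NULL) {
  trait_type <- match.arg(trait_type)
  stopifnot(all(p > 0 & p <= 1), all(maf > 0 & maf <= 0.5), all(n >= 2))
  if (is.null(w))
    w <- if (trait_type == "quantitative") PRIOR_SD_QUANTITATIVE^2
         else PRIOR_SD_CASE_CONTROL^2
  if (any(p < P_CLIP_MIN)) {
    warning("p-value(s) below 1e-300 clipped", call. = FALSE)
    p <- pmax(p, P_CLIP_MIN)
  }
  z <- stats::qnorm(p / 2, lower.tail = FALSE)
  v <- 1 / (2 * n * maf * (1 - maf))
  if (trait_type == "case-control") {
    if (is.null(case_fraction) || case_fraction <= 0 || case_fraction >= 1)
      stop("case-control route requires case_fraction in (0,1)")
    v <- v / (case_fraction * (1 - case_fraction))
  }
  r <- w / (w + v)
  0.5 * (log1p(-r) + r * z^2)
}

#' @keywords internal
.logsumexp <- function(x) {
  if (length(x) == 0) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' @keywords internal
.logsum_offdiag <- function(l1, l2) {
  # logsumexp over all pairs i != j of l1[i] + l2[j], exact in O(n^2)
  n <- length(l1)
  s <- outer(l1, l2, "+")
  diag(s) <- -Inf
  .logsumexp(as.numeric(s))
}

#' Posterior probabilities of the five colocalization hypotheses
#'
#' Enumerates causal configurations in log space.  With S1 = logsumexp(l1),
#' S2 = logsumexp(l2) and S12 = logsumexp(l1 + l2), the unnormalized log
#' weights are H0 = 0, H1 = log p1 + S1, H2 = log p2 + S2,
#' H3 = log p1 + log p2 + log(exp(S1 + S2) - exp(S12)) (the i != j sum,
#' computed stably), H4 = log p12 + S12; posteriors are their softmax.  For
#' a single SNP there is no i != j configuration and H3 has zero weight.
#'
#' @param l1,l2 aligned numeric vectors of per-SNP log ABFs for the two
#'   traits (same variants, same order).
#' @param priors a [coloc_priors()].
#' @return A `coloc_result` list: pp0..pp4, n_snps, priors, pp4_pp3
#'   (Inf when pp3 underflows to 0), label (see [interpret_coloc()]).
#' @export
coloc_posteriors <- function(l1, l2, priors = coloc_priors()) {
  if (length(l1) != length(l2))
    stop("ABF vectors must be aligned on the same variants")
  n <- length(l1)
  if (n < 1) stop("at least one SNP required")
  if (any(!is.finite(l1)) || any(!is.finite(l2)))
    stop("non-finite log ABF values")
  s1 <- .logsumexp(l1)
  s2 <- .logsumexp(l2)
  s12 <- .logsumexp(l1 + l2)
  h0 <- 0
  h1 <- log(priors$p1) + s1
  h2 <- log(priors$p2) + s2
  d <- s1 + s2
  if (n == 1) {
    # single SNP: no i != j configuration exists
    h3 <- -Inf
  } else if (d - s12 > 1e-3) {
    # well-conditioned: subtract the diagonal mass in log space
    h3 <- log(priors$p1) + log(priors$p2) + d + log1p(-exp(s12 - d))
  } else {
    # exp(d) and exp(s12) nearly cancel (one SNP dominates both traits);
    # sum the i != j terms directly so PP3 stays finite and accurate
    h3 <- log(priors$p1) + log(priors$p2) + .logsum_offdiag(l1, l2)
  }
  h4 <- log(priors$p12) + s12
  lw <- c(h0, h1, h2, h3, h4)
  pp <- exp(lw - .logsumexp(lw))
  pp <- pp / sum(pp)
  res <- structure(list(pp0 = pp[1], pp1 = pp[2], pp2 = pp[3],
                        pp3 = pp[4], pp4 = pp[5], n_snps = n,
                        priors = priors,
                        pp4_pp3 = if (pp[4] == 0) Inf else pp[5] / pp[4],
                        label = NA_character_),
                   class = "coloc_result")
  res$label <- interpret_coloc(res)
  res
}

#' Interpret a colocalization result
#'
#' Maps PP4 to the interpretive bands: above 0.900 a single shared causal
#' variant; 0.700 to 0.900 likely; 0.300 to 0.700 limited evidence; below
#' 0.300 no support.  The PP4/PP3 ratio appends a qualifier: at least 5.00
#' indicates further support for colocalization, at least 3.00 likely
#' colocalization.
#'
#' @param result a `coloc_result`.
#' @return character label.
#' @export
interpret_coloc <- function(result) {
  pp4 <- result$pp4
  base <- if (pp4 > 0.900) "single shared causal variant"
  else if (pp4 > 0.700) "likely single shared causal variant"
  else if (pp4 >= 0.300) "limited evidence"
  else "no colocalization support"
  ratio <- result$pp4_pp3
  qual <- if (is.infinite(ratio) || ratio >= 5.00) "further support"
  else if (ratio >= 3.00) "likely colocalization"
  else NA_character_
  if (is.na(qual)) base else paste0(base, " (", qual, ")")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("coloc over %d SNPs: PP0=%.3f PP1=%.3f PP2=%.3f PP3=%.3f PP4=%.3f\n",
              x$n_snps, x$pp0, x$pp1, x$pp2, x$pp3, x$pp4))
  cat(sprintf("PP4/PP3 = %.3g; %s\n", x$pp4_pp3, x$label))
  invisible(x)
}

#' @keywords internal
.table_labf <- function(p, beta, se, n, maf, trait_type, case_fraction, w,
                        route = c("auto", "beta-se", "p-maf-n")) {
  route <- match.arg(route)
  if (route == "auto")
    route <- if (all(!is.na(beta)) && all(!is.na(se)) && all(se > 0))
      "beta-se" else "p-maf-n"
  if (route == "beta-se") {
    ok <- !is.na(beta) & !is.na(se) & se > 0
    labf <- rep(NA_real_, length(p))
    labf[ok] <- labf_from_beta_se(beta[ok], se[ok], w)
  } else {
    ok <- !is.na(p) & !is.na(maf) & !is.na(n)
    labf <- rep(NA_real_, length(p))
    if (any(ok))
      labf[ok] <- labf_from_p(p[ok], maf[ok], n[ok], trait_type,
                              case_fraction, w)
  }
  list(labf = labf, ok = ok, route = route)
}

#' Colocalization of two traits in a locus window
#'
#' Convenience pipeline: restrict both tables to the window, harmonize onto
#' shared variants, compute per-trait log ABFs (route chosen from available
#' fields: (beta, se) when complete, else (p, MAF, N)), and run
#' [coloc_posteriors()].  Records lacking the fields its route needs are
#' excluded with a message.
#'
#' @param a,b `sumstat_table`s for the two traits.
#' @param window a [locus_window()].
#' @param priors a [coloc_priors()].
#' @param w1,w2 prior effect-size variances per trait; defaults follow each
#'   table's trait type (sd 0.15 quantitative, 0.2 case-control).
#' @param route "auto", "beta-se" or "p-maf-n", applied to both traits.
#' @return A `coloc_result`, or NULL (with a message) when no shared SNP
#'   with usable fields remains in the window.
#' @export
coloc_region <- function(a, b, window, priors = coloc_priors(),
                         w1 = NULL, w2 = NULL, route = "auto") {
  wa <- extract_window(a, window)
  wb <- extract_window(b, window)
  pair <- harmonize_pair(wa, wb)
  if (nrow(pair) == 0) {
    message("no shared variants in window; colocalization undefined")
    return(NULL)
  }
  default_w <- function(t) {
    if (attr(t, "trait_type") == "case-control") PRIOR_SD_CASE_CONTROL^2
    else PRIOR_SD_QUANTITATIVE^2
  }
  if (is.null(w1)) w1 <- default_w(a)
  if (is.null(w2)) w2 <- default_w(b)
  la <- .table_labf(pair$p_a, pair$beta_a, pair$se_a, pair$n_a, pair$maf_a,
                    attr(a, "trait_type"), attr(a, "case_fraction"), w1,
                    route)
  lb <- .table_labf(pair$p_b, pair$beta_b, pair$se_b, pair$n_b, pair$maf_b,
                    attr(b, "trait_type"), attr(b, "case_fraction"), w2,
                    route)
  ok <- la$ok & lb$ok
  if (sum(!ok) > 0)
    message(sum(!ok), " shared variant(s) lacked fields for the ABF route ",
            "and were excluded")
  if (!any(ok)) {
    message("no usable shared variants in window; colocalization undefined")
    return(NULL)
  }
  res <- coloc_posteriors(la$labf[ok], lb$labf[ok], priors)
  res$routes <- c(trait1 = la$route, trait2 = lb$route)
  res$snps <- pair$rsid[ok]
  res
}
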