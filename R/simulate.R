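# Synthetic data with known ground truth: LD-structured genotype panels,
# GWAS summary statistics under the five colocalization scenarios H0-H4,
# and single-cell count matrices with donor structure and planted disease
# fold changes.
#
# Haplotypes come from a stationary latent Gaussian AR(1) process
# thresholded per SNP to hit its target allele frequency; genotypes are the
# sum of two independent haplotypes.  This gives direct control over the LD
# decay (adjacent-SNP latent correlation ld_rho) at desk-scale speed;
# colocalization behavior depends only on LD structure and effect
# placement, not on genealogy.

#' Specification of a synthetic genotype panel
#'
#' @param n_individuals number of diploid samples.
#' @param n_snps number of variants.
#' @param maf_range length-2 numeric in (0, 0.5]: target allele frequencies
#'   are drawn uniformly in this range.
#' @param ld_rho latent AR(1) correlation between adjacent SNPs in [0, 1).
#' @param chrom chromosome label.
#' @param start_pos position of the first SNP.
#' @param spacing bases between adjacent SNPs.
#' @param seed integer seed; the panel is deterministic given the spec.
#' @return A `panel_spec` list.
#' @export
panel_spec <- function(n_individuals = 1000, n_snps = 300,
                       maf_range = c(0.05, 0.5), ld_rho = 0.95,
                       chrom = "1", start_pos = 1000000L, spacing = 2000L,
                       seed = 1L) {
  stopifnot(n_individuals >= 2, n_snps >= 1,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            ld_rho >= 0, ld_rho < 1, spacing >= 1)
  structure(list(n_individuals = n_individuals, n_snps = n_snps,
                 maf_range = maf_range, ld_rho = ld_rho, chrom = chrom,
                 start_pos = as.integer(start_pos),
                 spacing = as.integer(spacing), seed = as.integer(seed)),
            class = "panel_spec")
}

#' @keywords internal
.sim_haplotypes <- function(n_hap, spec, freqs) {
  # latent Gaussian AR(1) across SNPs, thresholded per SNP at qnorm(1-f)
  z <- matrix(0, n_hap, spec$n_snps)
  z[, 1] <- stats::rnorm(n_hap)
  if (spec$n_snps > 1) {
    rho <- spec$ld_rho
    innov_sd <- sqrt(1 - rho^2)
    for (j in 2:spec$n_snps)
      z[, j] <- rho * z[, j - 1] + innov_sd * stats::rnorm(n_hap)
  }
  thr <- stats::qnorm(1 - freqs)
  # TRUE where the haplotype carries the alternate allele
  sweep(z, 2, thr, ">") + 0
}

#' @keywords internal
.sim_genotypes <- function(n_ind, spec, freqs) {
  .sim_haplotypes(n_ind, spec, freqs) + .sim_haplotypes(n_ind, spec, freqs)
}

#' Simulate an LD-structured genotype panel
#'
#' @param spec a [panel_spec()].
#' @return A [genotype_panel()] carrying its spec and the target allele
#'   frequencies as attributes, so that GWAS cohorts of any size can later
#'   be drawn from the same generative process.
#' @export
simulate_panel <- function(spec = panel_spec()) {
  set.seed(spec$seed)
  freqs <- stats::runif(spec$n_snps, spec$maf_range[1], spec$maf_range[2])
  g <- .sim_genotypes(spec$n_individuals, spec, freqs)
  variants <- data.frame(
    rsid = sprintf("snp%04d", seq_len(spec$n_snps)),
    chrom = spec$chrom,
    pos = spec$start_pos + (seq_len(spec$n_snps) - 1L) * spec$spacing,
    stringsAsFactors = FALSE)
  panel <- genotype_panel(g, variants)
  attr(panel, "spec") <- spec
  attr(panel, "target_freqs") <- freqs
  panel
}

#' Simulate GWAS summary statistics on a panel's LD structure
#'
#' Draws a fresh cohort of `n` individuals from the panel's generative
#' process (so the GWAS sample size is decoupled from the LD reference
#' size).  Quantitative traits: phenotype = sum of causal dosage effects +
#' standard normal noise; per-SNP marginal OLS gives beta, se and p.
#' Case-control traits: a liability threshold at prevalence
#' `case_fraction` assigns case status; per-SNP score test of the 2x2
#' genotype-by-status association gives z, with beta = U/V and
#' se = 1/sqrt(V) from the score statistic.  Cohort MAF and n are attached
#' per record.
#'
#' @param panel a [simulate_panel()] result.
#' @param causal_idx integer indices of causal SNPs (may be empty).
#' @param betas per-causal-SNP effect sizes on the trait / liability scale.
#' @param n cohort size.
#' @param trait_type "quantitative" or "case-control".
#' @param case_fraction target case fraction for case-control traits.
#' @param seed integer seed.
#' @param trait_label label stored on the table.
#' @return A `sumstat_table`.
#' @export
simulate_gwas <- function(panel, causal_idx = integer(0), betas = numeric(0),
                          n = 10000,
                          trait_type = c("quantitative", "case-control"),
                          case_fraction = 0.5, seed = 1L,
                          trait_label = "sim_trait") {
  trait_type <- match.arg(trait_type)
  stopifnot(length(causal_idx) == length(betas))
  spec <- attr(panel, "spec")
  freqs <- attr(panel, "target_freqs")
  if (is.null(spec)) stop("panel must come from simulate_panel()")
  set.seed(seed)
  g <- .sim_genotypes(n, spec, freqs)
  genetic <- if (length(causal_idx))
    g[, causal_idx, drop = FALSE] %*% betas else rep(0, n)
  if (trait_type == "quantitative") {
    y <- as.numeric(genetic) + stats::rnorm(n)
    # vectorized per-SNP marginal OLS
    gc <- sweep(g, 2, colMeans(g))
    yc <- y - mean(y)
    sxx <- colSums(gc^2)
    sxy <- as.numeric(crossprod(gc, yc))
    beta <- sxy / sxx
    rss <- sum(yc^2) - beta * sxy
    sigma2 <- rss / (n - 2)
    se <- sqrt(sigma2 / sxx)
    tstat <- beta / se
    p <- 2 * stats::pt(-abs(tstat), n - 2)
  } else {
    liab <- as.numeric(genetic) +
      stats::rnorm(n, sd = sqrt(max(1 - sum(betas^2 * 2 * freqs[causal_idx] *
                                              (1 - freqs[causal_idx])), 0.01)))
    thr <- stats::quantile(liab, 1 - case_fraction)
    ycc <- as.numeric(liab > thr)
    ybar <- mean(ycc)
    gc <- sweep(g, 2, colMeans(g))
    u <- as.numeric(crossprod(gc, ycc - ybar))
    vv <- ybar * (1 - ybar) * colSums(gc^2)
    z <- u / sqrt(vv)
    beta <- u / vv
    se <- 1 / sqrt(vv)
    p <- 2 * stats::pnorm(-abs(z))
  }
  p <- pmax(p, P_CLIP_MIN)
  freq <- colMeans(g) / 2
  df <- data.frame(rsid = panel$variants$rsid, chrom = panel$variants$chrom,
                   pos = panel$variants$pos,
                   effect_allele = "A", other_allele = "G",
                   beta = beta, se = se, p = p, n = n,
                   maf = pmin(pmax(pmin(freq, 1 - freq), 1e-4), 0.5),
                   stringsAsFactors = FALSE)
  out <- sumstat_table(df, trait_type = trait_type,
                       case_fraction = if (trait_type == "case-control")
                         case_fraction else NULL,
                       trait_label = trait_label)
  attr(out, "causal_idx") <- causal_idx
  attr(out, "causal_betas") <- betas
  out
}

#' @keywords internal
.beta_for_h2 <- function(h2, freq) {
  # effect explaining h2 of unit trait variance at allele frequency freq
  sqrt(h2 / (2 * freq * (1 - freq)))
}

#' Specification of a two-trait colocalization scenario
#'
#' @param hypothesis "H0" (neither trait associated), "H1"/"H2" (one trait
#'   only), "H3" (distinct causal variants in near-linkage-equilibrium) or
#'   "H4" (one shared causal variant).
#' @param causal1,causal2 panel indices of the causal SNP for trait 1 / 2
#'   (used per hypothesis; equal for H4, distinct for H3).
#' @param h2_1,h2_2 fraction of trait variance explained by the causal SNP
#'   (in (0, 0.5)).
#' @param n1,n2 GWAS sample sizes for the two traits.
#' @param trait_types,case_fractions per-trait types / case fractions.
#' @param seed integer seed.
#' @return A `scenario_spec` list.
#' @export
scenario_spec <- function(hypothesis = c("H4", "H0", "H1", "H2", "H3"),
                          causal1 = 150L, causal2 = 150L,
                          h2_1 = 0.02, h2_2 = 0.02,
                          n1 = 20000, n2 = 5000,
                          trait_types = c("quantitative", "quantitative"),
                          case_fractions = c(0.5, 0.5), seed = 1L) {
  hypothesis <- match.arg(hypothesis)
  stopifnot(h2_1 > 0, h2_1 < 0.5, h2_2 > 0, h2_2 < 0.5)
  if (hypothesis == "H4" && causal1 != causal2)
    stop("H4 requires a shared causal SNP (causal1 == causal2)")
  if (hypothesis == "H3" && causal1 == causal2)
    stop("H3 requires distinct causal SNPs")
  structure(list(hypothesis = hypothesis, causal1 = as.integer(causal1),
                 causal2 = as.integer(causal2), h2_1 = h2_1, h2_2 = h2_2,
                 n1 = n1, n2 = n2, trait_types = trait_types,
                 case_fractions = case_fractions, seed = as.integer(seed)),
            class = "scenario_spec")
}

#' Simulate a pair of trait summary statistics under a scenario
#'
#' Both traits are simulated on the same panel's LD structure.  For H3 the
#' causal pair must be in near-linkage-equilibrium (panel r-squared below
#' `h3_max_r2`), which is verified before simulating.
#'
#' @param panel a [simulate_panel()] result.
#' @param spec a [scenario_spec()].
#' @param h3_max_r2 maximum panel r-squared tolerated between the H3 causal
#'   pair (default 0.01).
#' @return list with elements trait1, trait2 (`sumstat_table`s) and truth
#'   (the spec).
#' @export
simulate_scenario <- function(panel, spec = scenario_spec(),
                              h3_max_r2 = 0.01) {
  hyp <- spec$hypothesis
  if (hyp == "H3") {
    r2 <- ld_r2(panel, spec$causal1, spec$causal2)$r2
    if (r2 >= h3_max_r2)
      stop(sprintf(
        "H3 causal pair has panel r2 = %.3g >= %.3g; pick a low-LD pair",
        r2, h3_max_r2))
  }
  freqs <- attr(panel, "target_freqs")
  c1 <- if (hyp %in% c("H1", "H3", "H4")) spec$causal1 else integer(0)
  c2 <- if (hyp %in% c("H2", "H3", "H4"))
    (if (hyp == "H4") spec$causal1 else spec$causal2) else integer(0)
  b1 <- if (length(c1)) .beta_for_h2(spec$h2_1, freqs[c1]) else numeric(0)
  b2 <- if (length(c2)) .beta_for_h2(spec$h2_2, freqs[c2]) else numeric(0)
  t1 <- simulate_gwas(panel, c1, b1, spec$n1, spec$trait_types[1],
                      spec$case_fractions[1], seed = spec$seed * 2L + 1L,
                      trait_label = "trait1")
  t2 <- simulate_gwas(panel, c2, b2, spec$n2, spec$trait_types[2],
                      spec$case_fractions[2], seed = spec$seed * 2L + 2L,
                      trait_label = "trait2")
  list(trait1 = t1, trait2 = t2, truth = spec)
}

#' Specification of a synthetic single-cell experiment
#'
#' @param n_donors_per_condition donors in each of disease and control.
#' @param cell_types named list: cell type -> length-2 integer range of
#'   cells per donor.
#' @param n_genes number of genes.
#' @param base_mean_meanlog,base_mean_sdlog log-normal parameters for
#'   per-gene base means.
#' @param dispersion NB dispersion (Var = mu + dispersion * mu^2) at the
#'   cell level.
#' @param donor_sd donor random-effect standard deviation on the log scale.
#' @param de_genes named numeric vector: gene index -> planted log2 fold
#'   change (disease vs control); names are coerced to integer indices.
#' @param de_base_mean base mean forced on planted genes (NULL keeps their
#'   drawn means).
#' @param seed integer seed.
#' @return An `sc_sim_spec` list.
#' @export
sc_sim_spec <- function(n_donors_per_condition = 8,
                        cell_types = list(typeA = c(20L, 60L),
                                          typeB = c(20L, 60L)),
                        n_genes = 1000,
                        base_mean_meanlog = 0.5, base_mean_sdlog = 1,
                        dispersion = 0.1, donor_sd = 0.15,
                        de_genes = numeric(0), de_base_mean = 50,
                        seed = 1L) {
  stopifnot(dispersion > 0, donor_sd >= 0, n_donors_per_condition >= 1)
  structure(list(n_donors_per_condition = n_donors_per_condition,
                 cell_types = cell_types, n_genes = n_genes,
                 base_mean_meanlog = base_mean_meanlog,
                 base_mean_sdlog = base_mean_sdlog,
                 dispersion = dispersion, donor_sd = donor_sd,
                 de_genes = de_genes, de_base_mean = de_base_mean,
                 seed = as.integer(seed)),
            class = "sc_sim_spec")
}

#' Simulate single-cell counts with donor structure and planted DE
#'
#' Per cell, counts are negative-binomial with mean
#' `base_mean * donor_effect * fold_change^(condition is disease)` and the
#' spec's dispersion; donor effects are log-normal with sd `donor_sd`.
#' Planted fold changes apply only to the genes named in `de_genes`.
#'
#' @param spec an [sc_sim_spec()].
#' @return A [cell_counts()]; the planted truth (gene indices and log2 fold
#'   changes) is attached as attribute "truth".
#' @export
simulate_sc_counts <- function(spec = sc_sim_spec()) {
  set.seed(spec$seed)
  base_mean <- stats::rlnorm(spec$n_genes, spec$base_mean_meanlog,
                             spec$base_mean_sdlog)
  de_idx <- as.integer(names(spec$de_genes))
  l2fc <- rep(0, spec$n_genes)
  if (length(de_idx)) {
    l2fc[de_idx] <- as.numeric(spec$de_genes)
    if (!is.null(spec$de_base_mean)) base_mean[de_idx] <- spec$de_base_mean
  }
  fc <- 2^l2fc
  donors <- c(paste0("D", seq_len(spec$n_donors_per_condition), "_dis"),
              paste0("D", seq_len(spec$n_donors_per_condition), "_con"))
  conditions <- rep(c("disease", "control"),
                    each = spec$n_donors_per_condition)
  donor_mult <- exp(stats::rnorm(length(donors), 0, spec$donor_sd))
  size <- 1 / spec$dispersion
  blocks <- list(); metas <- list(); k <- 0
  for (d in seq_along(donors)) {
    for (ct in names(spec$cell_types)) {
      rng <- spec$cell_types[[ct]]
      n_cells <- sample(rng[1]:rng[2], 1)
      mu <- base_mean * donor_mult[d]
      if (conditions[d] == "disease") mu <- mu * fc
      cnt <- matrix(stats::rnbinom(n_cells * spec$n_genes, size = size,
                                   mu = rep(mu, each = n_cells)),
                    nrow = n_cells)
      k <- k + 1
      blocks[[k]] <- cnt
      metas[[k]] <- data.frame(
        barcode = sprintf("%s_%s_c%04d", donors[d], ct, seq_len(n_cells)),
        donor_id = donors[d], cell_type = ct, condition = conditions[d],
        stringsAsFactors = FALSE)
    }
  }
  counts <- do.call(rbind, blocks)
  meta <- do.call(rbind, metas)
  out <- cell_counts(counts, meta,
                     sprintf("gene%04d", seq_len(spec$n_genes)))
  attr(out, "truth") <- list(de_idx = de_idx, log2fc = l2fc,
                             base_mean = base_mean)
  out
}

#' Write a complete demo dataset
#'
#' Emits the same text formats the I/O functions consume: a dosage panel,
#' two harmonizable summary-statistics tables under an H4 scenario, and a
#' small single-cell MTX dataset with planted fold changes.
#'
#' @param dir output directory.
#' @param seed integer seed.
#' @return the directory, invisibly.
#' @export
write_demo_fixtures <- function(dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  panel <- simulate_panel(panel_spec(n_individuals = 200, n_snps = 60,
                                     seed = seed))
  write_panel_tsv(panel, file.path(dir, "panel_dosages.tsv"),
                  file.path(dir, "panel_variants.tsv"))
  sc <- simulate_scenario(panel, scenario_spec(
    hypothesis = "H4", causal1 = 30L, causal2 = 30L,
    n1 = 5000, n2 = 2000, seed = seed))
  write_sumstats(sc$trait1, file.path(dir, "trait1_sumstats.tsv"))
  write_sumstats(sc$trait2, file.path(dir, "trait2_sumstats.tsv"))
  m <- simulate_sc_counts(sc_sim_spec(
    n_donors_per_condition = 3,
    cell_types = list(typeA = c(15L, 25L)), n_genes = 250,
    de_genes = stats::setNames(c(1, -1), c(5, 10)), seed = seed))
  write_sc_counts(m, file.path(dir, "sc"))
  invisible(dir)
}
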