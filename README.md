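# pleiocoloc

Integration analysis for pairs of GWAS traits and molecular QTLs: find
pleiotropic loci shared between two traits, test whether a GWAS signal and
a QTL signal are driven by the same causal variant, nominate candidate
causal genes through LD proxies, and quantify how those genes' expression
changes in diseased tissue from single-cell data.

It is written for statistical geneticists who have summary statistics
(variant, alleles, beta/se or p, N, MAF), a genotype reference panel for
LD, QTL catalogs, and annotated single-cell counts — and who want each
stage of the GWAS-to-gene-to-tissue chain as a tested, scriptable function
rather than a chain of web services.

## The statistics at the core

**Overlap enrichment.** Each trait's genome-wide-significant hits
(p ≤ 5×10⁻⁸) are LD-clumped to independent leads; leads are matched across
traits by panel r². With n₁, n₂ leads, n_s shared, and M_e effective
independent SNPs in the LD population, expected overlap = n₁n₂/M_e, fold
enrichment = n_s / expected, and significance is a one-sided Fisher exact
test over the M_e universe, BH-adjusted across trait pairs.

**Colocalization.** Per-SNP approximate Bayes factors under a normal
effect prior N(0, W):

    log ABF = ½ [ log(1 − r) + r z² ],   r = W / (W + V)

computed from (beta, se) or, when only p-values are published, from
(p, MAF, N) with V = 1/(2Nf(1−f)) (÷ s(1−s) for case-control with case
fraction s). Posterior probabilities PP0–PP4 of the five hypotheses (no
association / trait 1 only / trait 2 only / distinct causal variants /
one shared causal variant) come from log-space enumeration under priors
p1 = p2 = 10⁻⁴, p12 = 10⁻⁵. PP4 > 0.900 is interpreted as a single shared
causal variant, 0.700–0.900 likely, 0.300–0.700 limited evidence; the
PP4/PP3 ratio ≥ 5.00 marks further support, ≥ 3.00 likely colocalization.

**eGene nomination.** Conditionally independent QTL catalog entries whose
variant is the query SNP or an LD proxy (r² > 0.50) yield one candidate
per (gene, context), keeping the best proxy.

**Pseudobulk DE.** Cells with < 500 counts, then cell-type clusters with
< 10 cells, are removed; counts are summed per donor × cell type, and per
gene a fixed-dispersion negative-binomial GLM with median-of-ratios size
factors gives a Wald test of disease vs control, BH-adjusted within cell
type (\* p_adj < 0.05, \*\* < 0.001, \*\*\* < 0.0001).

A synthetic-data module generates all inputs with known truth:
AR(1)-latent LD panels, GWAS cohorts under scenarios H0–H4, and
single-cell counts with donor effects and planted fold changes.

## Worked example

```r
library(pleiocoloc)

dir <- file.path(tempdir(), "demo")
write_demo_fixtures(dir, seed = 1)   # panel + H4 trait pair + sc counts

panel <- read_panel_tsv(file.path(dir, "panel_dosages.tsv"),
                        file.path(dir, "panel_variants.tsv"))
t1 <- read_sumstats(file.path(dir, "trait1_sumstats.tsv"))
t2 <- read_sumstats(file.path(dir, "trait2_sumstats.tsv"))

# colocalization at the planted locus (SNP 30 of the demo panel)
w <- locus_window("1", panel$variants$pos[30], 500000)
coloc_region(t1, t2, w)
#> coloc over 60 SNPs: PP0=0.000 PP1=0.000 PP2=0.000 PP3=0.000 PP4=1.000
#> PP4/PP3 = 1.2e+09; single shared causal variant (further support)

# pairwise overlap report (Me supplied per LD population)
trait_pair_overlap(t1, t2, panel, me = 10000)$report
#>   n1_pcut n2_pcut Nshare_all N_expected fold     p
#> 1       4       1          1      4e-04 2500 4e-04

# LD proxies of the lead SNP
head(find_proxies(panel, 30, r2_min = 0.5), 3)
#>      rsid chrom     pos        r2 distance
#> 1 snp0028     1 1054000 0.5272907     4000
```

The demo scenario plants one variant causal for both traits, so the
posterior concentrates on H4 (PP4 ≈ 1) and the shared lead is recovered in
the overlap report: 4 independent leads for the larger study, 1 for the
smaller, 1 shared against an expectation of 4×10⁻⁴ under M_e = 10,000 —
a 2,500-fold enrichment.

The `run_overlap()` / `run_coloc()` / `run_de()` functions drive the same
stages from a single YAML configuration and write TSV reports plus a run
manifest; `vignettes/colocalization-methods.Rmd` documents the models,
priors, thresholds and design decisions.

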