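---
title: "Methods: pleiotropy, colocalization and pseudobulk differential expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pleiotropy, colocalization and pseudobulk differential expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pleiocoloc)
```

# Scope

`pleiocoloc` integrates GWAS and molecular QTL (eQTL/mQTL) summary
statistics to answer four linked questions: do two traits share more
genome-wide-significant loci than chance predicts; is a shared association
signal driven by one causal variant; which genes does that variant
plausibly regulate; and how does the nominated gene's expression change in
diseased tissue at single-cell resolution.  Everything runs from delimited
text inputs (summary statistics, dosage panels, MatrixMarket counts), and a
synthetic-data generator reproduces the structure of each input with known
ground truth so the whole pipeline is testable offline.

# Cross-phenotype overlap

Each trait's hits at the genome-wide threshold ($p \le 5\times10^{-8}$) are
reduced to independent lead SNPs by greedy LD clumping: repeatedly take the
smallest-$p$ remaining hit and remove hits with panel $r^2$ at or above
`clump_r2` to it.  Leads from the two traits are matched one-to-one,
greedily by descending $r^2$, counting a pair as shared when the leads
coincide or have $r^2 \ge$ `share_r2`.  With $n_1$, $n_2$ independent
leads, $n_s$ shared, and $M_e$ the effective number of independent SNPs in
the LD population, the expected overlap is $n_1 n_2 / M_e$ and the fold
enrichment is $n_s$ divided by that expectation.  Significance comes from a
one-sided Fisher exact test on the $2\times2$ table over the $M_e$
universe; this reduces to the expected-count arithmetic in the mean and is
the documented test of the cross-phenotype tool the arithmetic mirrors.
$M_e$ is a required configuration scalar (population-specific, taken from
published effective-SNP-count tables), not something the package estimates.
`clump_r2` and `share_r2` default to 0.4; no published value fixes them, so
they are surfaced in the configuration and logged rather than hidden.

# Colocalization model

At a locus, each SNP's evidence for association with one trait is a
Wakefield-style approximate Bayes factor under a normal effect prior
$N(0, W)$: with $V$ the squared standard error and $z$ the Wald ratio,

$$\log \mathrm{ABF} = \tfrac12\left[\log(1 - r) + r z^2\right],
\qquad r = \frac{W}{W+V}.$$

When a dataset publishes only $p$-values, $z$ is recovered from the
two-sided $p$ and $V$ is approximated from allele frequency $f$ and sample
size $N$: $V = 1/(2Nf(1-f))$ for a quantitative trait, divided additionally
by $s(1-s)$ for a case-control trait with case fraction $s$.  This route is
direction-blind (the sign of the effect is lost), which is acceptable
because the posterior depends on $z^2$ only.  $p$-values below $10^{-300}$
are clipped there to avoid infinite quantiles; the trait standard deviation
is fixed at 1 because $p$-value inputs cannot estimate it (logged as an
assumption).  The prior effect standard deviation defaults to 0.15 in
trait-SD units for quantitative traits and 0.2 on the log-odds scale for
case-control traits, both configurable ($W$ = sd$^2$).

The five hypotheses — no association (H0), trait 1 only (H1), trait 2 only
(H2), two distinct causal variants (H3), one shared causal variant (H4) —
get posterior probabilities by enumerating single-causal-variant
configurations with per-SNP priors $p_1 = p_2 = 10^{-4}$ and
$p_{12} = 10^{-5}$ (the conventional defaults).  All sums run in log space:
with $S_1$, $S_2$, $S_{12}$ the logsumexp of the per-SNP log-ABFs for trait
1, trait 2 and their elementwise sum, the unnormalized log weights are $0$,
$\log p_1 + S_1$, $\log p_2 + S_2$,
$\log p_1 p_2 + \log\!\big(e^{S_1+S_2} - e^{S_{12}}\big)$ and
$\log p_{12} + S_{12}$, and the posteriors are their softmax.

**Numerical choices.**  The H3 weight subtracts the diagonal ($i = j$) mass
from the full cross product.  When one SNP dominates both traits — exactly
the strong-H4 regime — $S_1 + S_2$ and $S_{12}$ agree to near machine
precision and the subtraction cancels catastrophically.  Rather than
flooring PP3 at zero (which makes the PP4/PP3 support ratio infinite), the
engine switches to an exact $O(n^2)$ logsumexp over the $i \ne j$
configurations whenever $S_1 + S_2 - S_{12} \le 10^{-3}$; the fast
`log1p`-based subtraction is used otherwise.  PP3 therefore stays finite
and accurate down to its true magnitude, and the ratio is reported as a
number.  A single-SNP locus has no $i \ne j$ configuration, so its H3
weight is exactly zero.

**Interpretation.**  PP4 above 0.900 is read as a single shared causal
variant; 0.700–0.900 as likely; 0.300–0.700 as limited evidence; below
0.300 as no colocalization support.  The band wording is ambiguous at its
endpoints, so the implemented bands are contiguous and exhaustive with
0.300 and 0.700 assigned to the middle band.  The PP4/PP3 ratio appends a
qualifier: $\ge 5.00$ further support, $\ge 3.00$ likely colocalization.

Multi-causal-variant colocalization (SuSiE-style), fine-mapping credible
sets and conditional analysis are out of scope: the engine assumes at most
one causal variant per trait per locus, and violations of that assumption
push probability toward H3.

# Locus windows and harmonization

A "1 Mb window" around a variant of interest is implemented as a closed
interval of ±500 kb (total 1 Mb), with the half-width configurable for
users who read the phrase as ±1 Mb.  Positions are 1-based.  Tables are
matched on (chromosome, position, unordered allele set); swapped
effect/other alleles flip the second trait's beta sign.  Palindromic
(A/T, C/G) variants are retained with a warning — the $p$-value ABF route
is magnitude-only, so an unresolved strand flip does not change the
posterior — and a strict mode drops them.

# Candidate eGene nomination

A QTL catalog (one row per variant × feature × context, carrying a
conditionally-independent flag computed upstream) is scanned for entries
whose variant is the query SNP or an LD proxy at $r^2 > 0.50$.  One
candidate is emitted per (feature, context), keeping the maximum-$r^2$
proxy.  LD is composite $r^2$ from unphased dosage correlation with
pairwise-complete missing-data handling; at the thresholds in use (0.50,
0.80, 0.90) the distinction from haplotype-phase $r^2$ is immaterial and
unphased panels remain usable.  The genotype-stratified statistics are
ordinary least squares of the raw measurement on allele count (slope $t$
test, $n-2$ df) and an unpaired Student $t$ test (Welch optional) — raw
because covariate-adjusted residuals are an upstream concern, and the
plotted quantities these tests annotate are unadjusted.

# Pseudobulk differential expression

Cells with fewer than 500 total counts are removed first; cell-type
clusters left with fewer than 10 cells are then dropped entirely.  The
filter order is deliberate: cluster sizes change after low-count cells
leave, and the 10-cell minimum should apply to cells that will actually be
analyzed.  Counts are summed per donor × cell type, and per cell type with
at least 2 donors per condition the model per gene is

$$\log \mu = \log(\mathrm{sf}) + \beta_0 + \beta_1 \cdot
\mathbb{1}[\mathrm{disease}],$$

a negative-binomial GLM with median-of-ratios size factors and per-gene
method-of-moments dispersion $\hat\alpha = \max\{(s^2 - \bar m)/\bar m^2,
10^{-8}\}$ on normalized counts pooled across conditions.  The Wald
statistic $\beta_1/\mathrm{se}$ gets a two-sided normal $p$, BH-adjusted
within cell type; $\log_2$ fold change is $\beta_1/\ln 2$.  Known
deviations from full DESeq2-style pipelines, accepted on purpose: no
dispersion shrinkage across genes, no fold-change shrinkage, no outlier
handling.  Consequently per-gene $p$-values will not reproduce a given
package's output on real data; what the tests establish instead is
calibration (false-positive fraction at adjusted $p < 0.05$ stays near the
nominal level under a global null) and recovery (planted $\log_2$ fold
changes are estimated with small bias).  Pooled-moments dispersion is
conservative for genes with very large true effects, since between-group
signal inflates the variance estimate.  The bulk path filters genes whose
maximum count across samples is below 5 (a sum-based alternative is
selectable) and divides by size factors.  When no gene is expressed in
every sample, size factors fall back to genes nonzero in at least 90% of
samples with geometric means over nonzero entries, with a warning.

# Synthetic data: what it emulates

`simulate_panel()` draws haplotypes from a stationary latent Gaussian
AR(1) process thresholded per SNP at its target allele frequency
(frequencies uniform in `maf_range`, default 0.05–0.5); genotypes are the
sum of two independent haplotypes.  The latent adjacent-SNP correlation
`ld_rho` (default 0.95) gives realistic monotone LD decay without a
coalescent simulation; colocalization behavior depends only on LD structure
and effect placement, not genealogy.  `simulate_gwas()` draws a fresh
cohort from the same process — mimicking the real situation where the LD
reference (here 1,000 individuals) and the GWAS cohort (tens of thousands)
are different samples of one population — builds phenotypes from causal
dosages plus unit normal noise, and reports per-SNP marginal OLS (or a
liability-threshold case-control design with a per-SNP score test).
Scenario presets place causal SNPs for the H0–H4 hypotheses; H3 requires a
causal pair verified to have panel $r^2 < 0.01$.  Effect sizes are
parameterized by variance explained (default 2% per causal SNP, a strong
but realistic single-locus signal; GWAS sample sizes default to 20,000 and
5,000, echoing a large disease GWAS paired with a smaller QTL study).

`simulate_sc_counts()` draws cell-level negative-binomial counts with mean
= gene base mean × donor effect × condition fold change.  Defaults chosen
once as realistic for pseudobulk benchmarking: 8 donors per condition,
20–60 cells per donor per cell type, 1,000 genes with log-normal base
means (meanlog 0.5, sdlog 1, so cells carry roughly 2,000–3,000 total
counts and clear the 500-count filter), cell-level NB dispersion 0.1, and
a log-scale donor random effect of sd 0.15 that induces the within-donor
correlation pseudobulking exists to respect.  Planted genes default to
base mean 50 so fold-change recovery is assessed away from the
low-count floor.

What the generator does *not* emulate: recombination hotspots and realistic
LD block boundaries, allele-frequency/effect-size coupling, ambient RNA,
doublets, batch effects, or cell-type-specific gene programs.  Passing
tests on synthetic data therefore demonstrate the statistical machinery is
correct and calibrated under its stated model, not that any particular
real-data result will reproduce.

# Problem sizes in the tests

The routine suite exercises loci of 60–300 SNPs with panels of 200–1,000
individuals and simulated cohorts up to 20,000; the scenario-recovery
checks use 50 replicates per hypothesis and the DE calibration run uses
1,000 genes at 8+8 donors.  These sizes were chosen so the full suite
completes on a laptop-class single core in a few minutes while keeping
every Monte Carlo margin wide.

# Open design points, resolved

- **Window convention** — "within a 1 Mb window" is read as a 1 Mb total
  span (±500 kb); `half_width` overrides it.
- **Lead matching for overlap** — the published description does not fix
  the LD threshold or matching rule for shared-variant counting; both are
  explicit configuration (`share_r2`, greedy one-to-one by descending
  $r^2$) rather than silently assumed.
- **Equal-variance vs Welch** — "unpaired t-test" defaults to Student's
  equal-variance form; `welch = TRUE` switches.
- **Gene count filter** — "counts less than five" is applied to the
  max-across-samples statistic; a sum-based reading is available.
- **Filter order** — cell-count filter before cluster-size filter, as
  argued above; both thresholds configurable.
- **Curated extra candidates** — literature-derived eGene additions enter
  as a user-supplied list; the package encodes no manual judgment.

# A worked miniature

```{r demo, message = FALSE, warning = FALSE}
dir <- file.path(tempdir(), "pleiocoloc-demo")
write_demo_fixtures(dir, seed = 1)

panel <- read_panel_tsv(file.path(dir, "panel_dosages.tsv"),
                        file.path(dir, "panel_variants.tsv"))
t1 <- read_sumstats(file.path(dir, "trait1_sumstats.tsv"))
t2 <- read_sumstats(file.path(dir, "trait2_sumstats.tsv"))

w <- locus_window("1", panel$variants$pos[30], 500000)
coloc_region(t1, t2, w)
```

The demo scenario plants one SNP causal for both traits, so PP4 dominates
and the label lands in the top interpretive band.
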