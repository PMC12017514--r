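---
title: "Mapping genetic risk through chromatin interactomes: models and methods"
author: "chromrisk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping genetic risk through chromatin interactomes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromrisk)
```

# The problem

Most GWAS risk variants for complex brain disorders are noncoding and often
lie far from the genes they regulate.  Promoter-anchored chromatin
interaction assays (PLAC-seq-style data at 5 kb bin resolution) physically
link distal regulatory elements — enhancers marked by H3K27ac without
promoter-proximal H3K4me3 — to the gene promoters they contact.  chromrisk
implements the analysis chain that exploits such maps:

1. **Loop classification**: label each 5 kb anchor bin against H3K4me3,
   H3K27ac and ATAC peaks and the TSS catalogue, then classify each loop
   into one of eight interaction categories (promoter-to-enhancer,
   promoter-to-promoter, promoter-to-ATAC, promoter-to-promoter/enhancer,
   promoter-to-other, H3K4me3-to-H3K4me3, H3K4me3-to-other, other).
2. **SNP-to-gene annotation**: assign promoter and exonic SNPs to genes by
   position, and intronic/intergenic SNPs that fall in enhancers to the
   genes whose promoters or exons their loops touch.
3. **Gene-level association**: an LD-aware quadratic-form test on the sum
   of squared SNP Z-scores per gene, with Benjamini–Hochberg control.
4. **Partitioned heritability**: stratified LD score regression of per-SNP
   chi-square statistics on annotation-partitioned LD scores, with
   block-jackknife inference and enrichment ratios.
5. **Cell-type and pathway enrichment**: a bootstrap test of expression
   specificity of risk-gene sets, and hypergeometric pathway
   over-representation.

A seeded synthetic-data generator emulates all inputs so the chain is
testable end to end without external downloads.

# Coordinate and labeling conventions

All user-facing tables use BED-style 0-based half-open intervals; 1-based
file dialects are converted at the boundary.  Two intervals overlap when
they share at least one base.  Overlap queries are delegated internally to
GenomicRanges/IRanges, the field-standard interval engine, with conversion
confined to a single helper layer.

A bin is a **promoter** when it overlaps both an H3K4me3 and an H3K27ac
peak and lies within 2,000 bp of a TSS (distance measured from any base of
the bin to the nearest TSS).  A peak is **distal** when its own distance to
every TSS exceeds 2,000 bp; an **enhancer** bin overlaps a distal H3K27ac
peak.  Because a 5 kb bin can contain both a promoter-proximal peak cluster
and a separate distal H3K27ac peak, a bin can satisfy both definitions; the
label precedence is

> promoter/enhancer > promoter > enhancer > H3K4me3-distal > ATAC-only > other,

mirroring the existence of a distinct promoter/enhancer class in such
classifications.  Enhancer–enhancer pairs fall into *other* and
enhancer–H3K4me3 pairs into *H3K4me3-to-other*; the source classifications
do not pin these residual placements down, so the precedence rule above is
the package's explicit choice.

Unordered loop pairs are stored canonically (lexicographically smaller
anchor first).  Duplicate records of the same canonical pair are collapsed
keeping the **minimum** interaction FDR — the most favorable evidence for
the contact; input files in the wild do contain duplicates and no standard
tie rule exists.

# SNP-to-gene annotation (the interactome-aware gene map)

Promoters are defined per isoform as 1,500 bp upstream to 500 bp
downstream of the TSS, strand-aware and clipped at coordinate 0.  Loops are
first filtered to interaction FDR < 0.01 with at least one anchor
overlapping a promoter (active, promoter-anchored contacts).  The four
annotation modes are:

* **full** — positional (promoter/exon containment, multi-gene assignment
  allowed) plus interactional: an intronic or intergenic SNP inside an
  enhancer region and inside a loop anchor bin is assigned to every gene
  whose promoter or exon the partner anchor overlaps.  A SNP already
  assigned positionally is never re-routed through loops.
* **positional_only** — the positional part, by default restricted to SNPs
  lying in filtered-loop anchor bins that overlap a promoter or exon.  The
  alternative reading (all positional SNPs genome-wide) is available via
  `bin_restricted = FALSE`; the restricted reading matches "SNPs
  overlapping interaction bins" most literally.
* **enhancer_only** — the interactional part alone.
* **window10kb** — the proximity baseline: every SNP within 10 kb of a
  gene's exon-union span, no chromatin data.

Gene spans written to the `.genes.annot` output are the min/max over the
positional features that contributed SNPs, falling back to the gene body —
the output format requires a span and this choice covers all assigned
positional SNPs.

Loop downsampling (`downsample_loops`) draws a uniform sample without
replacement, deterministically in its seed; cross-cell-type comparisons use
10 iterations with consecutive seeds, following the practice of equalizing
loop counts (e.g. to 60,000) before comparing gene yields.

# The gene-level test

Under the null, the vector of SNP Z-scores for a gene is approximately
multivariate normal with correlation matrix `R` estimated from a reference
panel.  The test statistic is `T = sum(z_j^2)` ("SNP-wise mean" family; the
sum and the mean differ by the fixed SNP count, so the test is identical).
Its null law is the quadratic form `sum(lambda_i * chi2_1)` with
`lambda_i` the eigenvalues of `R`.

`quadform_pvalue()` evaluates the tail by a Ruben-type mixture-series
expansion: with scale `beta = min(lambda)` the quadratic form is an
infinite mixture of central chi-square distributions with positive weights,
so the truncation error is bounded by the unexpanded weight mass and the
upper tail is accumulated directly (no `1 - cdf` cancellation for small
p).  For identity LD the series terminates at its first term and reproduces
the chi-square survival function exactly.  When the eigenvalue spread makes
the series converge too slowly (more than 10,000 terms), the package falls
back to Imhof's numerical inversion on a finite interval chosen from the
integrand's analytic envelope, and finally to a Satterthwaite–Welch gamma
approximation.  Numerical guards: `R` must be symmetric; if its smallest
eigenvalue is negative a ridge of 1e-6 is added and negative eigenvalues
are truncated at zero (rank-deficient LD, e.g. duplicated SNPs, is thereby
handled); p-values are floored at the smallest positive double.

Benjamini–Hochberg q-values are computed within each run (one trait, one
cell type, one annotation mode), and `significant` flags q < 0.05.
Top-gene sets use plain p thresholds (5e-8; 5e-12 for very well-powered
GWAS, where the milder threshold would return unwieldy set sizes).

# Stratified LD score regression

For SNP `j` and annotation `C`, the LD score is
`l(j,C) = sum_{k in C, |bp_k-bp_j| <= window} r2_adj(j,k)` with the
small-sample correction `r2_adj = r2 - (1-r2)/(n-2)`.  The regression model
is `E[chi2_j] = N * sum_C tau_C * l(j,C) + intercept`, fitted by weighted
least squares over all annotations jointly with `1/max(l(j,base), 1)`
weights — a single-pass proxy for the heteroscedasticity and overcounting
corrections (the reference implementation's iteratively updated weights are
out of scope and documented as such).  Proportion of heritability for `C`
is `sum_{j in C} h2_j / sum_j h2_j` with `h2_j = sum_D a_{jD} tau_D`, and
enrichment is that proportion divided by the proportion of SNPs.  A
delete-one block jackknife over contiguous equal-count SNP blocks (default
200; configurable down for small panels) yields coefficient standard
errors, one-sided coefficient p-values, and enrichment standard errors
(two-sided p against 1).  Reporting follows the field's conventions:
q-values by Benjamini–Hochberg across the run grid, and `-log10(q)` set to
0.0 wherever the coefficient z-score is negative.

**Window choice.**  `compute_ld_scores()` defaults to a 1 Mb window, a
conventional genome-scale choice standing in for the 1 cM genetic-map
window (toy genomes have no genetic map).  For the package's own simulated
study conditions the pipeline and tests use a 50 kb window instead: the
synthetic LD blocks span roughly 16 kb, and with a 500-sample panel every
additional uncorrelated SNP pair inside the window contributes pure
sampling noise to the LD-score regressors.  That noise attenuates the base
coefficient (a classical errors-in-variables effect) and inflates
enrichment ratios by tens of percent.  Matching the window to the panel's
actual LD reach — exactly the logic behind the 1 cM convention — removes
the bias; the tolerance checks in the test suite were only attainable once
the window respected the simulated LD structure.

**Degenerate designs.**  A disjoint exhaustive partition of SNPs makes the
all-ones base column the sum of the parts; `fit_sldsc(weight_ld = ...)`
accepts the weighting LD scores separately so such partitions can be fitted
without the collinear base column.  Collinear annotation sets are rejected
with the offending columns named.

# Cell-type and pathway enrichment

Specificity of gene `g` in cell type `c` is its mean expression in `c`
divided by the sum of its means across cell types (rows sum to 1).  The
bootstrap test scores a target set by summed specificity (equivalent to the
mean for a fixed set size) and resamples sets of the same size — distinct
genes, uniformly from the matrix universe, mirroring how a target list is
constituted — `n_boot` times (default 10,000).  The empirical p-value
`(1 + #(boot >= obs))/(n_boot + 1)` is never zero, and
`z = (obs - mean)/SD` gives the familiar effect scale.  Expression-level
matched sampling (binning the universe by overall expression) is not
applied by default because the reference analyses do not state its use; the
uniform bootstrap is the documented behavior.

Pathway over-representation uses the hypergeometric upper tail
`P(X >= k)` with BH correction at q < 0.05; the ranked-input mode of
gprofiler-style tools is deliberately not reproduced (input order is
accepted and ignored, documented divergence).  Pathways with literally
identical gene sets are collapsed keeping the one with the **highest**
corrected p-value — as printed in the source convention; because that rule
is surprising (one might expect the most significant), the opposite rule is
available via `rule = "lowest_q"`.

# The synthetic-data generator

`sim_config()` fixes the study conditions; all generators are pure
functions of it (per-stage child seeds are derived deterministically from
the root seed, so stages can be rerun independently).

* **Genome** (default 2 chromosomes x 2 Mb, 5 kb bins, 40 genes with 1–3
  isoforms): TSSs sit at bin centers so each TSS's 2 kb proximity zone is
  confined to its own bin; 90% of TSSs carry H3K4me3+H3K27ac (and ATAC)
  peaks; 20% of peak-bearing promoter bins additionally carry an edge
  H3K27ac peak distal to every TSS, realizing the promoter/enhancer class;
  two distal enhancer bins per gene plus H3K4me3-only, ATAC-only and empty
  bins.  Loops are drawn from the enumerated feasible anchor pairs of each
  category (same chromosome, within ~1 Mb), targeting a configurable
  category mix (defaults put promoter-to-enhancer first at 35%, echoing the
  observation that promoter-to-enhancer is the most common class); when a
  category's feasible pairs run short the shortfall moves to categories
  with slack, and a category with no feasible pair at all is a geometry
  error.  85% of loops receive FDR below 0.01 by default.
* **LD panel**: SNPs in blocks of 10 with AR(1) latent correlation
  (`rho = 0.8` within block, independence across blocks).  Dosages are
  continuous, imputed-style values `2*maf + sqrt(2*maf*(1-maf)) * z`, so
  the realized correlation equals the nominal AR(1) value — thresholded
  binary haplotypes would attenuate it.  MAF is uniform on [0.05, 0.48].
* **GWAS**: per-SNP effect variances give each named annotation its share
  of total h2 (default total 0.3 when signal is requested), the remainder
  spread over unannotated SNPs; true enrichment is recorded in the truth
  record.  Marginal Z-scores are `sqrt(N) R beta + MVN(0, R)` with `R` the
  panel's **empirical** block correlations, so the heritability regression
  and the gene test see exactly the LD that generated the signal.
* **Expression**: a gene-level baseline (gamma), log-normal gene-by-cell-
  type variation (`noise_sd = 0.3`, making specificity continuous as in
  real references — with zero variation the specificity lattice produces
  heavy bootstrap ties and conservative p-values), and 25 marker genes per
  cell type elevated 10-fold.

What the generator does **not** emulate: realistic allele-frequency
spectra, genetic maps in cM, population structure, cross-block LD,
trans-chromosomal contacts, peak-calling noise, or single-cell sampling
noise in the expression reference.  Passing tests therefore demonstrate the
correctness and calibration of the machinery under a controlled generative
model, not performance on real cohort data.

# Problem sizes used by the test suite

The suite's statistical checks run at sizes chosen to make their
conclusions meaningful while staying comfortably interactive: quadratic-
form p-values are checked against a 200,000-draw Monte-Carlo null (k = 5,
AR(1) rho = 0.7) and against the chi-square survival function up to k = 50;
gene-test calibration uses 400 genes in independent LD blocks (4,000 SNPs,
500-sample panel); heritability recovery uses 4,000 SNPs with 10% of SNPs
carrying 50% of h2 (true enrichment 5.0), a stratified null annotation with
true enrichment exactly 1.0, and 20 GWAS replicates for coverage;
cell-type-enrichment calibration uses 1,000 random target lists of 12 genes
against a 300-gene, 4-cell-type matrix.  The exhaustive annotation oracle
runs on a 50-gene / 500-SNP genome.

# Known limitations

* The gene statistic reproduces the published statistic family
  faithfully but is not bit-compatible with the MAGMA binaries (whose
  internal approximations are not re-derived here).
* The stratified regression uses single-pass weights and a small
  configurable baseline rather than the 97-annotation baseline model; on
  richly overlapping annotation sets the single-pass weighting is an
  approximation.
* Enrichment ratios are ratio estimates; at small SNP counts their
  point estimates are noisy and slightly biased upward (Jensen), which the
  jackknife intervals reflect.
* Interaction FDR enters only as a filter threshold; the package does not
  model the loop-calling statistics themselves.
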