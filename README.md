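# chromrisk

Chromatin interactome annotation and gene-level genetic risk mapping.

Most GWAS risk variants for brain disorders are noncoding and often sit far
from the genes they regulate. Promoter-anchored chromatin interaction maps
(PLAC-seq-style loops at 5 kb resolution) physically connect distal
enhancers to the promoters they contact, and can be used both to ask *which
cell type's* regulatory landscape carries a disease's heritability and
*which genes* the noncoding risk variants point at. chromrisk implements
that analysis chain for epigenomics and statistical-genetics practitioners:

- **Loop classification** — label 5 kb anchor bins against H3K4me3,
  H3K27ac and ATAC peaks and the TSS catalogue; classify loops into eight
  interaction categories (promoter-to-enhancer, promoter-to-promoter, …,
  other); degree and midpoint-distance summaries.
- **Interactome-aware SNP-to-gene annotation** — promoter (1.5 kb up /
  500 bp down per isoform) and exon SNPs assigned positionally; intronic
  and intergenic SNPs in enhancers routed to genes through significant
  (FDR < 0.01), promoter-anchored loops; positional-only, enhancer-only and
  10 kb-proximity modes; seeded loop downsampling; output in the MAGMA
  `.genes.annot` dialect.
- **LD-aware gene association** — per gene, the sum of squared SNP
  Z-scores `T = Σ z_j²` tested against its quadratic-form null
  `Σ λ_i χ²₁` with `λ` the eigenvalues of the panel-derived SNP correlation
  matrix (Ruben series with Imhof and Satterthwaite fallbacks), BH-corrected
  across genes.
- **Stratified LD score regression** — `E[χ²_j] = N Σ_C τ_C ℓ(j,C) + 1`
  fitted jointly across annotations by weighted least squares, with
  bias-corrected windowed LD scores, block-jackknife standard errors,
  heritability proportions and enrichment ratios, and the
  negative-coefficient-z ⇒ 0.0 reporting convention.
- **Cell-type and pathway enrichment** — bootstrap expression-weighted
  cell-type enrichment of risk-gene sets against a specificity matrix, and
  hypergeometric pathway over-representation with duplicate-set collapsing.
- **Synthetic data** — seeded generators for toy genomes/peaks/loops,
  block-AR(1) LD panels, GWAS summary statistics with
  annotation-partitioned heritability, and marker-structured expression
  matrices, so the whole pipeline runs and is tested without downloads.

See the methods vignette (`vignettes/chromrisk-methods.Rmd`) for the models,
assumptions, parameter choices and limitations.

## Worked example

```r
library(chromrisk)

cfg <- sim_config(seed = 1, enrichment_spec = c(enhancer = 0.5))
g   <- simulate_genome(cfg)

al <- annotate_loops(g$loops, g$peaks, g$genes)
head(category_counts(al), 4)
#>                        category count fraction
#> 1          promoter_to_enhancer   140     0.35
#> 2          promoter_to_promoter    32     0.08
#> 3              promoter_to_atac    28     0.07
#> 4 promoter_to_promoter_enhancer    24     0.06
round(distance_stats(al)$summary)
#>    mean     min     max
#>  455571   20000 1000000
```

Promoter-to-enhancer contacts dominate (35% of 400 loops) and span 20 kb to
1 Mb between anchor midpoints. Now simulate a GWAS whose heritability is
concentrated at enhancer bins, build the interactome-aware annotation, and
test genes:

```r
panel <- simulate_ld_panel(cfg)
annot <- bins_to_annotations(g$truth$bin_labels, panel$snps)
gw    <- simulate_gwas(panel, annot, cfg)
qc    <- qc_sumstats(gw$sumstats)

tss <- tss_sites(g$genes)
enh <- g$peaks$h3k27ac[
  label_bins(g$peaks$h3k27ac, g$peaks$h3k4me3, g$peaks$h3k27ac,
             g$peaks$atac, tss) == "enhancer", ]
map <- build_annotation("full", qc, g$genes, g$loops, enh)
map
#> gene_snp_map: 36 genes, 91 gene-SNP assignments

res <- run_gene_tests(map, qc, panel)
head(res[order(res$p), ], 3)
#>    gene_id n_snps stat         p         q mean_n significant
#> 14    g018      5 1055 2.32e-137 8.34e-136  50000        TRUE
#> 34    g016      1  506 5.08e-112 9.15e-111  50000        TRUE
#> 35    g035      2  338  9.88e-72  1.19e-70  50000        TRUE
sum(res$significant)
#> [1] 30
```

With half of the simulated heritability placed on enhancer-bin SNPs, 30 of
36 annotated genes reach gene-level FDR < 0.05, led by genes whose enhancer
contacts carry the strongest signal. The stratified regression recovers the
same architecture at the annotation level:

```r
ld  <- compute_ld_scores(panel, annot, window_bp = 5e4)
fit <- fit_sldsc(qc$z^2, ld, annot, N = cfg$gwas_n, n_blocks = 50)
fit[, c("annotation", "coef_z", "prop_snps", "prop_h2", "enrichment")]
#>          annotation coef_z prop_snps prop_h2 enrichment
#> 1              base  0.995     1.000   1.000       1.00
#> 2             total  2.673     0.245   0.759       3.09
#> 3 promoter_enhancer -0.385     0.150   0.593       3.94
#> 4          promoter  0.226     0.044   0.104       2.37
#> 5          enhancer  1.020     0.119   0.561       4.69
```

Enhancer bins hold 12% of SNPs but 56% of heritability (enrichment 4.7),
the pattern the generator was told to produce. `run_pipeline(pipeline_config())`
chains all stages — simulation, classification, annotation, gene tests,
downsampling, heritability, cell-type enrichment (EWCE-style), pathway
over-representation and cross-mode overlaps — writing per-stage TSVs and a
checksummed manifest.

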