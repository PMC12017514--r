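# Annotation matrices, stratified LD scores, munging and the partitioned
# heritability regression.

test_that("SNP-to-annotation membership matches a brute-force scan", {
  g <- simulate_genome(sim_config(seed = 17, n_genes = 14, n_loops = 100))
  panel <- simulate_ld_panel(sim_config(seed = 17, n_snps = 400))
  bl <- g$truth$bin_labels
  am <- bins_to_annotations(bl, panel$snps)
  expect_true(all(am[, "base"] == 1L))
  cats <- list(
    total = unique(bl$label),
    promoter_enhancer = c("promoter", "enhancer", "promoter_enhancer"),
    promoter = c("promoter", "promoter_enhancer"),
    enhancer = c("enhancer", "promoter_enhancer"))
  for (nm in names(cats)) {
    rows <- bl[bl$label %in% cats[[nm]], ]
    want <- vapply(seq_len(nrow(panel$snps)), function(i) {
      any(rows$chrom == panel$snps$chrom[i] &
            panel$snps$bp[i] >= rows$start & panel$snps$bp[i] < rows$end)
    }, TRUE)
    expect_equal(am[, nm], as.integer(want), ignore_attr = TRUE)
  }
  # nesting: every category is inside 'total'
  expect_true(all(am[, "promoter_enhancer"] <= am[, "total"]))
})

test_that("LD scores match an all-pairs brute-force computation", {
  cfg <- sim_config(seed = 23, n_chrom = 2, n_snps = 300, n_samples = 300,
                    ld_block_size = 6, ld_rho = 0.7)
  panel <- simulate_ld_panel(cfg)
  m <- nrow(panel$snps)
  set.seed(1)
  annot <- cbind(base = rep(1L, m),
                 cat = as.integer(runif(m) < 0.3))
  rownames(annot) <- panel$snps$snp_id
  window <- 2e5
  got <- compute_ld_scores(panel, annot, window_bp = window)
  n <- nrow(panel$geno)
  want <- matrix(0, m, 2)
  R <- cor(panel$geno)
  for (j in 1:m) {
    for (k in 1:m) {
      if (panel$snps$chrom[j] != panel$snps$chrom[k]) next
      if (abs(panel$snps$bp[j] - panel$snps$bp[k]) > window) next
      r2 <- R[j, k]^2
      r2 <- r2 - (1 - r2) / (n - 2)
      want[j, ] <- want[j, ] + r2 * annot[k, ]
    }
  }
  expect_equal(unname(got), want, tolerance = 1e-10)
})

test_that("LD scores behave in analytic limit cases", {
  # independent SNPs: base score ~ 1 (self term only, bias-corrected)
  p0 <- simulate_ld_panel(sim_config(seed = 2, n_snps = 200,
                                     n_samples = 2000, ld_rho = 0))
  annot <- cbind(base = rep(1L, 200))
  rownames(annot) <- p0$snps$snp_id
  l0 <- compute_ld_scores(p0, annot)
  expect_equal(mean(l0[, "base"]), 1, tolerance = 0.05)

  # a duplicated SNP column adds ~1 to its twin's score
  pd <- p0
  pd$geno[, 2] <- pd$geno[, 1]
  ld <- compute_ld_scores(pd, annot)
  expect_equal(ld[1, "base"] - l0[1, "base"], 1, tolerance = 0.05)

  # AR(1) block: within 5% of the analytic sum of rho^(2d) after correction
  rho <- 0.8
  p1 <- simulate_ld_panel(sim_config(seed = 3, n_chrom = 1, n_snps = 50,
                                     n_samples = 2000, ld_rho = rho,
                                     ld_block_size = 50))
  a1 <- cbind(base = rep(1L, 50)); rownames(a1) <- p1$snps$snp_id
  l1 <- compute_ld_scores(p1, a1)
  j <- 25  # central SNP
  analytic <- sum(rho^(2 * abs(seq_len(50) - j)))
  expect_equal(unname(l1[j, "base"]), analytic, tolerance = 0.05 * analytic)

  expect_error(compute_ld_scores(list(geno = matrix(0, 2, 3),
                                      snps = p0$snps[1:3, ]), annot[1:3, ]),
               "samples")
})

test_that("munging applies the imputation, MAF, strand and duplicate filters", {
  ss <- data.frame(
    snp_id = c("rs1", "rs2", "rs3", "rs4", "rs4", "rs6"),
    chrom = "1", bp = 1:6 * 100L,
    a1 = c("A", "A", "C", "A", "A", "A"),
    a2 = c("G", "T", "G", "G", "G", "G"),
    z = rnorm(6), p = runif(6), n = 1000,
    info = c(0.95, 0.95, 0.95, 0.95, 0.95, 0.85),
    maf = c(0.02, 0.2, 0.2, 0.2, 0.2, 0.2))
  out <- munge_for_ldsc(ss)
  expect_equal(out$snp_id, "rs1")          # MAF 0.02 > 0.01, kept
  rep <- attr(out, "report")
  expect_equal(rep$strand_ambiguous, 2L)   # rs2 is A/T, rs3 is C/G
  expect_equal(rep$duplicated_id, 2L)      # both rs4 records
  expect_equal(rep$low_info, 1L)           # rs6
  # restriction to a well-imputed SNP list
  keep <- munge_for_ldsc(ss, keep_snps = c("rs1"))
  expect_equal(keep$snp_id, "rs1")
  expect_error(munge_for_ldsc(ss[6, ]), "survive")
})

sldsc_fixture <- function(seed = 42) {
  cfg <- sim_config(seed = seed, n_chrom = 4, chrom_length = 2e6,
                    n_snps = 4000, ld_block_size = 8, ld_rho = 0.6,
                    n_samples = 500, gwas_n = 1e5, h2_total = 0.4,
                    enrichment_spec = c(enh = 0.5))
  panel <- simulate_ld_panel(cfg)
  m <- nrow(panel$snps)
  set.seed(99)
  enh <- sort(sample(m, m / 10))
  # stratified null: 10% of enriched and 10% of background SNPs, so its
  # true heritability share is exactly proportional (enrichment 1.0)
  null_ann <- sort(c(sample(enh, length(enh) / 10),
                     sample(setdiff(seq_len(m), enh), (m - length(enh)) / 10)))
  annot <- cbind(base = 1L, enh = as.integer(seq_len(m) %in% enh),
                 null = as.integer(seq_len(m) %in% null_ann))
  rownames(annot) <- panel$snps$snp_id
  ld <- compute_ld_scores(panel, annot, window_bp = 5e4)
  list(cfg = cfg, panel = panel, annot = annot, ld = ld,
       enh_ids = panel$snps$snp_id[enh])
}

test_that("the stratified regression recovers a built-in 5x enrichment", {
  fx <- sldsc_fixture()
  gw <- simulate_gwas(fx$panel, list(enh = fx$enh_ids), fx$cfg)
  expect_equal(unname(gw$truth$enrichment["enh"]), 5.0)
  fit <- fit_sldsc(gw$sumstats$z^2, fx$ld, fx$annot, N = fx$cfg$gwas_n,
                   n_blocks = 100)
  row <- fit[fit$annotation == "enh", ]
  ci <- row$enrichment + c(-1.96, 1.96) * row$enrichment_se
  expect_true(ci[1] <= 5 && 5 <= ci[2])
  expect_gt(row$coef_z, 2)
  # base bookkeeping
  expect_equal(fit$enrichment[fit$annotation == "base"], 1)
  expect_equal(fit$prop_snps[fit$annotation == "base"], 1)
  # total h2 on the right scale (point estimate; precision is asserted via
  # the jackknife CIs above)
  expect_gt(attr(fit, "h2_total"), 0.2)
  expect_lt(attr(fit, "h2_total"), 0.8)
})

test_that("null data give intercept ~1 and coefficient CIs covering zero", {
  cfg <- sim_config(seed = 12, n_chrom = 2, n_snps = 2000, ld_block_size = 8,
                    ld_rho = 0.6, n_samples = 400, gwas_n = 1e5, h2_total = 0)
  panel <- simulate_ld_panel(cfg)
  m <- nrow(panel$snps)
  set.seed(3)
  annot <- cbind(base = 1L, cat = as.integer(runif(m) < 0.2))
  rownames(annot) <- panel$snps$snp_id
  ld <- compute_ld_scores(panel, annot)
  gw <- simulate_gwas(panel, NULL, cfg)
  fit <- fit_sldsc(gw$sumstats$z^2, ld, annot, N = cfg$gwas_n, n_blocks = 50)
  expect_equal(attr(fit, "intercept"), 1, tolerance = 0.1)
  for (i in seq_len(nrow(fit))) {
    expect_lt(abs(fit$tau[i]) , 2.5 * fit$tau_se[i] + 1e-12)
  }
})

test_that("heritability proportions over disjoint exhaustive annotations
           sum to one", {
  fx <- sldsc_fixture(seed = 5)
  m <- nrow(fx$panel$snps)
  inside <- fx$annot[, "enh"] == 1L
  # disjoint exhaustive partition: base would be their sum, so the weights
  # come in separately and the partition is fitted directly
  annot <- cbind(enh = as.integer(inside), rest = as.integer(!inside))
  rownames(annot) <- fx$panel$snps$snp_id
  ld <- compute_ld_scores(fx$panel, annot, window_bp = 5e4)
  gw <- simulate_gwas(fx$panel, list(enh = fx$enh_ids), fx$cfg)
  fit <- fit_sldsc(gw$sumstats$z^2, ld, annot, N = fx$cfg$gwas_n,
                   n_blocks = 100, weight_ld = fx$ld[, "base"])
  expect_equal(sum(fit$prop_h2), 1, tolerance = 1e-6)
  expect_equal(sum(fit$prop_snps), 1)
  # and the enriched side of the partition carries most of the signal
  expect_gt(fit$enrichment[fit$annotation == "enh"], 2)
})

test_that("degenerate designs are rejected with names", {
  fx <- sldsc_fixture(seed = 6)
  annot <- fx$annot
  annot <- cbind(annot, enh_copy = annot[, "enh"])
  ld <- cbind(fx$ld, enh_copy = fx$ld[, "enh"])
  gw <- simulate_gwas(fx$panel, list(enh = fx$enh_ids), fx$cfg)
  expect_error(fit_sldsc(gw$sumstats$z^2, ld, annot, N = 1e5,
                         n_blocks = 50), "collinear")
  expect_error(fit_sldsc(gw$sumstats$z[1:10]^2, fx$ld[1:10, ],
                         fx$annot[1:10, ], N = 1e5, n_blocks = 20),
               "exceeds")
})

test_that("the significance table applies the negative-z zero convention", {
  fit <- data.frame(
    annotation = c("base", "enh", "prom"),
    coef_z = c(1, 2.5, -0.5),
    enrichment = c(1, 4, 0.4),
    enrichment_p = c(NA, 0.005, 0.02))
  tab <- enrichment_heatmap_table(list(run1 = fit, run2 = fit))
  expect_equal(nrow(tab), 4L)                     # base rows dropped
  expect_true(all(tab$neglog10_q[tab$annotation == "prom"] == 0))
  expect_equal(tab$q, p.adjust(tab$enrichment_p, "BH"))
  q <- tab$q[tab$annotation == "enh"][1]
  expect_equal(tab$neglog10_q[tab$annotation == "enh"][1], -log10(q))
  # -log10(q) arithmetic: q = 0.01 -> 2
  one <- data.frame(annotation = "enh", coef_z = 3, enrichment = 2,
                    enrichment_p = 0.01)
  expect_equal(enrichment_heatmap_table(list(r = one))$neglog10_q, 2)
})
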