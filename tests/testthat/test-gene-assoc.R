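# Summary-statistic QC, the quadratic-form gene test and its null, FDR
# control, top-gene thresholds and set overlaps.

test_that("QC drops SE<=0, N outliers and sex/mito chromosomes, keeps indels", {
  set.seed(1)
  ss <- data.frame(
    snp_id = paste0("rs", 1:60),
    chrom = c("1", "2", "X", "chrY", "MT", "3", "4", rep("5", 53)),
    bp = 1:60 * 100L,
    a1 = c("A", "AT", rep("A", 58)),   # rs2 is an indel
    a2 = "G",
    z = rnorm(60), p = runif(60),
    n = c(rep(1000, 5), 1e6, rep(1000, 54)),  # rs6 far above mean + 5 SD
    info = 1, maf = 0.2,
    se = c(rep(0.1, 6), 0, rep(0.1, 53)))     # rs7 has SE = 0
  out <- qc_sumstats(ss)
  rep <- attr(out, "report")
  expect_false(any(c("rs3", "rs4", "rs5", "rs6", "rs7") %in% out$snp_id))
  expect_true(all(c("rs1", "rs2") %in% out$snp_id))  # indel kept
  expect_equal(rep$se_nonpositive, 1L)
  expect_equal(rep$sex_or_mito_chrom, 3L)
  expect_equal(rep$n_outlier, 1L)
  expect_equal(rep$output, nrow(out))
  expect_error(qc_sumstats(ss[3:5, ]), "survive")
})

test_that("the gene statistic is the sum of squared Z-scores", {
  expect_equal(gene_statistic(2), 4)
  expect_equal(gene_statistic(c(1, 1, 1)), 3)
  expect_equal(gene_statistic(rep(0, 5)), 0)
  expect_error(gene_statistic(numeric()), "at least one")
})

test_that("quadform p-values reproduce closed forms", {
  expect_equal(quadform_pvalue(4, diag(1)),
               pchisq(4, 1, lower.tail = FALSE), tolerance = 1e-8)
  expect_equal(quadform_pvalue(3, diag(3)),
               pchisq(3, 3, lower.tail = FALSE), tolerance = 1e-8)
  # perfectly correlated pair: eigenvalues (2, 0), T = 8 -> P(chi2_1 >= 4)
  R <- matrix(1, 2, 2)
  expect_equal(quadform_pvalue(8, R),
               pchisq(4, 1, lower.tail = FALSE), tolerance = 1e-8)
  expect_equal(quadform_pvalue(0, diag(3)), 1)
  expect_error(quadform_pvalue(1, matrix(c(1, 0.5, 0.1, 1), 2)), "symmetric")
})

test_that("quadform matches the chi-square survival function for R = I", {
  for (k in c(1, 2, 5, 10, 20, 50)) {
    for (s in c(0.3, 1, 2, 4)) {
      expect_equal(quadform_pvalue(s * k, diag(k)),
                   pchisq(s * k, k, lower.tail = FALSE), tolerance = 1e-6)
    }
  }
})

test_that("quadform p-values are monotone decreasing in the statistic", {
  R <- 0.7^abs(outer(1:6, 1:6, "-"))
  p <- vapply(seq(0.5, 30, length.out = 25), quadform_pvalue, 0, R = R)
  expect_true(all(diff(p) < 0))
})

test_that("quadform agrees with a Monte-Carlo null under AR(1) LD", {
  k <- 5; rho <- 0.7
  R <- rho^abs(outer(1:k, 1:k, "-"))
  set.seed(123)
  L <- chol(R)
  z <- matrix(rnorm(200000 * k), ncol = k) %*% L
  stats <- rowSums(z^2)
  for (s in c(5, 10, 20)) {
    p_mc <- mean(stats >= s)
    se <- sqrt(p_mc * (1 - p_mc) / length(stats))
    expect_lt(abs(quadform_pvalue(s, R) - p_mc), 2 * se + 1e-12)
  }
})

test_that("gene tests flow through annotation map, panel LD and BH", {
  cfg <- sim_config(seed = 8, n_snps = 300, n_samples = 400,
                    ld_block_size = 5, ld_rho = 0.6, h2_total = 0)
  panel <- simulate_ld_panel(cfg)
  gw <- simulate_gwas(panel, NULL, cfg)
  blocks <- split(panel$snps$snp_id, panel$snps$block)
  map <- gene_snp_map(
    stats::setNames(blocks, paste0("gene", seq_along(blocks))),
    data.frame(gene_id = paste0("gene", seq_along(blocks)),
               chrom = "chr1", start = 0L, stop = 1L))
  res <- run_gene_tests(map, gw$sumstats, panel)
  expect_equal(nrow(res), length(blocks))
  expect_true(all(res$q >= res$p))
  expect_true(all(res$p > 0 & res$p <= 1))
  sizes <- stats::setNames(lengths(blocks), paste0("gene", seq_along(blocks)))
  expect_equal(res$n_snps, unname(sizes[res$gene_id]))
  # deterministic on identical inputs
  res2 <- run_gene_tests(map, gw$sumstats, panel)
  expect_identical(res, res2)
  # genes with no usable SNPs are skipped and reported
  map2 <- gene_snp_map(c(map$snps, list(ghost = "rs_none")),
                       rbind(map$spans,
                             data.frame(gene_id = "ghost", chrom = "chr1",
                                        start = 0L, stop = 1L)))
  expect_message(res3 <- run_gene_tests(map2, gw$sumstats, panel), "skipped")
  expect_equal(attr(res3, "skipped"), "ghost")
})

test_that("an enhancer-loop signal is found by the interactome annotation
           but missed by the 10 kb window", {
  # gene at 100-103 kb; causal SNPs sit in an enhancer bin 50 kb away
  tr <- data.frame(gene_id = "G", transcript_id = "G.t1", chrom = "chr1",
                   strand = "+", tss = 100000L)
  ex <- data.frame(gene_id = "G", transcript_id = "G.t1", chrom = "chr1",
                   start = 100000L, end = 103000L, strand = "+")
  gm <- gene_model(tr, ex)
  enh <- data.frame(chrom = "chr1", start = 151000L, end = 152000L)
  loops <- loop_set(data.frame(chromA = "chr1", startA = 100000L,
                               endA = 105000L, chromB = "chr1",
                               startB = 150000L, endB = 155000L, fdr = 1e-4))
  snps <- data.frame(
    snp_id = c("c1", "c2", "n1", "n2", "n3", "n4"), chrom = "chr1",
    bp = c(151200L, 151800L, 100500L, 101500L, 102200L, 102800L),
    a1 = "A", a2 = "G",
    z = c(8, 7.5, 0.3, -0.5, 0.2, 0.1))
  snps$p <- 2 * pnorm(-abs(snps$z)); snps$n <- 5e4
  set.seed(4)
  panel <- list(geno = matrix(rnorm(200 * 6), 200, 6,
                              dimnames = list(NULL, snps$snp_id)))
  suppressMessages({
    full <- build_annotation("full", snps, gm, loops, enh)
    win <- build_annotation("window10kb", snps, gm)
  })
  res_full <- run_gene_tests(full, snps, panel)
  res_win <- run_gene_tests(win, snps, panel)
  expect_true(res_full$significant[res_full$gene_id == "G"])
  expect_lt(res_full$p, 1e-10)
  expect_false(any(c("c1", "c2") %in% win$snps$G))
  expect_gt(res_win$p, 0.05)
})

test_that("BH q-values reproduce the textbook step-up values", {
  p <- c(0.005, 0.01, 0.03, 0.04)
  expect_equal(p.adjust(p, "BH"), c(0.02, 0.02, 0.04, 0.04))
  # and run_gene_tests applies exactly this correction
  res <- data.frame(p = p)
  expect_equal(p.adjust(res$p, "BH"), c(0.02, 0.02, 0.04, 0.04))
})

test_that("top-gene thresholds act on the p-value", {
  res <- data.frame(gene_id = c("a", "b"), p = c(4e-8, 1e-13))
  expect_setequal(top_genes(res, 5e-8), c("a", "b"))
  expect_equal(top_genes(res, 5e-12), "b")
  expect_length(top_genes(res[0, ], 5e-8), 0)
  expect_error(top_genes(res, 0), "positive")
})

test_that("overlap counts are exclusive and sum to the union", {
  oc <- overlap_counts(list(S1 = c("A", "B"), S2 = c("B", "C")))
  expect_equal(oc$count[oc$combination == "S1"], 1L)
  expect_equal(oc$count[oc$combination == "S2"], 1L)
  expect_equal(oc$count[oc$combination == "S1&S2"], 1L)
  expect_equal(sum(oc$count), 3L)

  same <- overlap_counts(list(a = c("x", "y"), b = c("x", "y")))
  expect_equal(same$count[same$combination == "a&b"], 2L)
  expect_equal(sum(same$count), 2L)

  # five random sets against a brute-force membership tally
  set.seed(99)
  sets <- lapply(1:5, function(i) sample(letters, sample(5:15, 1)))
  names(sets) <- paste0("set", 1:5)
  oc5 <- overlap_counts(sets)
  expect_equal(sum(oc5$count), length(unique(unlist(sets))))
  for (el in unique(unlist(sets))) {
    combo <- paste(names(sets)[vapply(sets, function(s) el %in% s, TRUE)],
                   collapse = "&")
    expect_gte(oc5$count[oc5$combination == combo], 1L)
  }
  expect_error(overlap_counts(list(a = "x")), "two sets")
})
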