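# Promoter construction, loop filtering, positional and interactional SNP
# assignment (with brute-force oracles), annotation modes and downsampling.

test_that("isoform promoters span 1.5 kb upstream / 500 bp downstream", {
  tr <- data.frame(gene_id = c("A", "B", "C"),
                   transcript_id = c("A.t1", "B.t1", "C.t1"),
                   chrom = "chr1", strand = c("+", "-", "+"),
                   tss = c(10000L, 10000L, 1000L))
  ex <- data.frame(gene_id = tr$gene_id, transcript_id = tr$transcript_id,
                   chrom = "chr1",
                   start = c(10000L, 9500L, 1000L),
                   end = c(10200L, 10001L, 1200L),
                   strand = tr$strand)
  pr <- build_promoters(gene_model(tr, ex))
  expect_equal(pr$start, c(8500L, 9500L, 0L))
  expect_equal(pr$end, c(10500L, 11500L, 1500L))
  expect_equal(pr$end - pr$start, c(2000L, 2000L, 1500L))  # clipped at 0
})

test_that("loop filtering keeps significant promoter-anchored interactions", {
  gm <- toy_gene_model()
  pr <- build_promoters(gm)
  # anchors: [10000,15000) overlaps G1's promoter; [20000,25000) none
  loops <- loop_set(data.frame(
    chromA = "chr1",
    startA = c(10000L, 10000L, 20000L),
    endA = c(15000L, 15000L, 25000L),
    chromB = "chr1",
    startB = c(30000L, 40000L, 40000L),
    endB = c(35000L, 45000L, 45000L),
    fdr = c(0.001, 0.02, 0.001)))
  suppressMessages(fl <- filter_loops(loops, pr))
  expect_equal(nrow(fl), 1L)         # fdr 0.02 out; unanchored 0.001 out
  expect_equal(fl$startB, 30000L)
  suppressMessages(fl0 <- filter_loops(loops, pr, fdr_max = 0.05))
  expect_equal(nrow(fl0), 2L)
})

test_that("positional assignment matches the brute-force containment scan", {
  gm <- toy_gene_model()
  pr <- build_promoters(gm)
  set.seed(42)
  snps <- data.frame(snp_id = sprintf("rs%02d", 1:60), chrom = "chr1",
                     bp = sort(sample(0:70000, 60)))
  map <- assign_positional(snps, pr, gm$exons)
  expect_equal(sort_pairs(map_pairs(map)),
               sort_pairs(brute_positional(snps, pr, gm$exons)))
  # SNP inside G1's promoter is assigned to G1
  one <- data.frame(snp_id = "rsX", chrom = "chr1", bp = 9000L)
  m1 <- assign_positional(one, pr, gm$exons)
  expect_equal(m1$snps$G1, "rsX")
})

test_that("a SNP in an exon shared by two genes maps to both", {
  tr <- data.frame(gene_id = c("G1", "G2"),
                   transcript_id = c("G1.t1", "G2.t1"),
                   chrom = "chr1", strand = "+", tss = c(100L, 150L))
  ex <- data.frame(gene_id = c("G1", "G2"),
                   transcript_id = c("G1.t1", "G2.t1"), chrom = "chr1",
                   start = c(100L, 150L), end = c(400L, 500L), strand = "+")
  gm <- gene_model(tr, ex)
  snp <- data.frame(snp_id = "rs1", chrom = "chr1", bp = 300L)
  map <- assign_positional(snp, build_promoters(gm), gm$exons)
  expect_setequal(names(map$snps), c("G1", "G2"))
})

test_that("interactional assignment matches exhaustive enumeration", {
  gm <- toy_gene_model()
  pr <- build_promoters(gm)
  tss <- tss_sites(gm)
  enhancers <- data.frame(chrom = "chr1",
                          start = c(31000L, 41000L), end = c(31800L, 41600L))
  loops <- loop_set(data.frame(
    chromA = "chr1",
    startA = c(10000L, 55000L, 40000L),
    endA = c(15000L, 60000L, 45000L),
    chromB = "chr1",
    startB = c(30000L, 30000L, 20000L),
    endB = c(35000L, 35000L, 25000L),
    fdr = 0.001))
  set.seed(9)
  snps <- data.frame(snp_id = sprintf("rs%02d", 1:80), chrom = "chr1",
                     bp = sort(sample(0:70000, 80)))
  map <- assign_interactional(snps, loops, enhancers, pr, gm$exons)
  expect_equal(sort_pairs(map_pairs(map)),
               sort_pairs(brute_interactional(snps, loops, enhancers, pr,
                                              gm$exons)))

  # intergenic SNP in an enhancer bin looped to G1's promoter reaches G1
  snp <- data.frame(snp_id = "rsE", chrom = "chr1", bp = 31500L)
  m <- assign_interactional(snp, loops, enhancers, pr, gm$exons)
  expect_true("rsE" %in% m$snps$G1)

  # same SNP with the loop failing the FDR filter gets nothing
  weak <- loop_set(data.frame(chromA = "chr1", startA = 10000L, endA = 15000L,
                              chromB = "chr1", startB = 30000L, endB = 35000L,
                              fdr = 0.5))
  suppressMessages(fl <- filter_loops(weak, pr))
  m0 <- assign_interactional(snp, fl, enhancers, pr, gm$exons)
  expect_equal(length(m0$snps), 0L)
})

test_that("positional assignments are never re-routed through loops", {
  gm <- toy_gene_model()
  pr <- build_promoters(gm)
  enhancers <- data.frame(chrom = "chr1", start = 9000L, end = 12000L)
  loops <- loop_set(data.frame(chromA = "chr1", startA = 10000L,
                               endA = 15000L, chromB = "chr1",
                               startB = 55000L, endB = 60000L, fdr = 0.001))
  # SNP inside G1's promoter (and an enhancer region): not eligible
  snp <- data.frame(snp_id = "rsP", chrom = "chr1", bp = 9100L)
  m <- assign_interactional(snp, loops, enhancers, pr, gm$exons)
  expect_equal(length(m$snps), 0L)
})

test_that("annotation modes compose as documented", {
  g <- simulate_genome(sim_config(seed = 13, n_genes = 20, n_loops = 150,
                                  frac_significant = 0.9))
  panel <- simulate_ld_panel(sim_config(seed = 13, n_snps = 800))
  snps <- panel$snps
  tss <- tss_sites(g$genes)
  enh <- distal_peaks(g$peaks$h3k27ac, tss)
  suppressMessages({
    full <- build_annotation("full", snps, g$genes, g$loops, enh)
    pos <- build_annotation("positional_only", snps, g$genes, g$loops, enh)
    pos_all <- build_annotation("positional_only", snps, g$genes, g$loops,
                                enh, bin_restricted = FALSE)
    eo <- build_annotation("enhancer_only", snps, g$genes, g$loops, enh)
    win <- build_annotation("window10kb", snps, g$genes)
  })
  # full = positional union interactional, and a superset of each mode
  pr <- build_promoters(g$genes)
  suppressMessages(fl <- filter_loops(g$loops, pr))
  pos_full <- assign_positional(snps, pr, g$genes$exons)
  inter <- assign_interactional(snps, fl, enh, pr, g$genes$exons)
  want <- unique(rbind(map_pairs(pos_full), map_pairs(inter)))
  expect_equal(sort_pairs(map_pairs(full)), sort_pairs(want))
  # every single-mode assignment is contained in the full annotation
  full_keys <- with(map_pairs(full), paste(gene_id, snp_id))
  for (m in list(pos, pos_all, eo)) {
    expect_true(all(with(map_pairs(m), paste(gene_id, snp_id)) %in%
                      full_keys))
  }
  # bin-restricted positional is a subset of unrestricted positional
  expect_true(all(with(map_pairs(pos), paste(gene_id, snp_id)) %in%
                    with(map_pairs(pos_all), paste(gene_id, snp_id))))
  expect_gte(length(full$snps), length(eo$snps))
  expect_error(build_annotation("enhancer_only", snps, g$genes), "needs")
})

test_that("the 10 kb window annotation is boundary-inclusive", {
  tr <- data.frame(gene_id = "G", transcript_id = "G.t1", chrom = "chr1",
                   strand = "+", tss = 50000L)
  ex <- data.frame(gene_id = "G", transcript_id = "G.t1", chrom = "chr1",
                   start = 50000L, end = 52000L, strand = "+")
  gm <- gene_model(tr, ex)
  snps <- data.frame(snp_id = c("in1", "in2", "out"), chrom = "chr1",
                     bp = c(50000L - 9999L, 40000L, 39999L))
  map <- build_annotation("window10kb", snps, gm)
  expect_setequal(map$snps$G, c("in1", "in2"))
})

test_that("downsampling is uniform, seeded and never invents records", {
  g <- simulate_genome(sim_config(seed = 21, n_genes = 12, n_loops = 80))
  n <- nrow(g$loops)
  same <- downsample_loops(g$loops, n, seed = 5)
  expect_equal(as.data.frame(same), as.data.frame(g$loops))
  a <- downsample_loops(g$loops, 30, seed = 5)
  b <- downsample_loops(g$loops, 30, seed = 5)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c <- downsample_loops(g$loops, 30, seed = 6)
  expect_false(identical(as.data.frame(a), as.data.frame(c)))
  key <- paste(g$loops$chromA, g$loops$startA, g$loops$chromB, g$loops$startB)
  expect_true(all(paste(a$chromA, a$startA, a$chromB, a$startB) %in% key))
  expect_equal(anyDuplicated(paste(a$chromA, a$startA, a$chromB, a$startB)),
               0L)
  expect_error(downsample_loops(g$loops, n + 1L, seed = 1), "downsample")
})

test_that("repeated downsampling yields varying downstream gene counts", {
  g <- simulate_genome(sim_config(seed = 31, n_genes = 20, n_loops = 200,
                                  frac_significant = 0.95))
  panel <- simulate_ld_panel(sim_config(seed = 31, n_snps = 600))
  tss <- tss_sites(g$genes)
  enh <- distal_peaks(g$peaks$h3k27ac, tss)
  counts <- vapply(0:9, function(it) {
    dl <- downsample_loops(g$loops, 80, seed = 100 + it)
    suppressMessages(m <- build_annotation("full", panel$snps, g$genes, dl,
                                           enh))
    length(m$snps)
  }, 0)
  expect_length(counts, 10L)
  expect_gt(stats::sd(counts), 0)
})
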