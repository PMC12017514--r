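# Seeded generators for toy genomes, peaks, loops, LD panels, GWAS summary
# statistics with annotation-partitioned heritability, and cell-type
# expression matrices.  All generators are pure functions of the config
# (seed included): per-stage child seeds are derived deterministically.

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generators with the study's
#' default conditions: 5 kb loop bins, block-diagonal AR(1) LD, GWAS
#' Z-scores whose heritability is concentrated in chosen annotations, and a
#' cell-type expression matrix with marker-gene blocks.
#'
#' @param seed Root seed; per-stage child seeds are derived from it.
#' @param n_chrom Number of toy chromosomes.
#' @param chrom_length Chromosome length in bp; must be a multiple of
#'   `bin_size`.
#' @param bin_size Loop anchor bin width in bp (default 5000, the PLAC-seq
#'   resolution).
#' @param n_genes Number of genes.
#' @param n_snps Number of panel SNPs.
#' @param ld_block_size SNPs per LD block.
#' @param ld_rho AR(1) within-block correlation, in `[0, 1)`.
#' @param n_samples Reference-panel sample count.
#' @param gwas_n GWAS sample size.
#' @param h2_total Total SNP heritability on the standardized scale.
#' @param enrichment_spec Named numeric: annotation name -> share of
#'   `h2_total` carried by SNPs of that annotation.  Shares must sum to <= 1;
#'   the remainder is spread uniformly over SNPs outside all named
#'   annotations.
#' @param n_cell_types Number of cell types in the expression matrix.
#' @param n_marker_genes Marker genes per cell type.
#' @param marker_fold Expression fold-elevation of marker genes.
#' @param noise_sd SD of log-normal gene-by-cell-type expression variation
#'   (default 0.3); set to 0 for exactly uniform non-marker specificity.
#' @param promoter_peak_frac Fraction of TSSs bearing H3K4me3+H3K27ac peaks.
#' @param pe_frac Fraction of peak-bearing TSS bins that additionally carry a
#'   distal H3K27ac peak (yielding the promoter/enhancer bin class).
#' @param enhancers_per_gene Distal enhancer bins placed per gene.
#' @param n_loops Number of chromatin loops to draw.
#' @param frac_significant Fraction of loops with interaction FDR below 0.01.
#' @param loop_mix Named numeric giving target shares of the eight loop
#'   categories; normalized internally.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_chrom = 2L,
                       chrom_length = 2e6,
                       bin_size = 5000L,
                       n_genes = 40L,
                       n_snps = 2000L,
                       ld_block_size = 10L,
                       ld_rho = 0.8,
                       n_samples = 500L,
                       gwas_n = 5e4,
                       h2_total = 0.3,
                       enrichment_spec = numeric(),
                       n_cell_types = 4L,
                       n_marker_genes = 25L,
                       marker_fold = 10,
                       noise_sd = 0.3,
                       promoter_peak_frac = 0.9,
                       pe_frac = 0.2,
                       enhancers_per_gene = 2L,
                       n_loops = 400L,
                       frac_significant = 0.85,
                       loop_mix = NULL) {
  if (is.null(loop_mix)) {
    loop_mix <- c(promoter_to_enhancer = 0.35, promoter_to_other = 0.15,
                  h3k4me3_to_other = 0.12, other = 0.12,
                  promoter_to_promoter = 0.08, promoter_to_atac = 0.07,
                  promoter_to_promoter_enhancer = 0.06,
                  h3k4me3_to_h3k4me3 = 0.05)
  }
  cfg <- list(seed = as.integer(seed), n_chrom = as.integer(n_chrom),
              chrom_length = chrom_length, bin_size = as.integer(bin_size),
              n_genes = as.integer(n_genes), n_snps = as.integer(n_snps),
              ld_block_size = as.integer(ld_block_size), ld_rho = ld_rho,
              n_samples = as.integer(n_samples), gwas_n = gwas_n,
              h2_total = h2_total, enrichment_spec = enrichment_spec,
              n_cell_types = as.integer(n_cell_types),
              n_marker_genes = as.integer(n_marker_genes),
              marker_fold = marker_fold, noise_sd = noise_sd,
              promoter_peak_frac = promoter_peak_frac, pe_frac = pe_frac,
              enhancers_per_gene = as.integer(enhancers_per_gene),
              n_loops = as.integer(n_loops),
              frac_significant = frac_significant,
              loop_mix = loop_mix / sum(loop_mix))
  if (cfg$chrom_length %% cfg$bin_size != 0) {
    .stopf("bin_size must divide chrom_length")
  }
  if (cfg$ld_rho < 0 || cfg$ld_rho >= 1) .stopf("ld_rho must be in [0, 1)")
  if (length(cfg$enrichment_spec) && sum(cfg$enrichment_spec) > 1 + 1e-12) {
    .stopf("enrichment_spec shares must sum to <= 1")
  }
  if (cfg$frac_significant < 0 || cfg$frac_significant > 1) {
    .stopf("frac_significant must be in [0, 1]")
  }
  structure(cfg, class = c("sim_config", "list"))
}

# evenly sized split of n items over k groups
.split_count <- function(n, k) {
  base <- n %/% k
  extra <- n %% k
  base + (seq_len(k) <= extra)
}

#' Simulate a toy genome: gene model, peak sets and chromatin loops
#'
#' Places genes (1-3 transcripts each) at bin centers, H3K4me3+H3K27ac peaks
#' at a configurable fraction of TSSs, distal H3K27ac-only enhancer bins,
#' distal H3K4me3-only bins and ATAC-only bins, then draws loops between
#' labeled bins so that all eight loop categories are realized.  Interaction
#' FDRs are drawn with `frac_significant` of loops below the 0.01 cutoff.
#'
#' @param cfg A [sim_config()].
#' @return A list with elements `genes` (a [gene_model()]), `peaks`
#'   (list of `h3k4me3`, `h3k27ac`, `atac` interval data.frames), `loops`
#'   (a [loop_set()]) and `truth` (generator intent: `bin_labels` with one
#'   labeled row per feature bin, and `loop_categories`).
#' @export
simulate_genome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  .with_seed(.child_seed(cfg$seed, 1L), {
    bs <- cfg$bin_size
    n_bins <- as.integer(cfg$chrom_length / bs)
    chroms <- paste0("chr", seq_len(cfg$n_chrom))
    genes_per_chrom <- .split_count(cfg$n_genes, cfg$n_chrom)

    transcripts <- list(); exons <- list()
    bin_rows <- list()   # chrom, bin index, label
    k4 <- list(); k27 <- list(); atac <- list()
    gid <- 0L; tid <- 0L

    for (ci in seq_len(cfg$n_chrom)) {
      ch <- chroms[ci]
      n_g <- genes_per_chrom[ci]
      spacing <- n_bins %/% (n_g + 1L)
      if (n_g > 0 && spacing < 5L) {
        .stopf("geometry cannot place %d genes on %d bins (chromosome %s)",
               n_g, n_bins, ch)
      }
      tss_bins <- spacing * seq_len(n_g)

      # feature bins: everything at least 2 bins away from every TSS bin
      blocked <- unique(c(tss_bins, tss_bins - 1L, tss_bins + 1L))
      free_bins <- setdiff(seq_len(n_bins), blocked)
      free_bins <- free_bins[sample.int(length(free_bins))]
      n_enh <- cfg$enhancers_per_gene * n_g
      n_k4d <- max(4L, round(0.25 * n_enh))
      n_atac <- max(3L, round(0.25 * n_enh))
      n_other <- max(6L, round(0.4 * n_enh))
      if (length(free_bins) < n_enh + n_k4d + n_atac + n_other) {
        .stopf("geometry cannot place requested feature bins on %s", ch)
      }
      enh_bins <- free_bins[seq_len(n_enh)]
      k4_bins <- free_bins[n_enh + seq_len(n_k4d)]
      atac_bins <- free_bins[n_enh + n_k4d + seq_len(n_atac)]
      other_bins <- free_bins[n_enh + n_k4d + n_atac + seq_len(n_other)]

      has_peak <- runif(n_g) < cfg$promoter_peak_frac
      if (n_g > 0 && !any(has_peak)) has_peak[1] <- TRUE
      is_pe <- has_peak & runif(n_g) < cfg$pe_frac
      if (any(has_peak) && !any(is_pe)) is_pe[which(has_peak)[1]] <- TRUE

      for (g in seq_len(n_g)) {
        gid <- gid + 1L
        bin0 <- (tss_bins[g] - 1L) * bs     # bin start
        tss0 <- bin0 + bs %/% 2L            # gene TSS at bin center
        strand <- sample(c("+", "-"), 1L)
        n_tx <- sample(1:3, 1L)
        for (t in seq_len(n_tx)) {
          tid <- tid + 1L
          shift <- if (t == 1L) 0L else sample(0:150, 1L)
          tss <- if (strand == "+") tss0 + shift else tss0 - shift
          n_ex <- sample(2:4, 1L)
          lens <- sample(150:400, n_ex, replace = TRUE)
          gaps <- sample(200:800, n_ex, replace = TRUE)
          off <- cumsum(c(0L, (lens + gaps)[-n_ex]))
          if (strand == "+") {
            es <- tss + off; ee <- es + lens
          } else {
            ee <- tss - off + 1L; es <- ee - lens
          }
          transcripts[[tid]] <- data.frame(
            gene_id = sprintf("g%03d", gid),
            transcript_id = sprintf("g%03d.t%d", gid, t),
            chrom = ch, strand = strand, tss = tss)
          exons[[tid]] <- data.frame(
            gene_id = sprintf("g%03d", gid),
            transcript_id = sprintf("g%03d.t%d", gid, t),
            chrom = ch, start = es, end = ee, strand = strand)
        }
        if (has_peak[g]) {
          k4[[length(k4) + 1L]] <- data.frame(
            chrom = ch, start = tss0 - 400L, end = tss0 + 400L)
          k27[[length(k27) + 1L]] <- data.frame(
            chrom = ch, start = tss0 - 350L, end = tss0 + 450L)
          atac[[length(atac) + 1L]] <- data.frame(
            chrom = ch, start = tss0 - 300L, end = tss0 + 300L)
          if (is_pe[g]) {  # distal H3K27ac peak at the bin's left edge
            k27[[length(k27) + 1L]] <- data.frame(
              chrom = ch, start = bin0, end = bin0 + 250L)
          }
        }
        bin_rows[[length(bin_rows) + 1L]] <- data.frame(
          chrom = ch, bin = tss_bins[g],
          label = if (!has_peak[g]) "other"
                  else if (is_pe[g]) "promoter_enhancer" else "promoter")
      }
      mid_peak <- function(bins, width = 600L) {
        s <- (bins - 1L) * bs + (bs - width) %/% 2L
        data.frame(chrom = ch, start = s, end = s + width)
      }
      if (n_enh) {
        k27[[length(k27) + 1L]] <- mid_peak(enh_bins)
        atac[[length(atac) + 1L]] <- mid_peak(enh_bins, 400L)
      }
      if (n_k4d) k4[[length(k4) + 1L]] <- mid_peak(k4_bins)
      if (n_atac) atac[[length(atac) + 1L]] <- mid_peak(atac_bins, 400L)
      add_bins <- function(bins, label) {
        if (length(bins)) data.frame(chrom = ch, bin = bins, label = label)
      }
      bin_rows[[length(bin_rows) + 1L]] <- add_bins(enh_bins, "enhancer")
      bin_rows[[length(bin_rows) + 1L]] <- add_bins(k4_bins, "h3k4me3_distal")
      bin_rows[[length(bin_rows) + 1L]] <- add_bins(atac_bins, "atac_only")
      bin_rows[[length(bin_rows) + 1L]] <- add_bins(other_bins, "other")
    }

    bins <- do.call(rbind, bin_rows)
    bins$start <- (bins$bin - 1L) * bs
    bins$end <- bins$start + bs
    peaks <- list(
      h3k4me3 = do.call(rbind, k4),
      h3k27ac = do.call(rbind, k27),
      atac = do.call(rbind, atac)
    )
    peaks <- lapply(peaks, function(p) {
      p <- p[order(p$chrom, p$start), , drop = FALSE]
      p$strand <- "."
      rownames(p) <- NULL
      p
    })

    loops <- .simulate_loops(cfg, bins)
    genes <- gene_model(do.call(rbind, transcripts), do.call(rbind, exons))
    truth_bins <- bins[order(bins$chrom, bins$start),
                       c("chrom", "start", "end", "label")]
    rownames(truth_bins) <- NULL
    list(genes = genes, peaks = peaks, loops = loops$loops,
         truth = list(bin_labels = truth_bins,
                      loop_categories = loops$categories))
  })
}

# draw loops between labeled bins so every requested category is realized
.simulate_loops <- function(cfg, bins) {
  bs <- cfg$bin_size
  max_span <- max(2L, as.integer(1e6 / bs))   # loop reach: ~1 Mb
  mix <- cfg$loop_mix
  counts <- round(mix * cfg$n_loops)
  if (cfg$n_loops >= length(mix)) counts <- pmax(counts, 1L)
  while (sum(counts) > cfg$n_loops) counts[which.max(counts)] <-
    counts[which.max(counts)] - 1L
  while (sum(counts) < cfg$n_loops) counts[which.max(mix)] <-
    counts[which.max(mix)] + 1L

  promish <- bins$label %in% c("promoter", "promoter_enhancer")
  pools <- list(
    prom = which(promish),
    prom_plain = which(bins$label == "promoter"),
    pe = which(bins$label == "promoter_enhancer"),
    enh = which(bins$label == "enhancer"),
    k4 = which(bins$label == "h3k4me3_distal"),
    atac = which(bins$label == "atac_only"),
    oth = which(bins$label == "other")
  )
  side_pools <- list(
    promoter_to_enhancer = list("prom", "enh"),
    promoter_to_promoter = list("prom_plain", "prom_plain"),
    promoter_to_atac = list("prom", "atac"),
    promoter_to_promoter_enhancer = list("prom", "pe"),
    promoter_to_other = list("prom", "oth"),
    h3k4me3_to_h3k4me3 = list("k4", "k4"),
    h3k4me3_to_other = list("k4", "oth"),
    other = list("enh", "enh")
  )
  # enumerate all feasible (same-chromosome, within-reach, unused) anchor
  # pairs per category, then sample the requested count without replacement
  enum_pairs <- function(pa, pb) {
    if (!length(pa) || !length(pb)) {
      return(data.frame(a = integer(), b = integer()))
    }
    eg <- expand.grid(i = pa, j = pb)
    keep <- eg$i != eg$j &
      bins$chrom[eg$i] == bins$chrom[eg$j] &
      abs(bins$bin[eg$i] - bins$bin[eg$j]) <= max_span
    eg <- eg[keep, , drop = FALSE]
    unique(data.frame(a = pmin(eg$i, eg$j), b = pmax(eg$i, eg$j)))
  }
  all_pairs <- lapply(names(counts), function(cat) {
    pools_ab <- side_pools[[cat]]
    pairs <- enum_pairs(pools[[pools_ab[[1]]]], pools[[pools_ab[[2]]]])
    if (cat == "other") {  # enhancer-enhancer plus unanchored pairs
      pairs <- unique(rbind(pairs, enum_pairs(pools$oth, pools$oth)))
    }
    pairs
  })
  names(all_pairs) <- names(counts)
  avail <- vapply(all_pairs, nrow, 0L)
  if (any(avail == 0L)) {
    .stopf("geometry cannot realize any '%s' loop; enlarge the genome",
           names(avail)[avail == 0L][1])
  }
  # cap categories at their feasible pair counts; give the shortfall to
  # categories with slack, largest target share first
  counts <- pmin(counts, avail)
  while (sum(counts) < cfg$n_loops) {
    slack <- avail - counts
    if (all(slack <= 0L)) {
      .stopf("geometry cannot place %d loops (%d feasible pairs); enlarge the genome",
             cfg$n_loops, sum(avail))
    }
    grow <- which(slack > 0L)[which.max(mix[slack > 0L])]
    counts[grow] <- counts[grow] +
      min(slack[grow], cfg$n_loops - sum(counts))
  }
  sel_a <- integer(); sel_b <- integer(); cats <- character()
  for (cat in names(counts)) {
    pairs <- all_pairs[[cat]]
    n_cat <- counts[[cat]]
    if (n_cat == 0L) next
    take <- pairs[sample.int(nrow(pairs), n_cat), , drop = FALSE]
    sel_a <- c(sel_a, take$a); sel_b <- c(sel_b, take$b)
    cats <- c(cats, rep(cat, n_cat))
  }
  df <- data.frame(
    chromA = bins$chrom[sel_a], startA = bins$start[sel_a],
    endA = bins$end[sel_a],
    chromB = bins$chrom[sel_b], startB = bins$start[sel_b],
    endB = bins$end[sel_b],
    fdr = NA_real_)
  n_sig <- round(cfg$frac_significant * nrow(df))
  sig <- sample(c(rep(TRUE, n_sig), rep(FALSE, nrow(df) - n_sig)))
  df$fdr <- ifelse(sig, runif(nrow(df), 0, 0.0095),
                   runif(nrow(df), 0.011, 0.9))
  loops <- loop_set(df, resolution = bs, cell_type = "sim")
  canon_key <- function(x) {
    ka <- paste(x$chromA, x$startA); kb <- paste(x$chromB, x$startB)
    ifelse(ka <= kb, paste(ka, kb), paste(kb, ka))
  }
  key_in <- canon_key(df)
  key_out <- canon_key(loops)
  categories <- data.frame(
    chromA = loops$chromA, startA = loops$startA,
    chromB = loops$chromB, startB = loops$startB,
    category = cats[match(key_out, key_in)],
    stringsAsFactors = FALSE)
  list(loops = loops, categories = categories)
}

#' Simulate an LD reference panel with block-diagonal AR(1) correlation
#'
#' SNPs are placed on the toy genome and grouped into blocks of
#' `ld_block_size` consecutive SNPs; dosages are continuous, imputed-style
#' values `2*maf + sqrt(2*maf*(1-maf)) * z` where the latent standard-normal
#' `z` follows an AR(1) process with parameter `ld_rho` within each block and
#' blocks are independent.
#'
#' @param cfg A [sim_config()].
#' @return A list with `geno` (n_samples x n_snps matrix, columns named by
#'   SNP ID) and `snps` (data.frame: `snp_id`, `chrom`, `bp`, `a1`, `a2`,
#'   `maf`, `block`).
#' @export
simulate_ld_panel <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  .with_seed(.child_seed(cfg$seed, 2L), {
    chroms <- paste0("chr", seq_len(cfg$n_chrom))
    per_chrom <- .split_count(cfg$n_snps, cfg$n_chrom)
    snps <- do.call(rbind, lapply(seq_len(cfg$n_chrom), function(ci) {
      n <- per_chrom[ci]
      bp <- sort(sample.int(cfg$chrom_length, n)) - 1L
      data.frame(chrom = chroms[ci], bp = bp)
    }))
    m <- nrow(snps)
    snps$snp_id <- sprintf("rs%05d", seq_len(m))
    snps$a1 <- "A"; snps$a2 <- "G"
    snps$maf <- runif(m, 0.05, 0.48)
    # blocks never span chromosomes
    blk <- integer(m); b <- 0L
    for (ch in unique(snps$chrom)) {
      ii <- which(snps$chrom == ch)
      blk[ii] <- b + ceiling(seq_along(ii) / cfg$ld_block_size)
      b <- max(blk[ii])
    }
    snps$block <- blk
    geno <- matrix(0, cfg$n_samples, m,
                   dimnames = list(NULL, snps$snp_id))
    rho <- cfg$ld_rho
    for (bb in unique(blk)) {
      jj <- which(blk == bb)
      z <- matrix(0, cfg$n_samples, length(jj))
      z[, 1] <- rnorm(cfg$n_samples)
      if (length(jj) > 1) {
        for (k in 2:length(jj)) {
          z[, k] <- rho * z[, k - 1] + sqrt(1 - rho^2) * rnorm(cfg$n_samples)
        }
      }
      geno[, jj] <- sweep(sweep(z, 2, sqrt(2 * snps$maf[jj] *
                                             (1 - snps$maf[jj])), "*"),
                          2, 2 * snps$maf[jj], "+")
    }
    list(geno = geno,
         snps = snps[c("snp_id", "chrom", "bp", "a1", "a2", "maf", "block")])
  })
}

# coerce annotation input (named list of SNP ids, or 0/1 matrix) to a
# logical membership matrix aligned with panel SNPs
.membership_matrix <- function(annotations, snp_ids) {
  if (is.null(annotations) || !length(annotations)) {
    return(matrix(logical(0), length(snp_ids), 0,
                  dimnames = list(snp_ids, NULL)))
  }
  if (is.matrix(annotations)) {
    a <- annotations[match(snp_ids, rownames(annotations)), , drop = FALSE]
    a[is.na(a)] <- 0
    return(a > 0)
  }
  out <- vapply(annotations, function(ids) snp_ids %in% ids,
                logical(length(snp_ids)))
  dimnames(out) <- list(snp_ids, names(annotations))
  out
}

#' Simulate GWAS summary statistics over an LD panel
#'
#' Per-SNP effect variances are set so each annotation named in
#' `cfg$enrichment_spec` carries its share of `h2_total`, with the remainder
#' spread over SNPs outside all named annotations.  Marginal Z-scores are
#' drawn per LD block as `Z = sqrt(N) R beta + MVN(0, R)` with `R` the
#' panel's empirical correlation, so downstream LD-aware methods see the
#' same LD that generated the signal.
#'
#' @param panel Output of [simulate_ld_panel()].
#' @param annotations Named list of SNP-ID vectors (or a 0/1 matrix with SNP
#'   rownames) defining the annotations referenced by the enrichment spec;
#'   may be `NULL` when the enrichment specification is empty.
#' @param cfg A [sim_config()]; uses `gwas_n`, `h2_total`, `enrichment_spec`
#'   and the seed.
#' @return A list with `sumstats` (data.frame in the [read_sumstats()]
#'   schema) and `truth` (per-SNP effect variances, true per-annotation
#'   enrichment, `h2_total`, the stage seed).
#' @export
simulate_gwas <- function(panel, annotations = NULL, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  spec <- cfg$enrichment_spec
  if (length(spec) && cfg$h2_total <= 0) {
    .stopf("h2_total must be > 0 when enrichment_spec is non-empty")
  }
  seed <- .child_seed(cfg$seed, 3L)
  .with_seed(seed, {
    snps <- panel$snps
    m <- nrow(snps)
    memb <- .membership_matrix(annotations, snps$snp_id)
    sigma2 <- numeric(m)
    if (cfg$h2_total > 0) {
      named <- intersect(names(spec), colnames(memb))
      if (length(spec) && length(named) < length(spec)) {
        .stopf("enrichment_spec names missing from annotations: %s",
               paste(setdiff(names(spec), colnames(memb)), collapse = ", "))
      }
      in_any <- if (length(named)) rowSums(memb[, named, drop = FALSE]) > 0
                else rep(FALSE, m)
      leftover <- 1 - sum(spec)
      if (any(!in_any) && leftover > 0) {
        sigma2[!in_any] <- leftover * cfg$h2_total / sum(!in_any)
      }
      for (a in named) {
        ma <- sum(memb[, a])
        if (ma == 0) .stopf("annotation '%s' has no SNPs", a)
        sigma2[memb[, a]] <- sigma2[memb[, a]] + spec[[a]] * cfg$h2_total / ma
      }
    }
    beta <- rnorm(m, 0, sqrt(sigma2))
    z <- numeric(m)
    for (bb in unique(snps$block)) {
      jj <- which(snps$block == bb)
      if (length(jj) == 1L) {
        z[jj] <- sqrt(cfg$gwas_n) * beta[jj] + rnorm(1)
        next
      }
      R <- cor(panel$geno[, jj, drop = FALSE])
      L <- tryCatch(chol(R), error = function(e)
        chol(R + diag(1e-6, nrow(R))))
      z[jj] <- sqrt(cfg$gwas_n) * as.vector(R %*% beta[jj]) +
        as.vector(crossprod(L, rnorm(length(jj))))
    }
    truth_enr <- if (length(spec)) {
      vapply(names(spec), function(a) {
        (sum(sigma2[memb[, a]]) / cfg$h2_total) / (sum(memb[, a]) / m)
      }, 0)
    } else numeric()
    ss <- data.frame(
      snp_id = snps$snp_id, chrom = snps$chrom, bp = snps$bp,
      a1 = snps$a1, a2 = snps$a2, z = z, p = 2 * pnorm(-abs(z)),
      n = cfg$gwas_n, info = runif(m, 0.92, 1),
      maf = pmin(pmax(colMeans(panel$geno) / 2, 1e-3), 0.5),
      stringsAsFactors = FALSE)
    list(sumstats = ss,
         truth = list(sigma2 = sigma2, enrichment = truth_enr,
                      h2_total = cfg$h2_total, seed = seed))
  })
}

#' Simulate a gene-by-cell-type mean-expression matrix
#'
#' Each cell type receives `n_marker_genes` marker genes whose expression is
#' elevated `marker_fold`-fold over the gene's baseline; every gene-by-cell-
#' type mean additionally carries log-normal variation of SD `noise_sd`,
#' emulating the continuous variation of real expression references.  With
#' `marker_fold = 1` and `noise_sd = 0` specificity is exactly uniform.
#'
#' @param cfg A [sim_config()].
#' @param gene_ids Optional gene IDs for the rows; defaults to
#'   `g001..g<n_genes>` matching [simulate_genome()].
#' @return A numeric matrix (genes x cell types) with a `markers` attribute:
#'   a named list of marker gene IDs per cell type.
#' @export
simulate_expression <- function(cfg, gene_ids = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_cell_types < 2L) .stopf("n_cell_types must be >= 2")
  .with_seed(.child_seed(cfg$seed, 4L), {
    if (is.null(gene_ids)) gene_ids <- sprintf("g%03d", seq_len(cfg$n_genes))
    n_g <- length(gene_ids)
    cts <- c("microglia", "neuron", "oligodendrocyte", "astrocyte",
             paste0("celltype", seq_len(max(0, cfg$n_cell_types - 4L)) + 4L))
    cts <- cts[seq_len(cfg$n_cell_types)]
    if (cfg$n_cell_types * cfg$n_marker_genes > n_g) {
      .stopf("marker sets (%d x %d) exceed gene count %d",
             cfg$n_cell_types, cfg$n_marker_genes, n_g)
    }
    marker_ids <- split(
      sample(gene_ids, cfg$n_cell_types * cfg$n_marker_genes),
      rep(cts, each = cfg$n_marker_genes))
    base <- rgamma(n_g, shape = 2, scale = 2) + 0.1
    expr <- matrix(rep(base, cfg$n_cell_types), n_g, cfg$n_cell_types,
                   dimnames = list(gene_ids, cts))
    if (cfg$noise_sd > 0) {
      expr <- expr * exp(matrix(rnorm(n_g * cfg$n_cell_types,
                                      sd = cfg$noise_sd),
                                n_g, cfg$n_cell_types))
    }
    for (ct in cts) {
      expr[marker_ids[[ct]], ct] <- expr[marker_ids[[ct]], ct] *
        cfg$marker_fold
    }
    attr(expr, "markers") <- marker_ids[cts]
    expr
  })
}
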