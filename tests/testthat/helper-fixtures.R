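# Shared in-code fixtures and brute-force oracles.

# two genes on opposite strands, one with two isoforms
toy_gene_model <- function() {
  transcripts <- data.frame(
    gene_id = c("G1", "G1", "G2"),
    transcript_id = c("G1.t1", "G1.t2", "G2.t1"),
    chrom = c("chr1", "chr1", "chr1"),
    strand = c("+", "+", "-"),
    tss = c(10000L, 10100L, 60000L))
  exons <- data.frame(
    gene_id = c("G1", "G1", "G1", "G2", "G2"),
    transcript_id = c("G1.t1", "G1.t1", "G1.t2", "G2.t1", "G2.t1"),
    chrom = "chr1",
    start = c(10000L, 11000L, 10100L, 59001L, 57000L),
    end = c(10300L, 11400L, 10500L, 60001L, 57500L),
    strand = c("+", "+", "+", "-", "-"))
  gene_model(transcripts, exons)
}

toy_loop_df <- function() {
  data.frame(
    chromA = "chr1", startA = c(10000L, 0L, 20000L, 20000L),
    endA = c(15000L, 5000L, 25000L, 25000L),
    chromB = "chr1", startB = c(0L, 10000L, 50000L, 40000L),
    endB = c(5000L, 15000L, 55000L, 45000L),
    fdr = c(0.02, 0.005, 0.001, 0.03))
}

# brute-force O(n*m) overlap oracle (>= 1 shared bp, same chromosome)
brute_overlap_pairs <- function(a, b) {
  out <- list()
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] == b$chrom[j] &&
          max(a$start[i], b$start[j]) < min(a$end[i], b$end[j])) {
        out[[length(out) + 1L]] <- c(i, j)
      }
    }
  }
  if (!length(out)) return(data.frame(a_idx = integer(), b_idx = integer()))
  m <- do.call(rbind, out)
  data.frame(a_idx = m[, 1], b_idx = m[, 2])
}

# brute-force positional assignment: SNP inside any promoter/exon of a gene
brute_positional <- function(snps, promoters, exons) {
  feats <- rbind(promoters[c("gene_id", "chrom", "start", "end")],
                 exons[c("gene_id", "chrom", "start", "end")])
  out <- list()
  for (i in seq_len(nrow(snps))) {
    for (j in seq_len(nrow(feats))) {
      if (snps$chrom[i] == feats$chrom[j] &&
          snps$bp[i] >= feats$start[j] && snps$bp[i] < feats$end[j]) {
        out[[length(out) + 1L]] <- data.frame(gene_id = feats$gene_id[j],
                                              snp_id = snps$snp_id[i])
      }
    }
  }
  if (!length(out)) return(data.frame(gene_id = character(),
                                      snp_id = character()))
  unique(do.call(rbind, out))
}

# brute-force interactional assignment over (SNP, loop, gene) triples
brute_interactional <- function(snps, loops, enhancers, promoters, exons) {
  feats <- rbind(promoters[c("gene_id", "chrom", "start", "end")],
                 exons[c("gene_id", "chrom", "start", "end")])
  in_iv <- function(bp, chrom, iv) {
    any(chrom == iv$chrom & bp >= iv$start & bp < iv$end)
  }
  ov_iv <- function(chrom, s, e, iv) {
    which(chrom == iv$chrom & pmax(s, iv$start) < pmin(e, iv$end))
  }
  df <- as.data.frame(loops)
  out <- list()
  for (i in seq_len(nrow(snps))) {
    if (in_iv(snps$bp[i], snps$chrom[i], feats)) next    # not intronic/intergenic
    if (!in_iv(snps$bp[i], snps$chrom[i], enhancers)) next
    for (l in seq_len(nrow(df))) {
      for (side in c("A", "B")) {
        oth <- if (side == "A") "B" else "A"
        anch <- c(df[[paste0("chrom", side)]][l], df[[paste0("start", side)]][l],
                  df[[paste0("end", side)]][l])
        if (!(snps$chrom[i] == anch[1] &&
              snps$bp[i] >= as.integer(anch[2]) &&
              snps$bp[i] < as.integer(anch[3]))) next
        hits <- ov_iv(df[[paste0("chrom", oth)]][l],
                      df[[paste0("start", oth)]][l],
                      df[[paste0("end", oth)]][l], feats)
        for (h in hits) {
          out[[length(out) + 1L]] <- data.frame(gene_id = feats$gene_id[h],
                                                snp_id = snps$snp_id[i])
        }
      }
    }
  }
  if (!length(out)) return(data.frame(gene_id = character(),
                                      snp_id = character()))
  unique(do.call(rbind, out))
}

# gene_snp_map -> sorted (gene_id, snp_id) pair frame for comparisons
map_pairs <- function(map) {
  if (!length(map$snps)) return(data.frame(gene_id = character(),
                                           snp_id = character()))
  df <- data.frame(gene_id = rep(names(map$snps), lengths(map$snps)),
                   snp_id = unlist(map$snps, use.names = FALSE))
  df[order(df$gene_id, df$snp_id), ]
}

sort_pairs <- function(df) {
  df <- df[order(df$gene_id, df$snp_id), ]
  rownames(df) <- NULL
  df
}

# TSS-distal H3K27ac peaks (enhancer regions), computed independently
distal_peaks <- function(peaks, tss, window = 2000) {
  keep <- vapply(seq_len(nrow(peaks)), function(i) {
    on_chr <- tss$bp[tss$chrom == peaks$chrom[i]]
    if (!length(on_chr)) return(TRUE)
    d <- vapply(on_chr, function(t) {
      if (t >= peaks$start[i] && t < peaks$end[i]) 0
      else min(abs(t - peaks$start[i]), abs(t - (peaks$end[i] - 1L)))
    }, 0)
    min(d) > window
  }, TRUE)
  peaks[keep, , drop = FALSE]
}
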