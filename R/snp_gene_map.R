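# Construction of SNP-to-gene annotations: isoform promoters, the
# promoter-anchored significant-loop filter, positional (promoter/exon) and
# interactional (enhancer-loop) SNP assignment, the composed annotation
# modes, and seeded loop downsampling.

#' Isoform promoter intervals
#'
#' One promoter per transcript spanning 1,500 bp upstream to 500 bp
#' downstream of the TSS, strand-aware, clipped at position 0.
#'
#' @param genes A [gene_model()].
#' @return Data frame with columns `gene_id`, `transcript_id`, `chrom`,
#'   `start`, `end`, `strand` (0-based half-open; width 2,000 bp unless
#'   clipped).
#' @export
build_promoters <- function(genes) {
  tr <- genes$transcripts
  plus <- tr$strand == "+"
  start <- ifelse(plus, tr$tss - 1500L, tr$tss - 500L)
  end <- ifelse(plus, tr$tss + 500L, tr$tss + 1500L)
  data.frame(gene_id = tr$gene_id, transcript_id = tr$transcript_id,
             chrom = tr$chrom, start = pmax(start, 0L), end = end,
             strand = tr$strand, stringsAsFactors = FALSE)
}

#' Filter loops to significant, promoter-anchored interactions
#'
#' Retains loops with interaction FDR below `fdr_max` and at least one
#' anchor overlapping a promoter interval.
#'
#' @param loops A [loop_set()].
#' @param promoters Promoter intervals from [build_promoters()].
#' @param fdr_max FDR cutoff (default 0.01).
#' @return The filtered [loop_set()]; dropped counts are reported with a
#'   message.
#' @export
filter_loops <- function(loops, promoters, fdr_max = 0.01) {
  df <- as.data.frame(loops)
  sig <- df$fdr < fdr_max
  anchored <-
    .overlaps_any(data.frame(chrom = df$chromA, start = df$startA,
                             end = df$endA), promoters) |
    .overlaps_any(data.frame(chrom = df$chromB, start = df$startB,
                             end = df$endB), promoters)
  keep <- sig & anchored
  message(sum(!sig), " loops failed FDR < ", fdr_max, "; ",
          sum(sig & !anchored), " significant loops without a promoter anchor")
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, resolution = attr(loops, "resolution"),
            cell_type = attr(loops, "cell_type"),
            class = c("loop_set", "data.frame"))
}

# gene body spans (exon union) per gene
.gene_bodies <- function(exons) {
  sp <- do.call(rbind, lapply(split(exons, exons$gene_id), function(e) {
    data.frame(gene_id = e$gene_id[1], chrom = e$chrom[1],
               start = min(e$start), end = max(e$end))
  }))
  rownames(sp) <- NULL
  sp
}

# assemble a gene_snp_map from (gene_id, snp_id, feature start/end) hits;
# span per gene = min/max over the features that contributed SNPs, falling
# back to the gene body for genes absent from `hits`
.map_from_hits <- function(hits, snps, exons, gene_ids = NULL) {
  if (is.null(gene_ids)) gene_ids <- unique(hits$gene_id)
  bodies <- .gene_bodies(exons)
  snp_lists <- list()
  spans <- list()
  for (g in gene_ids) {
    h <- hits[hits$gene_id == g, , drop = FALSE]
    ids <- unique(h$snp_id)
    ord <- order(snps$bp[match(ids, snps$snp_id)], ids)
    snp_lists[[g]] <- ids[ord]
    b <- bodies[bodies$gene_id == g, , drop = FALSE]
    if (nrow(h)) {
      spans[[g]] <- data.frame(gene_id = g, chrom = h$chrom[1],
                               start = min(h$fstart), stop = max(h$fend))
    } else {
      spans[[g]] <- data.frame(gene_id = g, chrom = b$chrom,
                               start = b$start, stop = b$end)
    }
  }
  gene_snp_map(snp_lists, do.call(rbind, spans))
}

#' Assign promoter and exon SNPs directly to genes
#'
#' A SNP position contained in any isoform promoter or exon interval is
#' assigned to that interval's gene; a SNP may map to multiple genes.
#'
#' @param snps Summary-statistics data.frame (needs `snp_id`, `chrom`, `bp`).
#' @param promoters Promoter intervals from [build_promoters()].
#' @param exons Exon intervals (e.g. `genes$exons`), used both for
#'   assignment and for gene-body fallback spans.
#' @return A [gene_snp_map()] over the genes that received >= 1 SNP.
#' @export
assign_positional <- function(snps, promoters, exons) {
  feats <- rbind(
    promoters[c("gene_id", "chrom", "start", "end")],
    exons[c("gene_id", "chrom", "start", "end")])
  h <- .points_in_intervals(snps, feats)
  hits <- data.frame(
    gene_id = feats$gene_id[h$interval_idx],
    snp_id = snps$snp_id[h$point_idx],
    chrom = feats$chrom[h$interval_idx],
    fstart = feats$start[h$interval_idx],
    fend = feats$end[h$interval_idx],
    stringsAsFactors = FALSE)
  hits <- unique(hits)
  .map_from_hits(hits, snps, exons)
}

#' Assign intronic/intergenic enhancer SNPs to genes through loops
#'
#' Only SNPs outside every promoter and exon (intronic or intergenic) and
#' inside an enhancer region are eligible.  Such a SNP is assigned to gene
#' `g` when it lies in a loop anchor bin whose partner anchor overlaps a
#' promoter or exon of `g`.  Loops should already have passed
#' [filter_loops()].
#'
#' @param snps Summary-statistics data.frame.
#' @param loops Filtered [loop_set()].
#' @param enhancers Enhancer region intervals (e.g. TSS-distal H3K27ac
#'   peaks).
#' @param promoters,exons Feature intervals with `gene_id` (promoters from
#'   [build_promoters()]).
#' @return A [gene_snp_map()] over the genes that received >= 1 SNP; spans
#'   fall back to the gene body.
#' @export
assign_interactional <- function(snps, loops, enhancers, promoters, exons) {
  feats <- rbind(
    promoters[c("gene_id", "chrom", "start", "end")],
    exons[c("gene_id", "chrom", "start", "end")])
  in_feat <- rep(FALSE, nrow(snps))
  in_feat[unique(.points_in_intervals(snps, feats)$point_idx)] <- TRUE
  in_enh <- rep(FALSE, nrow(snps))
  in_enh[unique(.points_in_intervals(snps, enhancers)$point_idx)] <- TRUE
  eligible <- which(!in_feat & in_enh)
  df <- as.data.frame(loops)
  if (!length(eligible) || !nrow(df)) {
    return(gene_snp_map(stats::setNames(list(), character()),
                        data.frame(gene_id = character(), chrom = character(),
                                   start = integer(), stop = integer())))
  }
  esnps <- snps[eligible, , drop = FALSE]
  hits <- list()
  for (side in c("A", "B")) {
    this <- data.frame(chrom = df[[paste0("chrom", side)]],
                       start = df[[paste0("start", side)]],
                       end = df[[paste0("end", side)]])
    other_side <- if (side == "A") "B" else "A"
    partner <- data.frame(chrom = df[[paste0("chrom", other_side)]],
                          start = df[[paste0("start", other_side)]],
                          end = df[[paste0("end", other_side)]])
    sh <- .points_in_intervals(esnps, this)       # eligible SNP in anchor
    ph <- .overlap_pairs(partner, feats)          # partner anchor -> gene
    if (!nrow(sh) || !nrow(ph)) next
    merged <- merge(sh, ph, by.x = "interval_idx", by.y = "a_idx")
    if (!nrow(merged)) next
    hits[[side]] <- data.frame(
      gene_id = feats$gene_id[merged$b_idx],
      snp_id = esnps$snp_id[merged$point_idx],
      stringsAsFactors = FALSE)
  }
  hits <- unique(do.call(rbind, hits))
  if (is.null(hits) || !nrow(hits)) {
    return(gene_snp_map(stats::setNames(list(), character()),
                        data.frame(gene_id = character(), chrom = character(),
                                   start = integer(), stop = integer())))
  }
  # spans: gene body (interactional SNPs sit outside the gene's features)
  bodies <- .gene_bodies(exons)
  snp_lists <- lapply(split(hits$snp_id, hits$gene_id), function(ids) {
    ids <- unique(ids)
    ids[order(snps$bp[match(ids, snps$snp_id)], ids)]
  })
  spans <- bodies[match(names(snp_lists), bodies$gene_id), , drop = FALSE]
  names(spans)[names(spans) == "end"] <- "stop"
  gene_snp_map(snp_lists, spans)
}

# union of two gene_snp_maps; spans expand to cover both
.merge_maps <- function(a, b) {
  genes <- union(names(a$snps), names(b$snps))
  snps <- lapply(genes, function(g) {
    unique(c(a$snps[[g]], b$snps[[g]]))
  })
  names(snps) <- genes
  spans <- lapply(genes, function(g) {
    sa <- a$spans[a$spans$gene_id == g, , drop = FALSE]
    sb <- b$spans[b$spans$gene_id == g, , drop = FALSE]
    s <- rbind(sa, sb)
    data.frame(gene_id = g, chrom = s$chrom[1],
               start = min(s$start), stop = max(s$stop))
  })
  gene_snp_map(snps, do.call(rbind, spans))
}

#' Build a SNP-to-gene annotation in one of four modes
#'
#' \describe{
#'   \item{full}{Union of positional (promoter/exon) and interactional
#'     (enhancer-loop) assignments.}
#'   \item{positional_only}{Positional assignments; by default restricted to
#'     SNPs lying in filtered-loop anchor bins that overlap a promoter or
#'     exon (`bin_restricted = FALSE` keeps all positional SNPs).}
#'   \item{enhancer_only}{Interactional assignments only.}
#'   \item{window10kb}{Proximity annotation: every SNP within `window_bp`
#'     of a gene's span (exon union) is assigned to it; no loops used.}
#' }
#'
#' @param mode One of `"full"`, `"positional_only"`, `"enhancer_only"`,
#'   `"window10kb"`.
#' @param snps Summary-statistics data.frame.
#' @param genes A [gene_model()].
#' @param loops A [loop_set()] (unfiltered; the significant promoter-anchored
#'   subset is taken internally).  Not needed for `window10kb`.
#' @param enhancers Enhancer region intervals.  Not needed for `window10kb`.
#' @param fdr_max Loop FDR cutoff (default 0.01).
#' @param bin_restricted Logical; see `positional_only` above.
#' @param window_bp Proximity window for `window10kb` (default 10,000).
#' @return A [gene_snp_map()].
#' @export
build_annotation <- function(mode = c("full", "positional_only",
                                      "enhancer_only", "window10kb"),
                             snps, genes, loops = NULL, enhancers = NULL,
                             fdr_max = 0.01, bin_restricted = TRUE,
                             window_bp = 10000) {
  mode <- match.arg(mode)
  exons <- genes$exons
  if (mode == "window10kb") {
    bodies <- .gene_bodies(exons)
    win <- data.frame(gene_id = bodies$gene_id, chrom = bodies$chrom,
                      start = pmax(bodies$start - window_bp, 0),
                      end = bodies$end + window_bp)
    h <- .points_in_intervals(snps, win)
    hits <- data.frame(gene_id = win$gene_id[h$interval_idx],
                       snp_id = snps$snp_id[h$point_idx],
                       chrom = win$chrom[h$interval_idx],
                       fstart = win$start[h$interval_idx],
                       fend = win$end[h$interval_idx])
    return(.map_from_hits(unique(hits), snps, exons))
  }
  if (is.null(loops) || is.null(enhancers)) {
    .stopf("mode '%s' needs loops and enhancers", mode)
  }
  promoters <- build_promoters(genes)
  fl <- filter_loops(loops, promoters, fdr_max = fdr_max)
  pos <- assign_positional(snps, promoters, exons)
  if (mode == "positional_only") {
    if (!bin_restricted) return(pos)
    feats <- rbind(promoters[c("gene_id", "chrom", "start", "end")],
                   exons[c("gene_id", "chrom", "start", "end")])
    df <- as.data.frame(fl)
    anchors <- unique(rbind(
      data.frame(chrom = df$chromA, start = df$startA, end = df$endA),
      data.frame(chrom = df$chromB, start = df$startB, end = df$endB)))
    feat_anchor <- anchors[.overlaps_any(anchors, feats), , drop = FALSE]
    in_bin <- rep(FALSE, nrow(snps))
    in_bin[unique(.points_in_intervals(snps, feat_anchor)$point_idx)] <- TRUE
    keep_ids <- snps$snp_id[in_bin]
    snp_lists <- lapply(pos$snps, function(ids) ids[ids %in% keep_ids])
    snp_lists <- snp_lists[lengths(snp_lists) > 0]
    return(gene_snp_map(snp_lists,
                        pos$spans[pos$spans$gene_id %in% names(snp_lists), ,
                                  drop = FALSE]))
  }
  inter <- assign_interactional(snps, fl, enhancers, promoters, exons)
  if (mode == "enhancer_only") return(inter)
  .merge_maps(pos, inter)
}

#' Downsample a loop set without replacement
#'
#' Uniform, seed-deterministic sample of `n` loops; the intended use for
#' cross-cell-type comparisons is 10 iterations with seeds
#' `seed + 0 .. seed + 9`.
#'
#' @param loops A [loop_set()].
#' @param n Number of loops to keep; must not exceed the loop count.
#' @param seed Integer seed.
#' @return A [loop_set()] with `n` records.
#' @export
downsample_loops <- function(loops, n, seed) {
  df <- as.data.frame(loops)
  if (n > nrow(df)) {
    .stopf("cannot downsample %d loops to %d", nrow(df), n)
  }
  idx <- .with_seed(seed, sample.int(nrow(df), n))
  out <- df[sort(idx), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, resolution = attr(loops, "resolution"),
            cell_type = attr(loops, "cell_type"),
            class = c("loop_set", "data.frame"))
}
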