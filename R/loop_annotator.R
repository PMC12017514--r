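# Labeling of loop anchor bins against epigenomic peaks and a gene model,
# classification of loops into the eight interaction categories, and degree /
# distance statistics over promoter-to-enhancer interactions.

#' Bin label levels
#' @export
bin_label_levels <- c("promoter_enhancer", "promoter", "enhancer",
                      "h3k4me3_distal", "atac_only", "other")

#' Loop category levels
#' @export
loop_category_levels <- c("promoter_to_enhancer", "promoter_to_promoter",
                          "promoter_to_atac", "promoter_to_promoter_enhancer",
                          "promoter_to_other", "h3k4me3_to_h3k4me3",
                          "h3k4me3_to_other", "other")

#' Label anchor bins against peak sets and TSSs
#'
#' A bin is a `promoter` when it overlaps both an H3K4me3 and an H3K27ac
#' peak and lies within 2,000 bp of a TSS; an `enhancer` when it overlaps an
#' H3K27ac peak that is itself distal (> 2,000 bp) to every TSS, without a
#' promoter call; `promoter_enhancer` when it satisfies both; `h3k4me3_distal`
#' when it overlaps a TSS-distal H3K4me3 peak without a promoter or enhancer
#' call; `atac_only` when it overlaps an ATAC peak and is devoid of H3K4me3
#' and H3K27ac; otherwise `other`.  Precedence:
#' promoter_enhancer > promoter > enhancer > h3k4me3_distal > atac_only >
#' other.  Distances are measured from any base of the bin (or peak) to the
#' nearest TSS.
#'
#' @param bins Data frame of bins (`chrom`, `start`, `end`).
#' @param h3k4me3,h3k27ac,atac Peak interval data.frames.
#' @param tss Data frame of TSS positions (`chrom`, `bp`), e.g. from
#'   [tss_sites()].
#' @param tss_window Promoter proximity window in bp (default 2000).
#' @return Factor of labels with levels `bin_label_levels`, one per bin.
#' @export
label_bins <- function(bins, h3k4me3, h3k27ac, atac, tss,
                       tss_window = 2000) {
  bin_near <- .dist_to_points(bins, tss) <= tss_window
  k27_distal <- h3k27ac[.dist_to_points(h3k27ac, tss) > tss_window, ,
                        drop = FALSE]
  k4_distal <- h3k4me3[.dist_to_points(h3k4me3, tss) > tss_window, ,
                       drop = FALSE]
  ov_k4 <- .overlaps_any(bins, h3k4me3)
  ov_k27 <- .overlaps_any(bins, h3k27ac)
  ov_k27_distal <- .overlaps_any(bins, k27_distal)
  ov_k4_distal <- .overlaps_any(bins, k4_distal)
  ov_atac <- .overlaps_any(bins, atac)

  prom <- ov_k4 & ov_k27 & bin_near
  lbl <- rep("other", nrow(bins))
  lbl[ov_atac & !ov_k4 & !ov_k27] <- "atac_only"
  lbl[ov_k4_distal & !prom & !ov_k27_distal] <- "h3k4me3_distal"
  lbl[ov_k27_distal & !prom] <- "enhancer"
  lbl[prom & !ov_k27_distal] <- "promoter"
  lbl[prom & ov_k27_distal] <- "promoter_enhancer"
  factor(lbl, levels = bin_label_levels)
}

#' Classify loops from their two anchor labels
#'
#' If either anchor is a promoter (a `promoter_enhancer` bin counts as
#' promoter-side), the category is `promoter_to_X` with `X` the partner's
#' class; an `h3k4me3_distal` partner falls into `promoter_to_other`.  When
#' both anchors are promoter-side, the pair is `promoter_to_promoter_enhancer`
#' if either is a `promoter_enhancer` bin, else `promoter_to_promoter`.
#' Failing a promoter side, pairs with an `h3k4me3_distal` anchor are
#' `h3k4me3_to_h3k4me3` (both) or `h3k4me3_to_other`; everything else
#' (including enhancer-to-enhancer) is `other`.
#'
#' @param label_a,label_b Anchor labels (values of `bin_label_levels`).
#' @return Factor of categories with levels `loop_category_levels`.
#' @export
classify_loops <- function(label_a, label_b) {
  a <- as.character(label_a); b <- as.character(label_b)
  if (length(a) != length(b)) .stopf("label vectors differ in length")
  promish <- function(x) x %in% c("promoter", "promoter_enhancer")
  partner_class <- function(x) {
    ifelse(x == "enhancer", "promoter_to_enhancer",
    ifelse(x == "atac_only", "promoter_to_atac",
           "promoter_to_other"))
  }
  out <- rep("other", length(a))
  pa <- promish(a); pb <- promish(b)
  both <- pa & pb
  out[both] <- ifelse(a[both] == "promoter_enhancer" |
                        b[both] == "promoter_enhancer",
                      "promoter_to_promoter_enhancer",
                      "promoter_to_promoter")
  one <- xor(pa, pb)
  partner <- ifelse(pa, b, a)
  out[one] <- partner_class(partner[one])
  k4a <- a == "h3k4me3_distal"; k4b <- b == "h3k4me3_distal"
  k4 <- !pa & !pb & (k4a | k4b)
  out[k4] <- ifelse(k4a[k4] & k4b[k4], "h3k4me3_to_h3k4me3",
                    "h3k4me3_to_other")
  factor(out, levels = loop_category_levels)
}

#' Label and classify every loop in a loop set
#'
#' @param loops A [loop_set()].
#' @param peaks List with elements `h3k4me3`, `h3k27ac`, `atac` (interval
#'   data.frames).
#' @param genes A [gene_model()] supplying the TSS set.
#' @param tss_window Promoter proximity window in bp.
#' @return The loop records with added columns `label_a`, `label_b`,
#'   `category`.
#' @export
annotate_loops <- function(loops, peaks, genes, tss_window = 2000) {
  df <- as.data.frame(loops)
  anchors <- unique(rbind(
    data.frame(chrom = df$chromA, start = df$startA, end = df$endA),
    data.frame(chrom = df$chromB, start = df$startB, end = df$endB)))
  tss <- tss_sites(genes)
  lab <- label_bins(anchors, peaks$h3k4me3, peaks$h3k27ac, peaks$atac, tss,
                    tss_window = tss_window)
  key <- paste(anchors$chrom, anchors$start)
  df$label_a <- lab[match(paste(df$chromA, df$startA), key)]
  df$label_b <- lab[match(paste(df$chromB, df$startB), key)]
  df$category <- classify_loops(df$label_a, df$label_b)
  df
}

#' Loop counts and fractions per category
#'
#' @param annotated Output of [annotate_loops()].
#' @return Data frame with one row per category: `category`, `count`,
#'   `fraction`; counts sum to the loop total.
#' @export
category_counts <- function(annotated) {
  if (!nrow(annotated)) .stopf("empty loop set")
  if (anyNA(annotated$category)) .stopf("unlabeled loop anchors present")
  tab <- table(factor(annotated$category, levels = loop_category_levels))
  data.frame(category = names(tab), count = as.integer(tab),
             fraction = as.integer(tab) / nrow(annotated),
             stringsAsFactors = FALSE)
}

#' Degree distributions of promoter-to-enhancer interactions
#'
#' Restricted to `promoter_to_enhancer` loops: a promoter bin's degree is
#' its number of distinct enhancer partner bins, and vice versa.
#'
#' @param annotated Output of [annotate_loops()].
#' @return List of two data.frames (`enhancers_per_promoter`,
#'   `promoters_per_enhancer`) with columns `degree`, `n_bins`.
#' @export
degree_distributions <- function(annotated) {
  pe <- annotated[annotated$category == "promoter_to_enhancer", ,
                  drop = FALSE]
  promish <- pe$label_a %in% c("promoter", "promoter_enhancer")
  prom_key <- ifelse(promish, paste(pe$chromA, pe$startA),
                     paste(pe$chromB, pe$startB))
  enh_key <- ifelse(promish, paste(pe$chromB, pe$startB),
                    paste(pe$chromA, pe$startA))
  pairs <- unique(data.frame(prom = prom_key, enh = enh_key))
  hist_of <- function(keys) {
    if (!length(keys)) {
      return(data.frame(degree = integer(), n_bins = integer()))
    }
    deg <- table(keys)
    tab <- table(as.integer(deg))
    data.frame(degree = as.integer(names(tab)), n_bins = as.integer(tab))
  }
  list(enhancers_per_promoter = hist_of(pairs$prom),
       promoters_per_enhancer = hist_of(pairs$enh))
}

#' Midpoint distances of promoter-to-enhancer interactions
#'
#' @param annotated Output of [annotate_loops()].
#' @return List with `distances` (per intrachromosomal loop,
#'   `|mid(anchorA) - mid(anchorB)|`), `summary` (mean, min, max) and
#'   `n_trans_excluded` (trans-chromosomal pairs dropped, also reported
#'   with a message).
#' @export
distance_stats <- function(annotated) {
  pe <- annotated[annotated$category == "promoter_to_enhancer", ,
                  drop = FALSE]
  trans <- pe$chromA != pe$chromB
  if (any(trans)) {
    message(sum(trans), " trans-chromosomal pairs excluded from distances")
  }
  cis <- pe[!trans, , drop = FALSE]
  d <- abs((cis$startA + cis$endA) / 2 - (cis$startB + cis$endB) / 2)
  list(distances = d,
       summary = c(mean = if (length(d)) mean(d) else NA_real_,
                   min = if (length(d)) min(d) else NA_real_,
                   max = if (length(d)) max(d) else NA_real_),
       n_trans_excluded = sum(trans))
}
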