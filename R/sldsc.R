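# Stratified LD score regression: annotation construction from labeled loop
# anchor bins, windowed LD-score computation with small-sample bias
# correction, summary-statistic munging, the jointly fitted partitioned
# heritability regression with block-jackknife inference, and the
# heatmap-style significance table.

#' Build a SNP-by-annotation membership matrix from labeled anchor bins
#'
#' A SNP belongs to a category when its position lies in any anchor bin of
#' that category: `total` (any bin), `promoter_enhancer` (bins labeled
#' promoter, enhancer or promoter_enhancer), `promoter` (promoter or
#' promoter_enhancer bins) and `enhancer` (enhancer or promoter_enhancer
#' bins).  An all-ones `base` annotation is always included.
#'
#' @param bin_labels Data frame with `chrom`, `start`, `end`, `label`
#'   (values of `bin_label_levels`), e.g. anchor bins labeled with
#'   [label_bins()].
#' @param snps Data frame with `snp_id`, `chrom`, `bp`.
#' @return Integer 0/1 matrix, SNPs x annotations, rownames = SNP IDs,
#'   columns `base`, `total`, `promoter_enhancer`, `promoter`, `enhancer`.
#' @export
bins_to_annotations <- function(bin_labels, snps) {
  cats <- list(
    total = bin_label_levels,
    promoter_enhancer = c("promoter", "enhancer", "promoter_enhancer"),
    promoter = c("promoter", "promoter_enhancer"),
    enhancer = c("enhancer", "promoter_enhancer"))
  out <- matrix(0L, nrow(snps), 1L + length(cats),
                dimnames = list(snps$snp_id, c("base", names(cats))))
  out[, "base"] <- 1L
  for (nm in names(cats)) {
    bl <- bin_labels[bin_labels$label %in% cats[[nm]], , drop = FALSE]
    hit <- unique(.points_in_intervals(snps, bl)$point_idx)
    out[hit, nm] <- 1L
  }
  out
}

#' Stratified LD scores over a base-pair window
#'
#' For SNP `j` and annotation `C`,
#' `l(j, C) = sum over SNPs k in C with |bp_k - bp_j| <= window_bp of
#' r2_adj(j, k)` where `r2_adj = r2 - (1 - r2) / (n - 2)` is the
#' small-sample bias-corrected squared correlation estimated from the panel
#' (self term included).
#'
#' @param panel Reference panel from [simulate_ld_panel()].
#' @param annot SNP-by-annotation 0/1 matrix aligned with (or rownamed by)
#'   the panel SNPs.
#' @param window_bp Window in bp (default 1e6).
#' @return Numeric matrix, SNPs x annotations, same colnames as `annot`.
#' @export
compute_ld_scores <- function(panel, annot, window_bp = 1e6) {
  geno <- panel$geno
  snps <- panel$snps
  n <- nrow(geno)
  if (n < 3L) .stopf("LD-score bias correction needs >= 3 panel samples")
  if (!is.null(rownames(annot))) {
    annot <- annot[match(snps$snp_id, rownames(annot)), , drop = FALSE]
  }
  annot <- as.matrix(annot)
  storage.mode(annot) <- "double"
  xs <- scale(geno)
  out <- matrix(0, nrow(snps), ncol(annot),
                dimnames = list(snps$snp_id, colnames(annot)))
  for (ch in unique(snps$chrom)) {
    ii <- which(snps$chrom == ch)
    bp <- snps$bp[ii]
    lo <- findInterval(bp - window_bp - 0.5, bp) + 1L
    hi <- findInterval(bp + window_bp + 0.5, bp)
    chunk_size <- 256L
    for (cs in seq(1L, length(ii), by = chunk_size)) {
      ce <- min(cs + chunk_size - 1L, length(ii))
      nb <- seq(min(lo[cs:ce]), max(hi[cs:ce]))
      r <- crossprod(xs[, ii[cs:ce], drop = FALSE],
                     xs[, ii[nb], drop = FALSE]) / (n - 1)
      r2 <- r^2
      r2 <- r2 - (1 - r2) / (n - 2)
      # zero out pairs outside each SNP's window
      in_win <- outer(bp[cs:ce], bp[nb],
                      function(a, b) abs(a - b) <= window_bp)
      r2[!in_win] <- 0
      out[ii[cs:ce], ] <- out[ii[cs:ce], ] +
        r2 %*% annot[ii[nb], , drop = FALSE]
    }
  }
  out
}

#' Munge summary statistics for LD score regression
#'
#' Drops records with `INFO <= info_min`, `MAF <= maf_min`,
#' strand-ambiguous alleles (A/T and C/G pairs), duplicated SNP IDs (all
#' occurrences) and, when `keep_snps` is given, everything outside that
#' well-imputed SNP list.
#'
#' @param ss Summary-statistics data.frame.
#' @param info_min Imputation-quality cutoff (default 0.9; records at or
#'   below are dropped; missing INFO passes).
#' @param maf_min Minor-allele-frequency cutoff (default 0.01).
#' @param keep_snps Optional character vector of SNP IDs to restrict to.
#' @return The filtered data.frame with a `report` attribute; errors if
#'   nothing survives.
#' @export
munge_for_ldsc <- function(ss, info_min = 0.9, maf_min = 0.01,
                           keep_snps = NULL) {
  report <- list(input = nrow(ss))
  bad_info <- !is.na(ss$info) & ss$info <= info_min
  bad_maf <- !is.na(ss$maf) & ss$maf <= maf_min
  al <- paste0(toupper(ss$a1), toupper(ss$a2))
  ambiguous <- al %in% c("AT", "TA", "CG", "GC")
  dup <- ss$snp_id %in% ss$snp_id[duplicated(ss$snp_id)]
  off_list <- if (is.null(keep_snps)) rep(FALSE, nrow(ss))
              else !(ss$snp_id %in% keep_snps)
  report$low_info <- sum(bad_info)
  report$low_maf <- sum(bad_maf)
  report$strand_ambiguous <- sum(ambiguous)
  report$duplicated_id <- sum(dup)
  report$off_snp_list <- sum(off_list)
  keep <- !(bad_info | bad_maf | ambiguous | dup | off_list)
  report$output <- sum(keep)
  if (!any(keep)) .stopf("no summary statistics survive munging")
  out <- ss[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "report") <- report
  out
}

# per-annotation heritability shares and enrichments implied by coefficients
.sldsc_stats <- function(tau, annot, prop_snps) {
  h2_j <- as.vector(annot %*% tau)
  h2_tot <- sum(h2_j)
  h2_c <- vapply(seq_len(ncol(annot)), function(k)
    sum(h2_j[annot[, k] > 0]), 0)
  prop_h2 <- h2_c / h2_tot
  list(h2_total = h2_tot, prop_h2 = prop_h2,
       enrichment = prop_h2 / prop_snps)
}

#' Fit stratified LD score regression with block-jackknife inference
#'
#' Weighted least squares of per-SNP chi-square statistics on
#' `N * l(j, C)` across all annotations jointly plus an intercept, with
#' `1 / max(l(j, base), 1)` weights as a heteroscedasticity and overcounting
#' proxy.  A delete-one block jackknife over `n_blocks` contiguous SNP
#' blocks yields coefficient standard errors (one-sided coefficient p) and
#' standard errors for the enrichment (proportion of heritability divided by
#' proportion of SNPs; two-sided p against 1).
#'
#' @param chisq Per-SNP chi-square statistics (squared Z), ordered along the
#'   genome.
#' @param ld LD-score matrix from [compute_ld_scores()] (must contain a
#'   `base` column).
#' @param annot The matching SNP-by-annotation 0/1 membership matrix.
#' @param N GWAS sample size (scalar or per-SNP vector).
#' @param n_blocks Number of jackknife blocks (default 200).
#' @param weight_ld Optional per-SNP total (base) LD scores used only for
#'   the regression weights; defaults to `ld[, "base"]`.  Supplying it
#'   allows fitting a disjoint exhaustive partition without the (then
#'   collinear) all-ones base column.
#' @return Data frame with one row per annotation: `annotation`, `tau`,
#'   `tau_se`, `coef_z`, `coef_p`, `prop_snps`, `prop_h2`, `enrichment`,
#'   `enrichment_se`, `enrichment_p`; attributes `intercept`, `h2_total`,
#'   `n_blocks`.
#' @export
fit_sldsc <- function(chisq, ld, annot, N, n_blocks = 200L,
                      weight_ld = NULL) {
  m <- length(chisq)
  if (n_blocks > m) .stopf("n_blocks (%d) exceeds SNP count (%d)",
                           n_blocks, m)
  if (is.null(weight_ld)) {
    if (!"base" %in% colnames(ld)) {
      .stopf("ld must contain a 'base' column (or supply weight_ld)")
    }
    weight_ld <- ld[, "base"]
  }
  annot <- as.matrix(annot)[, colnames(ld), drop = FALSE]
  storage.mode(annot) <- "double"
  X <- cbind(intercept = 1, ld * as.numeric(N))
  w <- 1 / pmax(weight_ld, 1)
  qx <- qr(sqrt(w) * X)
  if (qx$rank < ncol(X)) {
    drop_cols <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    .stopf("singular regression design; collinear annotation(s): %s",
           paste(drop_cols, collapse = ", "))
  }
  prop_snps <- colMeans(annot)
  blocks <- split(seq_len(m), ceiling(seq_len(m) / (m / n_blocks)))
  n_blocks <- length(blocks)

  wls <- function(idx) {
    lm.wfit(X[idx, , drop = FALSE], chisq[idx], w[idx])$coefficients
  }
  full <- wls(seq_len(m))
  stat_of <- function(coef) {
    tau <- coef[-1]
    s <- .sldsc_stats(tau, annot, prop_snps)
    c(tau, s$enrichment, s$h2_total)
  }
  k <- ncol(annot)
  full_stat <- stat_of(full)
  pseudo <- matrix(0, n_blocks, length(full_stat))
  for (b in seq_len(n_blocks)) {
    coef_b <- wls(setdiff(seq_len(m), blocks[[b]]))
    pseudo[b, ] <- n_blocks * full_stat - (n_blocks - 1) * stat_of(coef_b)
  }
  se <- apply(pseudo, 2L, sd) / sqrt(n_blocks)
  tau <- full_stat[seq_len(k)]
  tau_se <- se[seq_len(k)]
  enr <- full_stat[k + seq_len(k)]
  enr_se <- se[k + seq_len(k)]
  coef_z <- tau / tau_se
  s_full <- .sldsc_stats(tau, annot, prop_snps)
  is_base <- colnames(annot) == "base"
  enrichment_p <- 2 * pnorm(-abs(enr - 1) / enr_se)
  enrichment_p[is_base] <- NA_real_
  out <- data.frame(
    annotation = colnames(annot),
    tau = tau, tau_se = tau_se, coef_z = coef_z,
    coef_p = pnorm(coef_z, lower.tail = FALSE),
    prop_snps = prop_snps, prop_h2 = s_full$prop_h2,
    enrichment = enr, enrichment_se = enr_se,
    enrichment_p = enrichment_p,
    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "intercept") <- unname(full[1])
  attr(out, "h2_total") <- s_full$h2_total
  attr(out, "n_blocks") <- n_blocks
  out
}

#' Long-format significance table across fits
#'
#' Combines stratified-regression fits from a grid of runs (e.g. disease x
#' cell type), recomputes Benjamini-Hochberg q-values across all
#' non-base annotations jointly, and reports `-log10(q)` zeroed wherever the
#' coefficient z-score is negative (such enrichments are treated as
#' nonsignificant).
#'
#' @param fits Named list of [fit_sldsc()] outputs; names identify the runs
#'   (e.g. `"AD:microglia"`).
#' @return Data frame with columns `run`, `annotation`, `coef_z`,
#'   `enrichment`, `enrichment_p`, `q`, `neglog10_q`.
#' @export
enrichment_heatmap_table <- function(fits) {
  if (!length(fits)) .stopf("need at least one fit")
  if (is.null(names(fits))) names(fits) <- paste0("run", seq_along(fits))
  long <- do.call(rbind, lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    f <- f[f$annotation != "base", , drop = FALSE]
    data.frame(run = nm, annotation = f$annotation, coef_z = f$coef_z,
               enrichment = f$enrichment, enrichment_p = f$enrichment_p,
               stringsAsFactors = FALSE)
  }))
  long$q <- p.adjust(long$enrichment_p, method = "BH")
  long$neglog10_q <- ifelse(long$coef_z < 0, 0, -log10(long$q))
  rownames(long) <- NULL
  long
}
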