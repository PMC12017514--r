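# GWAS summary-statistic QC, the SNP-wise mean gene-level association test
# (sum of squared Z with an LD-aware quadratic-form null), FDR control,
# top-gene thresholding and cross-trait overlap counting.

#' Quality-control GWAS summary statistics
#'
#' Drops records with non-positive standard error (when an `se` column is
#' present), SNPs whose per-SNP sample size exceeds the mean by more than
#' `n_sd` standard deviations, and records on the X, Y and mitochondrial
#' chromosomes.  Indels and multiallelic records are kept.
#'
#' @param ss Summary-statistics data.frame ([read_sumstats()] schema).
#' @param n_sd Sample-size outlier cutoff in SDs above the mean (default 5).
#' @return The filtered data.frame with a `report` attribute counting each
#'   drop reason.  Errors if nothing survives.
#' @export
qc_sumstats <- function(ss, n_sd = 5) {
  report <- list(input = nrow(ss))
  if (!is.null(ss$se)) {
    bad_se <- !is.na(ss$se) & ss$se <= 0
  } else bad_se <- rep(FALSE, nrow(ss))
  report$se_nonpositive <- sum(bad_se)
  n_hi <- ss$n > mean(ss$n) + n_sd * sd(ss$n)
  n_hi[is.na(n_hi)] <- FALSE
  report$n_outlier <- sum(n_hi)
  chr <- toupper(sub("^CHR", "", toupper(as.character(ss$chrom))))
  sex_mito <- chr %in% c("X", "Y", "MT", "M")
  report$sex_or_mito_chrom <- sum(sex_mito)
  keep <- !bad_se & !n_hi & !sex_mito
  report$output <- sum(keep)
  if (!any(keep)) .stopf("no summary statistics survive QC")
  out <- ss[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "report") <- report
  out
}

#' Gene test statistic: sum of squared SNP Z-scores
#'
#' @param z Numeric vector of per-SNP Z-scores (length >= 1).
#' @return `sum(z^2)`.
#' @export
gene_statistic <- function(z) {
  if (!length(z)) .stopf("gene statistic needs at least one SNP")
  sum(z^2)
}

# Ruben-type series for P(sum lambda_i chi^2_1 >= q): the quadratic form is
# expanded as a mixture of central chi-square cdfs with scale beta = min
# lambda; all mixture weights are then positive, so the truncation error is
# bounded by the untouched weight mass.
.ruben_upper <- function(q, lambda, max_terms = 10000L) {
  nu <- length(lambda)
  beta <- min(lambda)
  gam <- 1 - beta / lambda
  a0 <- exp(0.5 * sum(log(beta / lambda)))
  if (!is.finite(a0) || a0 == 0) return(NA_real_)
  a <- numeric(max_terms + 1L)
  b <- numeric(max_terms)
  a[1] <- a0
  gpow <- rep(1, nu)
  # upper tail accumulated directly: all terms positive, no cancellation,
  # and the untouched weight mass bounds the truncation error
  upper <- a0 * pchisq(q / beta, nu, lower.tail = FALSE)
  mass <- a0
  for (k in seq_len(max_terms)) {
    gpow <- gpow * gam
    b[k] <- sum(gpow)
    a[k + 1L] <- sum(b[seq_len(k)] * a[k:1]) / (2 * k)
    upper <- upper + a[k + 1L] * pchisq(q / beta, nu + 2 * k,
                                        lower.tail = FALSE)
    mass <- mass + a[k + 1L]
    if (1 - mass < max(1e-14, 1e-7 * upper)) {
      return(min(upper, 1))
    }
  }
  NA_real_
}

# Imhof numerical inversion on a finite interval chosen from the analytic
# truncation bound for the integrand's envelope.
.imhof_upper <- function(q, lambda, eps = 1e-9) {
  k <- length(lambda)
  theta <- function(u) 0.5 * colSums(atan(outer(lambda, u))) - q * u / 2
  rho <- function(u) exp(0.25 * colSums(log1p(outer(lambda, u)^2)))
  f <- function(u) sin(theta(u)) / (u * rho(u))
  log_prod_sqrt <- 0.5 * sum(log(lambda))
  upper <- exp((-log(pi * eps * k / 2) - log_prod_sqrt) * 2 / k)
  upper <- min(max(upper, 50), 1e7)
  val <- integrate(f, lower = 0, upper = upper, rel.tol = 1e-8,
                   abs.tol = 1e-10, subdivisions = 10000L)$value
  0.5 + val / pi
}

#' Tail probability of a quadratic form in correlated normals
#'
#' Computes `p = P(sum_i lambda_i chi^2_1 >= stat)` where the `lambda_i` are
#' the eigenvalues of the LD correlation matrix `R` - the null distribution
#' of the sum-of-squared-Z gene statistic when the SNP Z-scores are
#' `MVN(0, R)`.  Evaluated by a Ruben-type chi-square mixture series with a
#' computable truncation bound, falling back to Imhof's numerical inversion
#' and finally to a Satterthwaite-Welch gamma approximation when the series
#' does not converge.
#'
#' @param stat Observed statistic (sum of squared Z-scores).
#' @param R Symmetric SNP correlation matrix.  A ridge of `ridge` is added
#'   when the smallest eigenvalue is negative; negative eigenvalues are then
#'   truncated at zero.
#' @param ridge Diagonal regularization (default 1e-6).
#' @return The p-value, floored at the smallest positive double.
#' @export
quadform_pvalue <- function(stat, R, ridge = 1e-6) {
  R <- as.matrix(R)
  if (!isSymmetric(unname(R), tol = 1e-8)) {
    .stopf("LD matrix must be symmetric")
  }
  lambda <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(lambda) < 0) {
    if (min(lambda) < -1e-8) {
      lambda <- eigen(R + diag(ridge, nrow(R)), symmetric = TRUE,
                      only.values = TRUE)$values
    }
    lambda <- pmax(lambda, 0)
  }
  lambda <- lambda[lambda > 1e-12]
  if (!length(lambda) || stat <= 0) return(1)
  satterthwaite <- function() {
    scale <- sum(lambda^2) / sum(lambda)
    df <- sum(lambda)^2 / sum(lambda^2)
    pchisq(stat / scale, df = df, lower.tail = FALSE)
  }
  p <- tryCatch(.ruben_upper(stat, lambda), error = function(e) NA_real_)
  if (is.na(p)) {
    p <- tryCatch(.imhof_upper(stat, lambda), error = function(e) NA_real_)
    if (is.na(p) || p < -1e-6 || p > 1 + 1e-6) p <- satterthwaite()
  }
  if (p < 1e-12) p <- max(p, satterthwaite(), .Machine$double.xmin)
  min(max(p, .Machine$double.xmin), 1)
}

#' Run LD-aware gene-level association tests
#'
#' For each gene in the annotation map, collects the Z-scores of its SNPs
#' (those present in both the summary statistics and the reference panel),
#' computes the sum-of-squared-Z statistic, and evaluates its tail
#' probability against the quadratic-form null with the panel-derived SNP
#' correlation matrix.  Benjamini-Hochberg q-values are computed across all
#' tested genes; `significant` flags `q < fdr`.
#'
#' @param map A [gene_snp_map()].
#' @param ss Summary-statistics data.frame.
#' @param panel Reference panel from [simulate_ld_panel()] (or any list with
#'   `geno` column-named by SNP ID).
#' @param fdr Significance threshold on the q-value (default 0.05).
#' @return Data frame with columns `gene_id`, `n_snps`, `stat`, `p`, `q`,
#'   `mean_n`, `significant`, plus a `skipped` attribute naming genes with
#'   no usable SNPs.
#' @export
run_gene_tests <- function(map, ss, panel, fdr = 0.05) {
  usable <- intersect(ss$snp_id, colnames(panel$geno))
  rows <- vector("list", length(map$snps))
  skipped <- character()
  for (i in seq_along(map$snps)) {
    g <- names(map$snps)[i]
    ids <- intersect(map$snps[[i]], usable)
    if (!length(ids)) {
      skipped <- c(skipped, g)
      next
    }
    z <- ss$z[match(ids, ss$snp_id)]
    stat <- gene_statistic(z)
    R <- if (length(ids) == 1L) matrix(1, 1, 1)
         else cor(panel$geno[, ids, drop = FALSE])
    rows[[i]] <- data.frame(
      gene_id = g, n_snps = length(ids), stat = stat,
      p = quadform_pvalue(stat, R),
      mean_n = mean(ss$n[match(ids, ss$snp_id)]),
      stringsAsFactors = FALSE)
  }
  if (length(skipped)) {
    message(length(skipped), " genes skipped: no SNPs in panel/sumstats")
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out)) .stopf("no genes could be tested")
  out$q <- p.adjust(out$p, method = "BH")
  out$significant <- out$q < fdr
  out <- out[c("gene_id", "n_snps", "stat", "p", "q", "mean_n",
               "significant")]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Genes below a p-value threshold
#'
#' @param results Output of [run_gene_tests()].
#' @param threshold P-value cutoff (e.g. 5e-8, or 5e-12 for very
#'   well-powered GWAS).
#' @return Character vector of gene IDs with `p < threshold`.
#' @export
top_genes <- function(results, threshold) {
  if (threshold <= 0) .stopf("threshold must be positive")
  results$gene_id[results$p < threshold]
}

#' Exclusive intersection counts across named gene sets
#'
#' For every non-empty combination of the input sets, counts the elements
#' belonging to exactly that combination (the quantities an UpSet plot
#' displays); counts sum to the size of the union.
#'
#' @param sets Named list of >= 2 character vectors.
#' @return Data frame with columns `combination` (set names joined by
#'   `"&"`), `degree` and `count`.
#' @export
overlap_counts <- function(sets) {
  if (length(sets) < 2L) .stopf("need at least two sets")
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    .stopf("sets must be named")
  }
  universe <- unique(unlist(sets))
  memb <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1L) memb <- matrix(memb, nrow = 1L,
                                             dimnames = list(NULL, names(sets)))
  pattern <- apply(memb, 1L, function(r) paste(names(sets)[r],
                                               collapse = "&"))
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), length(sets)))
  combos <- combos[rowSums(combos) > 0, , drop = FALSE]
  combo_names <- apply(combos, 1L, function(r)
    paste(names(sets)[as.logical(r)], collapse = "&"))
  tab <- table(pattern)
  data.frame(
    combination = combo_names,
    degree = rowSums(combos),
    count = as.integer(ifelse(combo_names %in% names(tab),
                              tab[combo_names], 0L)),
    row.names = NULL, stringsAsFactors = FALSE)
}
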