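# Expression-weighted cell-type enrichment (bootstrap) and hypergeometric
# pathway over-representation with duplicate-pathway collapsing.

#' Expression specificity matrix
#'
#' Specificity of gene `g` in cell type `c` is the gene's mean expression in
#' `c` divided by the sum of its means across all cell types, so rows sum
#' to 1.  Genes with zero total expression are dropped with a message.
#'
#' @param expr Nonnegative gene-by-cell-type matrix of mean expression.
#' @return Row-normalized matrix of the same shape (minus dropped genes).
#' @export
make_specificity <- function(expr) {
  expr <- as.matrix(expr)
  if (any(expr < 0)) .stopf("expression values must be nonnegative")
  tot <- rowSums(expr)
  if (any(tot == 0)) {
    message(sum(tot == 0), " all-zero genes dropped from specificity matrix")
  }
  expr <- expr[tot > 0, , drop = FALSE]
  sweep(expr, 1L, rowSums(expr), "/")
}

#' Bootstrap cell-type enrichment of a gene set
#'
#' The observed score per cell type is the summed specificity of the target
#' genes; the null distribution is obtained by resampling gene sets of the
#' same size (distinct genes, uniformly from the matrix universe, matching
#' how a target list is constituted) `n_boot` times.  The
#' empirical p-value is `(1 + #(boot >= obs)) / (n_boot + 1)` (never zero)
#' and `z = (obs - boot mean) / boot SD`.
#'
#' @param target_genes Character vector of gene IDs; those absent from the
#'   matrix are dropped with a message.
#' @param spec Specificity matrix from [make_specificity()].
#' @param n_boot Number of bootstrap resamples (default 10000).
#' @param seed Integer seed.
#' @param min_genes Minimum usable target genes (default 4).
#' @param alpha Significance level for the `significant` flag (default
#'   0.05).
#' @return Data frame with one row per cell type: `cell_type`, `observed`,
#'   `boot_mean`, `boot_sd`, `z`, `p`, `significant`.
#' @export
ewce_test <- function(target_genes, spec, n_boot = 10000L, seed = 1L,
                      min_genes = 4L, alpha = 0.05) {
  target_genes <- unique(target_genes)
  missing <- setdiff(target_genes, rownames(spec))
  if (length(missing)) {
    message(length(missing), " target genes absent from the matrix dropped")
  }
  target <- intersect(target_genes, rownames(spec))
  if (length(target) < min_genes) {
    .stopf("only %d target genes in the matrix (minimum %d)",
           length(target), min_genes)
  }
  nt <- length(target)
  obs <- colSums(spec[target, , drop = FALSE])
  .with_seed(seed, {
    # resampled sets mimic the target: nt distinct genes, drawn uniformly
    draws <- matrix(0L, n_boot, nt)
    for (b in seq_len(n_boot)) draws[b, ] <- sample.int(nrow(spec), nt)
    boot <- vapply(seq_len(ncol(spec)), function(cc) {
      rowSums(matrix(spec[, cc][draws], n_boot, nt))
    }, numeric(n_boot))
    bm <- colMeans(boot)
    bs <- apply(boot, 2L, sd)
    p <- vapply(seq_len(ncol(spec)), function(cc) {
      (1 + sum(boot[, cc] >= obs[cc])) / (n_boot + 1)
    }, 0)
    data.frame(cell_type = colnames(spec), observed = unname(obs),
               boot_mean = bm, boot_sd = bs,
               z = (unname(obs) - bm) / bs, p = p,
               significant = p < alpha,
               row.names = NULL, stringsAsFactors = FALSE)
  })
}

#' Pathway database
#'
#' @param pathways Named list: pathway ID -> character vector of gene IDs.
#' @param universe Character vector of background genes; pathway genes must
#'   all be contained in it.
#' @return A `pathway_db` list.
#' @export
pathway_db <- function(pathways, universe) {
  universe <- unique(universe)
  outside <- setdiff(unique(unlist(pathways)), universe)
  if (length(outside)) {
    .stopf("pathway genes outside the universe: %s",
           paste(head(outside, 3), collapse = ", "))
  }
  structure(list(pathways = lapply(pathways, unique), universe = universe),
            class = "pathway_db")
}

#' Hypergeometric over-representation test
#'
#' For each pathway, tests whether the target gene set overlaps it more
#' than expected under uniform sampling from the universe:
#' `p = P(X >= k)` for hypergeometric `X` with the pathway as successes and
#' the target size as draws.  Target genes outside the universe are dropped
#' with a message; input order is accepted but ignored by the test.
#' Benjamini-Hochberg q-values are computed across pathways.
#'
#' @param target_genes Character vector of genes (e.g. significant risk
#'   genes).
#' @param db A [pathway_db()].
#' @param alpha Significance level on the q-value (default 0.05).
#' @return Data frame with columns `pathway`, `pathway_size`, `overlap`,
#'   `p`, `q`, `significant`.
#' @export
ora_test <- function(target_genes, db, alpha = 0.05) {
  stopifnot(inherits(db, "pathway_db"))
  target <- unique(target_genes)
  if (!length(target)) .stopf("empty target gene set")
  outside <- setdiff(target, db$universe)
  if (length(outside)) {
    message(length(outside), " target genes outside the universe dropped")
    target <- setdiff(target, outside)
  }
  if (!length(target)) .stopf("no target genes inside the universe")
  nu <- length(db$universe)
  nt <- length(target)
  res <- do.call(rbind, lapply(names(db$pathways), function(pw) {
    genes <- db$pathways[[pw]]
    k <- length(intersect(target, genes))
    data.frame(pathway = pw, pathway_size = length(genes), overlap = k,
               p = phyper(k - 1, length(genes), nu - length(genes), nt,
                          lower.tail = FALSE),
               stringsAsFactors = FALSE)
  }))
  res$q <- p.adjust(res$p, method = "BH")
  res$significant <- res$q < alpha
  rownames(res) <- NULL
  res
}

#' Collapse pathways with identical gene sets
#'
#' Among pathways whose gene sets are identical, keeps exactly one: by
#' default the one with the highest FDR-corrected p-value (the printed
#' convention of the upstream enrichment tool); `rule = "lowest_q"` keeps
#' the most significant instead.  The others are flagged in a `collapsed`
#' column.
#'
#' @param results Output of [ora_test()] (needs `pathway` and `q`).
#' @param db The [pathway_db()] used for the test.
#' @param rule `"highest_q"` (default) or `"lowest_q"`.
#' @return `results` with an added logical `collapsed` column; kept rows are
#'   `FALSE`.
#' @export
collapse_duplicate_pathways <- function(results, db,
                                        rule = c("highest_q", "lowest_q")) {
  rule <- match.arg(rule)
  key <- vapply(results$pathway, function(pw) {
    paste(sort(db$pathways[[pw]]), collapse = "|")
  }, "")
  collapsed <- rep(FALSE, nrow(results))
  for (k in unique(key)) {
    ii <- which(key == k)
    if (length(ii) < 2L) next
    keep <- if (rule == "highest_q") ii[which.max(results$q[ii])]
            else ii[which.min(results$q[ii])]
    collapsed[setdiff(ii, keep)] <- TRUE
  }
  results$collapsed <- collapsed
  results
}
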