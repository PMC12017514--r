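# End-to-end orchestration: simulate -> classify loops -> build annotation
# -> gene tests -> stratified heritability -> cell-type and pathway
# enrichment -> cross-mode overlaps, with validation, per-stage outputs and
# a reproducibility manifest.

#' Pipeline configuration
#'
#' Collects every stage parameter with the study's default values: loop FDR
#' cutoff 0.01, 60,000-loop downsampling repeated 10 times, gene q-value
#' 0.05, top-gene p thresholds 5e-8 and 5e-12, and a root seed from which
#' each stage derives its own.
#'
#' @param seed Root seed.
#' @param outdir Output directory (created if absent).
#' @param sim A [sim_config()]; defaults to `sim_config(seed = seed)` with a
#'   50% heritability share on the enhancer annotation.
#' @param fdr_max Loop interaction FDR cutoff.
#' @param downsample_n Loop count for the downsampling stage; iterations are
#'   skipped with a note when it exceeds the simulated loop count.
#' @param downsample_iters Number of downsampling iterations.
#' @param gene_q Gene-level FDR threshold.
#' @param top_thresholds Numeric vector of top-gene p cutoffs.
#' @param n_boot Bootstrap resamples for the cell-type enrichment.
#' @param window_bp LD-score window in bp; sized to cover the panel's
#'   LD-block reach with margin (wider windows only add regressor noise
#'   from a finite panel).
#' @param n_jackknife Jackknife block count for the stratified regression.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L,
                            outdir = file.path(tempdir(), "chromrisk_run"),
                            sim = NULL,
                            fdr_max = 0.01,
                            downsample_n = 60000L,
                            downsample_iters = 10L,
                            gene_q = 0.05,
                            top_thresholds = c(5e-8, 5e-12),
                            n_boot = 1000L,
                            window_bp = 5e4,
                            n_jackknife = 50L) {
  if (is.null(sim)) {
    sim <- sim_config(seed = seed, enrichment_spec = c(enhancer = 0.5))
  }
  structure(list(seed = as.integer(seed), outdir = outdir, sim = sim,
                 fdr_max = fdr_max, downsample_n = as.integer(downsample_n),
                 downsample_iters = as.integer(downsample_iters),
                 gene_q = gene_q, top_thresholds = top_thresholds,
                 n_boot = as.integer(n_boot), window_bp = window_bp,
                 n_jackknife = as.integer(n_jackknife)),
            class = c("pipeline_config", "list"))
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the [pipeline_config()] arguments; a `sim` block
#' holds [sim_config()] arguments.
#'
#' @param path Path to a YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- y$sim
  y$sim <- NULL
  cfg <- do.call(pipeline_config, y)
  if (!is.null(sim_args)) {
    if (!is.null(sim_args$enrichment_spec)) {
      sim_args$enrichment_spec <- unlist(sim_args$enrichment_spec)
    }
    if (is.null(sim_args$seed)) sim_args$seed <- cfg$seed
    cfg$sim <- do.call(sim_config, sim_args)
  }
  cfg
}

#' Validate a pipeline configuration
#'
#' Collects every invariant violation instead of stopping at the first.
#'
#' @param cfg A `pipeline_config`.
#' @return Character vector of violations; empty when the config is valid.
#' @export
validate_config <- function(cfg) {
  bad <- character()
  chk <- function(cond, msg) if (!isTRUE(cond)) bad <<- c(bad, msg)
  chk(inherits(cfg, "pipeline_config"), "not a pipeline_config")
  chk(is.numeric(cfg$fdr_max) && cfg$fdr_max > 0 && cfg$fdr_max <= 1,
      "fdr_max must be in (0, 1]")
  chk(all(cfg$top_thresholds > 0), "top-gene thresholds must be positive")
  chk(cfg$gene_q > 0 && cfg$gene_q < 1, "gene_q must be in (0, 1)")
  chk(cfg$downsample_n > 0, "downsample_n must be positive")
  chk(cfg$downsample_iters > 0, "downsample_iters must be positive")
  chk(cfg$n_boot > 1, "n_boot must exceed 1")
  chk(cfg$window_bp > 0, "window_bp must be positive")
  chk(cfg$n_jackknife > 1, "n_jackknife must exceed 1")
  chk(inherits(cfg$sim, "sim_config"), "sim must be a sim_config")
  bad
}

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline on simulated inputs
#'
#' Executes the stages in dependency order - genome/loop simulation, loop
#' classification, LD panel and GWAS simulation, SNP-to-gene annotation
#' (full, positional-only, enhancer-only and 10 kb-window modes), gene-level
#' association, loop downsampling, stratified heritability regression,
#' cell-type enrichment and pathway over-representation, and cross-mode gene
#' overlaps - writing per-stage TSV outputs plus a manifest with the config,
#' stage seeds and output checksums.  A failing stage stops the run with the
#' stage named.
#'
#' @param cfg A [pipeline_config()]; validated first, and all violations are
#'   reported together.
#' @return Invisibly, a list with all stage results and the `manifest`.
#' @export
run_pipeline <- function(cfg) {
  bad <- validate_config(cfg)
  if (length(bad)) .stopf("invalid config:\n  - %s",
                          paste(bad, collapse = "\n  - "))
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      .stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  stage("simulate", {
    out$genome <- simulate_genome(cfg$sim)
    write_gene_model(out$genome$genes, file.path(cfg$outdir, "genes.tsv"))
    for (pk in names(out$genome$peaks)) {
      write_bed(out$genome$peaks[[pk]],
                file.path(cfg$outdir, paste0(pk, ".bed")))
    }
    write_bedpe_loops(out$genome$loops, file.path(cfg$outdir, "loops.tsv"))
  })

  stage("classify-loops", {
    out$annotated_loops <- annotate_loops(out$genome$loops,
                                          out$genome$peaks, out$genome$genes)
    out$category_counts <- category_counts(out$annotated_loops)
    out$degrees <- degree_distributions(out$annotated_loops)
    out$distances <- distance_stats(out$annotated_loops)
    .write_tsv(out$category_counts,
               file.path(cfg$outdir, "loop_categories.tsv"))
  })

  stage("simulate-gwas", {
    out$panel <- simulate_ld_panel(cfg$sim)
    bin_labels <- out$genome$truth$bin_labels
    out$annot_matrix <- bins_to_annotations(bin_labels, out$panel$snps)
    gw <- simulate_gwas(out$panel, out$annot_matrix, cfg$sim)
    out$sumstats <- gw$sumstats
    out$truth <- gw$truth
    write_sumstats(out$sumstats, file.path(cfg$outdir, "sumstats.tsv"))
  })

  stage("build-annot", {
    tss <- tss_sites(out$genome$genes)
    k27 <- out$genome$peaks$h3k27ac
    enhancer_regions <- k27[.dist_to_points(k27, tss) > 2000, , drop = FALSE]
    out$qc <- qc_sumstats(out$sumstats)
    out$maps <- list(
      full = build_annotation("full", out$qc, out$genome$genes,
                              out$genome$loops, enhancer_regions,
                              fdr_max = cfg$fdr_max),
      positional_only = build_annotation("positional_only", out$qc,
                                         out$genome$genes, out$genome$loops,
                                         enhancer_regions,
                                         fdr_max = cfg$fdr_max),
      enhancer_only = build_annotation("enhancer_only", out$qc,
                                       out$genome$genes, out$genome$loops,
                                       enhancer_regions,
                                       fdr_max = cfg$fdr_max),
      window10kb = build_annotation("window10kb", out$qc, out$genome$genes))
    write_magma_annot(out$maps$full,
                      file.path(cfg$outdir, "full.genes.annot"))
  })

  stage("gene-assoc", {
    out$gene_tests <- lapply(out$maps, function(m) {
      if (!length(m$snps)) return(NULL)
      run_gene_tests(m, out$qc, out$panel, fdr = cfg$gene_q)
    })
    .write_tsv(out$gene_tests$full,
               file.path(cfg$outdir, "gene_tests_full.tsv"))
  })

  stage("downsample", {
    n_loops <- nrow(out$genome$loops)
    if (cfg$downsample_n > n_loops) {
      message("downsampling skipped: ", cfg$downsample_n, " > ", n_loops,
              " loops")
      out$downsample <- NULL
    } else {
      tss <- tss_sites(out$genome$genes)
      k27 <- out$genome$peaks$h3k27ac
      enh <- k27[.dist_to_points(k27, tss) > 2000, , drop = FALSE]
      counts <- vapply(seq_len(cfg$downsample_iters) - 1L, function(it) {
        dl <- downsample_loops(out$genome$loops, cfg$downsample_n,
                               seed = cfg$seed + it)
        m <- build_annotation("full", out$qc, out$genome$genes, dl, enh,
                              fdr_max = cfg$fdr_max)
        gt <- run_gene_tests(m, out$qc, out$panel, fdr = cfg$gene_q)
        sum(gt$significant)
      }, 0)
      out$downsample <- data.frame(iteration = seq_along(counts),
                                   n_significant_genes = counts)
      .write_tsv(out$downsample, file.path(cfg$outdir, "downsample.tsv"))
    }
  })

  stage("sldsc", {
    munged <- munge_for_ldsc(out$qc)
    keep <- match(munged$snp_id, out$panel$snps$snp_id)
    panel_m <- list(geno = out$panel$geno[, keep, drop = FALSE],
                    snps = out$panel$snps[keep, , drop = FALSE])
    annot_m <- out$annot_matrix[keep, , drop = FALSE]
    keep_cols <- colnames(annot_m)[colSums(annot_m) > 0]
    annot_m <- annot_m[, keep_cols, drop = FALSE]
    ld <- compute_ld_scores(panel_m, annot_m, window_bp = cfg$window_bp)
    out$sldsc <- fit_sldsc(munged$z^2, ld, annot_m, N = munged$n,
                           n_blocks = min(cfg$n_jackknife, nrow(munged)))
    out$heatmap <- enrichment_heatmap_table(list(sim = out$sldsc))
    .write_tsv(out$sldsc, file.path(cfg$outdir, "sldsc.tsv"))
  })

  stage("ewce", {
    expr <- simulate_expression(cfg$sim,
                                unique(out$genome$genes$transcripts$gene_id))
    out$specificity <- make_specificity(expr)
    gt <- out$gene_tests$full
    target <- gt$gene_id[gt$significant]
    if (length(target) < 4L) {
      target <- gt$gene_id[order(gt$p)][seq_len(min(10L, nrow(gt)))]
    }
    out$ewce <- ewce_test(target, out$specificity, n_boot = cfg$n_boot,
                          seed = .child_seed(cfg$seed, 5L))
    out$markers <- attr(expr, "markers")
    .write_tsv(out$ewce, file.path(cfg$outdir, "ewce.tsv"))
  })

  stage("ora", {
    universe <- rownames(out$specificity)
    pathways <- out$markers
    names(pathways) <- paste0("markers_", names(pathways))
    extra <- .with_seed(.child_seed(cfg$seed, 6L), {
      lapply(1:4, function(i) sample(universe, min(15L, length(universe))))
    })
    names(extra) <- paste0("random_", 1:4)
    pathways <- c(pathways, extra)
    pathways$random_dup <- pathways$random_1   # identical set, for collapsing
    db <- pathway_db(pathways, universe)
    gt <- out$gene_tests$full
    target <- gt$gene_id[gt$significant]
    if (!length(target)) target <- gt$gene_id[order(gt$p)][1:5]
    out$ora <- collapse_duplicate_pathways(ora_test(target, db), db)
    .write_tsv(out$ora, file.path(cfg$outdir, "ora.tsv"))
  })

  stage("overlap", {
    sets <- lapply(out$gene_tests[c("full", "positional_only",
                                    "enhancer_only")], function(gt) {
      if (is.null(gt)) character() else gt$gene_id[gt$significant]
    })
    out$overlaps <- overlap_counts(sets)
    .write_tsv(out$overlaps, file.path(cfg$outdir, "overlaps.tsv"))
  })

  files <- list.files(cfg$outdir, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  manifest <- list(
    package_version = as.character(utils::packageVersion("chromrisk")),
    seed = cfg$seed,
    stage_seeds = vapply(1:6, function(s) .child_seed(cfg$seed, s), 0),
    config_hash = unname(tools::md5sum(
      .write_tsv(data.frame(key = "config",
                            value = paste(deparse(unclass(cfg)[
                              setdiff(names(cfg), "outdir")]),
                              collapse = "")),
                 file.path(cfg$outdir, "config_echo.tsv")))),
    checksums = as.list(tools::md5sum(sort(files)))
  )
  names(manifest$checksums) <- basename(sort(files))
  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  out$manifest <- manifest
  invisible(out)
}
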