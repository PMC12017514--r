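# Readers/writers and core coordinate containers.
#
# Conventions: all coordinates are BED-style 0-based half-open [start, end).
# Peaks/bins/promoters/exons are plain data.frames with columns
# chrom/start/end(/strand); chromatin loops are a "loop_set" data.frame;
# summary statistics a "sumstats"-shaped data.frame; SNP-to-gene annotations
# a "gene_snp_map" object mirroring the MAGMA .genes.annot dialect.

.validate_intervals <- function(df, what = "interval") {
  bad <- which(!(df$start < df$end))
  if (length(bad)) {
    .stopf("%s %d has start >= end (%d >= %d)", what, bad[1],
           df$start[bad[1]], df$end[bad[1]])
  }
  bad <- which(df$start < 0)
  if (length(bad)) .stopf("%s %d has negative start", what, bad[1])
  invisible(df)
}

#' Read a BED file of peaks or bins
#'
#' Reads a tab-delimited BED file (>= 3 columns, 0-based half-open) into a
#' data frame of validated genomic intervals sorted by chromosome and start.
#'
#' @param path Path to a BED file.
#' @return A data.frame with columns `chrom`, `start`, `end`, `strand`
#'   (`"."` when the file has no strand column) and, when present, `name`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    .stopf("malformed BED line %d in '%s': fewer than 3 columns",
           which(nf < 3L)[1], path)
  }
  chrom <- vapply(fields, `[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[`, "", 3L)))
  if (anyNA(start) || anyNA(end)) {
    .stopf("malformed BED line %d in '%s': non-numeric coordinates",
           which(is.na(start) | is.na(end))[1], path)
  }
  name <- if (all(nf >= 4L)) vapply(fields, `[`, "", 4L) else NULL
  strand <- if (all(nf >= 6L)) vapply(fields, `[`, "", 6L) else
    rep(".", length(chrom))
  strand[!strand %in% c("+", "-")] <- "."
  df <- data.frame(chrom = chrom, start = start, end = end,
                   strand = strand, stringsAsFactors = FALSE)
  if (!is.null(name)) df$name <- name
  bad <- which(!(df$start < df$end) | df$start < 0)
  if (length(bad)) {
    .stopf("malformed BED line %d in '%s': invalid interval [%d, %d)",
           bad[1], path, df$start[bad[1]], df$end[bad[1]])
  }
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write intervals as BED
#'
#' @param df Data frame with `chrom`, `start`, `end` and optionally `strand`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  .validate_intervals(df)
  out <- data.frame(df$chrom, df$start, df$end)
  if (!is.null(df$strand)) {
    out$name <- if (!is.null(df$name)) df$name else "."
    out$score <- 0L
    out$strand <- df$strand
  }
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# ---- loop sets -------------------------------------------------------------

#' Construct a loop set from anchor-pair records
#'
#' Anchors are fixed-width bins at the declared resolution.  Pairs are
#' unordered: records are canonicalized so the lexicographically smaller
#' anchor comes first, and duplicate canonical pairs are collapsed keeping
#' the minimum interaction FDR.
#'
#' @param df Data frame with columns `chromA`, `startA`, `endA`, `chromB`,
#'   `startB`, `endB`, `fdr` (0-based half-open anchors).
#' @param resolution Anchor bin width in bp (default 5000).
#' @param cell_type Optional cell-type label stored as an attribute.
#' @return A `loop_set` data.frame (canonical, deduplicated, sorted) with
#'   attributes `resolution` and `cell_type`.
#' @export
loop_set <- function(df, resolution = 5000L, cell_type = NA_character_) {
  need <- c("chromA", "startA", "endA", "chromB", "startB", "endB", "fdr")
  miss <- setdiff(need, names(df))
  if (length(miss)) .stopf("loop records lack column(s): %s",
                           paste(miss, collapse = ", "))
  df <- as.data.frame(df)[need]
  wA <- df$endA - df$startA
  wB <- df$endB - df$startB
  bad <- which(wA != resolution | wB != resolution)
  if (length(bad)) {
    .stopf("loop %d: anchor width (%d/%d) != resolution %d",
           bad[1], wA[bad[1]], wB[bad[1]], resolution)
  }
  if (any(df$fdr < 0 | df$fdr > 1)) {
    .stopf("loop %d: fdr outside [0, 1]", which(df$fdr < 0 | df$fdr > 1)[1])
  }
  swap <- df$chromB < df$chromA |
    (df$chromB == df$chromA & df$startB < df$startA)
  if (any(swap)) {
    tmp <- df[swap, c("chromA", "startA", "endA")]
    df[swap, c("chromA", "startA", "endA")] <-
      df[swap, c("chromB", "startB", "endB")]
    df[swap, c("chromB", "startB", "endB")] <- tmp
  }
  key <- paste(df$chromA, df$startA, df$chromB, df$startB)
  if (anyDuplicated(key)) {
    fdr_min <- tapply(df$fdr, key, min)
    df <- df[!duplicated(key), , drop = FALSE]
    df$fdr <- as.numeric(fdr_min[paste(df$chromA, df$startA,
                                       df$chromB, df$startB)])
  }
  df <- df[order(df$chromA, df$startA, df$chromB, df$startB), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, resolution = as.integer(resolution), cell_type = cell_type,
            class = c("loop_set", "data.frame"))
}

#' Read chromatin loops from a BEDPE-with-FDR file
#'
#' @param path Path to a tab-delimited file with columns
#'   chromA, startA, endA, chromB, startB, endB, fdr and a header line.
#' @inheritParams loop_set
#' @return A `loop_set`; see [loop_set()].
#' @export
read_bedpe_loops <- function(path, resolution = 5000L,
                             cell_type = NA_character_) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  loop_set(df, resolution = resolution, cell_type = cell_type)
}

#' Write a loop set to a BEDPE-with-FDR file
#'
#' @param loops A `loop_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedpe_loops <- function(loops, path) {
  write.table(as.data.frame(loops), path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# ---- gene models -----------------------------------------------------------

#' Construct a gene model from per-transcript records
#'
#' @param transcripts Data frame with columns `gene_id`, `transcript_id`,
#'   `chrom`, `strand` (`+`/`-`), `tss` (0-based bp of the transcription
#'   start site).
#' @param exons Data frame with columns `gene_id`, `transcript_id`, `chrom`,
#'   `start`, `end`, `strand` (0-based half-open).
#' @return A `gene_model` object: `list(transcripts =, exons =)`.
#' @details Every transcript must have at least one exon, and the TSS must
#'   coincide with the strand-appropriate transcript end: the first base of
#'   the leftmost exon on `+`, the last base of the rightmost exon on `-`.
#' @export
gene_model <- function(transcripts, exons) {
  transcripts <- as.data.frame(transcripts)
  exons <- as.data.frame(exons)
  .validate_intervals(exons, "exon")
  if (any(!nzchar(transcripts$gene_id))) .stopf("empty gene_id")
  if (anyDuplicated(transcripts$transcript_id)) {
    .stopf("duplicate transcript_id '%s'",
           transcripts$transcript_id[duplicated(transcripts$transcript_id)][1])
  }
  for (i in seq_len(nrow(transcripts))) {
    tid <- transcripts$transcript_id[i]
    ex <- exons[exons$transcript_id == tid, , drop = FALSE]
    if (!nrow(ex)) .stopf("transcript '%s' has no exons", tid)
    tss <- transcripts$tss[i]
    ok <- if (transcripts$strand[i] == "+") tss == min(ex$start)
          else tss == max(ex$end) - 1L
    if (!ok) {
      .stopf("transcript '%s': tss %d does not match its %s-strand 5' end",
             tid, tss, transcripts$strand[i])
    }
  }
  structure(list(transcripts = transcripts, exons = exons),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("gene_model: %d genes, %d transcripts, %d exons\n",
              length(unique(x$transcripts$gene_id)),
              nrow(x$transcripts), nrow(x$exons)))
  invisible(x)
}

#' Read a gene model from TSV
#'
#' Expects a header and columns `gene_id`, `transcript_id`, `chrom`,
#' `strand`, `tss`, `exon_starts`, `exon_ends`, the last two comma-separated
#' lists of 0-based half-open exon coordinates.
#'
#' @param path Path to the TSV file.
#' @return A [gene_model()].
#' @export
read_gene_model <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  starts <- strsplit(as.character(df$exon_starts), ",", fixed = TRUE)
  ends <- strsplit(as.character(df$exon_ends), ",", fixed = TRUE)
  nex <- lengths(starts)
  if (any(nex != lengths(ends))) {
    .stopf("row %d of '%s': exon_starts/exon_ends length mismatch",
           which(nex != lengths(ends))[1], path)
  }
  exons <- data.frame(
    gene_id = rep(df$gene_id, nex),
    transcript_id = rep(df$transcript_id, nex),
    chrom = rep(df$chrom, nex),
    start = as.integer(unlist(starts)),
    end = as.integer(unlist(ends)),
    strand = rep(df$strand, nex),
    stringsAsFactors = FALSE
  )
  gene_model(df[c("gene_id", "transcript_id", "chrom", "strand", "tss")],
             exons)
}

#' Write a gene model to TSV
#'
#' @param genes A [gene_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_model <- function(genes, path) {
  tr <- genes$transcripts
  ex <- genes$exons
  fmt <- function(tid, col) {
    e <- ex[ex$transcript_id == tid, , drop = FALSE]
    e <- e[order(e$start), , drop = FALSE]
    paste(e[[col]], collapse = ",")
  }
  tr$exon_starts <- vapply(tr$transcript_id, fmt, "", col = "start")
  tr$exon_ends <- vapply(tr$transcript_id, fmt, "", col = "end")
  write.table(tr, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Transcription start sites of a gene model
#'
#' @param genes A [gene_model()].
#' @return Data frame with one row per transcript: `gene_id`,
#'   `transcript_id`, `chrom`, `bp` (TSS position), `strand`.
#' @export
tss_sites <- function(genes) {
  tr <- genes$transcripts
  data.frame(gene_id = tr$gene_id, transcript_id = tr$transcript_id,
             chrom = tr$chrom, bp = tr$tss, strand = tr$strand,
             stringsAsFactors = FALSE)
}

# ---- GWAS summary statistics ----------------------------------------------

#' Read GWAS summary statistics
#'
#' Reads a tab-delimited file with header columns `SNP`, `CHR`, `BP`, `A1`,
#' `A2` and at least one of `Z` or (`P` plus `BETA` or `OR`); `N`, `INFO`,
#' `MAF` and `SE` are optional.  When `Z` is absent it is derived from the
#' p-value and the effect sign as `z = sign * qnorm(1 - p/2)`; when `P` is
#' absent it is derived as `p = 2 * pnorm(-|z|)`.
#'
#' @param path Path to the file.
#' @param n_default Sample size used to fill a missing `N` column; the number
#'   of filled records is reported with a message.
#' @return A data.frame with columns `snp_id`, `chrom`, `bp`, `a1`, `a2`,
#'   `z`, `p`, `n`, `info`, `maf` (and `se` when present in the input).
#' @export
read_sumstats <- function(path, n_default = 1e5) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  names(df) <- toupper(names(df))
  need <- c("SNP", "CHR", "BP", "A1", "A2")
  miss <- setdiff(need, names(df))
  if (length(miss)) .stopf("sumstats lack column(s): %s",
                           paste(miss, collapse = ", "))
  has_z <- "Z" %in% names(df)
  has_p <- "P" %in% names(df)
  if (!has_z && !has_p) .stopf("sumstats need a Z or a P column")
  if (has_z) {
    z <- as.numeric(df$Z)
    p <- if (has_p) as.numeric(df$P) else 2 * pnorm(-abs(z))
  } else {
    p <- as.numeric(df$P)
    if (any(p <= 0 | p > 1, na.rm = TRUE)) .stopf("p-values outside (0, 1]")
    sgn <- if ("BETA" %in% names(df)) sign(as.numeric(df$BETA))
           else if ("OR" %in% names(df)) sign(log(as.numeric(df$OR)))
           else .stopf("sumstats without Z need BETA or OR for the effect sign")
    z <- sgn * qnorm(p / 2, lower.tail = FALSE)
  }
  if ("N" %in% names(df)) {
    n <- as.numeric(df$N)
    if (anyNA(n)) {
      message(sum(is.na(n)), " records without N filled with ", n_default)
      n[is.na(n)] <- n_default
    }
  } else {
    message(nrow(df), " records without N filled with ", n_default)
    n <- rep(n_default, nrow(df))
  }
  out <- data.frame(
    snp_id = as.character(df$SNP), chrom = as.character(df$CHR),
    bp = as.integer(df$BP), a1 = as.character(df$A1),
    a2 = as.character(df$A2), z = z, p = p, n = n,
    info = if ("INFO" %in% names(df)) as.numeric(df$INFO) else NA_real_,
    maf = if ("MAF" %in% names(df)) as.numeric(df$MAF) else NA_real_,
    stringsAsFactors = FALSE
  )
  if ("SE" %in% names(df)) out$se <- as.numeric(df$SE)
  out
}

#' Write GWAS summary statistics
#'
#' Writes the tab-delimited dialect read by [read_sumstats()] (columns SNP,
#' CHR, BP, A1, A2, Z, P, N, INFO, MAF and optionally SE).
#'
#' @param ss Summary-statistics data.frame as returned by [read_sumstats()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(ss, path) {
  out <- data.frame(SNP = ss$snp_id, CHR = ss$chrom, BP = ss$bp,
                    A1 = ss$a1, A2 = ss$a2,
                    Z = sprintf("%.10g", ss$z), P = sprintf("%.10g", ss$p),
                    N = ss$n, INFO = ss$info, MAF = ss$maf)
  if (!is.null(ss$se)) out$SE <- ss$se
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- gene-to-SNP maps (MAGMA .genes.annot dialect) -------------------------

#' Construct a gene-to-SNP annotation map
#'
#' @param snps Named list: `gene_id` -> character vector of SNP IDs.
#' @param spans Data frame with columns `gene_id`, `chrom`, `start`, `stop`
#'   (the span printed in the .genes.annot location field).
#' @return A `gene_snp_map` object.
#' @export
gene_snp_map <- function(snps, spans) {
  if (!is.list(snps) || is.null(names(snps))) {
    .stopf("snps must be a named list of SNP-ID vectors")
  }
  spans <- as.data.frame(spans)
  miss <- setdiff(names(snps), spans$gene_id)
  if (length(miss)) .stopf("no span for gene '%s'", miss[1])
  spans <- spans[match(names(snps), spans$gene_id), , drop = FALSE]
  rownames(spans) <- NULL
  structure(list(snps = snps, spans = spans), class = "gene_snp_map")
}

#' @export
print.gene_snp_map <- function(x, ...) {
  cat(sprintf("gene_snp_map: %d genes, %d gene-SNP assignments\n",
              length(x$snps), sum(lengths(x$snps))))
  invisible(x)
}

#' Number of genes in a gene-to-SNP map
#' @param x A [gene_snp_map()].
#' @param ... Unused.
#' @export
length.gene_snp_map <- function(x) length(x$snps)

#' Write a gene-to-SNP map in the MAGMA .genes.annot dialect
#'
#' One line per gene: gene ID, `chrom:start:stop`, then the assigned SNP IDs,
#' all tab-separated.  Genes with zero SNPs are omitted and counted in a
#' message.
#'
#' @param map A [gene_snp_map()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_magma_annot <- function(map, path) {
  if (!length(map$snps)) .stopf("empty gene-to-SNP map")
  keep <- lengths(map$snps) > 0L
  if (any(!keep)) message(sum(!keep), " genes with zero SNPs omitted")
  if (!any(keep)) .stopf("all genes have zero SNPs")
  snps <- map$snps[keep]
  spans <- map$spans[keep, , drop = FALSE]
  lines <- vapply(seq_along(snps), function(i) {
    paste(c(names(snps)[i],
            sprintf("%s:%d:%d", spans$chrom[i], spans$start[i],
                    spans$stop[i]),
            snps[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a MAGMA .genes.annot file
#'
#' @param path Path to a file written by [write_magma_annot()].
#' @return A [gene_snp_map()].
#' @export
read_magma_annot <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 3L)) {
    .stopf("malformed .genes.annot line %d", which(lengths(fields) < 3L)[1])
  }
  ids <- vapply(fields, `[`, "", 1L)
  loc <- strsplit(vapply(fields, `[`, "", 2L), ":", fixed = TRUE)
  snps <- lapply(fields, function(f) f[-(1:2)])
  names(snps) <- ids
  spans <- data.frame(
    gene_id = ids,
    chrom = vapply(loc, `[`, "", 1L),
    start = as.integer(vapply(loc, `[`, "", 2L)),
    stop = as.integer(vapply(loc, `[`, "", 3L)),
    stringsAsFactors = FALSE
  )
  gene_snp_map(snps, spans)
}
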