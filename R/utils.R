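# Internal interval utilities.  User-facing tables are BED-style 0-based
# half-open; GenomicRanges (1-based closed) is used only behind these helpers.

.as_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = as.character(df$chrom),
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

# all (a_idx, b_idx) pairs sharing >= 1 bp on the same chromosome
.overlap_pairs <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) {
    return(data.frame(a_idx = integer(), b_idx = integer()))
  }
  h <- suppressWarnings(
    GenomicRanges::findOverlaps(.as_granges(a), .as_granges(b))
  )
  data.frame(a_idx = S4Vectors::queryHits(h), b_idx = S4Vectors::subjectHits(h))
}

.overlaps_any <- function(a, b) {
  out <- rep(FALSE, nrow(a))
  out[unique(.overlap_pairs(a, b)$a_idx)] <- TRUE
  out
}

# (point_idx, interval_idx) pairs with points$bp inside an interval
.points_in_intervals <- function(points, intervals) {
  pts <- data.frame(chrom = points$chrom, start = points$bp,
                    end = points$bp + 1L)
  h <- .overlap_pairs(pts, intervals)
  data.frame(point_idx = h$a_idx, interval_idx = h$b_idx)
}

# per interval: min over points of the bp distance between the interval's
# bases [start, end) and the point position; Inf if no point on the chromosome
.dist_to_points <- function(intervals, points) {
  out <- rep(Inf, nrow(intervals))
  if (nrow(intervals) == 0L || nrow(points) == 0L) return(out)
  for (ch in unique(intervals$chrom)) {
    ii <- which(intervals$chrom == ch)
    p <- sort(points$bp[points$chrom == ch])
    if (!length(p)) next
    s <- intervals$start[ii]
    e <- intervals$end[ii] - 1L           # last covered base
    i1 <- findInterval(e, p)              # rightmost point <= e
    i2 <- findInterval(s - 1L, p) + 1L    # leftmost point >= s
    d1 <- ifelse(i1 >= 1L, pmax(s - p[pmax(i1, 1L)], 0), Inf)
    d2 <- ifelse(i2 <= length(p), pmax(p[pmin(i2, length(p))] - e, 0), Inf)
    out[ii] <- pmin(d1, d2)
  }
  out
}

# run code with a temporary RNG state so generators are pure in their seed
.with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# deterministic child seed, kept inside 32-bit integer range
.child_seed <- function(seed, stage) {
  (as.numeric(seed) * 1103L + stage * 12289L) %% 2147483647
}

.stopf <- function(...) stop(sprintf(...), call. = FALSE)
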