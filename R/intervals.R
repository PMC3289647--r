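#' Read a BED file of binding regions
#'
#' Reads the first three (tab-separated) columns of a BED file into a
#' `GRanges`. BED coordinates are 0-based half-open; the returned object
#' uses the usual 1-based closed `GRanges` convention internally.
#'
#' @param path BED file path (>= 3 columns).
#' @param source Label attached to every interval (default: file basename).
#' @return A [GenomicRanges::GRanges] with a `source` metadata column,
#'   sorted by chromosome and start.
#' @export
read_bed <- function(path, source = basename(path)) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^(track|browser|#)", lines)]
  if (length(lines) == 0L) {
    return(GenomicRanges::GRanges(source = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < 3L)
      stop("BED line ", i, ": fewer than 3 tab-separated columns")
    s <- suppressWarnings(as.numeric(f[2L]))
    e <- suppressWarnings(as.numeric(f[3L]))
    if (is.na(s) || is.na(e))
      stop("BED line ", i, ": non-numeric coordinate")
    if (s < 0) stop("BED line ", i, ": negative start")
    if (s >= e) stop("BED line ", i, ": start >= end")
  }
  chrom <- vapply(fields, `[`, "", 1L)
  start0 <- as.numeric(vapply(fields, `[`, "", 2L))
  end0 <- as.numeric(vapply(fields, `[`, "", 3L))
  ord <- order(chrom, start0)
  gr <- GenomicRanges::GRanges(
    seqnames = factor(chrom[ord], levels = sort(unique(chrom))),
    ranges = IRanges::IRanges(start = start0[ord] + 1, end = end0[ord]),
    source = source)
  GenomicRanges::sort(gr)
}

#' Write intervals as BED3+ text (0-based half-open)
#'
#' @param gr A `GRanges`.
#' @param path Output path.
#' @param name Optional single name or per-interval names for column 4.
#' @return `path`, invisibly.
#' @export
write_bed <- function(gr, path, name = NULL) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr))
  if (!is.null(name)) df$name <- name
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Merge overlapping and book-ended intervals
#'
#' Coalesces intervals so the result is pairwise disjoint and
#' non-adjacent; per-base coverage is unchanged. Book-ended intervals
#' (half-open \[a,b) + \[b,c)) merge, since their coverage is contiguous.
#'
#' @param gr A `GRanges`.
#' @return A merged, sorted `GRanges` (metadata dropped).
#' @export
merge_intervals <- function(gr) {
  GenomicRanges::reduce(gr, ignore.strand = TRUE)
}

#' Consensus regions supported by every input set
#'
#' Positional k-way intersection: maximal intervals covered by at least one
#' interval from every input set. This is the "regions where all studies
#' agree" operation for ChIP binding-region sets.
#'
#' @param sets A list of >= 2 `GRanges`.
#' @return A merged `GRanges` covering exactly the positions present in
#'   every input.
#' @export
intersect_all <- function(sets) {
  if (!is.list(sets) || length(sets) < 2L)
    stop("'sets' must be a list of at least two interval sets")
  sets <- lapply(sets, merge_intervals)
  suppressWarnings(
    Reduce(function(a, b)
      GenomicRanges::intersect(a, b, ignore.strand = TRUE), sets))
}

#' Union of regions supported by any input set
#'
#' @param sets A list of >= 1 `GRanges`.
#' @return A merged `GRanges` covering exactly the positions present in at
#'   least one input.
#' @export
union_any <- function(sets) {
  if (!is.list(sets) || length(sets) < 1L)
    stop("'sets' must be a non-empty list of interval sets")
  suppressWarnings(
    merge_intervals(Reduce(function(a, b)
      GenomicRanges::union(a, b, ignore.strand = TRUE), sets)))
}

#' Test whether 1-based positions fall inside an interval set
#'
#' @param gr A `GRanges`.
#' @param chrom Chromosome identifier(s), recycled against `pos_1based`.
#' @param pos_1based 1-based position(s).
#' @return Logical vector, `TRUE` where the position is covered.
#' @export
regions_contain <- function(gr, chrom, pos_1based) {
  if (any(pos_1based < 1)) stop("positions are 1-based; must be >= 1")
  n <- max(length(chrom), length(pos_1based))
  chrom <- rep_len(as.character(chrom), n)
  pos_1based <- rep_len(pos_1based, n)
  if (length(gr) == 0L) return(rep(FALSE, n))
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos_1based, pos_1based))
  suppressWarnings(GenomicRanges::countOverlaps(q, gr, ignore.strand = TRUE) > 0L)
}

#' Total bases covered by an interval set
#' @param gr A `GRanges`.
#' @return Number of distinct covered bases.
#' @export
bases_covered <- function(gr) {
  sum(GenomicRanges::width(merge_intervals(gr)))
}
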