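#' Default ERE half-site core motifs
#'
#' The estrogen response element (ERE) is a 13-bp palindromic inverted
#' repeat, GGTCAnnnTGACC. Its two half-site cores are GGTCA and its reverse
#' complement TGACC; scanning both on the forward strand covers both
#' orientations without double counting.
#'
#' @return Named character vector of motif consensus strings. Names are the
#'   pattern labels; `n` (any base) is the only wildcard allowed.
#' @export
ere_patterns <- function() {
  c(GGTCA = "GGTCA", TGACC = "TGACC")
}

#' Full-site palindromic ERE pattern (optional, stricter scan)
#' @return Named character vector with the 13-bp GGTCAnnnTGACC consensus.
#' @export
ere_fullsite_pattern <- function() {
  c(ERE_FULL = "GGTCAnnnTGACC")
}

validate_patterns <- function(patterns) {
  if (length(patterns) == 0L) stop("'patterns' must be non-empty")
  if (is.null(names(patterns)) || any(!nzchar(names(patterns))))
    stop("'patterns' must be a named character vector (label = consensus)")
  for (p in patterns) {
    chars <- strsplit(p, "", fixed = TRUE)[[1L]]
    if (length(chars) == 0L || any(!chars %in% c("A", "C", "G", "T", "n")))
      stop("pattern '", p, "' must be non-empty over {A,C,G,T,n}")
  }
  invisible(patterns)
}

#' Scan masked sequence for motif occurrences
#'
#' Slides each consensus pattern along each sequence. A window matches when,
#' at every non-wildcard pattern position, the allele set of the (possibly
#' IUPAC-masked) window residue contains the consensus base — i.e. the
#' binding site exists under at least one allele. Masked positions inside
#' each hit are reported; whether they can disrupt the site is decided by
#' [filter_snp_disrupting()].
#'
#' @param seqs A [Biostrings::DNAStringSet] (or single named character
#'   string) of IUPAC-masked sequence, as from [read_masked_fasta()].
#' @param patterns Named character vector of consensus motifs over
#'   \{A,C,G,T,n\}; defaults to the two ERE half-site cores.
#' @param include_n Logical; treat `N` residues as masked SNP positions.
#'   Default `FALSE`: assembly gaps and unknown bases are not variants.
#' @return A data.frame with one row per hit: `chrom`, `start` (0-based),
#'   `end` (exclusive), `pattern_label`, `masked_offsets` (list column of
#'   0-based offsets within the hit), `masked_count`, and `disrupting`
#'   (`NA` until filtered). Sorted by chrom, start, pattern label;
#'   overlapping hits are all reported.
#' @export
scan_halfsites <- function(seqs, patterns = ere_patterns(), include_n = FALSE) {
  validate_patterns(patterns)
  if (is.character(seqs)) {
    if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
    seqs <- Biostrings::DNAStringSet(toupper(seqs))
  }
  out <- list()
  for (chrom in names(seqs)) {
    subject <- seqs[[chrom]]
    if (length(subject) == 0L) next
    schars <- strsplit(as.character(subject), "", fixed = TRUE)[[1L]]
    for (lab in names(patterns)) {
      consensus <- patterns[[lab]]
      pat <- Biostrings::DNAString(gsub("n", "N", consensus, fixed = TRUE))
      if (length(pat) > length(subject)) next
      # concrete pattern letters against free subject ambiguities: a masked
      # residue matches iff its allele set contains the consensus base;
      # pattern N columns are wildcards
      m <- Biostrings::matchPattern(pat, subject, fixed = FALSE)
      if (length(m) == 0L) next
      starts1 <- Biostrings::start(m)
      pchars <- strsplit(consensus, "", fixed = TRUE)[[1L]]
      plen <- length(pchars)
      offs <- lapply(starts1, function(s1) {
        win <- schars[s1:(s1 + plen - 1L)]
        which(is_ambiguity_code(win, include_n)) - 1L
      })
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom,
        start = starts1 - 1L,
        end = starts1 - 1L + plen,
        pattern_label = lab,
        masked_count = lengths(offs),
        disrupting = NA,
        stringsAsFactors = FALSE
      )
      out[[length(out)]]$masked_offsets <- offs
    }
  }
  if (length(out) == 0L) {
    hits <- data.frame(chrom = character(), start = integer(),
                       end = integer(), pattern_label = character(),
                       masked_count = integer(), disrupting = logical(),
                       stringsAsFactors = FALSE)
    hits$masked_offsets <- list()
    return(hits)
  }
  hits <- do.call(rbind, out)
  hits <- hits[order(hits$chrom, hits$start, hits$pattern_label), ]
  rownames(hits) <- NULL
  hits
}

#' Keep motif hits that a masked SNP can disrupt
#'
#' A hit is retained when at least one of its masked positions sits at a
#' non-wildcard motif column and its allele set contains a base different
#' from the consensus base there — i.e. one allele breaks the binding site.
#' A SNP in an `n` spacer column of a full-site pattern cannot disrupt the
#' site and does not qualify.
#'
#' @param hits Data.frame from [scan_halfsites()] run on `seqs`.
#' @param seqs The same sequences the hits were produced from.
#' @param patterns The same patterns used for the scan.
#' @return The subset of `hits` that a SNP can disrupt, with
#'   `disrupting = TRUE`.
#' @export
filter_snp_disrupting <- function(hits, seqs, patterns = ere_patterns()) {
  validate_patterns(patterns)
  if (is.character(seqs)) {
    if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
    seqs <- Biostrings::DNAStringSet(toupper(seqs))
  }
  if (nrow(hits) == 0L) return(hits)
  keep <- logical(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    offs <- hits$masked_offsets[[i]]
    if (length(offs) == 0L) next
    pchars <- strsplit(patterns[[hits$pattern_label[i]]], "", fixed = TRUE)[[1L]]
    schars <- strsplit(as.character(seqs[[hits$chrom[i]]]), "", fixed = TRUE)[[1L]]
    for (off in offs) {
      pc <- pchars[off + 1L]
      if (pc == "n") next  # spacer wildcard: no site base to break
      alleles <- iupac_allele_set(schars[hits$start[i] + off + 1L])
      if (any(alleles != pc)) { keep[i] <- TRUE; break }
    }
  }
  out <- hits[keep, , drop = FALSE]
  if (nrow(out)) out$disrupting <- TRUE
  rownames(out) <- NULL
  out
}

#' Write motif hits as BED6-like text
#'
#' Columns: chrom, start (0-based), end, pattern label, masked-position
#' count, strand (`.`). An optional companion TSV lists the 0-based masked
#' offsets within each hit.
#'
#' @param hits Data.frame from [scan_halfsites()] / [filter_snp_disrupting()].
#' @param path Output BED path.
#' @param offsets_path Optional path for the per-hit masked-offset TSV.
#' @return `path`, invisibly.
#' @export
write_hits_bed <- function(hits, path, offsets_path = NULL) {
  bed <- data.frame(hits$chrom, hits$start, hits$end, hits$pattern_label,
                    hits$masked_count, ".")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  if (!is.null(offsets_path)) {
    off <- data.frame(
      chrom = hits$chrom, start = hits$start, end = hits$end,
      pattern_label = hits$pattern_label,
      masked_offsets = vapply(hits$masked_offsets, paste, "", collapse = ","))
    utils::write.table(off, offsets_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  }
  invisible(path)
}
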