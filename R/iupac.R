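#' IUPAC nucleotide ambiguity codes
#'
#' Mapping from each of the 15 IUPAC nucleotide codes to the set of
#' unambiguous bases it denotes. In a SNP-masked genome an ambiguity code
#' marks a known polymorphic position and encodes its alleles (e.g. `Y`
#' for a C/T SNP).
#'
#' @format A named list of character vectors.
#' @export
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

#' Codes that denote more than one base (possible SNP positions)
#' @keywords internal
IUPAC_AMBIGUOUS <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N")

#' Bases encoded by an IUPAC nucleotide code
#'
#' @param code Single character, one of the 15 IUPAC codes (case
#'   insensitive).
#' @return Character vector of the unambiguous bases the code stands for.
#' @examples
#' iupac_allele_set("Y")  # C, T
#' iupac_allele_set("N")  # A, C, G, T
#' @export
iupac_allele_set <- function(code) {
  if (!is.character(code) || length(code) != 1L || nchar(code) != 1L)
    stop("'code' must be a single character")
  code <- toupper(code)
  set <- IUPAC_SETS[[code]]
  if (is.null(set))
    stop("unknown IUPAC code: '", code, "'")
  set
}

#' @keywords internal
is_ambiguity_code <- function(chars, include_n = FALSE) {
  amb <- if (include_n) IUPAC_AMBIGUOUS else setdiff(IUPAC_AMBIGUOUS, "N")
  chars %in% amb
}

#' Read a SNP-masked genome from a FASTA file
#'
#' Reads a (possibly multi-record, line-wrapped) FASTA file in which known
#' SNP positions have been replaced by IUPAC ambiguity codes, as in the
#' UCSC SNP-masked genome builds. Residues are upper-cased; record order is
#' preserved.
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] named by record identifier.
#' @export
read_masked_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  nonempty <- which(nzchar(trimws(lines)))
  if (length(nonempty) == 0L) stop("empty FASTA file: ", path)
  if (!startsWith(trimws(lines[nonempty[1L]]), ">"))
    stop("not FASTA: line ", nonempty[1L], " of ", path,
         " does not start a record header")
  # validate residues line by line so errors can name the offender
  pos_in_record <- 0L
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) next
    if (startsWith(ln, ">")) { pos_in_record <- 0L; next }
    chars <- strsplit(toupper(ln), "", fixed = TRUE)[[1L]]
    bad <- which(!chars %in% names(IUPAC_SETS))
    if (length(bad)) {
      stop("invalid residue '", chars[bad[1L]], "' at line ", i,
           ", record position ", pos_in_record + bad[1L])
    }
    pos_in_record <- pos_in_record + length(chars)
  }
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  Biostrings::DNAStringSet(toupper(seqs))
}
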