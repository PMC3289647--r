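#' Read a PLINK MAP file of SNP positions
#'
#' Columns: chromosome, rsid, genetic distance (ignored), 1-based base-pair
#' position.
#'
#' @param path MAP file path.
#' @return data.frame with columns `rsid`, `chrom`, `pos` (1-based).
#' @export
read_snp_map <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 4L) stop("MAP file needs 4 columns (chrom rsid cM bp)")
  out <- data.frame(rsid = as.character(df[[2L]]),
                    chrom = as.character(df[[1L]]),
                    pos = as.integer(df[[4L]]),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$rsid)) stop("duplicate rsid in MAP file")
  if (any(out$pos < 1L)) stop("MAP positions are 1-based; must be >= 1")
  out
}

empty_candidates <- function() {
  data.frame(rsid = character(), chrom = character(), pos = integer(),
             provenance = character(), provenance_secondary = character(),
             proxy_source = character(), proxy_r2 = numeric(),
             stringsAsFactors = FALSE)
}

#' Select SNPs lying inside a region set
#'
#' @param snps data.frame as from [read_snp_map()].
#' @param regions A `GRanges` of regions.
#' @param provenance Label recorded for each selected SNP, e.g.
#'   `"consensus_region"` or `"ere_halfsite"`.
#' @return Candidate data.frame (`rsid`, `chrom`, `pos`, `provenance`,
#'   `provenance_secondary`, `proxy_source`, `proxy_r2`) in input rsid
#'   order.
#' @export
snps_in_regions <- function(snps, regions, provenance) {
  if (nrow(snps) == 0L) return(empty_candidates())
  keep <- regions_contain(regions, snps$chrom, snps$pos)
  sel <- snps[keep, , drop = FALSE]
  data.frame(rsid = sel$rsid, chrom = sel$chrom, pos = sel$pos,
             provenance = rep_len(provenance, nrow(sel)),
             provenance_secondary = rep_len(NA_character_, nrow(sel)),
             proxy_source = rep_len(NA_character_, nrow(sel)),
             proxy_r2 = rep_len(NA_real_, nrow(sel)),
             stringsAsFactors = FALSE)
}

#' Read a pairwise LD table (HapMap text dialect)
#'
#' Whitespace-separated columns:
#' `pos1 pos2 population rsid_a rsid_b dprime r2 lod`.
#'
#' @param path LD text file path.
#' @return data.frame with columns `pos_a`, `pos_b`, `population`,
#'   `rsid_a`, `rsid_b`, `dprime`, `r2`.
#' @export
read_ld_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(data.frame(pos_a = integer(), pos_b = integer(),
                      population = character(), rsid_a = character(),
                      rsid_b = character(), dprime = numeric(),
                      r2 = numeric(), stringsAsFactors = FALSE))
  }
  fields <- strsplit(trimws(lines), "\\s+")
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < 8L)
      stop("LD table line ", i, ": expected 8 whitespace-separated fields")
    num <- suppressWarnings(as.numeric(f[c(1L, 2L, 6L, 7L, 8L)]))
    if (anyNA(num))
      stop("LD table line ", i, ": non-numeric field")
    r2 <- num[4L]
    if (r2 < 0 || r2 > 1)
      stop("LD table line ", i, ": r2 outside [0,1]")
  }
  data.frame(
    pos_a = as.integer(vapply(fields, `[`, "", 1L)),
    pos_b = as.integer(vapply(fields, `[`, "", 2L)),
    population = vapply(fields, `[`, "", 3L),
    rsid_a = vapply(fields, `[`, "", 4L),
    rsid_b = vapply(fields, `[`, "", 5L),
    dprime = as.numeric(vapply(fields, `[`, "", 6L)),
    r2 = as.numeric(vapply(fields, `[`, "", 7L)),
    stringsAsFactors = FALSE)
}

#' Substitute LD proxies for ungenotyped candidate SNPs
#'
#' Candidates already in the genotyped set pass through unchanged. For each
#' ungenotyped candidate the genotyped partner with maximal r2 at or above
#' `r2_min` is substituted (ties broken by smallest base-pair distance,
#' then lexicographic rsid). LD is symmetric: both pair orderings are
#' searched. Candidates with no qualifying proxy are dropped; their rsids
#' are returned in the `"dropped"` attribute and reported via `message()`.
#'
#' @param candidates Candidate data.frame (see [snps_in_regions()]).
#' @param genotyped Character vector of genotyped rsids.
#' @param ld data.frame from [read_ld_table()].
#' @param r2_min Inclusive r2 threshold, default 0.89.
#' @return Candidate data.frame; proxies carry `provenance = "ld_proxy"`,
#'   `proxy_source` (the original rsid) and `proxy_r2`.
#' @export
find_proxies <- function(candidates, genotyped, ld, r2_min = 0.89) {
  stopifnot(r2_min > 0, r2_min <= 1)
  if (nrow(candidates) == 0L) {
    out <- candidates
    attr(out, "dropped") <- character()
    return(out)
  }
  # symmetric long form: one row per (query, partner)
  pairs <- rbind(
    data.frame(query = ld$rsid_a, partner = ld$rsid_b,
               qpos = ld$pos_a, ppos = ld$pos_b, r2 = ld$r2,
               stringsAsFactors = FALSE),
    data.frame(query = ld$rsid_b, partner = ld$rsid_a,
               qpos = ld$pos_b, ppos = ld$pos_a, r2 = ld$r2,
               stringsAsFactors = FALSE))
  rows <- list()
  dropped <- character()
  for (i in seq_len(nrow(candidates))) {
    cand <- candidates[i, , drop = FALSE]
    if (cand$rsid %in% genotyped) {
      rows[[length(rows) + 1L]] <- cand
      next
    }
    hits <- pairs[pairs$query == cand$rsid &
                  pairs$partner %in% genotyped &
                  pairs$r2 >= r2_min, , drop = FALSE]
    if (nrow(hits) == 0L) {
      dropped <- c(dropped, cand$rsid)
      next
    }
    hits$dist <- abs(hits$ppos - hits$qpos)
    hits <- hits[order(-hits$r2, hits$dist, hits$partner), , drop = FALSE]
    best <- hits[1L, ]
    rows[[length(rows) + 1L]] <- data.frame(
      rsid = best$partner, chrom = cand$chrom, pos = best$ppos,
      provenance = "ld_proxy", provenance_secondary = cand$provenance,
      proxy_source = cand$rsid, proxy_r2 = best$r2,
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty_candidates()
  rownames(out) <- NULL
  if (length(dropped))
    message("find_proxies: no proxy at r2 >= ", r2_min, " for: ",
            paste(dropped, collapse = ", "))
  attr(out, "dropped") <- dropped
  out
}

#' Combine consensus-region and ERE-half-site candidate groups
#'
#' Union by rsid. When a SNP appears in both groups its primary provenance
#' is `consensus_region` and `ere_halfsite` is recorded secondarily.
#'
#' @param groupA Candidates from consensus regions.
#' @param groupB Candidates from disrupting ERE half-sites.
#' @return Deduplicated candidate data.frame sorted by chrom then pos.
#' @export
assemble_candidates <- function(groupA, groupB) {
  all <- rbind(groupA, groupB)
  if (nrow(all) == 0L) return(empty_candidates())
  prio <- c(consensus_region = 1L, ere_halfsite = 2L, ld_proxy = 3L)
  all$.prio <- prio[all$provenance]
  all <- all[order(all$rsid, all$.prio), , drop = FALSE]
  out <- list()
  for (id in unique(all$rsid)) {
    grp <- all[all$rsid == id, , drop = FALSE]
    row <- grp[1L, , drop = FALSE]
    other <- setdiff(unique(grp$provenance), row$provenance)
    if (length(other))
      row$provenance_secondary <- paste(other, collapse = ",")
    out[[length(out) + 1L]] <- row
  }
  out <- do.call(rbind, out)
  out$.prio <- NULL
  out <- out[order(out$chrom, out$pos, out$rsid), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read gene models from BED6 text
#'
#' Columns: chrom, start (0-based), end, name, score (ignored), strand.
#'
#' @param path BED6 path.
#' @return data.frame with `name`, `chrom`, `start` (0-based), `end`
#'   (exclusive), `strand`.
#' @export
read_genes_bed <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 6L) stop("gene BED needs 6 columns (incl. name, strand)")
  if (any(!df[[6L]] %in% c("+", "-"))) stop("gene strand must be + or -")
  data.frame(name = as.character(df[[4L]]), chrom = as.character(df[[1L]]),
             start = as.integer(df[[2L]]), end = as.integer(df[[3L]]),
             strand = df[[6L]], stringsAsFactors = FALSE)
}

#' Annotate SNPs with the nearest gene, strand-aware
#'
#' Distance is 0 for a SNP inside a gene body, otherwise base pairs to the
#' nearest gene boundary. Upstream/downstream follow gene orientation:
#' downstream of a reverse-strand gene means a lower coordinate than its
#' start.
#'
#' @param snps data.frame with `rsid`, `chrom`, `pos` (1-based).
#' @param genes data.frame as from [read_genes_bed()] (0-based half-open).
#' @return data.frame with `rsid`, `gene`, `relation`
#'   (`within`/`upstream`/`downstream`/`none`), `distance_bp`.
#' @export
annotate_nearest_gene <- function(snps, genes) {
  out <- data.frame(rsid = snps$rsid, gene = NA_character_,
                    relation = "none", distance_bp = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(snps))) {
    g <- genes[genes$chrom == snps$chrom[i], , drop = FALSE]
    if (nrow(g) == 0L) next
    pos0 <- snps$pos[i] - 1L
    dist <- ifelse(pos0 < g$start, g$start - pos0,
                   ifelse(pos0 >= g$end, pos0 - g$end + 1L, 0L))
    g <- g[order(dist, g$name), , drop = FALSE]
    d <- sort(dist)[1L]
    best <- g[1L, ]
    rel <- if (d == 0) "within" else {
      before <- pos0 < best$start
      if (best$strand == "+") {
        if (before) "upstream" else "downstream"
      } else {
        if (before) "downstream" else "upstream"
      }
    }
    out$gene[i] <- best$name
    out$relation[i] <- rel
    out$distance_bp[i] <- d
  }
  out
}
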