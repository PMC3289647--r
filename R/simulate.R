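#' Configuration for the synthetic-data generator
#'
#' Defines the study conditions emulated by the generator: a small masked
#' genome with planted ERE half-sites, three ChIP binding-region sets with
#' controlled three-way overlap, an LD table with pairs straddling the
#' proxy threshold, and case-control genotypes at the cohort sizes of the
#' two mood-disorder materials (bipolar disorder: 487/490 female and
#' 477/508 male cases/controls; major depression: 1200/1076 female and
#' 527/682 male).
#'
#' @param seed Integer master seed; every generator draws from a stream
#'   derived from it.
#' @param n_chroms,chrom_length Genome shape (default 2 x 100 kb).
#' @param n_planted_halfsites Motif copies planted per genome.
#' @param fraction_disrupting Fraction of planted sites carrying one
#'   IUPAC-masked position whose allele set includes a non-consensus base.
#' @param n_decoy_snps Masked SNP positions planted outside any motif.
#' @param region_count Binding regions per ChIP source.
#' @param region_length Region length in bases.
#' @param triple_overlap_fraction Fraction of regions shared (with a
#'   common core) by all three sources.
#' @param n_two_way Loci covered by exactly two sources.
#' @param cohorts Nested list `disease -> sex -> c(cases, controls)`.
#' @param causal_or Allelic odds ratio of the planted causal SNP.
#' @param causal_disease,causal_sex Stratum in which the causal effect is
#'   planted.
#' @param base_maf Range of control minor-allele frequencies.
#' @param missing_rate_person,missing_rate_snp Background missing-call
#'   rates.
#' @param n_high_missing_snps,n_high_missing_persons Planted QC victims
#'   (call-missing rate 0.2 per SNP, 0.3 per person).
#' @param n_hwe_violators Panel SNPs with excess heterozygosity in
#'   controls.
#' @param genotyped_fraction Fraction of SNPs genotyped on the array.
#' @param n_good_proxy,n_unproxied Ungenotyped candidates given a
#'   qualifying / only a sub-threshold LD partner.
#' @param r2_good,r2_bad r2 ranges for qualifying and sub-threshold pairs.
#' @param n_ld_pairs Background LD lines (r2 uniform on \[0,1\]).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 2L, chrom_length = 100000L,
                       n_planted_halfsites = 60L,
                       fraction_disrupting = 0.5,
                       n_decoy_snps = 240L,
                       region_count = 40L, region_length = 500L,
                       triple_overlap_fraction = 0.3,
                       n_two_way = 6L,
                       cohorts = list(
                         bipolar = list(female = c(cases = 487L, controls = 490L),
                                        male = c(cases = 477L, controls = 508L)),
                         depression = list(female = c(cases = 1200L, controls = 1076L),
                                           male = c(cases = 527L, controls = 682L))),
                       causal_or = 0.681,
                       causal_disease = "bipolar", causal_sex = "female",
                       base_maf = c(0.1, 0.5),
                       missing_rate_person = 0.01,
                       missing_rate_snp = 0.01,
                       n_high_missing_snps = 1L,
                       n_high_missing_persons = 1L,
                       n_hwe_violators = 2L,
                       genotyped_fraction = 0.75,
                       n_good_proxy = 2L, n_unproxied = 2L,
                       r2_good = c(0.90, 0.99), r2_bad = c(0.4, 0.88),
                       n_ld_pairs = 60L) {
  cfg <- as.list(environment())
  stopifnot(cfg$fraction_disrupting >= 0, cfg$fraction_disrupting <= 1,
            cfg$triple_overlap_fraction >= 0, cfg$triple_overlap_fraction <= 1,
            cfg$causal_or > 0, cfg$chrom_length >= 50L * cfg$n_planted_halfsites)
  structure(cfg, class = "sim_config")
}

# reverse lookup: unordered base pair -> IUPAC ambiguity code
pair_to_code <- function(b1, b2) {
  want <- sort(c(b1, b2))
  for (code in setdiff(names(IUPAC_SETS), c("A", "C", "G", "T", "N"))) {
    s <- IUPAC_SETS[[code]]
    if (length(s) == 2L && all(sort(s) == want)) return(code)
  }
  stop("no 2-base code for ", b1, "/", b2)
}

#' Simulate a SNP-masked genome with planted ERE half-sites
#'
#' Plants exact half-site copies at recorded coordinates on a random
#' background; a configured fraction carry one IUPAC-masked position whose
#' allele set includes a site-breaking allele (for a 5-bp half-site any
#' masked motif position does, since every ambiguity code spans at least
#' two bases, so non-disrupting planted sites are exact unmasked copies).
#' Decoy masked positions are planted outside motifs, and chance motif
#' occurrences in the background are scrubbed so that the planted
#' coordinates are exactly the scannable truth.
#'
#' @param cfg A [sim_config()].
#' @return List with `seqs` (a [Biostrings::DNAStringSet]) and `truth`
#'   (planted-site table and SNP table with alleles).
#' @export
simulate_genome <- function(cfg) {
  set.seed(cfg$seed + 1L)
  bases <- c("A", "C", "G", "T")
  pats <- ere_patterns()
  chroms <- paste0("chr", seq_len(cfg$n_chroms))
  chars <- lapply(chroms, function(ch)
    sample(bases, cfg$chrom_length, replace = TRUE))
  names(chars) <- chroms

  # distribute planted sites over chromosomes on disjoint 25-bp slots
  per_chrom <- diff(round(seq(0, cfg$n_planted_halfsites,
                              length.out = cfg$n_chroms + 1L)))
  n_disr <- round(cfg$fraction_disrupting * cfg$n_planted_halfsites)
  planted <- list()
  k <- 0L
  for (ci in seq_len(cfg$n_chroms)) {
    n_here <- per_chrom[ci]
    if (n_here == 0L) next
    slots <- seq(10L, cfg$chrom_length - 30L, by = 25L)
    if (length(slots) < n_here) stop("infeasible packing of planted sites")
    starts0 <- sort(sample(slots, n_here))
    for (s0 in starts0) {
      k <- k + 1L
      lab <- sample(names(pats), 1L)
      motif <- strsplit(pats[[lab]], "")[[1L]]
      disrupting <- k <= n_disr
      off <- NA_integer_; code <- NA_character_
      alt <- NA_character_
      if (disrupting) {
        off <- sample(0:4, 1L)
        cons <- motif[off + 1L]
        alt <- sample(setdiff(bases, cons), 1L)
        code <- pair_to_code(cons, alt)
        motif[off + 1L] <- code
      }
      chars[[chroms[ci]]][(s0 + 1L):(s0 + 5L)] <- motif
      planted[[k]] <- data.frame(
        chrom = chroms[ci], start = s0, end = s0 + 5L, pattern = lab,
        disrupting = disrupting, masked_offset = off, mask_code = code,
        stringsAsFactors = FALSE)
    }
  }
  planted <- if (length(planted)) do.call(rbind, planted) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               pattern = character(), disrupting = logical(),
               masked_offset = integer(), mask_code = character(),
               stringsAsFactors = FALSE)
  # interleave disrupting flags across chromosomes
  if (nrow(planted)) {
    planted <- planted[order(planted$chrom, planted$start), ]
    rownames(planted) <- NULL
  }

  protected <- new.env()
  mark <- function(chrom, pos1) assign(paste0(chrom, ":", pos1), TRUE,
                                       envir = protected)
  is_protected <- function(chrom, pos1)
    exists(paste0(chrom, ":", pos1), envir = protected)
  for (i in seq_len(nrow(planted)))
    for (p in (planted$start[i] + 1L):(planted$end[i]))
      mark(planted$chrom[i], p)

  # decoy masked SNPs outside planted sites
  decoys <- list()
  per_chrom_d <- diff(round(seq(0, cfg$n_decoy_snps,
                                length.out = cfg$n_chroms + 1L)))
  for (ci in seq_len(cfg$n_chroms)) {
    placed <- 0L; tries <- 0L
    while (placed < per_chrom_d[ci] && tries < 50L * per_chrom_d[ci]) {
      tries <- tries + 1L
      pos1 <- sample(10L:(cfg$chrom_length - 10L), 1L)
      if (is_protected(chroms[ci], pos1)) next
      ref <- chars[[chroms[ci]]][pos1]
      alt <- sample(setdiff(bases, ref), 1L)
      chars[[chroms[ci]]][pos1] <- pair_to_code(ref, alt)
      mark(chroms[ci], pos1)
      placed <- placed + 1L
      decoys[[length(decoys) + 1L]] <- data.frame(
        chrom = chroms[ci], pos = pos1, a1 = min(ref, alt),
        a2 = max(ref, alt), stringsAsFactors = FALSE)
    }
    if (placed < per_chrom_d[ci]) stop("infeasible packing of decoy SNPs")
  }

  # scrub chance motif occurrences so planted coordinates are the truth
  seqs <- Biostrings::DNAStringSet(vapply(chars, paste, "", collapse = ""))
  truth_key <- paste(planted$chrom, planted$start, planted$pattern)
  for (iter in 1:50) {
    hits <- scan_halfsites(seqs, pats)
    unwanted <- hits[!paste(hits$chrom, hits$start, hits$pattern_label) %in%
                       truth_key, , drop = FALSE]
    if (nrow(unwanted) == 0L) break
    if (iter == 50L) stop("infeasible packing: could not scrub chance hits")
    for (i in seq_len(nrow(unwanted))) {
      ch <- unwanted$chrom[i]
      win <- (unwanted$start[i] + 1L):(unwanted$end[i])
      free <- win[!vapply(win, function(p) is_protected(ch, p), logical(1))]
      if (length(free) == 0L) next
      pos1 <- free[[1L]]
      cons <- strsplit(pats[[unwanted$pattern_label[i]]], "")[[1L]]
      avoid <- cons[pos1 - unwanted$start[i]]
      chars[[ch]][pos1] <- sample(setdiff(bases, avoid), 1L)
    }
    seqs <- Biostrings::DNAStringSet(vapply(chars, paste, "", collapse = ""))
  }

  # SNP table: disrupting planted positions + decoys, rsids by position
  snp_rows <- list()
  for (i in seq_len(nrow(planted))) {
    if (!isTRUE(planted$disrupting[i])) next
    pos1 <- planted$start[i] + planted$masked_offset[i] + 1L
    al <- IUPAC_SETS[[planted$mask_code[i]]]
    snp_rows[[length(snp_rows) + 1L]] <- data.frame(
      chrom = planted$chrom[i], pos = pos1, a1 = al[1L], a2 = al[2L],
      kind = "ere_disrupting", stringsAsFactors = FALSE)
  }
  for (d in decoys)
    snp_rows[[length(snp_rows) + 1L]] <-
      cbind(d, data.frame(kind = "decoy", stringsAsFactors = FALSE))
  snps <- if (length(snp_rows)) do.call(rbind, snp_rows) else
    data.frame(chrom = character(), pos = integer(), a1 = character(),
               a2 = character(), kind = character(), stringsAsFactors = FALSE)
  if (nrow(snps)) {
    snps <- snps[order(snps$chrom, snps$pos), ]
    snps$rsid <- sprintf("rs%05d", seq_len(nrow(snps)))
    snps <- snps[, c("rsid", "chrom", "pos", "a1", "a2", "kind")]
    rownames(snps) <- NULL
  } else {
    snps$rsid <- character()
  }
  list(seqs = seqs, truth = list(planted = planted, snps = snps))
}

# disjoint-slot bookkeeping for region placement
slot_fits <- function(occupied, chrom, lo, hi) {
  occ <- occupied[[chrom]]
  if (is.null(occ) || nrow(occ) == 0L) return(TRUE)
  !any(lo < occ$hi & occ$lo < hi)
}

#' Simulate three ChIP binding-region sets with controlled overlap
#'
#' A configured fraction of loci is covered by all three sources with a
#' common core (the true consensus intervals); some loci are covered by
#' exactly two sources and the rest by one. Consensus and some single-set
#' loci are anchored on planted SNPs so that candidate selection has
#' members in every provenance class.
#'
#' @param cfg A [sim_config()].
#' @param truth Truth list from [simulate_genome()].
#' @return List with `sets` (three data.frames of 0-based half-open
#'   regions, named `chipA`/`chipB`/`chipC`) and the updated `truth`
#'   (`consensus` intervals; SNP flags `in_consensus`, `in_union`).
#' @export
simulate_chip_sets <- function(cfg, truth) {
  set.seed(cfg$seed + 2L)
  h <- cfg$region_length %/% 2L
  ext_max <- 150L
  # reserve the largest possible extent of a locus around its anchor
  pad <- cfg$region_length %/% 2L + ext_max + 110L
  chroms <- paste0("chr", seq_len(cfg$n_chroms))
  sets <- list(chipA = list(), chipB = list(), chipC = list())
  occupied <- list()
  consensus <- list()
  n_cons <- max(1L, round(cfg$triple_overlap_fraction * cfg$region_count))
  if (cfg$triple_overlap_fraction == 0) n_cons <- 0L

  snps <- truth$snps
  disr <- snps[snps$kind == "ere_disrupting", , drop = FALSE]
  deco <- snps[snps$kind == "decoy", , drop = FALSE]
  # anchor pools: disrupting SNPs first (consensus must contain some),
  # then decoys, then random background positions
  mk_anchor <- function(chrom, pos1) list(chrom = chrom, pos0 = pos1 - 1L)
  pool_disr <- lapply(seq_len(nrow(disr)), function(i)
    mk_anchor(disr$chrom[i], disr$pos[i]))
  pool_deco <- lapply(seq_len(nrow(deco)), function(i)
    mk_anchor(deco$chrom[i], deco$pos[i]))
  # a few disrupting-SNP anchors lead (so consensus regions contain ERE
  # SNPs), then a shuffled mix of the rest
  lead <- utils::head(pool_disr, 4L)
  rest <- c(utils::tail(pool_disr, -length(lead)), pool_deco)
  pool <- c(lead, if (length(rest)) rest[sample(length(rest))])
  rand_anchor <- function() mk_anchor(sample(chroms, 1L),
                                      sample(pad:(cfg$chrom_length - pad), 1L))
  take_anchor <- function() {
    while (length(pool) > 0L) {
      a <- pool[[1L]]; pool <<- pool[-1L]
      if (a$pos0 > pad && a$pos0 < cfg$chrom_length - pad &&
          slot_fits(occupied, a$chrom, a$pos0 - pad, a$pos0 + pad))
        return(a)
    }
    for (i in 1:200) {
      a <- rand_anchor()
      if (slot_fits(occupied, a$chrom, a$pos0 - pad, a$pos0 + pad)) return(a)
    }
    stop("infeasible packing of ChIP regions")
  }
  occupy <- function(chrom, lo, hi) {
    occupied[[chrom]] <<- rbind(occupied[[chrom]],
                                data.frame(lo = lo, hi = hi))
  }
  add_region <- function(set, chrom, s0, e0) {
    sets[[set]][[length(sets[[set]]) + 1L]] <<-
      data.frame(chrom = chrom, start = s0, end = e0,
                 stringsAsFactors = FALSE)
  }

  # three-way loci: one rotating source gets exactly the core, the other
  # two extend it, so the positional intersection equals the core
  for (i in seq_len(n_cons)) {
    a <- take_anchor()
    core <- c(a$pos0 - h, a$pos0 + h)
    exact <- (i %% 3L) + 1L
    for (s in 1:3) {
      e1 <- if (s == exact) 0L else sample(0:ext_max, 1L)
      e2 <- if (s == exact) 0L else sample(0:ext_max, 1L)
      add_region(names(sets)[s], a$chrom, core[1L] - e1, core[2L] + e2)
    }
    consensus[[length(consensus) + 1L]] <- data.frame(
      chrom = a$chrom, start = core[1L], end = core[2L],
      stringsAsFactors = FALSE)
    occupy(a$chrom, core[1L] - ext_max - 1L, core[2L] + ext_max + 1L)
  }

  # two-way loci (no third source): offset partial overlaps
  combos <- utils::combn(names(sets), 2L, simplify = FALSE)
  for (i in seq_len(cfg$n_two_way)) {
    a <- take_anchor()
    duo <- combos[[(i %% length(combos)) + 1L]]
    add_region(duo[1L], a$chrom, a$pos0 - h, a$pos0 + h)
    add_region(duo[2L], a$chrom, a$pos0 - h + 100L, a$pos0 + h + 100L)
    occupy(a$chrom, a$pos0 - h - 1L, a$pos0 + h + 101L)
  }

  # single-source loci fill each set to region_count
  for (s in names(sets)) {
    while (length(sets[[s]]) < cfg$region_count) {
      a <- take_anchor()
      add_region(s, a$chrom, a$pos0 - h, a$pos0 + h)
      occupy(a$chrom, a$pos0 - h - 1L, a$pos0 + h + 1L)
    }
  }

  sets <- lapply(sets, function(x) {
    df <- do.call(rbind, x)
    df <- df[order(df$chrom, df$start), ]
    rownames(df) <- NULL
    df
  })
  consensus <- if (length(consensus)) do.call(rbind, consensus) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               stringsAsFactors = FALSE)

  in_ivs <- function(chrom, pos1, ivs) {
    if (nrow(ivs) == 0L) return(rep(FALSE, length(pos1)))
    vapply(seq_along(pos1), function(i)
      any(ivs$chrom == chrom[i] & ivs$start <= pos1[i] - 1L &
            pos1[i] - 1L < ivs$end), logical(1))
  }
  all_regions <- do.call(rbind, sets)
  if (nrow(snps)) {
    truth$snps$in_consensus <- in_ivs(snps$chrom, snps$pos, consensus)
    truth$snps$in_union <- in_ivs(snps$chrom, snps$pos, all_regions)
  } else {
    truth$snps$in_consensus <- logical()
    truth$snps$in_union <- logical()
  }
  truth$consensus <- consensus
  list(sets = sets, truth = truth)
}

# case allele frequency implied by an allelic odds ratio on control
# frequency p0
or_shift <- function(p0, or) or * p0 / (1 - p0 + or * p0)

#' Simulate stratified case-control genotypes with planted effects
#'
#' Assembles the genotyped panel (a sampled fraction of the masked SNPs
#' plus LD partner SNPs for the planned proxies), draws per-SNP control
#' minor-allele frequencies, shifts the case frequency of the planted
#' causal SNP to the configured odds ratio in its stratum, draws genotypes
#' as two independent allele copies (Hardy-Weinberg) except for the
#' planted violators (excess heterozygosity in controls), and applies
#' person- and SNP-level missingness.
#'
#' @param cfg A [sim_config()].
#' @param truth Truth list from [simulate_chip_sets()].
#' @return List with `datasets` (named [genotype_dataset()]s, one per
#'   disease) and the updated `truth` (`causal`, `hwe_violators`,
#'   `high_missing_*`, `proxy_plan`, `expected_proxies`,
#'   `expected_dropped`, `genotyped` flags).
#' @export
simulate_genotypes <- function(cfg, truth) {
  set.seed(cfg$seed + 3L)
  snps <- truth$snps
  candidates <- snps$rsid[snps$in_consensus |
                            (snps$kind == "ere_disrupting" & snps$in_union)]
  genotyped <- stats::runif(nrow(snps)) < cfg$genotyped_fraction
  names(genotyped) <- snps$rsid

  causal <- candidates[candidates %in%
                         snps$rsid[snps$kind == "ere_disrupting" &
                                     snps$in_consensus]][1L]
  if (is.na(causal)) causal <- candidates[1L]
  if (is.na(causal)) stop("no candidate SNPs to plant an effect on")
  genotyped[causal] <- TRUE

  # plan ungenotyped candidates: some with a qualifying proxy, some without
  others <- setdiff(candidates, causal)
  n_gp <- min(cfg$n_good_proxy, length(others))
  good <- others[seq_len(n_gp)]
  others <- setdiff(others, good)
  n_up <- min(cfg$n_unproxied, length(others))
  bad <- others[seq_len(n_up)]
  genotyped[c(good, bad)] <- FALSE

  proxy_plan <- list()
  partner_rows <- list()
  next_id <- 0L
  add_partner <- function(cand, r2) {
    next_id <<- next_id + 1L
    i <- match(cand, snps$rsid)
    al <- sample(c("A", "C", "G", "T"), 2L)
    row <- data.frame(rsid = sprintf("rsP%04d", next_id),
                      chrom = snps$chrom[i],
                      pos = snps$pos[i] + sample(500:2000, 1L),
                      a1 = min(al), a2 = max(al), kind = "ld_partner",
                      in_consensus = FALSE, in_union = FALSE,
                      stringsAsFactors = FALSE)
    partner_rows[[length(partner_rows) + 1L]] <<- row
    proxy_plan[[length(proxy_plan) + 1L]] <<- data.frame(
      candidate = cand, partner = row$rsid, cand_pos = snps$pos[i],
      partner_pos = row$pos, r2 = r2, stringsAsFactors = FALSE)
    row$rsid
  }
  expected <- list()
  for (cand in good) {
    best <- add_partner(cand, stats::runif(1, cfg$r2_good[1], cfg$r2_good[2]))
    add_partner(cand, stats::runif(1, cfg$r2_bad[1], cfg$r2_bad[2]))
    expected[[length(expected) + 1L]] <- data.frame(
      candidate = cand, proxy = best,
      r2 = proxy_plan[[length(proxy_plan) - 1L]]$r2,
      stringsAsFactors = FALSE)
  }
  for (cand in bad)
    add_partner(cand, stats::runif(1, cfg$r2_bad[1], cfg$r2_bad[2]))

  snps$genotyped <- genotyped[snps$rsid]
  if (length(partner_rows)) {
    partners <- do.call(rbind, partner_rows)
    partners$genotyped <- TRUE
    snps <- rbind(snps, partners)
  }
  snps <- snps[order(snps$chrom, snps$pos), ]
  rownames(snps) <- NULL

  panel <- snps[snps$genotyped, , drop = FALSE]
  m <- nrow(panel)
  p0 <- stats::runif(m, cfg$base_maf[1], cfg$base_maf[2])
  names(p0) <- panel$rsid

  genotyped_cands <- intersect(candidates, panel$rsid)
  vio_pool <- setdiff(genotyped_cands, causal)
  violators <- utils::head(vio_pool, cfg$n_hwe_violators)
  hm_pool <- setdiff(vio_pool, violators)
  high_missing_snps <- utils::head(hm_pool, cfg$n_high_missing_snps)

  datasets <- list()
  hm_persons <- character()
  for (disease in names(cfg$cohorts)) {
    ind_rows <- list()
    for (sex in names(cfg$cohorts[[disease]])) {
      sizes <- cfg$cohorts[[disease]][[sex]]
      for (phe in c("cases", "controls")) {
        n <- sizes[[phe]]
        lab <- if (phe == "cases") "case" else "control"
        ids <- sprintf("%s_%s_%s_%04d", substr(disease, 1, 3),
                       substr(sex, 1, 1), lab, seq_len(n))
        ind_rows[[length(ind_rows) + 1L]] <- data.frame(
          fid = ids, id = ids, sex = sex, phenotype = lab,
          stringsAsFactors = FALSE)
      }
    }
    ind <- do.call(rbind, ind_rows)
    n_ind <- nrow(ind)
    geno <- matrix(NA_integer_, n_ind, m)
    is_causal_stratum <- disease == cfg$causal_disease &
      ind$sex == cfg$causal_sex & ind$phenotype == "case"
    for (j in seq_len(m)) {
      rs <- panel$rsid[j]
      p <- rep(p0[j], n_ind)
      if (rs == causal) p[is_causal_stratum] <- or_shift(p0[j], cfg$causal_or)
      g <- stats::rbinom(n_ind, 2L, p)
      if (rs %in% violators) {
        ctrl <- ind$phenotype == "control"
        force_het <- ctrl & stats::runif(n_ind) < 0.9
        g[force_het] <- 1L
      }
      geno[, j] <- g
    }
    # missingness: background person/SNP rates plus planted victims
    pr <- rep(cfg$missing_rate_person, n_ind)
    if (cfg$n_high_missing_persons > 0L) {
      vi <- seq_len(min(cfg$n_high_missing_persons, n_ind))
      pr[vi] <- 0.3
      hm_persons <- c(hm_persons, ind$id[vi])
    }
    sr <- rep(cfg$missing_rate_snp, m)
    sr[panel$rsid %in% high_missing_snps] <- 0.2
    if (any(pr > 0) || any(sr > 0)) {
      miss <- matrix(stats::runif(n_ind * m), n_ind, m) <
        outer(pr, rep(1, m)) |
        matrix(stats::runif(n_ind * m), n_ind, m) < outer(rep(1, n_ind), sr)
      geno[miss] <- NA_integer_
    }
    ds_snps <- data.frame(rsid = panel$rsid, chrom = panel$chrom,
                          pos = panel$pos, a1 = panel$a1, a2 = panel$a2,
                          stringsAsFactors = FALSE)
    datasets[[disease]] <- genotype_dataset(ind, ds_snps, geno)
  }

  truth$snps <- snps
  truth$candidates <- candidates
  truth$causal <- data.frame(rsid = causal, disease = cfg$causal_disease,
                             sex = cfg$causal_sex, or = cfg$causal_or,
                             stringsAsFactors = FALSE)
  truth$hwe_violators <- violators
  truth$high_missing_snps <- high_missing_snps
  truth$high_missing_persons <- hm_persons
  truth$proxy_plan <- if (length(proxy_plan)) do.call(rbind, proxy_plan) else
    data.frame(candidate = character(), partner = character(),
               cand_pos = integer(), partner_pos = integer(), r2 = numeric(),
               stringsAsFactors = FALSE)
  truth$expected_proxies <- if (length(expected)) do.call(rbind, expected) else
    data.frame(candidate = character(), proxy = character(), r2 = numeric(),
               stringsAsFactors = FALSE)
  truth$expected_dropped <- bad
  list(datasets = datasets, truth = truth)
}

#' Simulate a pairwise LD table straddling the proxy threshold
#'
#' Emits the planned candidate-partner pairs (qualifying and
#' sub-threshold) plus background pairs with r2 uniform on \[0,1\], in the
#' HapMap text dialect consumed by [read_ld_table()].
#'
#' @param cfg A [sim_config()].
#' @param truth Truth list from [simulate_genotypes()].
#' @return data.frame with the eight LD-table columns.
#' @export
simulate_ld_table <- function(cfg, truth) {
  set.seed(cfg$seed + 4L)
  rows <- list()
  add <- function(pos1, pos2, rsa, rsb, r2) {
    rows[[length(rows) + 1L]] <<- data.frame(
      pos1 = pos1, pos2 = pos2, population = "CEU", rsid_a = rsa,
      rsid_b = rsb, dprime = round(min(1, sqrt(r2) + 0.01), 4),
      r2 = round(r2, 4), lod = round(20 * r2, 2), stringsAsFactors = FALSE)
  }
  pp <- truth$proxy_plan
  for (i in seq_len(nrow(pp)))
    add(pp$cand_pos[i], pp$partner_pos[i], pp$candidate[i], pp$partner[i],
        pp$r2[i])
  snps <- truth$snps
  bg <- snps$rsid[!snps$rsid %in% c(pp$candidate, pp$partner)]
  if (length(bg) >= 2L) {
    for (i in seq_len(cfg$n_ld_pairs)) {
      duo <- sample(bg, 2L)
      ia <- match(duo[1L], snps$rsid); ib <- match(duo[2L], snps$rsid)
      add(snps$pos[ia], snps$pos[ib], duo[1L], duo[2L], stats::runif(1))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate every pipeline input with known ground truth
#'
#' Runs all four generators under a fixed seed and writes their outputs in
#' the standard text formats: a masked FASTA genome, three BED region
#' files, a genome-wide SNP MAP, PED/MAP genotypes per disease, the LD
#' table, and a JSON ground-truth file. Byte-identical outputs are
#' produced for identical configurations.
#'
#' @param cfg A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with `truth`, `datasets` and the named output
#'   `paths`.
#' @export
simulate_all <- function(cfg = sim_config(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  g <- simulate_genome(cfg)
  ch <- simulate_chip_sets(cfg, g$truth)
  gt <- simulate_genotypes(cfg, ch$truth)
  ld <- simulate_ld_table(cfg, gt$truth)
  truth <- gt$truth

  paths <- list(fasta = file.path(out_dir, "genome.fa"),
                chip = file.path(out_dir, paste0(names(ch$sets), ".bed")),
                snp_map = file.path(out_dir, "snps.map"),
                ld = file.path(out_dir, "ld.txt"),
                truth = file.path(out_dir, "truth.json"))
  Biostrings::writeXStringSet(g$seqs, paths$fasta, width = 70L)
  for (i in seq_along(ch$sets)) {
    df <- ch$sets[[i]]
    utils::write.table(df, paths$chip[i], sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  map <- data.frame(truth$snps$chrom, truth$snps$rsid, 0, truth$snps$pos)
  utils::write.table(map, paths$snp_map, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(ld, paths$ld, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  for (disease in names(gt$datasets)) {
    prefix <- file.path(out_dir, disease)
    write_ped_map(gt$datasets[[disease]], prefix)
    paths[[paste0("ped_", disease)]] <- paste0(prefix, ".ped")
    paths[[paste0("map_", disease)]] <- paste0(prefix, ".map")
  }
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(list(truth = truth, datasets = gt$datasets, paths = paths))
}
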