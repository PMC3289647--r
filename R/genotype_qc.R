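#' Construct a genotype dataset
#'
#' Container for a case-control genotype panel: individuals (with sex and
#' phenotype), SNP records, and a dosage matrix counting copies of each
#' SNP's A1 allele (`NA` = missing call). A1 is initially the
#' lexicographically smaller observed allele; the minor allele is
#' re-designated per analysis stratum at association time.
#'
#' @param ind data.frame with `fid`, `id`, `sex` (`"female"`/`"male"`),
#'   `phenotype` (`"case"`/`"control"`).
#' @param snps data.frame with `rsid`, `chrom`, `pos`, `a1`, `a2`.
#' @param geno Integer matrix, individuals x SNPs, values 0/1/2/`NA`.
#' @return An object of class `genotype_dataset`.
#' @export
genotype_dataset <- function(ind, snps, geno) {
  stopifnot(nrow(geno) == nrow(ind), ncol(geno) == nrow(snps))
  if (anyDuplicated(ind$id)) stop("individual ids must be unique")
  if (anyDuplicated(snps$rsid)) stop("rsids must be unique")
  stopifnot(all(ind$sex %in% c("female", "male")),
            all(ind$phenotype %in% c("case", "control")))
  dimnames(geno) <- list(ind$id, snps$rsid)
  structure(list(ind = ind, snps = snps, geno = geno),
            class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat("genotype_dataset:", nrow(x$ind), "individuals x",
      nrow(x$snps), "SNPs\n")
  cat("  cases:", sum(x$ind$phenotype == "case"),
      " controls:", sum(x$ind$phenotype == "control"),
      " females:", sum(x$ind$sex == "female"),
      " males:", sum(x$ind$sex == "male"), "\n")
  invisible(x)
}

#' Read PLINK PED/MAP text genotypes
#'
#' PED columns: FID IID PAT MAT SEX PHE followed by two allele columns per
#' SNP in MAP row order. Sex is coded 1 = male, 2 = female; phenotype
#' 1 = control, 2 = case; allele `0` = missing. A half-missing genotype
#' (one allele 0) is treated as missing with a warning.
#'
#' @param ped_path PED file path.
#' @param map_path MAP file path.
#' @return A [genotype_dataset()].
#' @export
read_ped_map <- function(ped_path, map_path) {
  map <- read_snp_map(map_path)
  if (!file.exists(ped_path)) stop("no such file: ", ped_path)
  lines <- readLines(ped_path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  n_snp <- nrow(map)
  n_ind <- length(lines)
  geno <- matrix(NA_integer_, n_ind, n_snp)
  ind <- data.frame(fid = character(n_ind), id = character(n_ind),
                    sex = character(n_ind), phenotype = character(n_ind),
                    stringsAsFactors = FALSE)
  allele_lists <- vector("list", n_snp)  # observed alleles per SNP
  raw <- vector("list", n_ind)
  half_missing <- 0L
  for (i in seq_len(n_ind)) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    if (length(f) != 6L + 2L * n_snp)
      stop("PED line ", i, ": expected ", 6L + 2L * n_snp,
           " fields for ", n_snp, " MAP SNPs, got ", length(f))
    sex <- f[5L]; phe <- f[6L]
    if (!sex %in% c("1", "2")) stop("PED line ", i, ": sex code must be 1/2")
    if (!phe %in% c("1", "2"))
      stop("PED line ", i, ": phenotype code must be 1/2")
    ind$fid[i] <- f[1L]; ind$id[i] <- f[2L]
    ind$sex[i] <- if (sex == "2") "female" else "male"
    ind$phenotype[i] <- if (phe == "2") "case" else "control"
    al <- matrix(f[-(1:6)], nrow = 2L)  # 2 x n_snp
    miss <- al[1L, ] == "0" | al[2L, ] == "0"
    half_missing <- half_missing +
      sum(xor(al[1L, ] == "0", al[2L, ] == "0"))
    al[, miss] <- NA_character_
    raw[[i]] <- al
    for (j in which(!miss))
      allele_lists[[j]] <- union(allele_lists[[j]], al[, j])
  }
  if (half_missing > 0L)
    warning(half_missing, " half-missing genotype(s) treated as missing")
  a1 <- vapply(allele_lists, function(a)
    if (length(a)) sort(a)[1L] else NA_character_, "")
  a2 <- vapply(allele_lists, function(a) {
    if (length(a) >= 2L) sort(a)[2L] else NA_character_
  }, "")
  for (i in seq_len(n_ind)) {
    al <- raw[[i]]
    geno[i, ] <- colSums(al == matrix(a1, 2L, n_snp, byrow = TRUE))
  }
  snps <- data.frame(rsid = map$rsid, chrom = map$chrom, pos = map$pos,
                     a1 = a1, a2 = a2, stringsAsFactors = FALSE)
  genotype_dataset(ind, snps, geno)
}

#' Write a genotype dataset as PLINK PED/MAP text
#'
#' @param ds A [genotype_dataset()].
#' @param prefix Output path prefix; writes `<prefix>.ped` and
#'   `<prefix>.map`.
#' @return The prefix, invisibly.
#' @export
write_ped_map <- function(ds, prefix) {
  map <- data.frame(ds$snps$chrom, ds$snps$rsid, 0, ds$snps$pos)
  utils::write.table(map, paste0(prefix, ".map"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  n_snp <- nrow(ds$snps)
  lines <- character(nrow(ds$ind))
  for (i in seq_len(nrow(ds$ind))) {
    g <- ds$geno[i, ]
    al1 <- ifelse(is.na(g), "0", ifelse(g >= 1L, ds$snps$a1, ds$snps$a2))
    al2 <- ifelse(is.na(g), "0", ifelse(g == 2L, ds$snps$a1, ds$snps$a2))
    lines[i] <- paste(c(ds$ind$fid[i], ds$ind$id[i], "0", "0",
                        if (ds$ind$sex[i] == "female") "2" else "1",
                        if (ds$ind$phenotype[i] == "case") "2" else "1",
                        as.vector(rbind(al1, al2))), collapse = " ")
  }
  writeLines(lines, paste0(prefix, ".ped"))
  invisible(prefix)
}

#' Subset a genotype dataset
#'
#' @param ds A [genotype_dataset()].
#' @param individuals Optional individual ids (or logical/integer index).
#' @param snps Optional rsids (or logical/integer index).
#' @return The subset dataset.
#' @export
subset_dataset <- function(ds, individuals = NULL, snps = NULL) {
  ik <- if (is.null(individuals)) seq_len(nrow(ds$ind))
        else if (is.character(individuals)) match(individuals, ds$ind$id)
        else individuals
  sk <- if (is.null(snps)) seq_len(nrow(ds$snps))
        else if (is.character(snps)) match(snps, ds$snps$rsid)
        else snps
  if (anyNA(ik)) stop("unknown individual id")
  if (anyNA(sk)) stop("unknown rsid")
  genotype_dataset(ds$ind[ik, , drop = FALSE],
                   ds$snps[sk, , drop = FALSE],
                   ds$geno[ik, sk, drop = FALSE])
}

#' Per-person missing genotype rate
#'
#' @param ds A [genotype_dataset()].
#' @param id Individual identifier (or omit for all individuals).
#' @return Fraction of missing calls over the dataset's SNPs.
#' @export
person_missing_rate <- function(ds, id = NULL) {
  if (is.null(id)) return(rowMeans(is.na(ds$geno)))
  if (!all(id %in% ds$ind$id)) stop("unknown individual id")
  rowMeans(is.na(ds$geno[match(id, ds$ind$id), , drop = FALSE]))
}

#' Per-SNP missing genotype rate within a stratum
#'
#' @param ds A [genotype_dataset()].
#' @param rsid SNP identifier (or omit for all SNPs).
#' @param stratum Optional logical/integer index or ids of individuals.
#' @return Fraction of missing calls among the stratum's individuals.
#' @export
snp_missing_rate <- function(ds, rsid = NULL, stratum = NULL) {
  if (!is.null(stratum)) ds <- subset_dataset(ds, individuals = stratum)
  g <- if (is.null(rsid)) ds$geno else {
    if (!all(rsid %in% ds$snps$rsid)) stop("unknown rsid")
    ds$geno[, match(rsid, ds$snps$rsid), drop = FALSE]
  }
  colMeans(is.na(g))
}

#' Minor allele frequency within a stratum
#'
#' Computed over non-missing alleles: `min(freq(A1), 1 - freq(A1))`.
#'
#' @inheritParams snp_missing_rate
#' @return Named numeric vector of MAFs.
#' @export
snp_maf <- function(ds, rsid = NULL, stratum = NULL) {
  if (!is.null(stratum)) ds <- subset_dataset(ds, individuals = stratum)
  g <- if (is.null(rsid)) ds$geno else {
    if (!all(rsid %in% ds$snps$rsid)) stop("unknown rsid")
    ds$geno[, match(rsid, ds$snps$rsid), drop = FALSE]
  }
  n_called <- colSums(!is.na(g))
  if (any(n_called == 0L))
    stop("MAF undefined (all calls missing) for: ",
         paste(colnames(g)[n_called == 0L], collapse = ", "))
  f1 <- colSums(g, na.rm = TRUE) / (2 * n_called)
  pmin(f1, 1 - f1)
}

#' Hardy-Weinberg exact test
#'
#' Conditional exact test of Hardy-Weinberg genotype proportions: given
#' the allele totals, the probability of every attainable heterozygote
#' count is enumerated and the two-sided p-value is the sum of
#' probabilities no larger than that of the observed configuration.
#'
#' @param n_het Observed heterozygote count.
#' @param n_hom1,n_hom2 Observed homozygote counts for the two alleles.
#' @return Exact p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_het, n_hom1, n_hom2) {
  if (any(c(n_het, n_hom1, n_hom2) < 0)) stop("counts must be >= 0")
  n <- n_het + n_hom1 + n_hom2
  if (n == 0) stop("no genotypes")
  n_rare <- 2L * min(n_hom1, n_hom2) + n_het
  if (n_rare == 0L) return(1)
  hets <- seq.int(n_rare %% 2L, min(n_rare, 2L * n - n_rare), by = 2L)
  # P(het = h | allele totals) up to a constant, in log space
  lp <- hets * log(2) - lfactorial(hets) -
    lfactorial((n_rare - hets) / 2) -
    lfactorial((2 * n - n_rare - hets) / 2)
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  obs <- p[match(n_het, hets)]
  min(1, sum(p[p <= obs * (1 + 1e-10)]))
}

#' Genotype QC thresholds
#'
#' Defaults: SNPs are excluded for missingness > 0.05, minor allele
#' frequency < 0.01, or Hardy-Weinberg exact p < 0.001 in controls;
#' individuals are excluded for missingness > 0.1.
#'
#' @param max_snp_missing Maximum per-SNP missing fraction.
#' @param min_maf Minimum minor allele frequency (cases + controls).
#' @param min_hwe_p_controls Minimum HWE exact p-value in controls.
#' @param max_person_missing Maximum per-person missing fraction.
#' @return A named list of thresholds.
#' @export
qc_thresholds <- function(max_snp_missing = 0.05, min_maf = 0.01,
                          min_hwe_p_controls = 0.001,
                          max_person_missing = 0.1) {
  t <- list(max_snp_missing = max_snp_missing, min_maf = min_maf,
            min_hwe_p_controls = min_hwe_p_controls,
            max_person_missing = max_person_missing)
  stopifnot(all(unlist(t) >= 0), all(unlist(t) <= 1))
  t
}

hwe_p_per_snp <- function(ds) {
  vapply(seq_len(nrow(ds$snps)), function(j) {
    g <- ds$geno[, j]
    g <- g[!is.na(g)]
    if (length(g) == 0L) return(NA_real_)
    hwe_exact_test(sum(g == 1L), sum(g == 2L), sum(g == 0L))
  }, numeric(1))
}

#' Apply genotype quality control to one analysis stratum
#'
#' Order of operations: (1) drop individuals whose missing rate exceeds
#' `max_person_missing`; then, recomputed on the remaining individuals,
#' drop SNPs by (2) missingness, (3) minor allele frequency over cases and
#' controls together, and (4) Hardy-Weinberg exact p-value computed in
#' controls only. Every exclusion is itemised in the report.
#'
#' @param ds A [genotype_dataset()] (already restricted to the analysis
#'   stratum, or pass `stratum`).
#' @param thresholds A [qc_thresholds()] list.
#' @param stratum Optional individual ids/index restricting the analysis.
#' @return List with `dataset` (the filtered [genotype_dataset()]) and
#'   `report` (excluded individuals/SNPs with reason and offending value,
#'   plus before/after counts).
#' @export
apply_qc <- function(ds, thresholds = qc_thresholds(), stratum = NULL) {
  if (!is.null(stratum)) ds <- subset_dataset(ds, individuals = stratum)
  n_ind0 <- nrow(ds$ind); n_snp0 <- nrow(ds$snps)

  pm <- person_missing_rate(ds)
  bad_ind <- pm > thresholds$max_person_missing
  excluded_individuals <- data.frame(
    id = ds$ind$id[bad_ind], reason = rep("person_missing", sum(bad_ind)),
    value = pm[bad_ind], stringsAsFactors = FALSE)
  ds <- subset_dataset(ds, individuals = which(!bad_ind))
  if (nrow(ds$ind) == 0L) stop("no individuals left after person QC")

  excl_snp <- list()
  drop_snps <- function(ds, bad, reason, value) {
    excl_snp[[length(excl_snp) + 1L]] <<- data.frame(
      rsid = ds$snps$rsid[bad], reason = rep(reason, sum(bad)),
      value = value[bad], stringsAsFactors = FALSE)
    subset_dataset(ds, snps = which(!bad))
  }

  sm <- snp_missing_rate(ds)
  ds <- drop_snps(ds, sm > thresholds$max_snp_missing, "snp_missing", sm)

  called <- colSums(!is.na(ds$geno))
  maf <- rep(NA_real_, nrow(ds$snps))
  maf[called > 0L] <- snp_maf(subset_dataset(ds, snps = which(called > 0L)))
  ds <- drop_snps(ds, is.na(maf) | maf < thresholds$min_maf, "maf",
                  maf)

  controls <- ds$ind$phenotype == "control"
  if (any(controls)) {
    hp <- hwe_p_per_snp(subset_dataset(ds, individuals = which(controls)))
    ds <- drop_snps(ds, !is.na(hp) & hp < thresholds$min_hwe_p_controls,
                    "hwe_controls", hp)
  }

  excluded_snps <- if (length(excl_snp)) do.call(rbind, excl_snp) else
    data.frame(rsid = character(), reason = character(), value = numeric(),
               stringsAsFactors = FALSE)
  report <- list(
    excluded_individuals = excluded_individuals,
    excluded_snps = excluded_snps,
    counts = list(individuals_before = n_ind0,
                  individuals_after = nrow(ds$ind),
                  snps_before = n_snp0, snps_after = nrow(ds$snps)),
    thresholds = thresholds)
  list(dataset = ds, report = report)
}
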