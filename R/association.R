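#' Round half away from zero at a fixed number of decimals
#'
#' Display rounding used for reported odds ratios, confidence bounds and
#' corrected p-values (half-up, so 0.0225 -> 0.023 at 3 decimals), as
#' opposed to R's round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 3) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5 + 1e-9) / f
}

#' Build the 2x2 allele table for one SNP in one stratum
#'
#' Counts minor/major alleles in cases and controls over non-missing
#' genotypes (two alleles per called individual). The minor allele is
#' designated by pooled case+control frequency within the stratum
#' (< 0.5; a tie is broken toward the lexicographically smaller allele).
#'
#' @param ds A [genotype_dataset()] restricted to the stratum (or pass
#'   `stratum`).
#' @param rsid SNP identifier.
#' @param stratum Optional individual ids/index restricting the analysis.
#' @return List of class `allele_table`: `a` (minor, cases), `b` (major,
#'   cases), `c` (minor, controls), `d` (major, controls), `minor`,
#'   `major`, `maf_cases`, `maf_controls`.
#' @export
allele_table <- function(ds, rsid, stratum = NULL) {
  if (!is.null(stratum)) ds <- subset_dataset(ds, individuals = stratum)
  j <- match(rsid, ds$snps$rsid)
  if (is.na(j)) stop("unknown rsid: ", rsid)
  g <- ds$geno[, j]
  case <- ds$ind$phenotype == "case"
  g_ca <- g[case & !is.na(g)]
  g_co <- g[!case & !is.na(g)]
  if (length(g_ca) + length(g_co) == 0L)
    stop("no non-missing genotypes for ", rsid)
  n1 <- sum(g_ca) + sum(g_co)              # A1 alleles
  n_tot <- 2L * (length(g_ca) + length(g_co))
  f1 <- n1 / n_tot
  # pooled-frequency minor designation; tie -> lexicographic (A1 is the
  # lexicographically smaller allele by construction)
  minor_is_a1 <- f1 <= 0.5
  count_minor <- function(g) if (minor_is_a1) sum(g) else 2L * length(g) - sum(g)
  a <- count_minor(g_ca); b <- 2L * length(g_ca) - a
  cc <- count_minor(g_co); d <- 2L * length(g_co) - cc
  structure(list(
    a = a, b = b, c = cc, d = d,
    minor = if (minor_is_a1) ds$snps$a1[j] else ds$snps$a2[j],
    major = if (minor_is_a1) ds$snps$a2[j] else ds$snps$a1[j],
    maf_cases = if (a + b > 0) a / (a + b) else NA_real_,
    maf_controls = if (cc + d > 0) cc / (cc + d) else NA_real_),
    class = "allele_table")
}

as_counts <- function(t) {
  if (inherits(t, "allele_table")) c(t$a, t$b, t$c, t$d)
  else if (is.numeric(t) && length(t) == 4L) as.vector(t)
  else stop("expected an allele_table or a numeric vector (a, b, c, d)")
}

#' Two-tailed Fisher's exact test on a 2x2 table
#'
#' Probability-mass convention: conditioning on the table margins, the
#' p-value is the sum of hypergeometric probabilities of every table whose
#' probability does not exceed that of the observed table.
#'
#' @param t An `allele_table` or numeric `c(a, b, c, d)` (row-wise 2x2).
#' @return Exact two-sided p-value in (0, 1].
#' @export
fisher_exact_two_sided <- function(t) {
  x <- as_counts(t)
  if (any(x < 0) || any(x != round(x))) stop("cells must be non-negative integers")
  a <- x[1]; b <- x[2]; c <- x[3]; d <- x[4]
  m <- a + b          # row 1 total
  n <- c + d          # row 2 total
  k <- a + c          # column 1 total
  if (m + n == 0) stop("empty table")
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Odds ratio with Woolf confidence interval
#'
#' `OR = (a d) / (b c)` for the minor allele; the confidence interval is
#' `exp(log OR -/+ z * sqrt(1/a + 1/b + 1/c + 1/d))` with
#' `z = qnorm(1 - (1 - confidence)/2)` (1.959964 at 95%).
#'
#' @param t An `allele_table` or numeric `c(a, b, c, d)`.
#' @param confidence Confidence level, default 0.95.
#' @param continuity Add Haldane-Anscombe 0.5 to every cell when any cell
#'   is zero (default `FALSE`: a zero cell is an error).
#' @return Named numeric: `or`, `l95`, `u95` (bounds at the requested
#'   level).
#' @export
odds_ratio_ci <- function(t, confidence = 0.95, continuity = FALSE) {
  x <- as_counts(t)
  if (any(x < 0)) stop("cells must be non-negative")
  if (any(x == 0)) {
    if (!continuity)
      stop("zero cell; enable continuity correction for OR/CI")
    x <- x + 0.5
  }
  or <- (x[1] * x[4]) / (x[2] * x[3])
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  se <- sqrt(sum(1 / x))
  c(or = or, l95 = exp(log(or) - z * se), u95 = exp(log(or) + z * se))
}

#' Bonferroni-correct a p-value by a study-wide multiplier
#'
#' @param p Raw p-value(s).
#' @param multiplier Number of tests corrected for.
#' @return Corrected numeric value(s) `p * multiplier`, uncapped; use
#'   [format_corrected_p()] for the conventional `">1"` display.
#' @export
bonferroni_correct <- function(p, multiplier) {
  stopifnot(multiplier >= 1)
  p * multiplier
}

#' Display a corrected p-value, printing ">1" when it exceeds 1
#'
#' @param p_corrected Corrected p-value(s) from [bonferroni_correct()].
#' @param digits Decimals for display (half-up), default 3.
#' @return Character vector.
#' @export
format_corrected_p <- function(p_corrected, digits = 3) {
  ifelse(p_corrected > 1, ">1",
         ifelse(p_corrected < 10^-digits / 2,
                formatC(p_corrected, format = "e", digits = 2),
                formatC(round_half_up(p_corrected, digits),
                        format = "f", digits = digits)))
}

#' Study-wide Bonferroni multiplier
#'
#' Product of the number of disease datasets, sexes, and panel SNPs; with
#' two diseases, two sexes and a 225-SNP panel this is 900. When per-
#' stratum QC leaves unequal panels the convention is a single factor from
#' the largest panel.
#'
#' @param n_diseases,n_sexes,panel_size Positive integers.
#' @return Integer multiplier.
#' @export
compute_multiplier <- function(n_diseases, n_sexes, panel_size) {
  stopifnot(n_diseases >= 1, n_sexes >= 1, panel_size >= 1)
  as.integer(n_diseases) * as.integer(n_sexes) * as.integer(panel_size)
}

#' Sex- and disease-stratified allelic association
#'
#' For each disease dataset and each sex, applies genotype QC to the
#' stratum, builds per-SNP allele tables, and computes the two-tailed
#' Fisher exact p, Bonferroni-corrected p, and minor-allele odds ratio
#' with Woolf 95% CI. With `multiplier = "auto"` the correction factor is
#' `n_diseases * n_sexes * max(post-QC panel size)` across strata.
#'
#' @param datasets Named list of [genotype_dataset()]s, one per disease
#'   (names are the disease labels).
#' @param thresholds [qc_thresholds()] applied independently per stratum.
#' @param multiplier `"auto"` or a fixed positive integer.
#' @param sexes Sexes analysed, default `c("female", "male")`.
#' @return List with `results` (data.frame: disease, sex, rsid, minor,
#'   major, a, b, c, d, maf_cases, maf_controls, p, p_corrected,
#'   p_corrected_display, or, l95, u95; sorted by stratum then p),
#'   `multiplier`, `panel_sizes`, and per-stratum `qc_reports`.
#' @export
run_stratified <- function(datasets, thresholds = qc_thresholds(),
                           multiplier = "auto",
                           sexes = c("female", "male")) {
  stopifnot(is.list(datasets), length(datasets) >= 1,
            !is.null(names(datasets)))
  strata <- list()
  for (disease in names(datasets)) {
    for (sex in sexes) {
      ds <- datasets[[disease]]
      idx <- which(ds$ind$sex == sex)
      if (length(idx) == 0L) next
      qc <- apply_qc(ds, thresholds, stratum = idx)
      strata[[paste(disease, sex, sep = ".")]] <-
        list(disease = disease, sex = sex, qc = qc)
    }
  }
  panel_sizes <- vapply(strata, function(s)
    nrow(s$qc$dataset$snps), integer(1))
  mult <- if (identical(multiplier, "auto")) {
    compute_multiplier(length(datasets), length(sexes), max(panel_sizes))
  } else {
    stopifnot(is.numeric(multiplier), multiplier >= 1)
    as.integer(multiplier)
  }
  rows <- list()
  for (s in strata) {
    ds <- s$qc$dataset
    for (rsid in ds$snps$rsid) {
      tab <- allele_table(ds, rsid)
      p <- fisher_exact_two_sided(tab)
      orci <- tryCatch(odds_ratio_ci(tab),
                       error = function(e) c(or = NA_real_, l95 = NA_real_,
                                             u95 = NA_real_))
      rows[[length(rows) + 1L]] <- data.frame(
        disease = s$disease, sex = s$sex, rsid = rsid,
        minor = tab$minor, major = tab$major,
        a = tab$a, b = tab$b, c = tab$c, d = tab$d,
        maf_cases = tab$maf_cases, maf_controls = tab$maf_controls,
        p = p, p_corrected = bonferroni_correct(p, mult),
        or = unname(orci["or"]), l95 = unname(orci["l95"]),
        u95 = unname(orci["u95"]), stringsAsFactors = FALSE)
    }
  }
  results <- if (length(rows)) do.call(rbind, rows) else
    data.frame()
  if (nrow(results)) {
    results$p_corrected_display <- format_corrected_p(results$p_corrected)
    results <- results[order(results$disease, results$sex, results$p,
                             results$rsid), ]
    rownames(results) <- NULL
  }
  list(results = results, multiplier = mult, panel_sizes = panel_sizes,
       qc_reports = lapply(strata, function(s) s$qc$report))
}
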