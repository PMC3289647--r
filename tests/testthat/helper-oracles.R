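# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: probabilities come from log-binomial
# coefficients, interval operations from per-base logical vectors, and
# motif matching from explicit enumeration of every ambiguity resolution.

# sample one element of a vector (unlike sample(), never treats a length-1
# numeric as 1:n)
pick <- function(v) v[sample.int(length(v), 1L)]

# hypergeometric 2x2 two-sided p by explicit enumeration over the free cell
oracle_fisher <- function(a, b, c, d) {
  m <- a + b; n <- c + d; K <- a + c
  ks <- max(0, K - n):min(K, m)
  logp <- lchoose(m, ks) + lchoose(n, K - ks) - lchoose(m + n, K)
  p <- exp(logp)
  p_obs <- exp(lchoose(m, a) + lchoose(n, K - a) - lchoose(m + n, K))
  min(1, sum(p[p <= p_obs * (1 + 1e-7)]))
}

# HWE exact p via absolute (unnormalised-by-support) genotype probabilities
oracle_hwe <- function(n_het, n_hom1, n_hom2) {
  N <- n_het + n_hom1 + n_hom2
  nr <- 2 * min(n_hom1, n_hom2) + n_het
  nc <- 2 * N - nr
  if (nr == 0) return(1)
  hets <- seq(nr %% 2, min(nr, nc), by = 2)
  lp <- vapply(hets, function(h) {
    hr <- (nr - h) / 2; hc <- (nc - h) / 2
    lfactorial(N) - lfactorial(hr) - lfactorial(h) - lfactorial(hc) +
      h * log(2) + lfactorial(nr) + lfactorial(nc) - lfactorial(2 * N)
  }, numeric(1))
  p <- exp(lp)
  obs <- p[match(n_het, hets)]
  min(1, sum(p[p <= obs * (1 + 1e-10)]))
}

# per-base coverage of a GRanges over a toy chromosome of length len
oracle_coverage <- function(gr, chrom, len) {
  v <- logical(len)
  gr <- gr[as.character(GenomicRanges::seqnames(gr)) == chrom]
  for (i in seq_along(gr)) {
    s <- GenomicRanges::start(gr)[i]; e <- GenomicRanges::end(gr)[i]
    v[s:e] <- TRUE
  }
  v
}

# brute-force motif scan: every window against every resolution of its
# ambiguity codes; returns hits and whether a masked (non-N) position can
# carry a site-breaking allele
oracle_scan <- function(seq_string, patterns, include_n = FALSE) {
  chars <- strsplit(toupper(seq_string), "")[[1L]]
  sets <- list(A = "A", C = "C", G = "G", T = "T",
               R = c("A","G"), Y = c("C","T"), S = c("C","G"),
               W = c("A","T"), K = c("G","T"), M = c("A","C"),
               B = c("C","G","T"), D = c("A","G","T"),
               H = c("A","C","T"), V = c("A","C","G"),
               N = c("A","C","G","T"))
  amb <- setdiff(c("R","Y","S","W","K","M","B","D","H","V","N"),
                 if (include_n) character() else "N")
  rows <- list()
  for (lab in names(patterns)) {
    pat <- strsplit(patterns[[lab]], "")[[1L]]
    L <- length(pat)
    if (L > length(chars)) next
    for (s0 in 0:(length(chars) - L)) {
      win <- chars[(s0 + 1):(s0 + L)]
      combos <- expand.grid(lapply(win, function(ch) sets[[ch]]),
                            stringsAsFactors = FALSE)
      ok <- apply(combos, 1L, function(res)
        all(pat == "n" | res == pat))
      if (!any(ok)) next
      masked <- which(win %in% amb) - 1L
      disrupting <- FALSE
      for (off in masked) {
        pc <- pat[off + 1L]
        if (pc == "n") next
        if (any(sets[[win[off + 1L]]] != pc)) disrupting <- TRUE
      }
      rows[[length(rows) + 1L]] <- data.frame(
        start = s0, pattern_label = lab, n_masked = length(masked),
        disrupting = disrupting, stringsAsFactors = FALSE)
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(start = integer(), pattern_label = character(),
               n_masked = integer(), disrupting = logical())
}

# random masked sequence: ACGT background with a few ambiguity codes
random_masked_seq <- function(len, n_masked = 5) {
  chars <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  if (n_masked > 0) {
    idx <- sample(len, min(n_masked, len))
    chars[idx] <- sample(c("R","Y","S","W","K","M"), length(idx),
                         replace = TRUE)
  }
  paste(chars, collapse = "")
}

# random interval set on one toy chromosome, as a GRanges
random_interval_set <- function(n, len, chrom = "toy", source = "rand") {
  s0 <- sample(0:(len - 2), n, replace = TRUE)
  w <- sample(1:max(2, len %/% 10), n, replace = TRUE)
  e0 <- pmin(len, s0 + w)
  GenomicRanges::GRanges(chrom, IRanges::IRanges(s0 + 1, e0),
                         source = source)
}

# small in-code genotype dataset: dosage matrix given directly
make_toy_dataset <- function(geno, sex = NULL, phenotype = NULL,
                             chrom = "chr1") {
  n <- nrow(geno); m <- ncol(geno)
  if (is.null(sex)) sex <- rep("female", n)
  if (is.null(phenotype))
    phenotype <- rep(c("case", "control"), length.out = n)
  ind <- data.frame(fid = sprintf("f%02d", 1:n), id = sprintf("i%02d", 1:n),
                    sex = sex, phenotype = phenotype,
                    stringsAsFactors = FALSE)
  snps <- data.frame(rsid = sprintf("rs%03d", 1:m), chrom = chrom,
                     pos = seq(100, by = 100, length.out = m),
                     a1 = "A", a2 = "G", stringsAsFactors = FALSE)
  genotype_dataset(ind, snps, geno)
}

# binomial-draw case/control dosages for one SNP at an allelic odds ratio
draw_stratum_geno <- function(n_cases, n_controls, p0, or = 1) {
  p1 <- or * p0 / (1 - p0 + or * p0)
  list(cases = stats::rbinom(n_cases, 2, p1),
       controls = stats::rbinom(n_controls, 2, p0))
}

# allele 2x2 counts (minor designated by pooled frequency) from dosages
tally_table <- function(g_cases, g_controls) {
  f1 <- (sum(g_cases) + sum(g_controls)) /
    (2 * (length(g_cases) + length(g_controls)))
  minor_is_1 <- f1 <= 0.5
  cnt <- function(g) if (minor_is_1) sum(g) else 2 * length(g) - sum(g)
  a <- cnt(g_cases); c <- cnt(g_controls)
  c(a = a, b = 2 * length(g_cases) - a,
    c = c, d = 2 * length(g_controls) - c)
}
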