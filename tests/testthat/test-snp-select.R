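toy_regions <- function(lines) {
  f <- tempfile(fileext = ".bed")
  writeLines(lines, f)
  read_bed(f)
}

test_that("SNP-in-region selection matches a linear scan", {
  snps <- data.frame(rsid = c("rs1", "rs2", "rs3"), chrom = "c",
                     pos = c(5L, 15L, 25L), stringsAsFactors = FALSE)
  regions <- toy_regions("c\t10\t20")
  sel <- snps_in_regions(snps, regions, "consensus_region")
  expect_equal(sel$rsid, "rs2")
  expect_equal(sel$provenance, "consensus_region")

  expect_equal(nrow(snps_in_regions(snps, GenomicRanges::GRanges(),
                                    "consensus_region")), 0L)

  set.seed(17)
  regions <- random_interval_set(20, 3000)
  snps <- data.frame(rsid = sprintf("rs%03d", 1:100), chrom = "toy",
                     pos = sample(1:3000, 100), stringsAsFactors = FALSE)
  sel <- snps_in_regions(snps, regions, "x")
  df <- data.frame(s0 = GenomicRanges::start(regions) - 1L,
                   e0 = GenomicRanges::end(regions))
  linear <- vapply(snps$pos, function(p)
    any(df$s0 <= p - 1 & p - 1 < df$e0), logical(1))
  expect_setequal(sel$rsid, snps$rsid[linear])
})

test_that("LD table parsing enforces the eight-column dialect", {
  f <- tempfile()
  writeLines("100 2100 CEU rs1 rs2 0.99 0.95 12.1", f)
  ld <- read_ld_table(f)
  expect_equal(nrow(ld), 1L)
  expect_equal(ld$r2, 0.95)
  expect_equal(ld$rsid_b, "rs2")

  writeLines(character(), f)
  expect_equal(nrow(read_ld_table(f)), 0L)

  writeLines(c("1 2 CEU a b 1 0.5 1", "1 2 CEU a b 1 0.6 1",
               "1 2 CEU a b 1 0.7 1", "1 2 CEU a b 1 oops 1",
               "1 2 CEU a b 1 0.9 1"), f)
  expect_error(read_ld_table(f), "line 4")

  writeLines("1 2 CEU a b 1 1.5 1", f)
  expect_error(read_ld_table(f), "r2 outside")
})

make_cand <- function(rsid, pos, prov = "consensus_region") {
  data.frame(rsid = rsid, chrom = "c", pos = pos, provenance = prov,
             provenance_secondary = NA_character_,
             proxy_source = NA_character_, proxy_r2 = NA_real_,
             stringsAsFactors = FALSE)
}

ld_row <- function(a, pa, b, pb, r2) {
  data.frame(pos_a = pa, pos_b = pb, population = "CEU", rsid_a = a,
             rsid_b = b, dprime = 1, r2 = r2, stringsAsFactors = FALSE)
}

test_that("proxy substitution picks the best qualifying genotyped partner", {
  cand <- make_cand("rs1", 100L)
  out <- find_proxies(cand, "rs1", ld_row("rs1", 100, "rs9", 500, 0.5))
  expect_identical(out$rsid, "rs1")
  expect_identical(out$provenance, "consensus_region")

  cand <- make_cand("rs1", 100L)
  ld <- rbind(ld_row("rs1", 100, "rsA", 700, 0.90),
              ld_row("rsB", 900, "rs1", 100, 0.95))
  out <- find_proxies(cand, c("rsA", "rsB"), ld)
  expect_equal(out$rsid, "rsB")          # max r2 wins, either orientation
  expect_equal(out$provenance, "ld_proxy")
  expect_equal(out$proxy_source, "rs1")
  expect_equal(out$proxy_r2, 0.95)

  # tie on r2: smaller distance, then lexicographic rsid
  ld <- rbind(ld_row("rs1", 100, "rsFar", 5100, 0.95),
              ld_row("rs1", 100, "rsNear", 600, 0.95))
  out <- find_proxies(make_cand("rs1", 100L), c("rsFar", "rsNear"), ld)
  expect_equal(out$rsid, "rsNear")
  ld <- rbind(ld_row("rs1", 100, "rsZ", 600, 0.95),
              ld_row("rs1", 100, "rsA", 600, 0.95))
  out <- find_proxies(make_cand("rs1", 100L), c("rsZ", "rsA"), ld)
  expect_equal(out$rsid, "rsA")

  # no qualifying partner: dropped and logged
  expect_message(
    out <- find_proxies(make_cand("rs1", 100L), "rsA",
                        ld_row("rs1", 100, "rsA", 600, 0.5)),
    "no proxy")
  expect_equal(nrow(out), 0L)
  expect_equal(attr(out, "dropped"), "rs1")
})

test_that("proxy substitution equals exhaustive search on random input", {
  set.seed(23)
  for (rep in 1:10) {
    n_cand <- 20L
    cands <- make_cand(sprintf("c%02d", 1:n_cand),
                       sample(1:100000, n_cand))
    geno <- sprintf("g%02d", 1:15)
    gpos <- stats::setNames(sample(1:100000, 15), geno)
    ld <- do.call(rbind, lapply(1:60, function(i) {
      a <- sample(c(cands$rsid, geno), 1)
      b <- sample(setdiff(c(cands$rsid, geno), a), 1)
      pa <- if (a %in% geno) gpos[[a]] else cands$pos[match(a, cands$rsid)]
      pb <- if (b %in% geno) gpos[[b]] else cands$pos[match(b, cands$rsid)]
      ld_row(a, pa, b, pb, round(stats::runif(1), 3))
    }))
    out <- suppressMessages(find_proxies(cands, geno, ld, r2_min = 0.7))
    # exhaustive oracle
    for (i in seq_len(nrow(cands))) {
      rs <- cands$rsid[i]
      hits <- rbind(
        data.frame(p = ld$rsid_b, r2 = ld$r2, d = abs(ld$pos_b - ld$pos_a))[
          ld$rsid_a == rs & ld$rsid_b %in% geno & ld$r2 >= 0.7, ],
        data.frame(p = ld$rsid_a, r2 = ld$r2, d = abs(ld$pos_b - ld$pos_a))[
          ld$rsid_b == rs & ld$rsid_a %in% geno & ld$r2 >= 0.7, ])
      got <- out[out$proxy_source %in% rs, ]
      if (nrow(hits) == 0L) {
        expect_equal(nrow(got), 0L)
        expect_true(rs %in% attr(out, "dropped"))
      } else {
        hits <- hits[order(-hits$r2, hits$d, hits$p), ]
        expect_equal(got$rsid, hits$p[1L])
        expect_equal(got$proxy_r2, hits$r2[1L])
      }
    }
    # invariants: proxies are genotyped and at or above the threshold
    prox <- out[out$provenance == "ld_proxy", ]
    expect_true(all(prox$rsid %in% geno))
    expect_true(all(prox$proxy_r2 >= 0.7))
  }
})

test_that("candidate assembly dedupes with consensus priority", {
  a <- make_cand(c("rs1", "rs2"), c(100L, 200L))
  b <- make_cand(c("rs3", "rs4", "rs5"), c(300L, 400L, 500L),
                 "ere_halfsite")
  out <- assemble_candidates(a, b)
  expect_equal(nrow(out), 5L)
  expect_equal(out$pos, sort(out$pos))

  b2 <- make_cand(c("rs1", "rs9"), c(100L, 900L), "ere_halfsite")
  out <- assemble_candidates(a, b2)
  expect_equal(nrow(out), 3L)
  r1 <- out[out$rsid == "rs1", ]
  expect_equal(r1$provenance, "consensus_region")
  expect_equal(r1$provenance_secondary, "ere_halfsite")

  # union-size oracle on random overlapping groups; idempotent; commutative
  set.seed(31)
  for (rep in 1:5) {
    ga <- make_cand(sample(sprintf("r%02d", 1:30), 12), sample(1e4, 12))
    gb <- make_cand(sample(sprintf("r%02d", 1:30), 12), sample(1e4, 12),
                    "ere_halfsite")
    out <- assemble_candidates(ga, gb)
    expect_equal(nrow(out), length(union(ga$rsid, gb$rsid)))
    expect_lte(nrow(out), nrow(ga) + nrow(gb))
    expect_equal(assemble_candidates(out, out[0, ])$rsid, out$rsid)
    expect_equal(assemble_candidates(gb, ga)$rsid, out$rsid)
  }
})

test_that("nearest-gene annotation is strand-aware", {
  genes <- data.frame(
    name = c("FWD", "REV"), chrom = "c",
    start = c(1000L, 5000L), end = c(2000L, 6000L),
    strand = c("+", "-"), stringsAsFactors = FALSE)
  snp <- function(pos) data.frame(rsid = "s", chrom = "c", pos = pos,
                                  stringsAsFactors = FALSE)
  ann <- annotate_nearest_gene(snp(1500L), genes)
  expect_equal(ann$relation, "within")
  expect_equal(ann$distance_bp, 0)

  ann <- annotate_nearest_gene(snp(2100L), genes)  # 0-based 2099, 100 bp 3'
  expect_equal(ann$gene, "FWD")
  expect_equal(ann$relation, "downstream")
  expect_equal(ann$distance_bp, 100)

  # downstream of a reverse-strand gene means lower coordinate
  ann <- annotate_nearest_gene(snp(4700L), genes)
  expect_equal(ann$gene, "REV")
  expect_equal(ann$relation, "downstream")
  expect_equal(ann$distance_bp, 5000 - 4699)

  ann <- annotate_nearest_gene(snp(6200L), genes)
  expect_equal(ann$gene, "REV")
  expect_equal(ann$relation, "upstream")

  # between the two genes: nearest boundary wins
  ann <- annotate_nearest_gene(snp(2500L), genes)
  expect_equal(ann$gene, "FWD")
  ann <- annotate_nearest_gene(snp(4500L), genes)
  expect_equal(ann$gene, "REV")

  ann <- annotate_nearest_gene(data.frame(rsid = "s", chrom = "other",
                                          pos = 1L), genes)
  expect_equal(ann$relation, "none")
})
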