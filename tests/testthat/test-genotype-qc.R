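write_ped_fixture <- function(ped_lines, map_lines) {
  prefix <- tempfile()
  writeLines(ped_lines, paste0(prefix, ".ped"))
  writeLines(map_lines, paste0(prefix, ".map"))
  prefix
}

test_that("PED/MAP reading codes A1 dosage, missingness and metadata", {
  prefix <- write_ped_fixture(
    c("f1 i1 0 0 2 2 A A", "f2 i2 0 0 1 1 A G"),
    "1\trs1\t0\t100")
  ds <- read_ped_map(paste0(prefix, ".ped"), paste0(prefix, ".map"))
  expect_equal(ds$ind$sex, c("female", "male"))
  expect_equal(ds$ind$phenotype, c("case", "control"))
  expect_equal(ds$snps$a1, "A")
  expect_equal(as.vector(ds$geno), c(2, 1))

  prefix <- write_ped_fixture(
    c("f1 i1 0 0 2 2 0 0", "f2 i2 0 0 1 1 A G"),
    "1\trs1\t0\t100")
  ds <- read_ped_map(paste0(prefix, ".ped"), paste0(prefix, ".map"))
  expect_true(is.na(ds$geno[1, 1]))

  prefix <- write_ped_fixture(
    c("f1 i1 0 0 2 2 A 0"), "1\trs1\t0\t100")
  expect_warning(
    ds <- read_ped_map(paste0(prefix, ".ped"), paste0(prefix, ".map")),
    "half-missing")
  expect_true(is.na(ds$geno[1, 1]))

  prefix <- write_ped_fixture(
    c("f1 i1 0 0 2 2 A A G G"), "1\trs1\t0\t100")
  expect_error(read_ped_map(paste0(prefix, ".ped"), paste0(prefix, ".map")),
               "expected 8 fields")
})

test_that("a 10 x 5 dataset round-trips through write-then-read", {
  set.seed(71)
  geno <- matrix(sample(c(0:2, NA), 50, replace = TRUE), 10, 5)
  ds <- make_toy_dataset(geno, sex = rep(c("female", "male"), 5))
  prefix <- tempfile()
  write_ped_map(ds, prefix)
  back <- read_ped_map(paste0(prefix, ".ped"), paste0(prefix, ".map"))
  expect_equal(back$ind$id, ds$ind$id)
  expect_equal(back$ind$sex, ds$ind$sex)
  expect_equal(back$ind$phenotype, ds$ind$phenotype)
  expect_equal(back$snps$rsid, ds$snps$rsid)
  expect_equal(unname(back$geno), unname(geno))
})

test_that("missing rates and MAF agree with direct counting", {
  g <- matrix(c(0, 1, 2, NA, 1,
                0, 0, 0, 1, NA), 5, 2)
  ds <- make_toy_dataset(g)
  expect_equal(unname(person_missing_rate(ds, "i01")), 0)
  expect_equal(unname(person_missing_rate(ds, "i04")), 0.5)
  expect_equal(unname(snp_missing_rate(ds, "rs001")), 0.2)
  # dosages 0,1,2 -> maf 0.5 ; 0,0,0,1 -> 0.125
  ds2 <- make_toy_dataset(matrix(c(0, 1, 2), 3, 1))
  expect_equal(unname(snp_maf(ds2, "rs001")), 0.5)
  ds3 <- make_toy_dataset(matrix(c(0, 0, 0, 1), 4, 1))
  expect_equal(unname(snp_maf(ds3, "rs001")), 0.125)

  set.seed(13)
  g <- matrix(sample(c(0:2, NA), 50, replace = TRUE,
                     prob = c(0.4, 0.3, 0.2, 0.1)), 10, 5)
  ds <- make_toy_dataset(g)
  for (j in 1:5) {
    col <- g[, j][!is.na(g[, j])]
    f <- sum(col) / (2 * length(col))
    expect_equal(unname(snp_maf(ds, sprintf("rs%03d", j))), min(f, 1 - f))
    expect_equal(unname(snp_missing_rate(ds, sprintf("rs%03d", j))),
                 mean(is.na(g[, j])))
  }
  expect_error(snp_maf(make_toy_dataset(matrix(NA_integer_, 3, 1)), "rs001"),
               "all calls missing")
})

test_that("HWE exact test equals enumeration and is symmetric", {
  expect_equal(hwe_exact_test(0, 0, 50), 1)
  # 4 minor alleles in 5 diploids: attainable het counts 0, 2, 4
  expect_equal(hwe_exact_test(2, 0, 3), oracle_hwe(2, 0, 3), tolerance = 1e-12)
  expect_equal(hwe_exact_test(57, 21, 22), oracle_hwe(57, 21, 22),
               tolerance = 1e-12)
  # full enumeration across genotype configurations up to 2N = 60 alleles
  for (N in c(5L, 11L, 17L, 30L)) {
    for (hom1 in seq(0L, N, by = max(1L, N %/% 5L))) {
      for (het in seq(0L, N - hom1, by = max(1L, N %/% 5L))) {
        hom2 <- N - hom1 - het
        expect_equal(hwe_exact_test(het, hom1, hom2),
                     oracle_hwe(het, hom1, hom2), tolerance = 1e-10)
        expect_equal(hwe_exact_test(het, hom1, hom2),
                     hwe_exact_test(het, hom2, hom1))
      }
    }
  }
  # sampled configurations up to 2N = 200 alleles; p is always in (0, 1]
  set.seed(41)
  for (rep in 1:30) {
    N <- pick(31:100)
    hom1 <- pick(0:N)
    het <- pick(0:(N - hom1))
    p <- hwe_exact_test(het, hom1, N - hom1 - het)
    expect_equal(p, oracle_hwe(het, hom1, N - hom1 - het), tolerance = 1e-10)
    expect_gt(p, 0)
    expect_lte(p, 1)
  }
  expect_error(hwe_exact_test(-1, 0, 2), "counts")
})

qc_fixture <- function(n = 60, m = 30, seed = 3) {
  set.seed(seed)
  geno <- matrix(rbinom(n * m, 2, 0.3), n, m)
  make_toy_dataset(geno, sex = rep("female", n),
                   phenotype = rep(c("case", "control"), each = n / 2))
}

test_that("QC excludes nothing on a clean dataset and is idempotent", {
  ds <- qc_fixture()
  out <- apply_qc(ds)
  expect_equal(nrow(out$report$excluded_individuals), 0L)
  expect_equal(nrow(out$report$excluded_snps), 0L)
  expect_equal(out$report$counts$snps_after, 30L)
  twice <- apply_qc(out$dataset)
  expect_equal(twice$dataset$geno, out$dataset$geno)
  expect_equal(nrow(twice$report$excluded_snps), 0L)
})

test_that("QC excludes planted violations with the right reasons", {
  ds <- qc_fixture()
  # SNP 4: rare (1 minor allele); SNP 6: all controls heterozygous
  # (gross HWE violation in controls)
  ds$geno[, 4] <- 0; ds$geno[5, 4] <- 1
  ds$geno[31:60, 6] <- 1
  # SNP 2: 10% missing; person 1: 4 of 30 missing (13%)
  ds$geno[sample(2:60, 6), 2] <- NA
  ds$geno[1, 1:4] <- NA
  out <- apply_qc(ds)
  ei <- out$report$excluded_individuals
  es <- out$report$excluded_snps
  expect_equal(ei$id, "i01")
  expect_equal(ei$reason, "person_missing")
  expect_equal(es$reason[es$rsid == "rs002"], "snp_missing")
  expect_equal(es$reason[es$rsid == "rs004"], "maf")
  expect_equal(es$reason[es$rsid == "rs006"], "hwe_controls")
  expect_lt(hwe_exact_test(30, 0, 0), 1e-3)  # the planted violation
  expect_false("rs006" %in% out$dataset$snps$rsid)
})

test_that("loosening a threshold never increases exclusions", {
  ds <- qc_fixture(seed = 9)
  ds$geno[sample(60, 4), 2] <- NA
  ds$geno[2, 1:8] <- NA
  base <- qc_thresholds()
  n_excl <- function(t) {
    out <- apply_qc(ds, t)
    nrow(out$report$excluded_snps) + nrow(out$report$excluded_individuals)
  }
  n0 <- n_excl(base)
  expect_lte(n_excl(qc_thresholds(max_snp_missing = 0.2)), n0)
  expect_lte(n_excl(qc_thresholds(min_maf = 0)), n0)
  expect_lte(n_excl(qc_thresholds(min_hwe_p_controls = 0)), n0)
  expect_lte(n_excl(qc_thresholds(max_person_missing = 0.5)), n0)
})
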