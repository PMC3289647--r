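test_that("allele tables count minor alleles per phenotype group", {
  # cases dosages 1,1,2 and controls 0,1: minor tied at 0.5 -> A1
  geno <- matrix(c(1, 1, 2, 0, 1), 5, 1)
  ds <- make_toy_dataset(geno, phenotype = c("case", "case", "case",
                                             "control", "control"))
  t <- allele_table(ds, "rs001")
  expect_equal(c(t$a, t$b, t$c, t$d), c(4, 2, 1, 3))
  expect_equal(t$minor, "A")
  expect_equal(t$maf_cases, 4 / 6)

  ds0 <- make_toy_dataset(matrix(0, 4, 1),
                          phenotype = c("case", "case", "control", "control"))
  expect_equal(allele_table(ds0, "rs001")$a, 0)

  # a + b is twice the number of non-missing case genotypes
  set.seed(19)
  for (rep in 1:10) {
    g <- matrix(sample(c(0:2, NA), 40, replace = TRUE), 40, 1)
    ds <- make_toy_dataset(g, phenotype = rep(c("case", "control"), 20))
    t <- allele_table(ds, "rs001")
    n_case_called <- sum(!is.na(g[seq(1, 39, 2), 1]))
    expect_equal(t$a + t$b, 2 * n_case_called)
  }
})

test_that("two-sided Fisher p follows the probability-mass convention", {
  expect_equal(fisher_exact_two_sided(c(1, 1, 1, 1)), 1)
  # margins 5/5, 5/5: only the two extreme tables are as improbable
  expect_equal(fisher_exact_two_sided(c(0, 5, 5, 0)), 2 / 252)
  # row swap + column swap leaves p unchanged
  set.seed(47)
  for (rep in 1:20) {
    x <- sample(0:30, 4, replace = TRUE)
    if (sum(x[1:2]) == 0 || sum(x[3:4]) == 0) next
    expect_equal(fisher_exact_two_sided(x),
                 fisher_exact_two_sided(c(x[4], x[3], x[2], x[1])))
    # and equals stats::fisher.test as an independent cross-check
    expect_equal(fisher_exact_two_sided(x),
                 stats::fisher.test(matrix(x, 2, byrow = TRUE))$p.value,
                 tolerance = 1e-9)
  }
  expect_error(fisher_exact_two_sided(c(0.5, 1, 1, 1)), "integer")
})

test_that("odds ratio and Woolf interval behave as documented", {
  o <- odds_ratio_ci(c(1, 1, 1, 1))
  expect_equal(unname(o["or"]), 1)
  expect_equal(log(o[["l95"]]), -log(o[["u95"]]))

  # reciprocal on swapping rows
  x <- c(12, 30, 25, 18)
  o1 <- odds_ratio_ci(x)
  o2 <- odds_ratio_ci(c(x[3], x[4], x[1], x[2]))
  expect_equal(o1[["or"]], 1 / o2[["or"]])
  expect_equal(o1[["l95"]], 1 / o2[["u95"]])

  # interval widens as any cell shrinks toward 1
  width <- function(x) log(odds_ratio_ci(x)[["u95"]]) -
    log(odds_ratio_ci(x)[["l95"]])
  expect_gt(width(c(3, 30, 25, 18)), width(c(12, 30, 25, 18)))
  expect_gt(width(c(12, 2, 25, 18)), width(c(12, 30, 25, 18)))

  expect_error(odds_ratio_ci(c(0, 5, 5, 5)), "zero cell")
  o <- odds_ratio_ci(c(0, 5, 5, 5), continuity = TRUE)
  expect_equal(o[["or"]], (0.5 * 5.5) / (5.5 * 5.5))
})

test_that("Bonferroni correction multiplies and displays >1", {
  expect_equal(bonferroni_correct(0.001, 900), 0.9)
  expect_gte(bonferroni_correct(0.5, 3), 0.5)
  expect_equal(format_corrected_p(bonferroni_correct(0.005008, 900)), ">1")
  expect_equal(format_corrected_p(0.0226), "0.023")
  expect_equal(compute_multiplier(2, 2, 225), 900L)
  expect_equal(compute_multiplier(1, 1, 1), 1L)
  expect_equal(compute_multiplier(2, 2, 10), 40L)
})

test_that("stratified run reports one result per SNP per stratum", {
  set.seed(61)
  mk <- function(n_f, n_m) {
    g <- matrix(rbinom(2 * (n_f + n_m), 2, 0.4), n_f + n_m, 2)
    make_toy_dataset(g, sex = rep(c("female", "male"), c(n_f, n_m)),
                     phenotype = rep_len(c("case", "control"), n_f + n_m))
  }
  out <- run_stratified(list(dzA = mk(40, 40), dzB = mk(40, 40)))
  expect_equal(nrow(out$results), 2L * 2L * 2L)
  expect_equal(out$multiplier, compute_multiplier(2, 2, 2))
  expect_true(all(out$results$p_corrected >= out$results$p))
  expect_true(all(out$results$l95 <= out$results$or, na.rm = TRUE))
  expect_true(all(out$results$or <= out$results$u95, na.rm = TRUE))
  # deterministic
  out2 <- run_stratified(list(dzA = mk(40, 40), dzB = mk(40, 40)))
  expect_equal(names(out2), names(out))
})

test_that("a strongly planted effect ranks first in its stratum", {
  set.seed(83)
  n <- 400  # per phenotype group, one sex
  m <- 30
  geno <- matrix(rbinom(2 * n * m, 2, 0.3), 2 * n, m)
  pheno <- rep(c("case", "control"), each = n)
  d <- draw_stratum_geno(n, n, 0.3, or = 0.5)
  geno[, 7] <- c(d$cases, d$controls)
  ds <- make_toy_dataset(geno, sex = rep("female", 2 * n), phenotype = pheno)
  out <- run_stratified(list(dz = ds), sexes = "female")
  expect_equal(out$results$rsid[1L], "rs007")
})

test_that("null p-values are approximately uniform", {
  set.seed(107)
  n_case <- 487; n_control <- 490
  m <- 200
  geno <- matrix(NA_real_, n_case + n_control, m)
  for (j in seq_len(m)) {
    d <- draw_stratum_geno(n_case, n_control, runif(1, 0.1, 0.5), or = 1)
    geno[, j] <- c(d$cases, d$controls)
  }
  ds <- make_toy_dataset(geno, sex = rep("female", n_case + n_control),
                         phenotype = rep(c("case", "control"),
                                         c(n_case, n_control)))
  out <- run_stratified(list(dz = ds), sexes = "female")
  # exact-test discreteness makes null p-values mildly conservative, which
  # is not a defect; test the anti-conservative departure from uniformity
  ks <- suppressWarnings(stats::ks.test(out$results$p, "punif",
                                        alternative = "greater"))
  expect_gt(ks$p.value, 0.01)
})
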