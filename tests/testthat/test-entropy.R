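test_that("shannon_entropy matches hand-evaluated values and conventions", {
  expect_equal(shannon_entropy(rep(1 / 3, 3)), log(3))
  expect_equal(shannon_entropy(c(1, 0, 0)), 0)
  # -(0.5 log 0.5 + 2 * 0.25 log 0.25), evaluated by hand
  expect_equal(shannon_entropy(c(0.5, 0.25, 0.25)), 1.039721, tolerance = 1e-6)
  expect_error(shannon_entropy(c(0.5, 0.6)), "sum to 1")
  expect_error(shannon_entropy(c(1.2, -0.2)), ">= 0")
})

test_that("entropy decomposition reproduces hand-computed tables", {
  d <- entropy_decomposition(genotype_counts(c(1, 1, 1), c(1, 1, 1)))
  expect_equal(d$h_case_control, log(2))
  expect_equal(d$h_symbols, log(3))
  expect_equal(d$h_symbols_cases, log(6) / 2)
  expect_equal(d$h_symbols_controls, log(6) / 2)
  expect_equal(d$mutual_information, 0)

  d2 <- entropy_decomposition(genotype_counts(c(2, 0, 0), c(0, 0, 2)))
  expect_equal(d2$h_case_control, log(2))
  expect_equal(d2$h_symbols, log(2))
  expect_equal(d2$h_symbols_cases, log(2) / 2)
  expect_equal(d2$h_symbols_controls, log(2) / 2)
  expect_equal(d2$mutual_information, log(2))
})

test_that("mutual information is zero iff case and control rows agree", {
  set.seed(73)
  for (i in 1:30) {
    row <- sample(0:20, 3, replace = TRUE)
    if (sum(row) == 0) row <- c(1, 1, 1)
    d <- entropy_decomposition(genotype_counts(row, row))
    expect_equal(d$mutual_information, 0, tolerance = 1e-12)
    other <- row + c(3, 0, 0)
    d2 <- entropy_decomposition(genotype_counts(row, other))
    expect_gt(d2$mutual_information, 0)
  }
})

test_that("entropy tests equal the likelihood-ratio G-statistic", {
  # Genotypic on the reference example
  r <- entropy_genotypic_test(genotype_counts(c(10, 20, 30), c(30, 20, 10)))
  expect_equal(r$statistic, g_stat_oracle(rbind(c(10, 20, 30), c(30, 20, 10))),
               tolerance = 1e-12)
  expect_equal(r$df, 2L)
  expect_equal(r$p_value,
               pchisq(r$statistic, 2, lower.tail = FALSE))

  # Allelic on the reference example
  ra <- entropy_allelic_test(allele_counts(c(40, 80), c(80, 40)))
  expect_equal(ra$statistic, g_stat_oracle(rbind(c(40, 80), c(80, 40))),
               tolerance = 1e-12)
  expect_equal(ra$df, 1L)

  # Property: exact algebraic identity over 1,000 random tables
  set.seed(74)
  for (i in 1:1000) {
    g <- random_genotype_table()
    expect_equal(entropy_genotypic_test(g)$statistic,
                 g_stat_oracle(unclass(g)), tolerance = 1e-9)
    a <- random_allele_table()
    expect_equal(entropy_allelic_test(a)$statistic,
                 g_stat_oracle(unclass(a)), tolerance = 1e-9)
  }
})

test_that("identical case/control distributions give statistic 0, p 1", {
  r <- entropy_genotypic_test(genotype_counts(c(5, 5, 5), c(5, 5, 5)))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  expect_false(r$degenerate)

  ra <- entropy_allelic_test(allele_counts(c(30, 70), c(30, 70)))
  expect_equal(ra$statistic, 0)
  expect_equal(ra$p_value, 1)
})

test_that("monomorphic SNPs are flagged degenerate, not errors", {
  r <- entropy_genotypic_test(genotype_counts(c(50, 0, 0), c(50, 0, 0)))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  expect_true(r$degenerate)
  expect_equal(r$df, 2L)  # df never adapts to empty classes

  ra <- entropy_allelic_test(allele_counts(c(100, 0), c(100, 0)))
  expect_true(ra$degenerate)
  expect_error(entropy_genotypic_test(genotype_counts(c(0, 0, 0), c(0, 0, 0))),
               "degenerate")
})

test_that("statistic is invariant to relabeling columns and swapping groups", {
  set.seed(75)
  for (i in 1:50) {
    g <- unclass(random_genotype_table())
    s0 <- entropy_genotypic_test(genotype_counts(g[1, ], g[2, ]))$statistic
    perm <- sample(3)
    expect_equal(entropy_genotypic_test(
      genotype_counts(g[1, perm], g[2, perm]))$statistic, s0,
      tolerance = 1e-12)
    expect_equal(entropy_genotypic_test(
      genotype_counts(g[2, ], g[1, ]))$statistic, s0, tolerance = 1e-12)
  }
})

test_that("statistic scales linearly when all counts are scaled", {
  set.seed(76)
  for (i in 1:20) {
    g <- unclass(random_genotype_table())
    s1 <- entropy_genotypic_test(genotype_counts(g[1, ], g[2, ]))$statistic
    for (k in c(2, 10, 37)) {
      sk <- entropy_genotypic_test(
        genotype_counts(k * g[1, ], k * g[2, ]))$statistic
      expect_equal(sk, k * s1, tolerance = 1e-9)
    }
  }
  # allelic: the spec's explicit x10 example
  a <- allele_counts(c(40, 80), c(80, 40))
  a10 <- allele_counts(c(400, 800), c(800, 400))
  expect_equal(entropy_allelic_test(a10)$statistic,
               10 * entropy_allelic_test(a)$statistic, tolerance = 1e-9)
})

test_that("statistics are non-negative and p-values lie in [0, 1]", {
  set.seed(77)
  for (i in 1:200) {
    r <- entropy_genotypic_test(random_genotype_table())
    expect_gte(r$statistic, 0)
    expect_gte(r$p_value, 0)
    expect_lte(r$p_value, 1)
  }
})
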