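test_that("Pearson chi-square tests match the textbook formula", {
  m <- rbind(c(10, 20, 30), c(30, 20, 10))
  r <- pearson_chisq_genotypic(genotype_counts(m[1, ], m[2, ]))
  expect_equal(r$statistic, pearson_oracle(m), tolerance = 1e-12)
  expect_equal(r$df, 2L)

  a <- rbind(c(40, 80), c(80, 40))
  ra <- pearson_chisq_allelic(allele_counts(a[1, ], a[2, ]))
  expect_equal(ra$statistic, pearson_oracle(a), tolerance = 1e-12)
  expect_equal(ra$df, 1L)

  # agreement with stats::chisq.test on tables with no empty margins
  set.seed(81)
  for (i in 1:50) {
    m <- matrix(sample(1:60, 6), 2, 3)
    r <- pearson_chisq_genotypic(genotype_counts(m[1, ], m[2, ]))
    ct <- suppressWarnings(chisq.test(m, correct = FALSE))
    expect_equal(r$statistic, unname(ct$statistic), tolerance = 1e-9)
    expect_equal(r$p_value, ct$p.value, tolerance = 1e-9)
  }
})

test_that("Pearson conventions: identical rows and empty classes", {
  r <- pearson_chisq_genotypic(genotype_counts(c(5, 5, 5), c(5, 5, 5)))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)

  # empty aa column contributes nothing, df stays 2
  r2 <- pearson_chisq_genotypic(genotype_counts(c(50, 10, 0), c(50, 10, 0)))
  expect_equal(r2$statistic, 0)
  expect_equal(r2$df, 2L)

  ra <- pearson_chisq_allelic(allele_counts(c(40, 80), c(80, 40)))
  rb <- pearson_chisq_allelic(allele_counts(c(80, 40), c(40, 80)))
  expect_equal(ra$statistic, rb$statistic)
})

test_that("Fisher 2x2 equals enumeration and stats::fisher.test", {
  # single table compatible with margins
  r <- fisher_exact_2x2(allele_counts(c(0, 10), c(0, 10)))
  expect_equal(r$p_value, 1)

  # perfect separation: only the observed table and its mirror are as extreme
  r2 <- fisher_exact_2x2(allele_counts(c(5, 0), c(0, 5)))
  expect_equal(r2$p_value, 2 / choose(10, 5), tolerance = 1e-12)
  expect_equal(r2$statistic, 1 / choose(10, 5), tolerance = 1e-12)
  expect_equal(r2$df, 0L)

  # exhaustive: every 2x2 table with total <= 12
  for (n in 1:12) {
    parts <- expand.grid(a = 0:n, b = 0:n, c = 0:n)
    parts <- parts[rowSums(parts) <= n, ]
    for (k in seq_len(nrow(parts))) {
      m <- matrix(c(parts$a[k], parts$b[k], parts$c[k],
                    n - parts$a[k] - parts$b[k] - parts$c[k]), 2, 2)
      p <- fisher_exact_2x2(allele_counts(m[1, ], m[2, ]))$p_value
      expect_equal(p, fisher22_oracle(m), tolerance = 1e-12)
    }
  }

  # random tables up to N = 40, against the oracle and fisher.test
  set.seed(82)
  for (i in 1:300) {
    m <- random_table_with_total(sample(2:40, 1), 2)
    p <- fisher_exact_2x2(allele_counts(m[1, ], m[2, ]))$p_value
    expect_equal(p, fisher22_oracle(m), tolerance = 1e-12)
    expect_equal(p, fisher.test(m)$p.value, tolerance = 1e-7)
  }
})

test_that("Fisher 2x3 equals enumeration and stats::fisher.test", {
  # single compatible table
  r <- fisher_exact_2x3(genotype_counts(c(10, 0, 0), c(10, 0, 0)))
  expect_equal(r$p_value, 1)

  r2 <- fisher_exact_2x3(genotype_counts(c(3, 2, 1), c(1, 2, 3)))
  m2 <- rbind(c(3, 2, 1), c(1, 2, 3))
  expect_equal(r2$p_value, fisher23_oracle(m2), tolerance = 1e-12)

  # exhaustive: every 2x3 table with total <= 7
  for (n in 1:7) {
    parts <- expand.grid(a = 0:n, b = 0:n, c = 0:n, d = 0:n, e = 0:n)
    parts <- parts[rowSums(parts) <= n, ]
    for (k in seq_len(nrow(parts))) {
      v <- unlist(parts[k, ])
      m <- matrix(c(v, n - sum(v)), 2, 3)
      p <- fisher_exact_2x3(genotype_counts(m[1, ], m[2, ]))$p_value
      expect_equal(p, fisher23_oracle(m), tolerance = 1e-12)
    }
  }

  # random tables up to N = 40
  set.seed(83)
  for (i in 1:200) {
    m <- random_table_with_total(sample(3:40, 1), 3)
    p <- fisher_exact_2x3(genotype_counts(m[1, ], m[2, ]))$p_value
    expect_equal(p, fisher23_oracle(m), tolerance = 1e-12)
    expect_equal(p, fisher.test(m)$p.value, tolerance = 1e-7)
  }
})

test_that("Fisher 2x3 enumeration cap raises an explicit error", {
  g <- genotype_counts(c(100, 100, 100), c(100, 100, 100))
  expect_error(fisher_exact_2x3(g, max_tables = 10), "exceeds cap")
})

test_that("Fisher and entropy allelic p-values rank SNPs almost identically", {
  # the regime where the exact and asymptotic tests are compared:
  # MAF 0.03, 5000 cases / 5000 controls
  sim <- snpentropy:::simulate_genotype_counts(
    sim_config(5000, 5000, 200, odds_ratio = 1.5, maf_controls = 0.03,
               seed = 84))
  res <- snpentropy:::run_tests_on_tables(sim$tables,
                                          c("entropy_allelic", "fisher_2x2"))
  rho <- cor(rank(res$p_value[, 1]), rank(res$p_value[, 2]))
  expect_gt(rho, 0.99)
})
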