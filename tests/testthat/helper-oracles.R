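# Independent oracles against which the package's statistics are checked.
# These recompute every quantity from first principles and share no code
# with the implementation.

# Likelihood-ratio G-statistic of a 2xK contingency table: 2 * sum O log(O/E)
# over observed-positive cells, E = row total * column total / N.
g_stat_oracle <- function(m) {
  n <- sum(m)
  e <- outer(rowSums(m), colSums(m)) / n
  pos <- m > 0
  2 * sum(m[pos] * log(m[pos] / e[pos]))
}

# Textbook Pearson X^2 with cells of zero expectation skipped.
pearson_oracle <- function(m) {
  n <- sum(m)
  e <- outer(rowSums(m), colSums(m)) / n
  pos <- e > 0
  sum((m[pos] - e[pos])^2 / e[pos])
}

# Two-sided Fisher p for a 2x2 table by explicit enumeration of every table
# compatible with the margins, point probabilities from the factorial
# formula. Same minimum-likelihood tie rule as the implementation.
fisher22_oracle <- function(m) {
  r <- rowSums(m); cl <- colSums(m); n <- sum(m)
  lp <- function(a) {
    tab <- c(a, r[1] - a, cl[1] - a, n - r[1] - cl[1] + a)
    if (any(tab < 0)) return(-Inf)
    sum(lfactorial(r)) + sum(lfactorial(cl)) - lfactorial(n) -
      sum(lfactorial(tab))
  }
  p_obs <- exp(lp(m[1, 1]))
  probs <- exp(vapply(0:min(r[1], cl[1]), lp, numeric(1)))
  min(1, sum(probs[probs <= p_obs * (1 + 1e-12)]))
}

# Freeman-Halton p for a 2x3 table: brute force over both free cells of the
# first row, no column reordering.
fisher23_oracle <- function(m) {
  r <- rowSums(m); cl <- colSums(m); n <- sum(m)
  lp <- function(a, b) {
    top <- c(a, b, r[1] - a - b)
    bot <- cl - top
    if (any(top < 0) || any(bot < 0)) return(-Inf)
    sum(lfactorial(r)) + sum(lfactorial(cl)) - lfactorial(n) -
      sum(lfactorial(c(top, bot)))
  }
  p_obs <- exp(lp(m[1, 1], m[1, 2]))
  probs <- c()
  for (a in 0:cl[1]) for (b in 0:cl[2])
    probs <- c(probs, exp(lp(a, b)))
  min(1, sum(probs[probs <= p_obs * (1 + 1e-12)]))
}

# Random non-empty 2x3 / 2x2 count tables for property tests.
random_genotype_table <- function(max_count = 50) {
  repeat {
    m <- matrix(sample(0:max_count, 6, replace = TRUE), 2, 3)
    if (sum(m) > 0) return(genotype_counts(m[1, ], m[2, ]))
  }
}

random_allele_table <- function(max_count = 100) {
  repeat {
    m <- matrix(sample(0:max_count, 4, replace = TRUE), 2, 2)
    if (sum(m) > 0) return(allele_counts(m[1, ], m[2, ]))
  }
}

# Random 2xK table with a given total (for the exact-test identity checks).
random_table_with_total <- function(n_total, k) {
  cells <- as.vector(stats::rmultinom(1, n_total, rep(1 / (2 * k), 2 * k)))
  matrix(cells, 2, k)
}
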