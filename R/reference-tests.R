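#' Conventional Pearson chi-square genotypic test
#'
#' The standard 2 df genotypic association test: `X^2 = sum((O - E)^2 / E)`
#' over the 2x3 genotype-by-status table, with expected counts
#' `E = row total * column total / N`. Cells whose expected count is zero
#' (empty genotype classes) contribute nothing and the degrees of freedom
#' stay at 2, mirroring the convention of [entropy_genotypic_test] so that
#' differences between the two tests reflect the statistics themselves.
#'
#' @param table a [genotype_counts] object.
#' @return An `assoc_test` object (df = 2).
#' @examples
#' pearson_chisq_genotypic(genotype_counts(c(10, 20, 30), c(30, 20, 10)))
#' @export
pearson_chisq_genotypic <- function(table) {
  stopifnot(inherits(table, "genotype_counts"))
  .pearson_test(table, df = 2L, test_name = "chisq_genotypic")
}

#' Conventional Pearson chi-square allelic test
#'
#' The standard 1 df allelic association test on the 2x2 allele-by-status
#' table; same conventions as [pearson_chisq_genotypic].
#'
#' @param table an [allele_counts] object.
#' @return An `assoc_test` object (df = 1); `n_used` is the total allele
#'   count.
#' @examples
#' pearson_chisq_allelic(allele_counts(c(40, 80), c(80, 40)))
#' @export
pearson_chisq_allelic <- function(table) {
  stopifnot(inherits(table, "allele_counts"))
  .pearson_test(table, df = 1L, test_name = "chisq_allelic")
}

.pearson_test <- function(table, df, test_name) {
  m <- unclass(table)
  n <- sum(m)
  if (n == 0) stop("empty table: degenerate", call. = FALSE)
  snp_id <- attr(table, "snp_id")
  if (.is_degenerate(m))
    return(new_test_result(0, df, 1, test_name, n, degenerate = TRUE,
                           snp_id = snp_id))
  e <- outer(rowSums(m), colSums(m)) / n
  pos <- e > 0
  stat <- sum((m[pos] - e[pos])^2 / e[pos])
  new_test_result(stat, df, stats::pchisq(stat, df, lower.tail = FALSE),
                  test_name, n, snp_id = snp_id)
}

#' Fisher exact test on a 2x2 allele table
#'
#' Two-sided Fisher exact test with the minimum-likelihood convention
#' standard in genetics software: conditioning on the margins, the p-value is
#' the sum of hypergeometric point probabilities of every table whose
#' probability does not exceed that of the observed table (relative tie
#' tolerance 1e-12). The `statistic` field carries the observed table's point
#' probability and `df` is reported as 0 (the test has no chi-square
#' reference distribution).
#'
#' @param table an [allele_counts] object (or any 2x2 case/control table of
#'   that class).
#' @return An `assoc_test` object.
#' @examples
#' fisher_exact_2x2(allele_counts(c(5, 0), c(0, 5)))   # p = 2 / choose(10, 5)
#' @export
fisher_exact_2x2 <- function(table) {
  stopifnot(inherits(table, "allele_counts"))
  m <- unclass(table)
  n <- sum(m)
  if (n == 0) stop("empty table: degenerate", call. = FALSE)
  snp_id <- attr(table, "snp_id")
  r1 <- sum(m["case", ])
  c1 <- sum(m[, 1])
  a_obs <- m["case", 1]
  support <- max(0L, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(support, c1, n - c1, r1)
  p_obs <- stats::dhyper(a_obs, c1, n - c1, r1)
  p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-12)]))
  new_test_result(p_obs, 0L, p, "fisher_2x2", n,
                  degenerate = .is_degenerate(m), snp_id = snp_id)
}

#' Fisher exact test on a 2x3 genotype table (Freeman-Halton)
#'
#' Exact conditional test on the 2x3 genotype-by-status table: with all
#' margins fixed, every compatible table is enumerated by iterating the
#' case-row entries of the two smallest column margins (the third entry is
#' then determined), its multivariate hypergeometric probability computed
#' from log-factorials, and the two-sided p-value taken as the sum of
#' probabilities not exceeding the observed table's (relative tie tolerance
#' 1e-12). This is full enumeration — exact by construction, never an
#' approximation; if the enumeration would exceed `max_tables` candidate
#' tables an error is raised rather than approximating.
#'
#' @param table a [genotype_counts] object.
#' @param max_tables enumeration size cap (default 1e8 candidate tables).
#' @return An `assoc_test` object; `statistic` is the observed table's point
#'   probability, `df` = 0.
#' @examples
#' fisher_exact_2x3(genotype_counts(c(3, 2, 1), c(1, 2, 3)))
#' @export
fisher_exact_2x3 <- function(table, max_tables = 1e8) {
  stopifnot(inherits(table, "genotype_counts"))
  m <- unclass(table)
  n <- sum(m)
  if (n == 0) stop("empty table: degenerate", call. = FALSE)
  snp_id <- attr(table, "snp_id")
  col_tot <- colSums(m)
  r1 <- sum(m["case", ])
  # iterate over the two smallest column margins; the third cell of the case
  # row is fixed by the row margin
  ord <- order(col_tot)
  cs <- col_tot[ord]
  obs <- m["case", ord]
  n_cand <- (cs[1] + 1) * (cs[2] + 1)
  if (n_cand > max_tables)
    stop(sprintf("Fisher 2x3 enumeration of %.3g tables exceeds cap %.3g",
                 n_cand, max_tables), call. = FALSE)
  a <- rep(0:cs[1], times = cs[2] + 1)
  b <- rep(0:cs[2], each = cs[1] + 1)
  cc <- r1 - a - b
  ok <- cc >= 0 & cc <= cs[3]
  a <- a[ok]; b <- b[ok]; cc <- cc[ok]
  log_denom <- lchoose(n, r1)
  logp <- lchoose(cs[1], a) + lchoose(cs[2], b) + lchoose(cs[3], cc) -
    log_denom
  p_obs <- exp(lchoose(cs[1], obs[1]) + lchoose(cs[2], obs[2]) +
                 lchoose(cs[3], obs[3]) - log_denom)
  probs <- exp(logp)
  p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-12)]))
  new_test_result(p_obs, 0L, p, "fisher_2x3", n,
                  degenerate = .is_degenerate(m), snp_id = snp_id)
}
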