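#' Shannon entropy of a discrete distribution
#'
#' Entropy in nats, `-sum(q * log(q))`, with the continuity convention
#' `0 * log(0) = 0`. Natural logarithms are used throughout the package: the
#' entropy test statistics are `-2 log` likelihood ratios, so their chi-square
#' asymptotics hold only in nats.
#'
#' @param q numeric vector of relative frequencies; must be non-negative and
#'   sum to 1 (tolerance 1e-9).
#' @return Entropy in nats (a non-negative scalar).
#' @examples
#' shannon_entropy(rep(1 / 3, 3))   # log(3)
#' shannon_entropy(c(1, 0, 0))      # 0
#' @export
shannon_entropy <- function(q) {
  if (!is.numeric(q) || anyNA(q)) stop("frequencies must be numeric", call. = FALSE)
  if (any(q < 0)) stop("frequencies must be >= 0", call. = FALSE)
  if (abs(sum(q) - 1) > 1e-9) stop("frequencies must sum to 1", call. = FALSE)
  -sum(.plogp(q))
}

# x * log(x) with 0 log 0 = 0; accepts vectors.
.plogp <- function(x) {
  out <- numeric(length(x))
  pos <- x > 0
  out[pos] <- x[pos] * log(x[pos])
  out
}

#' Entropy decomposition of a case-control count table
#'
#' Computes the four symbolic entropies (in nats) from which the entropy test
#' statistics are assembled:
#' \describe{
#'   \item{`h_case_control`}{entropy of the case/control split,
#'     `H(N_ca/N, N_co/N)`.}
#'   \item{`h_symbols`}{entropy of the pooled genotype (or allele) frequencies,
#'     column totals over `N`.}
#'   \item{`h_symbols_cases`, `h_symbols_controls`}{partial-group entropies
#'     `-sum_X (n(X, t)/N) log(n(X, t)/N)` using joint frequencies over the
#'     whole sample, so that their sum is the joint entropy of all
#'     (genotype, status) symbols.}
#' }
#' The mutual information between genotype and status is
#' `h_case_control + h_symbols - h_symbols_cases - h_symbols_controls`; it is
#' non-negative, and zero exactly when the genotype distribution is identical
#' in cases and controls.
#'
#' @param table a [genotype_counts] or [allele_counts] object.
#' @return A list of class `entropy_decomposition` with components
#'   `h_case_control`, `h_symbols`, `h_symbols_cases`, `h_symbols_controls`,
#'   `mutual_information` and `n` (total count).
#' @examples
#' entropy_decomposition(genotype_counts(c(1, 1, 1), c(1, 1, 1)))
#' @export
entropy_decomposition <- function(table) {
  if (!inherits(table, c("genotype_counts", "allele_counts")))
    stop("'table' must be a genotype_counts or allele_counts object",
         call. = FALSE)
  m <- unclass(table)
  n <- sum(m)
  if (n == 0) stop("empty table: degenerate", call. = FALSE)
  h_cc <- shannon_entropy(rowSums(m) / n)
  h_s  <- shannon_entropy(colSums(m) / n)
  h_ca <- -sum(.plogp(m["case", ] / n))
  h_co <- -sum(.plogp(m["control", ] / n))
  mi <- h_cc + h_s - h_ca - h_co
  structure(list(h_case_control = h_cc, h_symbols = h_s,
                 h_symbols_cases = h_ca, h_symbols_controls = h_co,
                 mutual_information = max(mi, 0), n = n),
            class = "entropy_decomposition")
}

#' @export
print.entropy_decomposition <- function(x, ...) {
  cat(sprintf(paste0("Entropy decomposition (nats, n = %d)\n",
                     "  h(C,Cc) = %.6f   h(S) = %.6f\n",
                     "  h(S,ca) = %.6f   h(S,co) = %.6f\n",
                     "  mutual information = %.6g\n"),
              x$n, x$h_case_control, x$h_symbols,
              x$h_symbols_cases, x$h_symbols_controls,
              x$mutual_information))
  invisible(x)
}

# Shared constructor for test results.
new_test_result <- function(statistic, df, p_value, test_name, n_used,
                            degenerate = FALSE, snp_id = NA_character_) {
  structure(list(statistic = statistic, df = df, p_value = p_value,
                 test_name = test_name, n_used = as.integer(n_used),
                 degenerate = isTRUE(degenerate),
                 snp_id = snp_id),
            class = "assoc_test")
}

#' @export
print.assoc_test <- function(x, ...) {
  cat(sprintf("%s%s\n  statistic = %.6g, df = %d, p = %.6g, n = %d%s\n",
              x$test_name,
              if (is.na(x$snp_id)) "" else paste0(" [", x$snp_id, "]"),
              x$statistic, x$df, x$p_value, x$n_used,
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

# A table is degenerate for testing when one margin carries no information:
# only one genotype/allele class present in the pooled sample, or one of the
# status groups is empty. The statistic is then identically zero.
.is_degenerate <- function(m) {
  sum(colSums(m) > 0) < 2 || sum(rowSums(m) > 0) < 2
}

#' Entropy genotypic association test
#'
#' The symbolic-entropy likelihood-ratio test on the 2x3 genotype-by-status
#' table. The statistic is
#' `GE = 2N * [h(C,Cc) + h(S) - h(S,ca) - h(S,co)]`,
#' i.e. 2N times the mutual information between genotype and status; it is
#' algebraically identical to the likelihood-ratio G-statistic
#' `2 * sum(O * log(O/E))` of the table and is referred to the chi-square
#' distribution with 2 degrees of freedom. The degrees of freedom stay at 2
#' even when a genotype class is absent from the pooled sample, which makes
#' the test conservative for very rare alleles.
#'
#' @param table a [genotype_counts] object with at least one individual.
#' @return An object of class `assoc_test` with components `statistic`, `df`,
#'   `p_value`, `test_name`, `n_used` and a `degenerate` flag (set for
#'   monomorphic SNPs or single-group tables, where the statistic is 0 and
#'   p = 1).
#' @examples
#' entropy_genotypic_test(genotype_counts(c(10, 20, 30), c(30, 20, 10)))
#' @export
entropy_genotypic_test <- function(table) {
  stopifnot(inherits(table, "genotype_counts"))
  .entropy_test(table, df = 2L, test_name = "entropy_genotypic")
}

#' Entropy allelic association test
#'
#' The allele-level counterpart of [entropy_genotypic_test]: the same
#' entropy decomposition applied to the 2x2 allele-by-status table, scaled by
#' the total allele count M (equal to 2N when no genotypes are missing), and
#' referred to chi-square with 1 degree of freedom. `AL = 2M * [h(C,Cc) +
#' h(A) - h(A,ca) - h(A,co)]` is the exact G-statistic of the allele table.
#'
#' @param table an [allele_counts] object.
#' @return An `assoc_test` object (df = 1); `n_used` is the total allele
#'   count.
#' @examples
#' entropy_allelic_test(allele_counts(c(40, 80), c(80, 40)))
#' @export
entropy_allelic_test <- function(table) {
  stopifnot(inherits(table, "allele_counts"))
  .entropy_test(table, df = 1L, test_name = "entropy_allelic")
}

.entropy_test <- function(table, df, test_name) {
  m <- unclass(table)
  n <- sum(m)
  if (n == 0) stop("empty table: degenerate", call. = FALSE)
  snp_id <- attr(table, "snp_id")
  if (.is_degenerate(m))
    return(new_test_result(0, df, 1, test_name, n, degenerate = TRUE,
                           snp_id = snp_id))
  dec <- entropy_decomposition(table)
  stat <- 2 * n * dec$mutual_information
  new_test_result(stat, df, stats::pchisq(stat, df, lower.tail = FALSE),
                  test_name, n, snp_id = snp_id)
}
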