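#' Case minor-allele frequency implied by an allelic odds ratio
#'
#' Given the control minor-allele frequency `p` and a target allelic odds
#' ratio, solves `[p_ca / (1 - p_ca)] / [p / (1 - p)] = OR` for the case
#' frequency: `p_ca = OR * p / (1 - p + OR * p)`. The odds ratio is defined
#' on allele frequencies; under Hardy-Weinberg equilibrium the genotype
#' frequencies in each group follow from its allele frequency.
#'
#' @param maf_controls control-group minor allele frequency, strictly in
#'   (0, 1).
#' @param odds_ratio positive allelic odds ratio (cases vs controls).
#' @return The case-group minor allele frequency, in (0, 1). Vectorized over
#'   both arguments.
#' @examples
#' case_maf_from_or(0.05, 2)    # 0.0952381
#' case_maf_from_or(0.2, 1)     # 0.2
#' @export
case_maf_from_or <- function(maf_controls, odds_ratio) {
  if (any(!is.finite(maf_controls)) || any(maf_controls <= 0) ||
      any(maf_controls >= 1))
    stop("'maf_controls' must lie strictly in (0, 1)", call. = FALSE)
  if (any(!is.finite(odds_ratio)) || any(odds_ratio <= 0))
    stop("'odds_ratio' must be positive", call. = FALSE)
  odds_ratio * maf_controls / (1 - maf_controls + odds_ratio * maf_controls)
}

#' Simulation configuration
#'
#' Bundles the parameters of one simulated dataset: group sizes, number of
#' SNPs, allelic odds ratio, control minor allele frequency (a fixed value or
#' `"random"` for per-SNP frequencies drawn uniformly from
#' `random_maf_bounds`), and the RNG seed.
#'
#' @param n_cases,n_controls group sizes (>= 1).
#' @param n_snps number of SNPs to simulate (>= 1).
#' @param odds_ratio allelic odds ratio attributed to every SNP (1 = null).
#' @param maf_controls control minor allele frequency in (0, 0.5], or the
#'   string `"random"`.
#' @param random_maf_bounds length-2 numeric: bounds of the uniform law used
#'   when `maf_controls = "random"`. The default (1e-6, 0.5) realizes an open
#'   lower bound at 0; SNPs that happen to be sampled monomorphic are kept
#'   and yield degenerate tests.
#' @param seed integer seed; every draw in [simulate_genotypes] is a pure
#'   function of the configuration including this seed.
#' @param label optional name for the configuration (used in reports).
#' @return An object of class `sim_config` (a list of the validated fields).
#' @examples
#' sim_config(500, 500, 100, odds_ratio = 2, maf_controls = 0.05, seed = 1)
#' @export
sim_config <- function(n_cases, n_controls, n_snps, odds_ratio = 1,
                       maf_controls = "random",
                       random_maf_bounds = c(1e-6, 0.5),
                       seed = 1L, label = NULL) {
  stopifnot(n_cases >= 1, n_controls >= 1, n_snps >= 1, odds_ratio > 0)
  random_maf <- identical(maf_controls, "random")
  if (!random_maf) {
    maf_controls <- as.numeric(maf_controls)
    if (!is.finite(maf_controls) || maf_controls <= 0 || maf_controls > 0.5)
      stop("'maf_controls' must be in (0, 0.5] or \"random\"", call. = FALSE)
  } else {
    stopifnot(length(random_maf_bounds) == 2,
              random_maf_bounds[1] > 0, random_maf_bounds[2] <= 1,
              random_maf_bounds[1] < random_maf_bounds[2])
  }
  if (is.null(label))
    label <- sprintf("OR=%g MAF=%s %d/%d", odds_ratio,
                     if (random_maf) "random" else format(maf_controls),
                     as.integer(n_cases), as.integer(n_controls))
  structure(list(n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 n_snps = as.integer(n_snps),
                 odds_ratio = odds_ratio,
                 maf_controls = if (random_maf) "random" else maf_controls,
                 random_maf_bounds = as.numeric(random_maf_bounds),
                 seed = as.integer(seed),
                 label = label),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("Simulation config: %s, %d SNPs, seed %d\n",
              x$label, x$n_snps, x$seed))
  invisible(x)
}

# Hardy-Weinberg genotype probabilities for codes (2, 1, 0) = (AA, Aa, aa)
# given minor allele frequency p.
hwe_probs <- function(p) c(p^2, 2 * p * (1 - p), (1 - p)^2)

#' Simulate case-control genotypes under Hardy-Weinberg equilibrium
#'
#' For each SNP the control group receives genotypes drawn from the HWE
#' distribution at the configured control minor allele frequency, and the
#' case group from HWE at the case frequency implied by the configured
#' allelic odds ratio ([case_maf_from_or]); with `odds_ratio = 1` both groups
#' share the same frequency (the null). Genotypes are drawn as group-level
#' multinomial counts — exactly equivalent to independent individual draws —
#' and expanded to an individual-by-SNP code matrix in a fixed order (cases
#' first, codes descending within each group).
#'
#' Reproducibility: one RNG stream is seeded from `config$seed`, from which a
#' per-SNP sub-seed is drawn up front; SNP j is therefore identical across
#' runs, and across configurations that differ only in `n_snps`.
#'
#' @param config a [sim_config] object.
#' @return A list of class `sim_dataset`: `genotypes` (integer matrix,
#'   individuals x SNPs, codes 0/1/2), `phenotype` (character,
#'   `"case"`/`"control"`), `snp_params` (data.frame with per-SNP `snp_id`,
#'   `maf_controls`, `maf_cases`, `odds_ratio`), and the `config`.
#' @examples
#' d <- simulate_genotypes(sim_config(50, 50, 3, odds_ratio = 2,
#'                                    maf_controls = 0.2, seed = 42))
#' dim(d$genotypes)
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  counts <- simulate_genotype_counts(config)
  n_ca <- config$n_cases
  n_co <- config$n_controls
  geno <- matrix(0L, nrow = n_ca + n_co, ncol = config$n_snps)
  for (j in seq_len(config$n_snps)) {
    m <- unclass(counts$tables[[j]])
    geno[, j] <- c(rep(c(2L, 1L, 0L), m["case", ]),
                   rep(c(2L, 1L, 0L), m["control", ]))
  }
  colnames(geno) <- counts$snp_params$snp_id
  structure(list(genotypes = geno,
                 phenotype = rep(c("case", "control"), c(n_ca, n_co)),
                 snp_params = counts$snp_params,
                 config = config),
            class = "sim_dataset")
}

# Group-level simulation: returns per-SNP genotype_counts tables without
# expanding to individuals. This is the path the experiment harness uses.
simulate_genotype_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  snp_seeds <- sample.int(2147483646L, config$n_snps)
  random_maf <- identical(config$maf_controls, "random")
  tables <- vector("list", config$n_snps)
  p_co <- p_ca <- numeric(config$n_snps)
  ids <- sprintf("snp%05d", seq_len(config$n_snps))
  for (j in seq_len(config$n_snps)) {
    set.seed(snp_seeds[j])
    pc <- if (random_maf)
      stats::runif(1, config$random_maf_bounds[1], config$random_maf_bounds[2])
    else config$maf_controls
    pa <- case_maf_from_or(pc, config$odds_ratio)
    cnt_ca <- stats::rmultinom(1, config$n_cases, hwe_probs(pa))[, 1]
    cnt_co <- stats::rmultinom(1, config$n_controls, hwe_probs(pc))[, 1]
    tables[[j]] <- genotype_counts(cnt_ca, cnt_co, snp_id = ids[j])
    p_co[j] <- pc
    p_ca[j] <- pa
  }
  list(tables = tables,
       snp_params = data.frame(snp_id = ids, maf_controls = p_co,
                               maf_cases = p_ca,
                               odds_ratio = config$odds_ratio,
                               stringsAsFactors = FALSE))
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("Simulated dataset: %d individuals (%d cases / %d controls), %d SNPs\n",
              nrow(x$genotypes), x$config$n_cases, x$config$n_controls,
              ncol(x$genotypes)))
  invisible(x)
}
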