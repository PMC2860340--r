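# Registry of per-SNP tests. Each entry takes a genotype_counts table and
# returns an assoc_test; allelic tests collapse it first.
.test_registry <- list(
  entropy_genotypic = function(tab) entropy_genotypic_test(tab),
  entropy_allelic   = function(tab) entropy_allelic_test(genotype_to_allele_table(tab)),
  chisq_genotypic   = function(tab) pearson_chisq_genotypic(tab),
  chisq_allelic     = function(tab) pearson_chisq_allelic(genotype_to_allele_table(tab)),
  fisher_2x2        = function(tab) fisher_exact_2x2(genotype_to_allele_table(tab)),
  fisher_2x3        = function(tab) fisher_exact_2x3(tab)
)

#' Names of the available association tests
#' @return Character vector of test identifiers accepted by
#'   [run_experiment] and [snp_association].
#' @export
available_tests <- function() names(.test_registry)

#' Empirical rejection rate at one or more significance levels
#'
#' `rate(alpha) = #\{p < alpha\} / length(p)`. Rejection uses the strict
#' inequality `p < alpha` (equivalently, statistic above the critical value);
#' the choice only matters for discrete Fisher p-values. Degenerate SNPs
#' (p = 1) count in the denominator, so rates estimate the unconditional
#' type-I error or power.
#'
#' @param p_values numeric vector of p-values in [0, 1].
#' @param alphas numeric vector of significance levels in (0, 1).
#' @return Named numeric vector of rates, one per alpha.
#' @examples
#' empirical_rejection_rate(c(0.001, 0.5, 0.9, 0.04), 0.05)  # 0.5
#' @export
empirical_rejection_rate <- function(p_values, alphas) {
  if (length(p_values) == 0) stop("no p-values supplied", call. = FALSE)
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  if (any(alphas <= 0 | alphas >= 1))
    stop("alphas must lie strictly in (0, 1)", call. = FALSE)
  stats::setNames(vapply(alphas, function(a) mean(p_values < a), numeric(1)),
                  format(alphas, trim = TRUE))
}

#' Experiment grid for size/power estimation
#'
#' A list of simulation configurations to run, the tests to apply to every
#' SNP, and the significance levels at which to count rejections.
#'
#' @param configs a [sim_config] or list of them.
#' @param alphas significance levels, strictly in (0, 1). Default: the seven
#'   levels from 0.05 down to 1e-7 used throughout the size/power analyses.
#' @param tests subset of [available_tests()].
#' @param seed optional master seed: when given, each configuration's seed is
#'   replaced by `(seed + small hash of the configuration parameters) mod
#'   (2^31 - 1)`, making cells independent and the whole grid reproducible
#'   from one integer.
#' @return An object of class `experiment_grid`.
#' @export
experiment_grid <- function(configs,
                            alphas = c(0.05, 0.01, 1e-3, 1e-4, 1e-5, 1e-6, 1e-7),
                            tests = c("entropy_genotypic", "entropy_allelic",
                                      "chisq_genotypic", "chisq_allelic"),
                            seed = NULL) {
  if (inherits(configs, "sim_config")) configs <- list(configs)
  stopifnot(length(configs) >= 1,
            all(vapply(configs, inherits, logical(1), "sim_config")))
  if (any(alphas <= 0 | alphas >= 1))
    stop("alphas must lie strictly in (0, 1)", call. = FALSE)
  tests <- match.arg(tests, available_tests(), several.ok = TRUE)
  if (!is.null(seed)) {
    configs <- lapply(seq_along(configs), function(i) {
      cf <- configs[[i]]
      cf$seed <- .config_seed(seed, cf, i)
      cf
    })
  }
  structure(list(configs = configs, alphas = sort(alphas, decreasing = TRUE),
                 tests = tests),
            class = "experiment_grid")
}

# Deterministic 31-bit seed from a master seed and the config parameters.
.config_seed <- function(master, config, index) {
  key <- paste(config$n_cases, config$n_controls, config$n_snps,
               config$odds_ratio, config$maf_controls, index, sep = ":")
  h <- 0
  for (v in utf8ToInt(key)) h <- (h * 31 + v) %% 2147483647
  as.integer((as.numeric(master) + h) %% 2147483646 + 1)
}

#' Run a size/power experiment grid
#'
#' For every configuration: simulate the per-SNP case-control genotype counts,
#' apply every requested test to every SNP, and aggregate empirical rejection
#' rates at every significance level. For the test pairs
#' (entropy_genotypic, chisq_genotypic) and (entropy_allelic, chisq_allelic),
#' when both members were run, the per-configuration chi-square gain summary
#' of [chisq_gain] is also reported. Deterministic given the configuration
#' seeds.
#'
#' @param grid an [experiment_grid].
#' @param keep_pvalues if `TRUE`, retain the per-SNP p-value matrix of every
#'   configuration in the result (`$pvalues`).
#' @param verbose print per-configuration progress (runtime, degenerate-SNP
#'   count).
#' @return An object of class `power_report`: a list with `rates` (data.frame
#'   with columns config, test, alpha, rejected, total, rate), `gains`
#'   (data.frame with columns config, comparison, mean_diff, mean_prop_gain,
#'   n_excluded), `degenerate` (per config x test degenerate-SNP counts),
#'   `grid`, and optionally `pvalues`.
#' @examples
#' g <- experiment_grid(sim_config(100, 100, 20, odds_ratio = 2,
#'                                 maf_controls = 0.2, seed = 7),
#'                      alphas = c(0.05, 0.01))
#' run_experiment(g)
#' @export
run_experiment <- function(grid, keep_pvalues = FALSE, verbose = FALSE) {
  stopifnot(inherits(grid, "experiment_grid"))
  rates <- list(); gains <- list(); degen <- list(); pv_keep <- list()
  pairs <- list(c("entropy_genotypic", "chisq_genotypic"),
                c("entropy_allelic", "chisq_allelic"))
  for (cf in grid$configs) {
    t0 <- proc.time()[["elapsed"]]
    sim <- simulate_genotype_counts(cf)
    res <- run_tests_on_tables(sim$tables, grid$tests)
    for (ts in grid$tests) {
      pv <- res$p_value[, ts]
      rej <- vapply(grid$alphas, function(a) sum(pv < a), numeric(1))
      rates[[length(rates) + 1L]] <- data.frame(
        config = cf$label, test = ts, alpha = grid$alphas,
        rejected = as.integer(rej), total = length(pv),
        rate = rej / length(pv), stringsAsFactors = FALSE)
      degen[[length(degen) + 1L]] <- data.frame(
        config = cf$label, test = ts,
        n_degenerate = sum(res$degenerate[, ts]),
        stringsAsFactors = FALSE)
    }
    for (pr in pairs) {
      if (all(pr %in% grid$tests)) {
        g <- chisq_gain(res$statistic[, pr[1]], res$statistic[, pr[2]])
        gains[[length(gains) + 1L]] <- data.frame(
          config = cf$label,
          comparison = paste(pr, collapse = " - "),
          mean_diff = g[["mean_diff"]],
          mean_prop_gain = g[["mean_prop_gain"]],
          n_excluded = g[["n_excluded"]], stringsAsFactors = FALSE)
      }
    }
    if (keep_pvalues) pv_keep[[cf$label]] <- res$p_value
    if (verbose)
      message(sprintf("[%s] %d SNPs, %.1fs, %d degenerate tests",
                      cf$label, cf$n_snps,
                      proc.time()[["elapsed"]] - t0, sum(res$degenerate)))
  }
  out <- list(rates = do.call(rbind, rates),
              gains = if (length(gains)) do.call(rbind, gains) else NULL,
              degenerate = do.call(rbind, degen),
              grid = grid)
  if (keep_pvalues) out$pvalues <- pv_keep
  structure(out, class = "power_report")
}

# Apply tests to a list of genotype_counts tables; returns matrices of
# statistics, p-values and degenerate flags (SNP x test).
run_tests_on_tables <- function(tables, tests) {
  tests <- match.arg(tests, available_tests(), several.ok = TRUE)
  n <- length(tables)
  stat <- pval <- matrix(NA_real_, n, length(tests),
                         dimnames = list(NULL, tests))
  degen <- matrix(FALSE, n, length(tests), dimnames = list(NULL, tests))
  for (i in seq_len(n)) {
    for (ts in tests) {
      r <- .test_registry[[ts]](tables[[i]])
      stat[i, ts] <- r$statistic
      pval[i, ts] <- r$p_value
      degen[i, ts] <- r$degenerate
    }
  }
  list(statistic = stat, p_value = pval, degenerate = degen)
}

#' @export
print.power_report <- function(x, digits = 4, ...) {
  cat("Empirical rejection rates\n")
  print(x$rates, digits = digits, row.names = FALSE)
  if (!is.null(x$gains)) {
    cat("\nMean statistic gains (entropy - conventional)\n")
    print(x$gains, digits = digits, row.names = FALSE)
  }
  invisible(x)
}

#' Mean chi-square gain between two matched sets of statistics
#'
#' Summarizes how much larger one test's statistic is than another's over the
#' same SNPs: the mean difference `mean(a - b)` and the mean proportional
#' gain `mean((a - b) / b)`, the latter over SNPs with `b > 0` (SNPs with a
#' zero reference statistic are excluded from the proportional mean and
#' counted in `n_excluded`).
#'
#' @param stats_a,stats_b numeric vectors of per-SNP statistics (same SNPs,
#'   same order), or lists of `assoc_test` objects.
#' @return Named numeric vector: `mean_diff`, `mean_prop_gain`, `n_excluded`.
#' @examples
#' chisq_gain(c(2, 4), c(1, 2))   # mean_diff 1.5, mean_prop_gain 1
#' @export
chisq_gain <- function(stats_a, stats_b) {
  stats_a <- .as_stat_vector(stats_a)
  stats_b <- .as_stat_vector(stats_b)
  if (length(stats_a) != length(stats_b))
    stop("statistic vectors must be matched (same SNPs, same order)",
         call. = FALSE)
  d <- stats_a - stats_b
  pos <- stats_b > 0
  c(mean_diff = mean(d),
    mean_prop_gain = if (any(pos)) mean(d[pos] / stats_b[pos]) else NA_real_,
    n_excluded = sum(!pos))
}

.as_stat_vector <- function(x) {
  if (is.list(x)) vapply(x, function(r) r$statistic, numeric(1)) else
    as.numeric(x)
}

#' Preset experiment grids
#'
#' Ready-made grids matching the three simulation designs used in the
#' size/power study:
#' \describe{
#'   \item{`"null_calibration"`}{10,000 null SNPs (odds ratio 1, control MAF
#'     uniform in (0, 0.5)), 500 cases / 500 controls — empirical type-I
#'     error of the chi-square-referenced tests.}
#'   \item{`"power_small"`}{100-SNP cells over odds ratios 1.25 / 1.5 / 2 and
#'     MAF 0.05 / 0.2 / 0.4 at 500/500 — power of the allelic and genotypic
#'     tests.}
#'   \item{`"low_maf"`}{1,000-SNP cells over odds ratios 1 / 1.5 / 1.8 and
#'     MAF 0.01 / 0.03 / 0.06 at 5,000/5,000 — behaviour on low-frequency
#'     markers (add the Fisher tests via `tests=` to compare exact and
#'     asymptotic tests).}
#' }
#'
#' @param name preset name.
#' @param seed master seed passed to [experiment_grid].
#' @param scale multiplier on the number of SNPs per cell (e.g. `scale = 0.1`
#'   for a quick look); at least 1 SNP per cell.
#' @param tests tests to run (default: the four chi-square-referenced tests).
#' @return An [experiment_grid].
#' @export
preset_grid <- function(name = c("null_calibration", "power_small", "low_maf"),
                        seed = 1L, scale = 1,
                        tests = c("entropy_genotypic", "entropy_allelic",
                                  "chisq_genotypic", "chisq_allelic")) {
  name <- match.arg(name)
  ns <- function(n) max(1L, as.integer(round(n * scale)))
  configs <- switch(name,
    null_calibration = list(
      sim_config(500, 500, ns(10000), odds_ratio = 1,
                 maf_controls = "random")),
    power_small = {
      grid <- expand.grid(or = c(1.25, 1.5, 2), maf = c(0.05, 0.2, 0.4))
      lapply(seq_len(nrow(grid)), function(i)
        sim_config(500, 500, ns(100), odds_ratio = grid$or[i],
                   maf_controls = grid$maf[i]))
    },
    low_maf = {
      grid <- expand.grid(or = c(1, 1.5, 1.8), maf = c(0.01, 0.03, 0.06))
      lapply(seq_len(nrow(grid)), function(i)
        sim_config(5000, 5000, ns(1000), odds_ratio = grid$or[i],
                   maf_controls = grid$maf[i]))
    })
  experiment_grid(configs, tests = tests, seed = seed)
}
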