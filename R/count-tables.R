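#' Genotype count table for one SNP
#'
#' Construct the 2x3 contingency table of genotype counts by case/control
#' status that every test in this package operates on. Genotypes are labelled
#' by the number of copies of the minor allele A: `AA` (two copies, code 2),
#' `Aa` (one copy, code 1) and `aa` (none, code 0).
#'
#' @param cases integer vector of length 3: counts of (AA, Aa, aa) in cases.
#' @param controls integer vector of length 3: counts of (AA, Aa, aa) in
#'   controls.
#' @param snp_id identifier for the SNP (single string).
#' @return An object of class `genotype_counts`: a 2x3 integer matrix with
#'   rows `case`, `control` and columns `AA`, `Aa`, `aa`, plus a `snp_id`
#'   attribute.
#' @examples
#' genotype_counts(c(10, 20, 30), c(30, 20, 10), "rs0001")
#' @export
genotype_counts <- function(cases, controls, snp_id = "snp") {
  .check_counts(cases, 3L, "cases")
  .check_counts(controls, 3L, "controls")
  m <- rbind(case = as.integer(round(cases)),
             control = as.integer(round(controls)))
  colnames(m) <- c("AA", "Aa", "aa")
  structure(m, snp_id = as.character(snp_id)[1], class = "genotype_counts")
}

#' Allele count table for one SNP
#'
#' The 2x2 contingency table of allele counts (minor allele `A`, major allele
#' `a`) by case/control status used by the allelic tests.
#'
#' @param cases integer vector of length 2: counts of (A, a) alleles in cases.
#' @param controls integer vector of length 2: counts of (A, a) alleles in
#'   controls.
#' @param snp_id identifier for the SNP.
#' @return An object of class `allele_counts`: a 2x2 integer matrix with rows
#'   `case`, `control` and columns `A`, `a`.
#' @examples
#' allele_counts(c(40, 80), c(80, 40))
#' @export
allele_counts <- function(cases, controls, snp_id = "snp") {
  .check_counts(cases, 2L, "cases")
  .check_counts(controls, 2L, "controls")
  m <- rbind(case = as.integer(round(cases)),
             control = as.integer(round(controls)))
  colnames(m) <- c("A", "a")
  structure(m, snp_id = as.character(snp_id)[1], class = "allele_counts")
}

.check_counts <- function(x, len, what) {
  if (length(x) != len || anyNA(x) || !is.numeric(x))
    stop(sprintf("'%s' must be %d non-missing numeric counts", what, len),
         call. = FALSE)
  if (any(x < 0)) stop(sprintf("'%s' counts must be >= 0", what), call. = FALSE)
  if (any(abs(x - round(x)) > 1e-8))
    stop(sprintf("'%s' counts must be whole numbers", what), call. = FALSE)
  invisible(TRUE)
}

#' @export
print.genotype_counts <- function(x, ...) {
  cat("Genotype counts for", attr(x, "snp_id"), "\n")
  print(unclass(x)[, , drop = FALSE])
  invisible(x)
}

#' @export
print.allele_counts <- function(x, ...) {
  cat("Allele counts for", attr(x, "snp_id"), "\n")
  print(unclass(x)[, , drop = FALSE])
  invisible(x)
}

#' Tabulate coded genotypes into a count table
#'
#' Cross-tabulates a vector of per-individual genotype codes (0/1/2 = number
#' of minor-allele copies, `NA` = missing) against case/control labels.
#' Individuals with a missing code at this SNP are excluded, so the effective
#' sample size may differ across SNPs (per-SNP listwise exclusion).
#'
#' @param codes integer vector of genotype codes in `{0, 1, 2, NA}`.
#' @param labels case/control labels, one per individual: a character/factor
#'   vector with values `"case"`/`"control"`.
#' @param snp_id identifier for the SNP.
#' @return A [genotype_counts] table over the non-missing individuals.
#' @examples
#' tabulate_genotypes(c(2, 1, 0, 2), c("case", "case", "control", "control"))
#' @export
tabulate_genotypes <- function(codes, labels, snp_id = "snp") {
  if (length(codes) != length(labels))
    stop("'codes' and 'labels' must have equal length", call. = FALSE)
  lab <- .as_phenotype(labels)
  bad <- !is.na(codes) & !(codes %in% c(0, 1, 2))
  if (any(bad))
    stop(sprintf("invalid genotype code(s): %s",
                 paste(unique(codes[bad]), collapse = ", ")), call. = FALSE)
  keep <- !is.na(codes)
  if (!any(keep))
    stop("all genotype codes are missing: degenerate table", call. = FALSE)
  codes <- codes[keep]
  lab <- lab[keep]
  cnt <- function(grp) {
    v <- codes[lab == grp]
    c(sum(v == 2L), sum(v == 1L), sum(v == 0L))
  }
  genotype_counts(cnt("case"), cnt("control"), snp_id = snp_id)
}

# Normalize phenotype labels to a character vector of "case"/"control".
# Accepts "case"/"control" strings/factors or the PLINK 1 = control / 2 = case
# numeric coding.
.as_phenotype <- function(labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.numeric(labels)) {
    if (!all(labels %in% c(1, 2)))
      stop("numeric phenotype must be coded 1 = control / 2 = case",
           call. = FALSE)
    return(ifelse(labels == 2, "case", "control"))
  }
  labels <- tolower(as.character(labels))
  if (!all(labels %in% c("case", "control")))
    stop("phenotype labels must be 'case' or 'control' (or 1/2)",
         call. = FALSE)
  labels
}

#' Collapse a genotype table to an allele table
#'
#' Each `AA` individual contributes two copies of the minor allele A, each
#' heterozygote one copy of each allele, and each `aa` individual two copies
#' of the major allele, separately in cases and controls. The total allele
#' count is exactly twice the number of genotyped individuals.
#'
#' @param table a [genotype_counts] object.
#' @return An [allele_counts] object with the same `snp_id`.
#' @examples
#' g <- genotype_counts(c(10, 20, 30), c(5, 10, 15))
#' genotype_to_allele_table(g)
#' @export
genotype_to_allele_table <- function(table) {
  stopifnot(inherits(table, "genotype_counts"))
  m <- unclass(table)
  al <- function(row) c(A = 2L * row[[1]] + row[[2]],
                        a = row[[2]] + 2L * row[[3]])
  allele_counts(al(m["case", ]), al(m["control", ]),
                snp_id = attr(table, "snp_id"))
}

# Pooled minor-allele frequency from a genotype table (frequency of the
# allele counted by the 0/1/2 coding; can exceed 0.5 if the designated
# allele is not actually minor in this sample).
pooled_maf <- function(table) {
  m <- unclass(table)
  n <- sum(m)
  if (n == 0) return(NA_real_)
  (2 * sum(m[, "AA"]) + sum(m[, "Aa"])) / (2 * n)
}
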