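#' Read case-control genotype data
#'
#' Reads a genotype matrix plus phenotype labels from either of two text
#' dialects:
#' \describe{
#'   \item{`"tsv"`}{a tab-separated matrix, one row per individual: a header
#'     of SNP ids plus one `phenotype` column; genotype cells are 0/1/2
#'     (minor-allele copies) or `NA`; phenotype is `case`/`control` (or the
#'     1 = control / 2 = case coding).}
#'   \item{`"ped_map"`}{PLINK text pedigree files: `.ped` rows of
#'     `FID IID PAT MAT SEX PHENO` followed by two allele characters
#'     (A/C/G/T, `0` = missing) per SNP, with phenotype 1 = control /
#'     2 = case, and a `.map` file (chromosome, SNP id, position columns)
#'     naming the SNPs. The minor allele of each SNP is determined from the
#'     pooled sample (ties broken toward the alphabetically first allele) and
#'     genotypes are coded as minor-allele counts; the chosen allele is
#'     reported so codes remain interpretable.}
#' }
#'
#' @param path path to the `.tsv`/`.ped` file (or a prefix, for `ped_map`,
#'   when both files share it).
#' @param format `"tsv"` or `"ped_map"`; default guessed from the extension.
#' @param map_path path to the `.map` file; defaults to `path` with its
#'   extension replaced by `.map`.
#' @return A list of class `genotype_data`: `genotypes` (integer matrix,
#'   individuals x SNPs, `NA` = missing), `phenotype`
#'   (`"case"`/`"control"`), `snp_ids`, and for `ped_map` input
#'   `minor_allele`/`major_allele` per SNP.
#' @export
read_genotypes <- function(path, format = c("auto", "tsv", "ped_map"),
                           map_path = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.ped$", path, ignore.case = TRUE)) "ped_map" else "tsv"
  switch(format, tsv = .read_tsv_genotypes(path),
         ped_map = .read_ped_map(path, map_path))
}

.read_tsv_genotypes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = "NA")
  if (!"phenotype" %in% names(df))
    stop("TSV genotype file must contain a 'phenotype' column", call. = FALSE)
  pheno <- .as_phenotype(df$phenotype)
  snp_cols <- setdiff(names(df), "phenotype")
  if (length(snp_cols) == 0) stop("no SNP columns found", call. = FALSE)
  g <- as.matrix(df[snp_cols])
  if (!is.numeric(g)) {
    bad_row <- which(apply(df[snp_cols], 1,
                           function(r) any(!is.na(r) &
                                           !r %in% c("0", "1", "2"))))[1]
    stop(sprintf("non-numeric genotype code at data line %d", bad_row),
         call. = FALSE)
  }
  bad <- which(!is.na(g) & !(g %in% c(0, 1, 2)), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("invalid genotype code %s at data line %d (SNP %s)",
                 g[bad[1, , drop = FALSE]], bad[1, 1], snp_cols[bad[1, 2]]),
         call. = FALSE)
  storage.mode(g) <- "integer"
  structure(list(genotypes = g, phenotype = pheno, snp_ids = snp_cols),
            class = "genotype_data")
}

.read_ped_map <- function(path, map_path = NULL) {
  ped_path <- if (grepl("\\.ped$", path, ignore.case = TRUE)) path
              else paste0(path, ".ped")
  if (is.null(map_path)) map_path <- sub("\\.ped$", ".map", ped_path,
                                         ignore.case = TRUE)
  if (!file.exists(ped_path)) stop("file not found: ", ped_path, call. = FALSE)
  if (!file.exists(map_path)) stop("file not found: ", map_path, call. = FALSE)
  map <- utils::read.table(map_path, header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(map) < 2) stop("malformed .map file: fewer than 2 columns",
                          call. = FALSE)
  snp_ids <- as.character(map[[2]])
  m <- length(snp_ids)

  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "[ \t]+")
  want <- 6L + 2L * m
  lens <- lengths(toks)
  if (any(lens != want))
    stop(sprintf(".ped line %d has %d fields, expected %d",
                 which(lens != want)[1], lens[lens != want][1], want),
         call. = FALSE)
  tk <- do.call(rbind, toks)
  pheno_raw <- tk[, 6]
  if (!all(pheno_raw %in% c("1", "2")))
    stop(sprintf(".ped line %d: phenotype '%s' outside {1 = control, 2 = case}",
                 which(!pheno_raw %in% c("1", "2"))[1],
                 pheno_raw[!pheno_raw %in% c("1", "2")][1]), call. = FALSE)
  pheno <- ifelse(pheno_raw == "2", "case", "control")
  al <- toupper(tk[, -(1:6), drop = FALSE])
  ok <- al %in% c("A", "C", "G", "T", "0")
  if (!all(ok)) {
    bad <- which(matrix(!ok, nrow(al)), arr.ind = TRUE)[1, ]
    stop(sprintf(".ped line %d: unknown allele character '%s'",
                 bad[1], al[bad[1], bad[2]]), call. = FALSE)
  }
  g <- matrix(NA_integer_, nrow(al), m)
  minor <- major <- character(m)
  for (j in seq_len(m)) {
    a1 <- al[, 2L * j - 1L]
    a2 <- al[, 2L * j]
    miss <- a1 == "0" | a2 == "0"
    obs <- c(a1[!miss], a2[!miss])
    alleles <- sort(unique(obs))
    if (length(alleles) > 2)
      stop(sprintf("SNP %s has %d alleles; only biallelic markers supported",
                   snp_ids[j], length(alleles)), call. = FALSE)
    if (length(alleles) == 0) {
      minor[j] <- major[j] <- NA_character_
      next
    }
    counts <- table(factor(obs, levels = alleles))
    # pooled-sample minor allele; tie broken toward the alphabetically first
    minor[j] <- alleles[which.min(counts)]
    major[j] <- if (length(alleles) == 2) setdiff(alleles, minor[j]) else minor[j]
    if (length(alleles) == 1) minor[j] <- alleles  # monomorphic: code all 2
    g[, j] <- (a1 == minor[j]) + (a2 == minor[j])
    g[miss, j] <- NA_integer_
  }
  structure(list(genotypes = g, phenotype = pheno, snp_ids = snp_ids,
                 minor_allele = minor, major_allele = major),
            class = "genotype_data")
}

#' @export
print.genotype_data <- function(x, ...) {
  cat(sprintf("Genotype data: %d individuals (%d cases / %d controls), %d SNPs\n",
              nrow(x$genotypes), sum(x$phenotype == "case"),
              sum(x$phenotype == "control"), ncol(x$genotypes)))
  invisible(x)
}

#' Write genotype data to TSV or PLINK text files
#'
#' The inverse of [read_genotypes]: writes the individuals-by-SNPs code
#' matrix either as the TSV dialect (codes 0/1/2, `NA` for missing, one
#' `phenotype` column) or as a `.ped`/`.map` pair, spelling code 2 as `A A`,
#' 1 as `A G`, 0 as `G G` and missing as `0 0`.
#'
#' @param data a `sim_dataset`, `genotype_data`, or list with `genotypes`,
#'   `phenotype` and optionally `snp_ids`.
#' @param path output path: the TSV file, or the prefix for `prefix.ped` /
#'   `prefix.map`.
#' @param format `"tsv"` or `"ped_map"`.
#' @return Invisibly, the path(s) written.
#' @export
write_genotypes <- function(data, path, format = c("tsv", "ped_map")) {
  format <- match.arg(format)
  g <- data$genotypes
  pheno <- .as_phenotype(data$phenotype)
  ids <- if (!is.null(data$snp_ids)) data$snp_ids
         else if (!is.null(colnames(g))) colnames(g)
         else sprintf("snp%05d", seq_len(ncol(g)))
  if (format == "tsv") {
    df <- as.data.frame(g)
    names(df) <- ids
    df$phenotype <- pheno
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(path))
  }
  ped_path <- paste0(path, ".ped")
  map_path <- paste0(path, ".map")
  spell <- c(`0` = "G G", `1` = "A G", `2` = "A A")
  n <- nrow(g)
  rows <- character(n)
  for (i in seq_len(n)) {
    gt <- ifelse(is.na(g[i, ]), "0 0", spell[as.character(g[i, ])])
    rows[i] <- paste(c(sprintf("F%04d", i), sprintf("I%04d", i), "0", "0",
                       "0", if (pheno[i] == "case") "2" else "1", gt),
                     collapse = " ")
  }
  writeLines(rows, ped_path)
  writeLines(sprintf("1\t%s\t0\t%d", ids, seq_along(ids)), map_path)
  invisible(c(ped_path, map_path))
}

#' Per-SNP association testing over a whole dataset
#'
#' Applies the requested tests to every SNP: each SNP is tabulated with
#' [tabulate_genotypes] (individuals missing at that SNP are excluded from
#' that SNP only) and every test run on the resulting table.
#'
#' @param data a `genotype_data` / `sim_dataset` / list with `genotypes`
#'   (individuals x SNPs code matrix), `phenotype`, optional `snp_ids`.
#' @param tests subset of [available_tests()].
#' @return A data.frame with one row per SNP in input order: `snp_id`,
#'   `n_cases_used`, `n_controls_used`, `maf_pooled`, `degenerate` (TRUE if
#'   the SNP is monomorphic / single-group), and `<test>_stat`, `<test>_df`,
#'   `<test>_p` columns per test.
#' @examples
#' d <- simulate_genotypes(sim_config(60, 60, 4, odds_ratio = 1.5,
#'                                    maf_controls = 0.3, seed = 9))
#' snp_association(d, tests = c("entropy_genotypic", "chisq_genotypic"))
#' @export
snp_association <- function(data,
                            tests = c("entropy_genotypic", "entropy_allelic",
                                      "chisq_genotypic", "chisq_allelic")) {
  tests <- match.arg(tests, available_tests(), several.ok = TRUE)
  g <- data$genotypes
  pheno <- .as_phenotype(data$phenotype)
  ids <- if (!is.null(data$snp_ids)) data$snp_ids
         else if (!is.null(colnames(g))) colnames(g)
         else sprintf("snp%05d", seq_len(ncol(g)))
  tables <- lapply(seq_len(ncol(g)), function(j)
    tabulate_genotypes(g[, j], pheno, snp_id = ids[j]))
  res <- run_tests_on_tables(tables, tests)
  base <- data.frame(
    snp_id = ids,
    n_cases_used = vapply(tables, function(t) sum(unclass(t)["case", ]),
                          numeric(1)),
    n_controls_used = vapply(tables, function(t) sum(unclass(t)["control", ]),
                             numeric(1)),
    maf_pooled = vapply(tables, pooled_maf, numeric(1)),
    degenerate = vapply(tables, function(t) .is_degenerate(unclass(t)),
                        logical(1)),
    stringsAsFactors = FALSE)
  for (ts in tests) {
    base[[paste0(ts, "_stat")]] <- res$statistic[, ts]
    base[[paste0(ts, "_df")]] <- rep(switch(ts, entropy_genotypic = 2L,
                                            chisq_genotypic = 2L,
                                            entropy_allelic = 1L,
                                            chisq_allelic = 1L, 0L),
                                     nrow(base))
    base[[paste0(ts, "_p")]] <- res$p_value[, ts]
  }
  base
}

#' Write association results (or any report) as TSV
#'
#' Tab-separated, one header row; p-value columns (names ending in `_p` or
#' named `p_value`) are rendered in scientific notation with 6 significant
#' digits.
#'
#' @param rows data.frame of results, e.g. from [snp_association].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_results <- function(rows, path) {
  stopifnot(is.data.frame(rows))
  out <- rows
  pcols <- grep("(_p$|^p_value$)", names(out), value = TRUE)
  for (cl in pcols) out[[cl]] <- sprintf("%.5e", rows[[cl]])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
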