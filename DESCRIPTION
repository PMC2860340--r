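Package: snpentropy
Title: Symbolic-Entropy Likelihood-Ratio Tests for Case-Control SNP Association
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Single-SNP case-control association testing based on symbolic
    entropy. Implements the entropy genotypic (2 df) and allelic (1 df)
    likelihood-ratio tests together with the conventional Pearson chi-square
    tests and Fisher exact tests (2x2 and Freeman-Halton 2x3) used as
    comparators in genetic association studies. Includes a Hardy-Weinberg
    genotype simulator that fixes the allelic odds ratio and control minor
    allele frequency, an experiment harness estimating empirical type-I error
    and power over simulation grids, readers for PLINK text (.ped/.map) and
    TSV genotype matrices, and a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
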