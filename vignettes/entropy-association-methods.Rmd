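---
title: "Entropy-based single-SNP association tests: model, conventions, simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Entropy-based single-SNP association tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpentropy)
```

## The model

A biallelic SNP partitions a case-control sample two ways: by genotype
(`AA`, `Aa`, `aa`, coded 2/1/0 copies of the minor allele `A`) and by status
(case/control). Under the null hypothesis of no association the genotype
distribution is the same in both status groups; the six joint
(genotype, status) cell probabilities then factor into the product of their
margins.

Treat the six cell counts as one multinomial observation of size `N`. The
likelihood-ratio statistic for the factorization null, `-2 log λ`, reduces
algebraically to an entropy expression: writing `h(·)` for Shannon entropy
in nats,

$$GE = 2N\,[\,h(C,C^c) + h(S) - h(S,ca) - h(S,co)\,],$$

where `h(C,Cc)` is the entropy of the case/control split, `h(S)` the
entropy of the pooled genotype frequencies, and the partial-group terms use
*joint* frequencies `n(X,t)/N`:

$$h(S,t) = -\sum_{X} \frac{n(X,t)}{N} \ln \frac{n(X,t)}{N}.$$

Two readings of `h(S,t)` are conceivable — joint frequencies `n(X,t)/N` or
within-group frequencies `n(X,t)/N_t`. Only the joint reading makes the
bracket the mutual information between genotype and status and `GE` the
exact multinomial likelihood-ratio G-statistic `2 Σ O ln(O/E)` of the 2×3
table; that identity is enforced to `1e-9` over random tables in the test
suite, with an independently coded G-statistic as the oracle. `GE` is
referred to `χ²(2)`.

The allelic test applies the identical decomposition to the 2×2 table of
allele counts (each individual contributes two alleles), scaled by the total
allele count `M` — equal to `2N` when no genotypes are missing — with 1 df.
Using `M` rather than any other multiplier again makes the statistic the
exact G-statistic of the allele table; this symmetry is the reason that
choice was made where the construction itself leaves the constant implicit.

Consistency follows from `-ln x > 1 - x`: the mutual information is zero
iff the case and control distributions coincide, and at fixed cell
frequencies the statistic is exactly linear in `N` (asserted as a property
test: scaling all counts by `k` scales the statistic by `k` to `1e-9`).

## Conventions that define the tests

* **Natural logarithms everywhere.** The chi-square reference distribution
  belongs to `-2 log λ`; entropies in bits would silently rescale the
  statistic.
* **`0 · ln 0 = 0`.** The continuity convention the entropy formula
  requires. A practical consequence: empty cells never produce
  `NaN`, so no grouping of rare categories is ever needed — a failure mode
  of entropy statistics that require differentiability in the cell
  frequencies.
* **Degrees of freedom are fixed** at 2 (genotypic) and 1 (allelic) even
  when a genotype or allele class is absent from the pooled sample. With a
  rare allele the third genotype class is often empty, the statistic
  effectively loses a dimension, and testing it against `χ²(2)` is
  conservative. That conservatism at MAF ≤ 1% is a deliberate, documented
  property of the procedure; adapting df would change the test.
* **Degenerate tables** (monomorphic SNP, or a single status group) get
  statistic 0, p = 1 and a `degenerate` flag rather than an error, so
  genome-scale scans and unconditional type-I-error estimates keep every
  SNP in the denominator.
* **Pearson comparators** skip cells with zero expected count and keep the
  same fixed df, mirroring the entropy convention so that any difference
  between the two tests is attributable to the statistics, not df
  bookkeeping.
* **Fisher exact tests** use the minimum-likelihood two-sided rule — the
  p-value sums the point probabilities of all margin-compatible tables not
  exceeding the observed table's — because it is the convention of the
  genetics software these tests are compared against. Ties are detected
  with a *relative* tolerance of `1e-12`: an additive tolerance would be a
  sizable fraction of the smallest point probabilities already at `N = 40`.
  The 2×3 (Freeman–Halton) version enumerates the case-row entries of the
  two smallest column margins with precomputed log-factorials; enumeration
  is exact by construction and refuses (with an explicit error, default cap
  `1e8` candidate tables) rather than approximating. For genotype tables
  this is rarely binding: at low MAF the two rare genotype columns are
  short, which is exactly the regime where an exact test is wanted.
* **Rejection is `p < α`** (strict), i.e. statistic strictly above the
  critical value; the distinction only matters for the discrete Fisher
  p-values.

## The simulator

The generator reproduces the study's data-generating algorithm. Per SNP:

1. fix the control minor allele frequency `p_co` — a configured value, or
   drawn uniformly from `(1e-6, 0.5)` for null panels (`1e-6` realizes the
   open lower bound; SNPs sampled monomorphic are *kept* and yield
   degenerate tests, preserving the unconditional reading of type-I
   error);
2. solve the allelic odds equation for cases,
   `p_ca = OR·p_co / (1 − p_co + OR·p_co)` — the odds ratio is defined on
   allele frequencies, the only formulation in which this closed form
   exists; genotype odds ratios then follow from HWE;
3. draw each group's genotype counts as one multinomial from the HWE
   probabilities `(p², 2p(1−p), (1−p)²)` — identical in law to independent
   individual draws, and expanded to an individual-level 0/1/2 matrix in a
   fixed order when a dataset (rather than count tables) is requested.

Reproducibility: one stream is seeded from the configuration seed and one
31-bit sub-seed per SNP is drawn up front, so SNP `j` is invariant to
`n_snps`, and experiment grids derive per-configuration seeds from a master
seed plus a parameter hash, making every cell independently reproducible.

What the generator deliberately does **not** emulate: linkage
disequilibrium between SNPs (every SNP is independent), population
structure or relatedness, genotyping error and missingness, deviation from
HWE within groups, and covariates. Passing size/power checks therefore
demonstrate the behaviour of the statistics under clean single-locus
sampling — the regime the study's tables describe — not robustness to the
confounders of real GWAS data. The file readers accept real data
(PLINK text or TSV, with per-SNP listwise exclusion of missing genotypes —
the minimal standard policy, chosen here since the original analysis left
missing-data handling unstated), but no claim about confounded data is
implied by the simulations.

## Parameters that matter

| Parameter | Units / range | Default | Why |
|---|---|---|---|
| `odds_ratio` | allelic odds ratio, > 0 | 1 | 1 = null; the study's effect sizes are 1.25–2 |
| `maf_controls` | frequency in (0, 0.5] or `"random"` | `"random"` | fixed for power cells; uniform (0, 0.5) for null calibration |
| `n_cases`, `n_controls` | individuals | — | 500/500 for the main grid, 5000/5000 for low-MAF cells |
| `alphas` | levels in (0, 1) | 0.05 … 1e-7 | the study's seven thresholds; no multiplicity correction, raw α only |
| `max_tables` (Fisher 2×3) | candidate tables | 1e8 | capacity guard; exceeding it is an error, never an approximation |

The mean statistic gain reported by `chisq_gain()` is the average of
(entropy − conventional) statistics over *all* SNPs of a run — not only
rejected ones, which the original description leaves open — with
zero-statistic SNPs excluded from the proportional version and counted.

## Problem sizes

The packaged checks run the study at its printed scale: the null
calibration uses 10,000 SNPs at 500/500, power cells 100 SNPs, the low-MAF
and Fisher-comparison cells 1,000 SNPs at 5,000/5,000, with a 10,000-SNP
rerun of the headline power cell to pin its converged value. Monte-Carlo
tolerances in the tests are three binomial standard errors of the printed
cell (a factor-of-2 band for the two small mean gains, which are single-run
estimates of means of order 0.003–0.05). Property checks use 1,000 random
tables for the G-identity and exhaustive-plus-random table sets for the
exact-test identities.

## Known limitations

* Asymptotic p-values only for the entropy and Pearson tests; no
  permutation option. For rare alleles the exact tests are the appropriate
  comparator, and both they and the entropy tests are conservative below
  MAF ≈ 1%.
* Biallelic autosomal markers only: no multi-allelic, X/haploid, dominance
  or recessive codings, covariates, or epistasis.
* The allelic test assumes the two alleles of an individual are
  independent draws (HWE within groups); the genotypic test does not.
* Uniformity of null p-values is checked through tail rejection rates, not
  histogram fits: on count tables the p-value distribution is a lattice,
  and fine-grained uniformity tests reject even perfectly calibrated
  discrete statistics.
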