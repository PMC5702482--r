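---
title: "Measuring ancestry-based assortative mating: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring ancestry-based assortative mating}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(assortmate)
```

## The statistic and its assumptions

The package measures how strongly spouses resemble each other in genetic
ancestry. The underlying model is that, in a population with sub-structure,
the leading principal components of the (normalized) genotype matrix are
ancestry axes, so an individual's genetic background is summarized by a
handful of PC scores. For a set of couples, the per-PC Pearson correlation
between husbands' and wives' scores is then a direct measure of
ancestry-assortative mating: 0 under random mate choice, approaching the
between-group variance fraction of that PC under strict within-group
marriage.

Assumptions worth stating explicitly:

* **Top PCs are ancestry, not family.** With enough SNPs this holds
  (ancestry eigenvalues grow with sample size times differentiation, while
  cryptic-relatedness eigenvalues are bounded by family size). At small SNP
  counts it can fail; see *Limitations*.
* **Correlation is scale-free.** Pearson correlation is invariant to
  positive affine transforms of either argument, so the well-known
  ambiguity in PC score scaling (eigenvector normalization conventions
  differ across PCA implementations) provably cannot affect any reported
  statistic. This is tested as a property.
* **Couples are identifiable from pedigrees.** A spouse pair is defined as
  a male–female couple with at least one child in common in the pedigree
  file; couples without recorded children are invisible to this analysis.

## Pipeline stages and tunable parameters

### SNP quality control (`qc_params`)

| parameter | default | meaning |
|---|---|---|
| `min_call_rate` | 0.95 | keep a SNP iff its fraction of non-missing calls is **strictly** greater |
| `min_maf` | 0.05 | keep iff minor allele frequency (from mean dosage/2 over observed calls) is **strictly** greater |
| `prune_window` | 50 SNPs | LD-pruning window length, counted in SNPs (not kb) |
| `prune_step` | 5 SNPs | window advance, counted in original map order |
| `max_r2` | 0.30 | pairwise dosage r² threshold |

Boundary SNPs are removed at equality — the filters implement the strict
inequalities their descriptions state, and idempotence (filtering twice
changes nothing) is tested. Pruning is greedy within each window over
currently-kept SNPs; when a pair exceeds the threshold the **later SNP in
map order** is removed, a deterministic PLINK-like tie-break. Windows never
span chromosomes. After completion no kept pair inside any window exceeds
the threshold; an exhaustive checker verifies this on randomized planted-LD
instances. r² uses pairwise-complete samples (no imputation at this stage);
an undefined r² (constant SNP on the overlap, or fewer than two shared
samples) never causes a removal and is counted. Internally all window r²
values are computed exactly via crossproducts of the zero-filled dosage
matrix and its missingness mask, which is algebraically identical to
per-pair complete-case Pearson correlation but runs at BLAS speed.

### PCA (`patterson_normalize`, `run_pca`, `orient_signs`)

Per SNP with observed-dosage mean `2p̂`, entries become
`(g − 2p̂)/sqrt(p̂(1−p̂))` and missing cells become 0 — mean imputation
after centering, the standard smartpca behavior. Monomorphic and
all-missing SNPs are dropped (and logged) first. Scores and eigenvalues
come from the eigendecomposition of `XXᵀ/M`; scores are unit-norm
eigenvectors, deterministic up to column sign. `k` (retained components)
defaults to 8 and the variance-explained summary reports the fraction of
the top-`K` (default 30) eigenvalue mass carried by the first `k` — both
match common practice of choosing components from a scree plot.

Two deliberate omissions: no iterative outlier removal (EIGENSOFT's
σ-based sample exclusion rounds) — determinism matters more here and the
analyses this package reproduces did not report exclusions — and no
Tracy–Widom significance testing. Raw eigenvector signs are never exposed
to downstream logic: `orient_signs` flips columns so an anchor group's mean
score satisfies a stated convention (by default, anchor negative on PC1 and
PC2), making quadrant rules like "East: PC1 < 0 and PC2 < 0" reproducible.
An anchor mean of exactly zero leaves the sign unchanged with a warning.

### Spouse pairs and strata

Pairs are emitted from in-common children, requiring both parents to have
pedigree rows with consistent sexes and genotypes (and, downstream, PC
scores); every exclusion reason is counted separately. Remarriage — one
individual with children by two partners — would break the "no individual
in two pairs" invariant, so a deterministic first-spouse rule applies: more
in-common children wins, ties go to the lexicographically smaller partner
id. Pair extraction is a pure function of the pedigree (row order never
matters; tested by permutation).

Stratification splits pairs by generation or enrollment site and builds an
"excluding-site" complement containing pairs in which **neither** member
was enrolled at the excluded site, supporting sensitivity analyses of
site-driven homogeneity.

### Correlation table (`spouse_pc_table`, `fisher_ci`, `correlation_pvalue`)

For each stratum and PC (default PCs 1–6) the table reports n, r, a
Fisher-z confidence interval `tanh(atanh(r) ∓ z/sqrt(n−3))` and a two-sided
p-value from `t = r·sqrt(n−2)/sqrt(1−r²)` with n−2 df. The Fisher-z method
was chosen because it reproduces, at two-decimal rounding, the published
interval endpoints of the family studies this package emulates when fed
their printed (r, n); the t-test is the standard correlation test (the
source analyses do not state theirs). Husband scores are the x vector by
convention — irrelevant to r, fixed for reproducible intermediate files.
Display rounding is half-up to two decimals; machine-readable outputs keep
full precision.

### The pairing null (`random_pairing`, `null_distribution`)

The null asks: how much spouse-PC correlation would coarse ethnicity
matching alone produce? Within each ethnicity group, males and females are
independently shuffled and matched positionally without replacement
(`min(n_male, n_female)` pairs per group; leftovers counted); per
replicate, each PC's correlation is computed over all groups pooled. The
default 1000 replicates are summarized by the mean and the empirical
2.5th/97.5th percentiles (order statistics with linear interpolation —
the "95% quantile interval" convention is not further specified in the
literature this follows, so the common type-7 definition is used).
Individuals of unknown sex or without an ethnicity label are excluded from
the candidate pool and counted. The comparison report flags `exceeds_null`
when the observed r lies strictly above the upper quantile and gives the
empirical exceedance proportion.

The candidate pool is configurable (PC-quadrant labels by default,
pedigree ethnicity labels as an alternative) because the null's meaning
depends on how coarse the labels are relative to true structure: if labels
recover the true mating groups exactly, within-label random pairing *is*
the mating process under full endogamy and the observed correlation cannot
exceed the null; the published contrast (observed far above the null)
arises because real labels — "East European", "North European" — each span
many finer ethnicities that real spouses match on. The acceptance suite
reproduces exactly this geometry with four simulated subpopulations merged
into two labels.

## The synthetic cohort generator

`simulate_cohort` emulates a two-generation family study drawn from
several closely related subpopulations:

* **Allele frequencies.** Ancestral frequencies uniform on [0.1, 0.9]
  (common SNPs, as after a MAF-filtered array intersection); subpopulation
  frequencies Balding–Nichols, `Beta(p(1−F)/F, (1−p)(1−F)/F)`, so
  `E = p`, `Var = F·p(1−p)`. Default `F_ST = 0.01`, the magnitude of
  differentiation among European ethnicities.
* **Founders.** `2 × n_founder_couples_per_pop` individuals per
  subpopulation, dosages `Binomial(2, p_kj)` at unlinked SNPs, sexes
  balanced.
* **Mating with an endogamy dial.** Each pairing event is, with
  probability `endogamy`, constrained to a same-subpopulation partner;
  otherwise the partner is drawn at random from the whole remaining pool.
  The complement of endogamy is therefore *random* mating, not forced
  out-marriage: a person who does not marry within their group marries
  whomever, which can still be a co-ethnic by chance. (Forced exogamy
  would produce strongly *negative* spouse-PC correlations with two
  subpopulations — a disassortative regime no human cohort shows.) The
  truth record keeps both the Bernoulli intent (`endogamous`) and the
  realized label comparison (`same_subpop`). Defaults 0.9 (founders) and
  0.4 (offspring) echo the published generational decline. Same-family
  partners are excluded; unmatched individuals are dropped and counted.
* **Children.** One allele from each parent independently per SNP
  (unlinked transmission; no recombination map — LD-pruning correctness is
  tested on separately constructed correlated-SNP fixtures instead).
  Family sizes default to `1 + Poisson(2)` (mean 3, no childless couples),
  a plausible completed family size for the pre-war birth cohorts these
  studies enroll. Offspring of mixed couples inherit one parent's label at
  random and are flagged admixed.
* **Linking children.** Offspring couples get one ungenotyped "linking
  child" pedigree row so that the in-common-children rule can discover
  them; genotyped generations remain exactly two.
* **Sites and missingness.** Each founder couple draws an enrollment site
  (default two sites, 50/50) inherited by descendants — enough to exercise
  the exclude-site analysis; genotype calls are masked independently at
  rate 0.02, matching arrays that pass a 0.95 call-rate screen.

Identical configuration and seed give a bit-identical cohort; the pipeline
derives per-stage seeds from the master seed by hashing stage names, so
adding a stage never perturbs earlier streams.

### What a green test does not establish

The simulator omits LD and recombination, admixture clines, age structure
and assortment on non-ancestry traits. Green property tests therefore
establish that the *machinery* (QC, PCA, pair extraction, correlation and
null computation) behaves correctly under a faithful but idealized
population model — not that real cohorts satisfy the model.

## Numerical choices and degenerate inputs

* Missing genotypes are `NA` in memory, never a numeric sentinel.
* `pearson_r` refuses constant input with a reason rather than returning a
  silent `NA`; strata with fewer than 4 pairs get no CI (the Fisher
  variance needs `n − 3 > 0`) and are flagged.
* `|r| = 1` gives a degenerate CI `(r, r)` with a warning and `p = 0`.
* Eigenvalues are clamped at zero; requested components beyond the rank
  bound `min(n − 1, M)` are truncated with a warning.
* Quadrant labels at an exact zero score are "unassigned" and counted.
* Sign orientation at an exactly-zero anchor mean: no flip, warning.

## Known limitations

* **Family-structure PCs at low SNP counts.** When couples' children enter
  the PCA and the SNP count is small, eigenvector noise aligns with family
  blocks: a couple's shared child pulls both parents' scores together,
  inflating spouse correlations on non-ancestry PCs and shifting observed
  correlations upward relative to a random-pairing null computed on the
  same scores. At the published scale (~70,000 SNPs, thousands of samples)
  ancestry eigenvalues dominate and the effect is negligible, but desk-
  scale simulations show it clearly; the calibration (coverage) test
  therefore scores spouses on a founders-only PCA. Users analysing small
  SNP panels should do likewise, or restrict attention to PC1.
* The null's meaning is relative to its labels (see above); reports should
  always state the candidate-pool definition, which the pipeline logs.
* No projection of new samples onto fixed loadings; no kb-based pruning;
  no multi-allelic variants; pedigrees are trusted, not inferred.
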