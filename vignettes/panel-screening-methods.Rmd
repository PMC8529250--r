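---
title: "Methods: population screening analysis for targeted gene panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population screening analysis for targeted gene panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelpop)
```

# Scope and model

`panelpop` analyzes multi-sample variant callsets from targeted
sequencing panels in population cohorts. The design target is a
catalog-style screening study: one panel of a few hundred disease genes,
one or two thousand individuals, and questions about what segregates in
the population rather than about any single proband. The pipeline
stages are:

1. **Consensus quality filter.** Each variant carries a filter status
   under two reference builds (the callset is produced twice,
   independently, against both builds and lifted to a common key space
   upstream of this package). A variant is retained only when both
   builds flag it `PASS` *and* every genotype carrying an alternate
   allele has genotype quality GQ = 99, the encoding ceiling. This is a
   deliberately conservative rule: a population catalog prefers false
   negatives over false positives, and the double-build agreement
   suppresses reference-specific alignment artifacts.

2. **Relatedness pruning.** Cryptic relatedness inflates allele
   frequencies and biases carrier rates, so pairs with estimated IBD
   proportion `PI_HAT > 0.33` are resolved before any counting (greedy
   removal of the individual in the most unresolved pairs; lexicographic
   tie-break for reproducibility).

3. **Classification.** Variants are partitioned into five impact
   classes with strict precedence — protein-truncating (stop-gain,
   frameshift, canonical splice), strictly damaging missense
   (deleterious by SIFT *and* damaging by PolyPhen-2), other missense,
   in-frame indels, everything else — and cross-tabulated with novelty
   (no dbSNP identifier) and allele-count tier (singleton, doubleton,
   AC ≥ 3). Clinical flags mark known pathogenic/likely pathogenic
   ClinVar variants (KP), high-confidence PTVs, and known rare PTVs
   (worldwide maximum AF below 0.1%).

4. **Population statistics.** Per-gene novel-variant enrichment and an
   allele-frequency overrepresentation screen against a reference
   population, both with exact tests and Benjamini–Hochberg correction
   within each analysis family.

5. **Clinical summary.** Carrier aggregation with union semantics,
   prevalence extrapolation by panel coverage, Hardy–Weinberg
   homozygote-frequency estimation for recessive alleles, and
   genotype–phenotype (penetrance) matching against configurable rules.

# Statistical choices

## Fisher's exact test

`fisher_exact_2x2()` is implemented directly from the hypergeometric
likelihood. The two-sided p-value uses the point-probability rule: sum
the probabilities of all tables with the observed margins that are no
more likely than the observed table, with a relative tie tolerance of
`1e-7` (matching the convention of `stats::fisher.test`, against which
the implementation is tested on random tables and verified exactly
against full enumeration for all tables with n ≤ 30). One-sided
alternatives use hypergeometric tail sums.

## Enrichment background convention

The per-gene enrichment test compares a gene's novel/known split against
"all genes taken together". That phrase is ambiguous: the comparison
cells may either *include* the focal gene (panel totals as-is) or
*exclude* it (disjoint cells). Both conventions are implemented;
`background = "inclusive"` is the default because it reproduces the
reference results this design was validated against; the exclusive
convention typically shifts p-values by ~5–10% at panel scale and is
available for sensitivity analysis. For one validation count pair
(27 novel / 107 known against 1,356 / 10,520) neither convention
reproduces the published value of 0.002 — both give ≈ 0.0037 — and the
corresponding acceptance expectation is left failing rather than
papered over; see `tests/testthat/test-acceptance.R`.

## Overrepresentation screen

Known pathogenic variants carried by at least 3 distinct individuals are
compared against reference-population allele counts by Fisher's exact
test on the raw allele counts (not frequencies), with the
Clopper–Pearson exact interval on the cohort frequency. Variants with
fewer carriers are excluded *before* testing — their frequencies are
dominated by sampling noise and would only dilute the BH correction.
One cohort-vs-cohort validation comparison is reproduced by the
one-sided test (p = 0.0456 against a published 0.045) and not by the
two-sided rule (0.065); the package therefore exposes `sidedness`
explicitly rather than hard-wiring either convention.

## Exact intervals and BH

`clopper_pearson_ci()` uses beta-distribution quantiles; coverage is
verified by simulation at the rare-allele operating point the package
cares about (p = 0.001, n ≈ 3,400). `bh_adjust()` is the standard
step-up, tested to `1e-12` against both `stats::p.adjust` and an
independent re-implementation.

## Relatedness estimator

`estimate_pi_hat()` is the method-of-moments estimator of standard
genetics toolkits: expected IBS-class counts given allele frequencies
under IBD ∈ {0, 1, 2} are inverted to class probabilities, constrained
to the simplex, and summarized as `PI_HAT = P(IBD=2) + P(IBD=1)/2`.
Two numerical details matter in practice:

* **Finite-sample moments.** Plug-in powers of the allele frequency are
  biased when the frequency is itself estimated from the cohort;
  the expectations therefore use unbiased factorial moments of the
  allele counts (draws without replacement) whenever the allele numbers
  are supplied.
* **Boundary handling.** Clamping all three class probabilities to
  [0, 1] and renormalizing the sum inflates unrelated pairs' estimates
  noticeably (mean ≈ 0.034 at 2,000 informative sites in simulation).
  The adopted order — a probability above 1 takes all the mass; a
  negative probability is zeroed and only the *remaining two* are
  renormalized — keeps unrelated pairs near zero (mean ≈ 0.022) while
  returning identical values for clearly related pairs.

Targeted panels are a hard setting for relatedness: most sites are too
rare to be informative (a site contributes IBS0 signal with probability
2p²q²). When fewer than `min_relatedness_sites` (default 500)
informative autosomal sites (MAF ≥ 1%) survive filtering, `run_pipeline`
skips threshold pruning with a warning instead of acting on
noise-dominated estimates — on sparse inputs the greedy pruner would
otherwise remove large swaths of genuinely unrelated individuals. The
pairwise estimates themselves remain available via
`pairwise_relatedness()` for manual inspection. Even above the guard,
users should expect a noise tail: at ~800 informative sites a small
percentage of unrelated pairs crosses 0.33, which is the honest behavior
of this estimator on panel data (genome-wide data with tens of thousands
of common sites does not have this problem).

## Chromosome X

The allele-number policy on chromosome X is configurable because
published panel studies are frequently silent about it despite including
X-linked genes. The default is sex-aware: males contribute one allele
(hemizygous; a diploid-coded alternate genotype counts one copy),
females two, unknown-sex samples two with a warning. A `diploid` policy
disables the adjustment. All headline statistics in the validation suite
are autosomal, so the default never affects them.

# The synthetic cohort generator

No individual genotypes are published for the study design this package
models, so the generator must produce inputs with *known ground truth*
that exercise every pipeline stage. Defaults are the study conditions:
1,685 individuals, ~12,000 discovered variants over 242 genes (28 of
them on the secondary-findings list), and a site-frequency spectrum in
which singletons and doubletons together make up 63.8% of discovered
variants.

* **Site-frequency spectrum.** True allele frequencies are drawn from a
  mixture: point masses at 1/(2n) and 2/(2n) (weight θ, split 2:1) and a
  log-uniform tail on [3/(2n), 0.5]. θ is solved numerically
  (`uniroot`) so that the *expected* singleton+doubleton fraction among
  discovered sites (AC ≥ 1 under binomial sampling) equals the target.
  This is calibrated analytically, before any data are drawn, not tuned
  to realized outputs.
* **Novelty.** The probability of being absent from dbSNP decays
  logistically in log10 of the population allele count, anchored at
  17.5% for singleton-scale frequencies — rare variants are novel,
  common variants are catalogued. Two randomly chosen genes receive an
  8-fold novelty odds boost (the planted enrichment signal).
* **Genotypes.** Hardy–Weinberg draws at the true frequencies,
  hemizygous on X for males. One duplicate pair and one parent–child
  pair are planted (genotype copy; Mendelian transmission of one
  parental allele). A configurable fraction of sites gets a non-PASS
  status in one build, and a fraction gets one sub-ceiling GQ on a
  carrier genotype, to exercise the consensus filter. GQ is `NA` where
  the genotype is missing.
* **Overrepresentation.** A handful of known pathogenic sites get cohort
  frequencies equal to their reference frequency times a planted ratio
  of 5–30.
* **Phenotypes.** Background measurements at population-plausible rates
  (QT ~ N(410, 18) ms, LDL-C ~ N(3.6, 0.9) mmol/l, log-normal
  triglycerides, sparse clinical flags); carriers of phenotype-linked
  pathogenic variants receive a matching measurement or flag with
  probability equal to the configured penetrance (default 0.19).
* **Seeding.** The master seed drives four derived streams (truth,
  genotypes, annotations, phenotypes at seed, seed+1, seed+2, seed+3),
  so each layer is independently reproducible.

Limits worth knowing: sites are independent (no linkage
disequilibrium), there is no population structure or admixture, reference
AFs are drawn around truth rather than from a real catalog, and the
annotation fields mirror the truth plan exactly (no annotation noise).
These are acceptable for validating counting, testing and recovery
logic; they make the generator unsuitable for benchmarking LD-aware
methods.

# Test strategy

Dataset-level totals of the motivating design are not reproducible
without the original genotypes, so the suite follows two tracks:

* **Oracle equivalence.** Fisher p-values against exhaustive
  enumeration (all tables with n ≤ 30) and `stats::fisher.test`;
  BH against `stats::p.adjust` and an independent step-up; CI bounds
  against `stats::binom.test` plus a coverage simulation; IBS counts
  against per-site brute force.
* **Parameter recovery.** On seeded synthetic cohorts: SFS composition,
  HWE genotype proportions, planted duplicate (PI_HAT ≈ 1) and
  parent–child (≈ 0.5) pairs, planted enrichment genes ranking at the
  top of the panel, all planted overrepresented alleles recovered,
  penetrance within binomial error, and null calibration of the
  overrepresentation screen (empirical type-I rate at most nominal).

Fixed-input headline statistics (enrichment p-values from printed count
pairs, exact CI margins, pooled HWE rates, carrier rates, the phenotype
confirmation rate) are asserted at reported precision in
`tests/testthat/test-acceptance.R` and recomputed by
`scripts/acceptance.R`.

# Workflow layout

The computation lives in the package (`R/`); the analysis itself is a
sequence of thin numbered drivers under `analysis/` (simulate → filter →
relatedness → classify → population statistics → clinical summary), each
of which narrates what it found and writes its tables under `results/`.
`run_pipeline()` performs the same stages in one call for programmatic
use, and is what the tests exercise end to end.
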