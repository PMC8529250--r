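# panelpop

Population screening analysis for targeted gene panels in R.

`panelpop` turns a multi-sample variant callset from a targeted
sequencing panel (a few hundred disease genes, one or two thousand
individuals) into a population variant catalog with clinical summaries.
It implements the full analysis chain of a catalog-style screening
study:

1. **Consensus quality filter** — a variant is retained only when it
   passes the caller's filters under *both* reference builds and every
   alternate-carrying genotype has GQ = 99 (the encoding ceiling).
2. **Relatedness pruning** — method-of-moments `PI_HAT` estimation from
   identity-by-state counts, with finite-sample (factorial-moment)
   corrections for cohort-estimated allele frequencies, and greedy
   removal of individuals in pairs with `PI_HAT > 0.33`.
3. **Impact and novelty classification** — five impact classes with
   strict precedence (PTV, strictly damaging missense, other missense,
   in-frame indel, other), crossed with dbSNP novelty and allele-count
   tier; clinical flags for known pathogenic (ClinVar P/LP), novel
   high-confidence PTVs, and known rare PTVs.
4. **Population statistics** — per-gene novel-variant enrichment and an
   allele-frequency overrepresentation screen against a reference
   population, both using an exact Fisher test with Benjamini–Hochberg
   correction, plus Clopper–Pearson intervals on cohort frequencies.
5. **Clinical summary** — carrier aggregation (union semantics),
   prevalence extrapolation by panel coverage, Hardy–Weinberg
   homozygote-rate estimation for recessive alleles, and
   genotype–phenotype (penetrance) matching against configurable YAML
   rules.

Because individual genotypes from such studies are rarely published,
the package ships a **synthetic cohort generator** with known ground
truth: a singleton-heavy site-frequency spectrum calibrated so that
singletons + doubletons make up 63.8% of discovered variants, planted
novelty-enriched genes, planted overrepresented pathogenic alleles,
planted duplicate and parent–child pairs, and phenotypes assigned to
carriers at a configurable penetrance (default 0.19). Every pipeline
stage can therefore be validated by parameter recovery.

## Worked example

Simulate a small cohort (200 samples, ~1,000 target sites), run the
whole pipeline, and look at the results. The small profile has too few
informative common sites for reliable relatedness pruning, so the
pipeline warns and skips that stage (estimates remain available via
`pairwise_relatedness()`); the default profile (1,685 samples, ~12,000
sites) prunes normally.

```r
library(panelpop)

sim <- simulate_cohort(cohort_config("small"), seed = 42)
res <- run_pipeline(pipeline_config(inputs = sim))
#> [input] 722 variants x 200 samples
#> [filter] retained 611 variants (111 rejected)
#> Warning: only 147 informative sites (min 500): skipping relatedness pruning
#> [classify] 611 variants (0 unannotated)

res$tables$variant_overview
#>                 impact_class known_ac_lt3 novel_ac_lt3 novel_not_second_ac_lt3
#> 1                        PTV            9            2                       2
#> 2 strictly_damaging_missense           44            7                       6
#> 3             other_missense           89           18                      18
#> 4              inframe_indel            6            0                       0
#> 5                      other          176           39                      36
#> 6                      total          324           66                      62
#>   known_ac_ge3 novel_ac_ge3 novel_not_second_ac_ge3
#> 1            3            0                       0
#> 2           26            0                       0
#> 3           52           12                      12
#> 4            0            0                       0
#> 5          115           13                      13
#> 6          196           25                      25
```

The overrepresentation screen recovers the planted high-frequency
pathogenic alleles (true planted frequency ratios are 5–30×):

```r
ov <- res$tables$overrepresentation
ov[ov$overrepresented, c("key", "cohort_af", "ref_af", "ratio", "q_value")]
#>                 key  cohort_af  ref_af     ratio      q_value
#>   chr22:7000037_T/C 0.02525253 0.00069 36.597863 6.442234e-12
#>    chr4:9000740_A/T 0.01500000 0.00080 18.750000 4.843855e-06
#>  chr18:21000222_C/T 0.15829146 0.11901  1.330069 4.607287e-02

res$prevalence$kp[c("raw_pct", "extrapolated_pct")]
#> $raw_pct
#> [1] 7.5
#> $extrapolated_pct
#> [1] 15
```

The core statistics are plain exported functions, usable on any counts:

```r
# Two-sided Fisher exact test (point-probability rule): a gene with
# 13 novel / 21 known variants against panel totals 1,356 / 10,520
fisher_exact_2x2(13, 21, 1356, 10520)
#> [1] 5.224514e-05

# Exact binomial CI on an allele seen 3 times in 3,370 chromosomes
clopper_pearson_ci(3, 3370)
#>          low         high
#> 0.0001836199 0.0025993394

# Expected recessive-disease frequency from pooled carrier counts of
# two pathogenic alleles (Hardy-Weinberg q^2, rounded to "1 in N")
hwe_homozygote_rate(c(8, 2), c(3370, 1388))$one_in_rounded
#> [1] 226000
```

## Analysis workflow

The computation lives in the package; the analysis itself is a sequence
of thin numbered drivers under `analysis/`, each narrating what it found
and writing its tables under `results/` (gitignored):

```sh
Rscript analysis/01_simulate_cohort.R    # default cohort, seed 1
Rscript analysis/02_consensus_filter.R   # dual-build + GQ filter
Rscript analysis/03_relatedness.R        # PI_HAT estimation + pruning
Rscript analysis/04_classify_variants.R  # impact/novelty/Ti-Tv tables
Rscript analysis/05_population_stats.R   # enrichment + overrepresentation
Rscript analysis/06_clinical_summary.R   # carriers, prevalence, penetrance
```

At the default scale (1,685 samples, ~12,000 sites, seed 1) the run
recovers its ground truth: the planted duplicate pair at `PI_HAT` = 1.00
and the parent–child pair at 0.50, panel Ti/Tv 3.08, cohort-vs-true
allele-frequency correlation R = 0.999, the planted novelty-enriched
gene as the top enrichment hit (p = 5.9e-11), all five testable planted
overrepresented alleles significant, and phenotype confirmation rates
near the configured penetrance.

## Input formats

`read_callset()` ingests a VCF (via `vcfR`) plus a TSV sidecar carrying
per-build filter status; `read_annotations()`, `read_samples()` and
`read_genes()` read validated TSV tables (controlled vocabularies are a
hard error on violation); phenotype-matching rules load from YAML via
`read_phenotype_rules()`. `simulate_cohort(..., dir = )` writes a
complete file bundle in exactly these formats, so the file-based and
in-memory routes are interchangeable (and tested to be byte-identical).
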