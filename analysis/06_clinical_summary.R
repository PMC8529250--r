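#!/usr/bin/env Rscript
# 06: Clinical summary.
#
# Carrier aggregation of the three clinical variant groups (known
# pathogenic, novel PTV, rare PTV) by gene category, prevalence with 2x
# panel-coverage extrapolation for the secondary-findings genes, and
# genotype-phenotype matching at the configured rules.

suppressPackageStartupMessages(library(panelpop))

sim <- readRDS(file.path("results", "cache_01_sim.rds"))
cls <- readRDS(file.path("results", "cache_04_classified.rds"))
cs <- readRDS(file.path("results", "cache_03_pruned.rds"))
cohort_n <- length(cs$samples)

cand <- clinical_candidates(cls, sim$genes)
cat(sprintf("clinical candidate pairs: %d (%d variants)\n",
            nrow(cand), length(unique(cand$key))))

carriers <- carrier_summary(cand, cohort_n)
print(carriers, row.names = FALSE)

acmg <- cand[cand$is_acmg59, ]
kp_carriers <- unique(acmg$sample_id[acmg$group == "KP"])
ptv_carriers <- unique(acmg$sample_id[acmg$group != "KP"])
kp_prev <- prevalence(length(kp_carriers), cohort_n, coverage_factor = 2)
ptv_prev <- prevalence(length(ptv_carriers), cohort_n, coverage_factor = 2)
cat(sprintf("\nsecondary-findings KP carriers: %d -> %.2f%% raw, %.2f%% extrapolated\n",
            length(kp_carriers), kp_prev$raw_pct, kp_prev$extrapolated_pct))
cat(sprintf("secondary-findings PTV carriers: %d -> %.2f%% raw, %.2f%% extrapolated\n",
            length(ptv_carriers), ptv_prev$raw_pct, ptv_prev$extrapolated_pct))

pheno <- match_phenotypes(acmg, sim$samples)
cat("\nphenotype confirmation by group (secondary-findings genes):\n")
print(pheno$summary, row.names = FALSE)

write_tsv(carriers, file.path("results", "carrier_summary.tsv"))
write_tsv(pheno$records, file.path("results", "penetrance_records.tsv"))
write_tsv(pheno$summary, file.path("results", "penetrance_summary.tsv"))
cat("\ntables: results/carrier_summary.tsv, penetrance_records.tsv, penetrance_summary.tsv\n")
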