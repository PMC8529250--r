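#!/usr/bin/env Rscript
# 03: Estimate pairwise relatedness and prune related individuals.
#
# Method-of-moments PI_HAT over IBS counts at autosomal sites with
# MAF >= 1%; pairs with PI_HAT > 0.33 are resolved by greedily removing
# the individual in the most unresolved pairs. Writes the above-threshold
# pairs and the removal log, and caches the pruned callset.

suppressPackageStartupMessages(library(panelpop))

sim <- readRDS(file.path("results", "cache_01_sim.rds"))
cs <- readRDS(file.path("results", "cache_02_filtered.rds"))

counts <- compute_site_counts(cs, sim$samples)
auto <- !is_chrx(cs$variants$chrom)
informative <- auto & !is.na(counts$af) & pmin(counts$af, 1 - counts$af) >= 0.01
cat(sprintf("informative autosomal sites (MAF >= 1%%): %d\n", sum(informative)))

pairs <- pairwise_relatedness(cs$dosage[auto, , drop = FALSE],
                              counts$af[auto], min_af = 0.01, counts$an[auto])
cat(sprintf("evaluated pairs: %d\n", nrow(pairs)))
cat(sprintf("mean PI_HAT: %.4f\n", mean(pairs$pi_hat, na.rm = TRUE)))

hot <- pairs[!is.na(pairs$pi_hat) & pairs$pi_hat > 0.33, ]
hot <- hot[order(-hot$pi_hat), ]
cat(sprintf("pairs above 0.33: %d (max %.3f)\n", nrow(hot), max(hot$pi_hat)))
# the planted duplicate and parent-child pairs should lead this list
print(head(hot, 5))

pruned <- prune_related(pairs, threshold = 0.33, samples = cs$samples)
cat(sprintf("removed %d individuals; %d retained\n",
            nrow(pruned$removed), length(pruned$retained)))

cs <- subset_samples(cs, pruned$retained)
counts2 <- compute_site_counts(cs, sim$samples)
cs <- subset_callset(cs, counts2$ac >= 1L)
cat(sprintf("variants still observed after pruning: %d\n", n_variants(cs)))

write_tsv(hot, file.path("results", "related_pairs.tsv"))
write_tsv(pruned$removed, file.path("results", "removed_samples.tsv"))
saveRDS(cs, file.path("results", "cache_03_pruned.rds"))
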