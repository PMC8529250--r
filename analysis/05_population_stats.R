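#!/usr/bin/env Rscript
# 05: Population statistics.
#
# (a) Per-gene novel-variant enrichment: Fisher's exact test of each
#     gene's novel/known split against the panel totals, BH-corrected
#     across genes.
# (b) Overrepresentation screen: known pathogenic variants with >= 3
#     carriers compared against reference-population allele counts, with
#     exact CIs on the cohort frequency and BH correction.

suppressPackageStartupMessages(library(panelpop))

sim <- readRDS(file.path("results", "cache_01_sim.rds"))
cls <- readRDS(file.path("results", "cache_04_classified.rds"))
ann_cl <- cls[cls$annotated, ]

per_gene <- do.call(rbind, lapply(split(ann_cl, ann_cl$gene), function(g) {
  data.frame(gene = g$gene[1], novel = sum(g$novelty == "novel"),
             known = sum(g$novelty == "known"))
}))
enr <- gene_novelty_enrichment(per_gene, background = "inclusive")
enr <- enr[order(enr$p_value), ]
cat("top novel-enrichment hits:\n")
print(head(enr, 5), row.names = FALSE)
cat(sprintf("planted enriched genes: %s\n",
            paste(sim$truth$enriched_genes, collapse = ", ")))

m <- match(ann_cl$key, sim$annotations$variant_key)
kp <- ann_cl$is_kp
ov <- af_overrepresentation(data.frame(
  key = ann_cl$key[kp], cohort_ac = ann_cl$ac[kp], cohort_an = ann_cl$an[kp],
  n_carriers = lengths(ann_cl$carriers[kp]),
  ref_ac = sim$annotations$ref_nfe_ac[m][kp],
  ref_an = sim$annotations$ref_nfe_an[m][kp]))
cat(sprintf("\noverrepresentation screen: %d tested, %d significant (q <= 0.05, ratio > 1)\n",
            nrow(ov), sum(ov$overrepresented)))
print(ov[ov$overrepresented, c("key", "cohort_af", "ref_af", "ratio",
                               "p_value", "q_value")], row.names = FALSE)
cat(sprintf("planted overrepresented keys recovered: %d of %d tested\n",
            sum(ov$key[ov$overrepresented] %in% sim$truth$overrep_keys),
            sum(ov$key %in% sim$truth$overrep_keys)))

write_tsv(enr, file.path("results", "gene_enrichment.tsv"))
write_tsv(ov, file.path("results", "overrepresentation.tsv"))
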