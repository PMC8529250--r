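Package: panelpop
Title: Population Screening Analysis for Targeted Gene Panels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Cohort variant-catalog analysis for targeted-panel population
    sequencing studies: dual-build consensus genotype filtering,
    method-of-moments relatedness (PI_HAT) pruning, variant impact and
    novelty classification, per-gene novel-variant enrichment by Fisher's
    exact test, allele-frequency overrepresentation against a reference
    population with Clopper-Pearson intervals and Benjamini-Hochberg
    correction, secondary-findings carrier rates with prevalence
    extrapolation, Hardy-Weinberg recessive-disease frequency estimation,
    and genotype-phenotype (penetrance) tabulation. Includes a synthetic
    cohort generator with known ground truth emulating the singleton-heavy
    site-frequency spectrum of rare-variant panel data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
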