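#' Pipeline configuration
#'
#' Collects every tunable parameter of the analysis with the defaults
#' used throughout: consensus GQ requirement 99, PI_HAT pruning threshold
#' 0.33, rare-PTV worldwide AF cutoff 0.1%, minimum 3 carriers for the
#' overrepresentation screen, 95% exact CIs, two-sided Fisher tests,
#' gene-inclusive enrichment background, and panel coverage factor 2 for
#' secondary-findings prevalence extrapolation.
#'
#' @param inputs either the list returned by [simulate_cohort()] or a
#'   named list of paths (`vcf`, `filters`, `annotations`, `samples`,
#'   `genes`)
#' @param ... parameter overrides (see Details in the source)
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(inputs, ...) {
  cfg <- list(
    inputs = inputs,
    gq_required = 99,
    pi_hat_max = 0.33,
    relatedness_min_af = 0.01,
    min_relatedness_sites = 500,
    rare_af_cutoff = 0.001,
    polyphen_strict = FALSE,
    chrx_policy = "sex_aware",
    min_carriers = 3,
    ci_level = 0.95,
    sidedness = "two_sided",
    background = "inclusive",
    min_ac_correlation = 3,
    alpha = 0.05,
    coverage_factor = 2,
    phenotype_rules = default_phenotype_rules(),
    ref_pop = "nfe",
    prune_relatives = TRUE,
    out_dir = NULL)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "pipeline_config")
}

load_inputs <- function(inputs) {
  if (!is.null(inputs$callset)) {
    list(callset = inputs$callset, annotations = inputs$annotations,
         samples = inputs$samples, genes = inputs$genes)
  } else {
    list(callset = read_callset(inputs$vcf, inputs$filters),
         annotations = read_annotations(inputs$annotations),
         samples = read_samples(inputs$samples),
         genes = read_genes(inputs$genes))
  }
}

#' Variant-carrier candidate pairs for clinical evaluation
#'
#' Builds the long table of (variant, carrier) pairs in the three
#' disjoint clinical groups, with precedence KP > novel PTV > rare PTV:
#' known pathogenic/likely pathogenic variants; novel high-confidence
#' protein-truncating variants; and known rare (worldwide max AF < 0.1%)
#' high-confidence PTVs not already counted as KP.
#'
#' @param classified output of [classify_variants()]
#' @param genes gene metadata from [read_genes()]
#' @return data.frame `key`, `gene`, `group`, `is_acmg59`, `inheritance`,
#'   `sample_id`
#' @export
clinical_candidates <- function(classified, genes) {
  cl <- classified[classified$annotated, , drop = FALSE]
  group <- ifelse(cl$is_kp, "KP",
           ifelse(cl$novelty == "novel" & cl$is_hc_ptv, "novel_PTV",
           ifelse(cl$is_rare_ptv & !cl$is_kp, "rare_PTV", NA_character_)))
  sel <- which(!is.na(group))
  if (!length(sel)) {
    return(data.frame(key = character(0), gene = character(0),
                      group = character(0), is_acmg59 = logical(0),
                      inheritance = character(0), sample_id = character(0)))
  }
  gm <- match(cl$gene[sel], genes$gene)
  reps <- lengths(cl$carriers[sel])
  data.frame(
    key = rep(cl$key[sel], reps), gene = rep(cl$gene[sel], reps),
    group = rep(group[sel], reps),
    is_acmg59 = rep(genes$is_acmg59[gm], reps),
    inheritance = rep(genes$inheritance[gm], reps),
    sample_id = unlist(cl$carriers[sel]), stringsAsFactors = FALSE)
}

#' Carrier summary by clinical group and gene category
#'
#' Aggregates the clinical candidate pairs into the publication-shaped
#' carrier table: for each group (KP, novel PTV, rare PTV) and gene
#' category (secondary-findings list; non-list dominant, recessive,
#' other) the number of variants, genes and distinct carriers.
#'
#' @param candidates from [clinical_candidates()]
#' @param cohort_n number of individuals in the analyzed cohort
#' @return data.frame with carrier counts and rates per cell
#' @export
carrier_summary <- function(candidates, cohort_n) {
  cat_of <- function(is_acmg, inh) {
    ifelse(is_acmg, "ACMG59",
    ifelse(inh == "AD", "non-ACMG AD",
    ifelse(inh == "AR", "non-ACMG AR", "other")))
  }
  candidates$category <- cat_of(candidates$is_acmg59, candidates$inheritance)
  cells <- expand.grid(group = unique(candidates$group),
                       category = c("ACMG59", "non-ACMG AD", "non-ACMG AR", "other"),
                       stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sub <- candidates[candidates$group == cells$group[i] &
                        candidates$category == cells$category[i], ]
    data.frame(group = cells$group[i], category = cells$category[i],
               n_variants = length(unique(sub$key)),
               n_genes = length(unique(sub$gene)),
               n_carriers = length(unique(sub$sample_id)),
               carrier_rate_pct = 100 * length(unique(sub$sample_id)) / cohort_n,
               stringsAsFactors = FALSE)
  }))
  out[out$n_variants > 0 | out$category == "ACMG59", , drop = FALSE]
}

#' Run the full analysis pipeline
#'
#' Stages: read inputs, consensus quality filter, relatedness pruning,
#' variant classification, per-gene novelty enrichment,
#' reference-population overrepresentation screen, QC summary, clinical
#' carrier summary with prevalence extrapolation, and genotype-phenotype
#' matching. Deterministic given inputs and configuration. Each stage
#' logs record counts to stderr.
#'
#' @param config a [pipeline_config()]
#' @return list with all stage outputs and the publication-shaped tables
#'   from [build_tables()]
#' @export
run_pipeline <- function(config) {
  inp <- load_inputs(config$inputs)
  cs <- inp$callset
  message(sprintf("[input] %d variants x %d samples", n_variants(cs),
                  length(cs$samples)))

  filt <- apply_consensus_filter(cs, config$gq_required)
  cs <- filt$callset
  message(sprintf("[filter] retained %d variants (%d rejected)",
                  n_variants(cs), nrow(filt$rejections)))

  relatedness <- NULL
  if (isTRUE(config$prune_relatives) && length(cs$samples) > 1) {
    cnt <- compute_site_counts(cs, inp$samples, config$chrx_policy)
    auto <- !is_chrx(cs$variants$chrom)
    informative <- sum(!is.na(cnt$af[auto]) &
                         pmin(cnt$af[auto], 1 - cnt$af[auto]) >=
                           config$relatedness_min_af)
    if (informative < config$min_relatedness_sites) {
      # threshold pruning on too few informative sites is noise-dominated
      warning(sprintf(
        "only %d informative sites (min %d): skipping relatedness pruning",
        informative, config$min_relatedness_sites))
    } else {
      pairs <- pairwise_relatedness(cs$dosage[auto, , drop = FALSE],
                                    cnt$af[auto], config$relatedness_min_af,
                                    cnt$an[auto])
      pruned <- prune_related(pairs, config$pi_hat_max, samples = cs$samples)
      cs <- subset_samples(cs, pruned$retained)
      counts <- compute_site_counts(cs, inp$samples, config$chrx_policy)
      cs <- subset_callset(cs, counts$ac >= 1L)
      message(sprintf("[relatedness] removed %d related samples; %d variants remain",
                      nrow(pruned$removed), n_variants(cs)))
      relatedness <- list(pairs = pairs, removed = pruned$removed)
    }
  }

  classified <- classify_variants(cs, inp$annotations, inp$samples,
                                  config$rare_af_cutoff,
                                  config$polyphen_strict, config$chrx_policy)
  message(sprintf("[classify] %d variants (%d unannotated)",
                  nrow(classified), sum(!classified$annotated)))

  ann_cl <- classified[classified$annotated, , drop = FALSE]
  per_gene <- do.call(rbind, lapply(split(ann_cl, ann_cl$gene), function(g) {
    data.frame(gene = g$gene[1], novel = sum(g$novelty == "novel"),
               known = sum(g$novelty == "known"), stringsAsFactors = FALSE)
  }))
  enrichment <- gene_novelty_enrichment(per_gene,
                                        background = config$background,
                                        sidedness = config$sidedness)

  ref_ac_col <- paste0("ref_", config$ref_pop, "_ac")
  ref_an_col <- paste0("ref_", config$ref_pop, "_an")
  am <- match(ann_cl$key, inp$annotations$variant_key)
  ref_ac <- inp$annotations[[ref_ac_col]][am]
  ref_an <- inp$annotations[[ref_an_col]][am]
  kp <- ann_cl$is_kp
  overrep <- af_overrepresentation(
    data.frame(key = ann_cl$key[kp], cohort_ac = ann_cl$ac[kp],
               cohort_an = ann_cl$an[kp],
               n_carriers = lengths(ann_cl$carriers[kp]),
               ref_ac = ref_ac[kp], ref_an = ref_an[kp],
               stringsAsFactors = FALSE),
    config$min_carriers, config$ci_level, config$sidedness, config$alpha)
  qc <- qc_summary(classified, ifelse(ref_an > 0, ref_ac / ref_an, NA)[
    match(classified$key, ann_cl$key)], config$min_ac_correlation)

  candidates <- clinical_candidates(classified, inp$genes)
  cohort_n <- length(cs$samples)
  carriers <- carrier_summary(candidates, cohort_n)
  acmg <- candidates[candidates$is_acmg59, , drop = FALSE]
  kp_acmg <- unique(acmg$sample_id[acmg$group == "KP"])
  ptv_acmg <- unique(acmg$sample_id[acmg$group %in% c("novel_PTV", "rare_PTV")])
  prev <- list(
    kp = prevalence(length(kp_acmg), cohort_n, config$coverage_factor),
    ptv = prevalence(length(ptv_acmg), cohort_n, config$coverage_factor))
  pheno <- match_phenotypes(acmg, inp$samples, config$phenotype_rules)

  results <- list(
    config = config, callset = cs, classified = classified,
    rejections = filt$rejections, relatedness = relatedness,
    enrichment = enrichment, overrepresentation = overrep, qc = qc,
    candidates = candidates, carriers = carriers, prevalence = prev,
    phenotypes = pheno, cohort_n = cohort_n)
  results$tables <- build_tables(results)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(results$tables)) {
      write_tsv(results$tables[[nm]], file.path(config$out_dir,
                                                paste0(nm, ".tsv")))
    }
  }
  results
}

#' Publication-shaped output tables
#'
#' Assembles the five report tables: the variant overview (impact class
#' by allele-count tier by novelty), the clinical variant list (novel
#' variants serialized as chrom:pos_ref/alt, known ones by rsid), the
#' overrepresentation screen, the carrier summary, and the penetrance
#' records.
#'
#' @param results list from [run_pipeline()]
#' @return named list of data.frames
#' @export
build_tables <- function(results) {
  cl <- results$classified
  cand <- results$candidates
  if (nrow(cand) > 0) {
    per_var <- unique(cand[, c("key", "gene", "group", "is_acmg59")])
    m <- match(per_var$key, cl$key)
    clinical <- data.frame(
      gene = per_var$gene,
      variant = ifelse(cl$novelty[m] == "novel", cl$key[m], cl$rsid[m]),
      group = per_var$group, is_acmg59 = per_var$is_acmg59,
      clinvar_class = cl$clinvar_class[m], ac = cl$ac[m],
      carriers = lengths(cl$carriers[m]), stringsAsFactors = FALSE)
    clinical <- clinical[order(clinical$gene, clinical$variant), ]
  } else {
    clinical <- data.frame(gene = character(0), variant = character(0),
                           group = character(0), is_acmg59 = logical(0),
                           clinvar_class = character(0), ac = integer(0),
                           carriers = integer(0))
  }
  pheno_records <- results$phenotypes$records
  if (is.null(pheno_records) || nrow(pheno_records) == 0) {
    pheno_records <- data.frame(key = character(0), gene = character(0),
                                group = character(0), sample_id = character(0),
                                matched = logical(0),
                                matched_phenotype = character(0),
                                evidence_source = character(0),
                                no_data = logical(0))
  }
  list(variant_overview = variant_overview(cl),
       clinical_variants = clinical,
       overrepresentation = as.data.frame(results$overrepresentation),
       carrier_summary = results$carriers,
       penetrance = pheno_records)
}
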