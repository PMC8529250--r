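#' Distinct carriers of a variant set
#'
#' Counts the individuals carrying at least one variant of the set; an
#' individual carrying several counts once (union semantics).
#'
#' @param keys variant keys defining the set
#' @param classified output of [classify_variants()] (provides the
#'   `carriers` list column)
#' @return list `n_variants`, `n_carriers`, `carriers` (sorted ids)
#' @export
count_carriers <- function(keys, classified) {
  idx <- match(keys, classified$key)
  if (anyNA(idx)) stop("unknown variant key(s): ",
                       paste(keys[is.na(idx)], collapse = ", "))
  carriers <- sort(unique(unlist(classified$carriers[idx])))
  list(n_variants = length(keys), n_carriers = length(carriers),
       carriers = carriers)
}

#' Carrier prevalence with panel-coverage extrapolation
#'
#' Raw prevalence is `100 * n_carriers / cohort_n` percent. When the
#' sequenced panel covers only part of the gene set of interest, the
#' extrapolated prevalence multiplies by `coverage_factor` (e.g. 2 when
#' the panel holds half the relevant genes), assuming comparable variant
#' yield in the unsequenced half; prevalence is linear in the factor.
#'
#' @param n_carriers distinct carriers
#' @param cohort_n cohort size
#' @param coverage_factor >= 1
#' @return list `raw_pct`, `extrapolated_pct`
#' @export
prevalence <- function(n_carriers, cohort_n, coverage_factor = 1) {
  stopifnot(cohort_n > 0, coverage_factor >= 1, n_carriers <= cohort_n)
  raw <- 100 * n_carriers / cohort_n
  list(raw_pct = raw, extrapolated_pct = raw * coverage_factor)
}

#' Recessive-disease homozygote frequency under Hardy-Weinberg
#'
#' Pools allele counts across cohorts (sum of AC over sum of AN), takes
#' the pooled allele frequency q and returns the expected homozygote
#' frequency q^2 as "one in 1/q^2", with a presentation form rounded to
#' the nearest thousand.
#'
#' @param ac,an vectors of per-cohort allele counts / numbers
#' @return list `q`, `homozygote_freq`, `one_in`, `one_in_rounded`;
#'   `defined = FALSE` when the pooled count is zero
#' @examples
#' hwe_homozygote_rate(c(8, 2), c(3370, 1388))  # one in ~226,000
#' @export
hwe_homozygote_rate <- function(ac, an) {
  stopifnot(length(ac) == length(an), all(an > 0), all(ac >= 0), all(ac <= an))
  q <- sum(ac) / sum(an)
  if (q == 0) {
    return(list(q = 0, homozygote_freq = 0, one_in = NA_real_,
                one_in_rounded = NA_real_, defined = FALSE))
  }
  one_in <- 1 / q^2
  list(q = q, homozygote_freq = q^2, one_in = one_in,
       one_in_rounded = round(one_in / 1000) * 1000, defined = TRUE)
}

#' Default genotype-phenotype matching rules
#'
#' Each rule maps a gene set to a phenotype predicate over the sample
#' table: a numeric threshold (`field`, `op`, `cutoff`) or a clinical
#' flag membership (`flag`), plus the clinical evidence source. Defaults:
#' prolonged QTc if QT > 450 ms (both sexes), hypobetalipoproteinemia if
#' LDL-C < 1.55 mmol/l, severe hypertriglyceridemia if TG > 10 mmol/l,
#' and flag-matched conditions (CAD, myopathy, cardiomyopathy, cerebral
#' infarction). All rules are overridable via a YAML list of the same
#' shape.
#'
#' @return list of rule lists
#' @export
default_phenotype_rules <- function() {
  list(
    list(phenotype = "prolonged QTc interval", source = "ECG",
         genes = c("KCNQ1", "KCNH2", "SCN5A", "CACNA1C"),
         field = "qt_ms", op = ">", cutoff = 450),
    list(phenotype = "hypobetalipoproteinemia", source = "biochemical",
         genes = c("APOB", "PCSK9", "ANGPTL3"),
         field = "ldl_c", op = "<", cutoff = 1.55),
    list(phenotype = "severe hypertriglyceridemia", source = "biochemical",
         genes = c("APOA5", "APOC3", "LPL"),
         field = "tg", op = ">", cutoff = 10),
    list(phenotype = "CAD", source = "CAD-validation",
         genes = c("MEF2A"), flag = "CAD"),
    list(phenotype = "cerebral infarction", source = "endpoint",
         genes = c("NOTCH3"), flag = "cerebral-infarction"),
    list(phenotype = "myopathy", source = "medical-record",
         genes = c("RYR1", "LAMA2", "DMD"), flag = "myopathy"),
    list(phenotype = "cardiomyopathy", source = "medical-record",
         genes = c("MYH7", "MYBPC3", "DSP", "LMNA", "FLNC"),
         flag = "hypertrophic-cardiomyopathy")
  )
}

#' Read phenotype rules from YAML
#' @param path YAML file holding a list of rules shaped like
#'   [default_phenotype_rules()]
#' @export
read_phenotype_rules <- function(path) yaml::read_yaml(path)

rule_matches <- function(rule, sample_row) {
  if (!is.null(rule$field)) {
    x <- sample_row[[rule$field]]
    if (is.null(x) || is.na(x)) return(FALSE)
    switch(rule$op, ">" = x > rule$cutoff, "<" = x < rule$cutoff,
           ">=" = x >= rule$cutoff, "<=" = x <= rule$cutoff,
           stop("unknown op: ", rule$op))
  } else if (!is.null(rule$flag)) {
    rule$flag %in% sample_row$clinical_flags[[1]]
  } else stop("rule needs a field or a flag")
}

#' Genotype-phenotype (penetrance) tabulation
#'
#' Evaluates every (variant, carrier) pair of the candidate set against
#' the phenotype rules whose gene list contains the variant's gene. A
#' carrier matches when any applicable rule is satisfied; carriers with
#' no usable phenotype data are evaluated as unmatched and flagged
#' `no-data`. Summary rates are reported per candidate group (e.g. KP /
#' novel PTV / rare PTV within or outside the secondary-findings gene
#' set), as matched over evaluated carriers.
#'
#' @param candidates data.frame with `key`, `gene`, `group`, `sample_id`
#'   (one row per variant-carrier pair)
#' @param sample_info from [read_samples()]
#' @param rules list of rules, see [default_phenotype_rules()]
#' @return list `records` (per-pair data.frame with `matched`,
#'   `matched_phenotype`, `evidence_source`, `no_data`) and `summary`
#'   (per group: `evaluated`, `matched`, `rate`)
#' @export
match_phenotypes <- function(candidates, sample_info,
                             rules = default_phenotype_rules()) {
  if (nrow(candidates) == 0) {
    return(list(records = data.frame(), summary = data.frame()))
  }
  recs <- lapply(seq_len(nrow(candidates)), function(i) {
    cand <- candidates[i, ]
    srow <- sample_info[sample_info$sample_id == cand$sample_id, , drop = FALSE]
    if (nrow(srow) == 0) stop("carrier not in sample table: ", cand$sample_id)
    no_data <- all(is.na(srow$qt_ms %||% NA), is.na(srow$ldl_c %||% NA),
                   is.na(srow$tg %||% NA),
                   length(srow$clinical_flags[[1]]) == 0)
    matched <- FALSE; phen <- NA_character_; src <- "none"
    for (rule in rules) {
      if (!(cand$gene %in% rule$genes)) next
      if (rule_matches(rule, srow)) {
        matched <- TRUE; phen <- rule$phenotype; src <- rule$source
        break
      }
    }
    data.frame(key = cand$key, gene = cand$gene, group = cand$group,
               sample_id = cand$sample_id, matched = matched,
               matched_phenotype = phen, evidence_source = src,
               no_data = no_data, stringsAsFactors = FALSE)
  })
  records <- do.call(rbind, recs)
  groups <- unique(records$group)
  summary <- do.call(rbind, lapply(groups, function(g) {
    r <- records[records$group == g, ]
    data.frame(group = g, evaluated = nrow(r), matched = sum(r$matched),
               rate = if (nrow(r) > 0) sum(r$matched) / nrow(r) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  list(records = records, summary = summary)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
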