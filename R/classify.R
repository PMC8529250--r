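ptv_consequences <- c("stop_gained", "frameshift", "splice_acceptor", "splice_donor")
impact_levels <- c("PTV", "strictly_damaging_missense", "other_missense",
                   "inframe_indel", "other")
ac_tier_levels <- c("singleton", "doubleton", "AC>=3")

#' Impact class from functional annotation
#'
#' Partitions variants into five impact classes by precedence:
#' protein-truncating (stop gain, frameshift, canonical splice
#' acceptor/donor), then missense split by prediction consensus
#' (strictly damaging = deleterious by SIFT and damaging by PolyPhen-2
#' simultaneously), then in-frame indels, then everything else
#' (synonymous, UTR, intron, non-canonical splice region, other).
#'
#' @param consequence consequence token(s) from the controlled vocabulary
#' @param sift,polyphen prediction tokens
#' @param polyphen_strict when TRUE only `probably_damaging` counts as
#'   damaging for the strict consensus; by default `possibly_damaging`
#'   counts too
#' @return character vector of impact classes
#' @export
classify_impact <- function(consequence, sift, polyphen, polyphen_strict = FALSE) {
  damaging_pp <- if (polyphen_strict) "probably_damaging" else
    c("probably_damaging", "possibly_damaging")
  ifelse(consequence %in% ptv_consequences, "PTV",
  ifelse(consequence == "missense",
         ifelse(sift == "deleterious" & polyphen %in% damaging_pp,
                "strictly_damaging_missense", "other_missense"),
  ifelse(consequence == "inframe_indel", "inframe_indel", "other")))
}

#' Novelty from database membership
#'
#' A variant is novel when it carries no dbSNP identifier. Presence in a
#' second comparison cohort is passed through so novel variants can be
#' sub-counted as "not seen in the second cohort" either.
#'
#' @param rsid dbSNP identifiers (NA or empty = absent)
#' @param in_second_cohort logical presence in the comparison cohort
#' @return data.frame `novelty` (`"known"`/`"novel"`), `in_second_cohort`
#' @export
assign_novelty <- function(rsid, in_second_cohort) {
  novel <- is.na(rsid) | !nzchar(rsid)
  data.frame(novelty = ifelse(novel, "novel", "known"),
             in_second_cohort = in_second_cohort,
             stringsAsFactors = FALSE)
}

#' Allele-count tier
#'
#' @param ac alternate allele counts
#' @return `"singleton"` (AC = 1), `"doubleton"` (AC = 2) or `"AC>=3"`
#' @export
assign_ac_tier <- function(ac) {
  ifelse(ac == 1L, "singleton", ifelse(ac == 2L, "doubleton", "AC>=3"))
}

#' Clinical flags: known pathogenic, high-confidence and rare PTVs
#'
#' `is_kp`: ClinVar pathogenic or likely pathogenic. `is_hc_ptv`:
#' protein-truncating with high truncation confidence. `is_rare_ptv`:
#' known (non-novel) high-confidence PTV whose worldwide maximum allele
#' frequency is unobserved or strictly below `rare_af_cutoff`; novel PTVs
#' are reported as their own clinical group, so they are excluded here.
#'
#' @param clinvar_class,truncation_confidence,max_af annotation fields
#' @param impact_class from [classify_impact()]
#' @param novelty from [assign_novelty()]
#' @param rare_af_cutoff strict upper bound on worldwide max AF (default
#'   0.1%)
#' @return data.frame `is_kp`, `is_hc_ptv`, `is_rare_ptv`
#' @export
flag_clinical <- function(clinvar_class, truncation_confidence, max_af,
                          impact_class, novelty, rare_af_cutoff = 0.001) {
  is_kp <- clinvar_class %in% c("pathogenic", "likely_pathogenic")
  is_hc_ptv <- impact_class == "PTV" & truncation_confidence == "high"
  is_rare_ptv <- is_hc_ptv & novelty == "known" &
    (is.na(max_af) | max_af < rare_af_cutoff)
  data.frame(is_kp = is_kp, is_hc_ptv = is_hc_ptv, is_rare_ptv = is_rare_ptv)
}

#' Classify a filtered callset against its annotations
#'
#' Joins per-site allele counts with the annotation snapshot and derives
#' all per-variant labels: impact class, novelty, allele-count tier,
#' clinical flags and the carrier list. Variants lacking an annotation
#' record are flagged (`annotated = FALSE`) and keep NA labels rather
#' than being dropped.
#'
#' @param cs a filtered callset
#' @param annotations from [read_annotations()]
#' @param sample_info optional, for sex-aware X allele counting
#' @param rare_af_cutoff,polyphen_strict see [flag_clinical()],
#'   [classify_impact()]
#' @param chrx_policy see [compute_site_counts()]
#' @return data.frame with one row per variant: key, gene, ac, an, af,
#'   impact_class, novelty, in_second_cohort, ac_tier, is_kp, is_hc_ptv,
#'   is_rare_ptv, max_af, clinvar_class, rsid, carriers (list column of
#'   sample ids), annotated
#' @export
classify_variants <- function(cs, annotations, sample_info = NULL,
                              rare_af_cutoff = 0.001, polyphen_strict = FALSE,
                              chrx_policy = c("sex_aware", "diploid")) {
  counts <- compute_site_counts(cs, sample_info, match.arg(chrx_policy))
  m <- match(counts$key, annotations$variant_key)
  ann <- annotations[m, , drop = FALSE]
  annotated <- !is.na(m)

  impact <- rep(NA_character_, nrow(counts))
  impact[annotated] <- classify_impact(ann$consequence[annotated],
                                       ann$sift[annotated],
                                       ann$polyphen[annotated],
                                       polyphen_strict)
  nov <- assign_novelty(ann$rsid, ann$in_second_cohort)
  flags <- flag_clinical(ann$clinvar_class, ann$truncation_confidence,
                         ann$max_af, impact, nov$novelty, rare_af_cutoff)
  carriers <- lapply(seq_len(nrow(counts)), function(i) {
    cs$samples[!is.na(cs$dosage[i, ]) & cs$dosage[i, ] >= 1L]
  })
  out <- data.frame(
    key = counts$key, gene = ann$gene, ac = counts$ac, an = counts$an,
    af = counts$af, consequence = ann$consequence,
    impact_class = impact, novelty = nov$novelty,
    in_second_cohort = nov$in_second_cohort,
    ac_tier = assign_ac_tier(counts$ac),
    is_kp = flags$is_kp, is_hc_ptv = flags$is_hc_ptv,
    is_rare_ptv = flags$is_rare_ptv,
    max_af = ann$max_af, clinvar_class = ann$clinvar_class, rsid = ann$rsid,
    annotated = annotated, stringsAsFactors = FALSE)
  out$carriers <- carriers
  out
}

is_transition <- function(ref, alt) {
  (ref == "A" & alt == "G") | (ref == "G" & alt == "A") |
    (ref == "C" & alt == "T") | (ref == "T" & alt == "C")
}

#' Transition/transversion ratio
#'
#' Computed over single-nucleotide variants only; transitions are A<->G
#' and C<->T. A set with zero transversions yields an NA ratio with
#' `defined = FALSE`.
#'
#' @param ref,alt allele strings (non-SNVs are ignored)
#' @return list `titv` (ratio), `transitions`, `transversions`, `defined`
#' @export
titv_ratio <- function(ref, alt) {
  snv <- nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  ti <- sum(is_transition(ref[snv], alt[snv]))
  tv <- sum(snv) - ti
  list(titv = if (tv > 0) ti / tv else NA_real_,
       transitions = ti, transversions = tv, defined = tv > 0)
}

#' Cohort QC summary: Ti/Tv ratios and reference AF correlation
#'
#' @param classified output of [classify_variants()]
#' @param ref_af reference-population allele frequency per variant (same
#'   order), NA when the variant is absent from the reference
#' @param min_ac minimum cohort AC for the AF correlation (frequencies of
#'   rarer variants are dominated by sampling noise)
#' @return list `titv_all`, `titv_coding` (missense + synonymous SNVs;
#'   coding classes are less exposed to alignment artifacts, so this
#'   ratio runs higher), `af_correlation`
#' @export
qc_summary <- function(classified, ref_af = NULL, min_ac = 3) {
  kd <- parse_variant_key(classified$key)
  all_titv <- titv_ratio(kd$ref, kd$alt)
  coding <- !is.na(classified$consequence) &
    classified$consequence %in% c("missense", "synonymous")
  coding_titv <- titv_ratio(kd$ref[coding], kd$alt[coding])
  r <- NA_real_
  if (!is.null(ref_af)) {
    use <- classified$ac >= min_ac & !is.na(ref_af)
    if (sum(use) >= 2) r <- cor(classified$af[use], ref_af[use])
  }
  list(titv_all = all_titv, titv_coding = coding_titv, af_correlation = r)
}

#' Publication-shaped variant overview table
#'
#' Cross-tabulates the five impact classes against allele-count tier
#' (AC < 3 vs AC >= 3) and novelty, with a parenthetical sub-count of
#' novel variants also absent from the second comparison cohort. Cells
#' sum to the number of classified variants.
#'
#' @param classified output of [classify_variants()] (annotated rows)
#' @return data.frame, one row per impact class plus a total row
#' @export
variant_overview <- function(classified) {
  cl <- classified[classified$annotated, , drop = FALSE]
  rare <- cl$ac < 3
  rows <- lapply(impact_levels, function(lvl) {
    sel <- cl$impact_class == lvl
    novel <- cl$novelty == "novel"
    nn <- novel & !cl$in_second_cohort
    data.frame(
      impact_class = lvl,
      known_ac_lt3 = sum(sel & rare & !novel),
      novel_ac_lt3 = sum(sel & rare & novel),
      novel_not_second_ac_lt3 = sum(sel & rare & nn),
      known_ac_ge3 = sum(sel & !rare & !novel),
      novel_ac_ge3 = sum(sel & !rare & novel),
      novel_not_second_ac_ge3 = sum(sel & !rare & nn))
  })
  out <- do.call(rbind, rows)
  total <- data.frame(impact_class = "total", t(colSums(out[, -1])))
  names(total) <- names(out)
  rbind(out, total)
}
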