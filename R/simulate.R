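# Cardiovascular secondary-findings genes covered by a typical targeted
# panel; used to give synthetic cohorts realistic gene symbols so the
# default phenotype rules apply out of the box.
acmg_panel_genes <- c(
  "ACTA2", "ACTC1", "APOB", "DSC2", "DSG2", "DSP", "GLA", "KCNH2", "KCNQ1",
  "LDLR", "LMNA", "MYBPC3", "MYH11", "MYH7", "MYL2", "MYL3", "PCSK9", "PKP2",
  "PRKAG2", "RYR1", "RYR2", "SCN5A", "SDHD", "SMAD3", "TMEM43", "TNNI3",
  "TNNT2", "TPM1")

extra_panel_genes <- c("MEF2A", "NOTCH3", "APOA5", "APOC3", "GAA", "LAMA2",
                       "MIB1", "PHKA1", "SYNE1", "SYNE2", "TTN", "DMD",
                       "ALMS1", "SURF1", "MTO1", "GLB1", "SCO2", "PMM2")

default_consequence_probs <- c(
  missense = 0.408, synonymous = 0.272, intron = 0.213, UTR = 0.040,
  splice_region = 0.030, stop_gained = 0.012, frameshift = 0.012,
  splice_acceptor = 0.004, splice_donor = 0.004, inframe_indel = 0.007,
  other = 0.008)

#' Synthetic cohort configuration
#'
#' Study conditions for the synthetic cohort generator. The default
#' profile matches a targeted-panel population study: 1,685 individuals,
#' ~12,000 discovered sites across 242 genes (28 in the
#' secondary-findings list), a singleton-plus-doubleton fraction of 63.8%
#' among discovered variants, a novel fraction highest among the rarest
#' variants, a handful of planted overrepresented known-pathogenic
#' alleles, and carrier penetrance of 0.19 for phenotype-linked variants.
#' The `small` profile (200 x 1,000) keeps test runs fast.
#'
#' @param profile `"default"` or `"small"`
#' @param ... named overrides of any config field
#' @return a list of generator parameters (class `cohort_config`)
#' @export
cohort_config <- function(profile = c("default", "small"), ...) {
  profile <- match.arg(profile)
  cfg <- list(
    n_individuals = 1685, n_sites = 12000, n_genes = 242, n_acmg_genes = 28,
    male_fraction = 0.373,
    singleton_doubleton_target = 0.638,
    tail_af_max = 0.5,
    novel_rate_rarest = 0.175, novel_logit_slope = -1.8,
    novel_second_cohort_rate = 0.041, second_cohort_an = 1388,
    n_enriched_genes = 2, enrichment_odds = 8,
    kp_fraction = 0.011,
    n_overrep = 6, overrep_ratio_range = c(5, 30),
    ref_an = 100000,
    penetrance = 0.19,
    frac_nonpass_a = 0.04, frac_nonpass_b = 0.06, frac_low_gq = 0.06,
    missing_rate = 0.002,
    titv_odds_coding = 3.48, titv_odds_noncoding = 2.2,
    sd_missense_rare = 0.32, sd_missense_common = 0.15,
    hc_ptv_rate = 0.85,
    n_duplicate_pairs = 1, n_parent_child_pairs = 1,
    inheritance_probs = c(AD = 0.37, AR = 0.32, XL = 0.02, other = 0.29),
    consequence_probs = default_consequence_probs)
  if (profile == "small") {
    cfg$n_individuals <- 200; cfg$n_sites <- 1000
    cfg$n_genes <- 40; cfg$n_acmg_genes <- 8
    cfg$n_overrep <- 3
  }
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  cfg$profile <- profile
  structure(cfg, class = "cohort_config")
}

# Probability that a site with true AF p is discovered (AC >= 1) or lands
# in the singleton/doubleton tier, with AC ~ Binomial(2n, p) under HWE.
ac_tier_probs <- function(p, two_n) {
  p0 <- dbinom(0, two_n, p); p1 <- dbinom(1, two_n, p); p2 <- dbinom(2, two_n, p)
  c(disc = 1 - p0, sd = p1 + p2)
}

# Solve for the point-mass weight theta of the AF mixture so that the
# expected singleton+doubleton fraction among DISCOVERED sites hits the
# configured target. The mixture: theta at {1/(2n) (2:1 over) 2/(2n)},
# 1 - theta log-uniform on [3/(2n), tail_af_max].
solve_sfs_theta <- function(two_n, target, tail_af_max) {
  m1 <- ac_tier_probs(1 / two_n, two_n)
  m2 <- ac_tier_probs(2 / two_n, two_n)
  grid <- 10^seq(log10(3 / two_n), log10(tail_af_max), length.out = 400)
  gt <- vapply(grid, ac_tier_probs, numeric(2), two_n = two_n)
  tail_disc <- mean(gt["disc", ]); tail_sd <- mean(gt["sd", ])
  pm_disc <- (2 * m1["disc"] + m2["disc"]) / 3
  pm_sd <- (2 * m1["sd"] + m2["sd"]) / 3
  f <- function(th) {
    (th * pm_sd + (1 - th) * tail_sd) / (th * pm_disc + (1 - th) * tail_disc) -
      target
  }
  if (f(1) < 0) stop("singleton/doubleton target unreachable: ", target)
  if (f(0) > 0) return(0)
  uniroot(f, c(0, 1), tol = 1e-9)$root
}

sample_snv_alleles <- function(n, ti_odds) {
  ti <- runif(n) < ti_odds / (1 + ti_odds)
  ti_pairs <- matrix(c("A", "G", "G", "A", "C", "T", "T", "C"), ncol = 2, byrow = TRUE)
  tv_pairs <- matrix(c("A", "C", "C", "A", "A", "T", "T", "A",
                       "G", "C", "C", "G", "G", "T", "T", "G"), ncol = 2, byrow = TRUE)
  out <- matrix("", n, 2)
  out[ti, ] <- ti_pairs[sample.int(4, sum(ti), replace = TRUE), , drop = FALSE]
  out[!ti, ] <- tv_pairs[sample.int(8, sum(!ti), replace = TRUE), , drop = FALSE]
  out
}

#' Generate the ground truth of a synthetic cohort
#'
#' Draws everything the downstream modules treat as unknown: true allele
#' frequencies from a singleton-heavy mixture calibrated to the
#' configured singleton+doubleton target, gene assignments with planted
#' novel-variant excesses in a few genes, consequence and prediction
#' labels (with a strictly-damaging fraction that decays with allele
#' frequency), novelty membership with probability decreasing in
#' frequency, ClinVar classes, reference-population true frequencies with
#' planted overrepresentation ratios for a few known-pathogenic alleles,
#' and the phenotype-link plan. The truth object fully determines the
#' emitted dataset given the seed.
#'
#' @param config a [cohort_config()]
#' @param seed integer master seed; downstream stages derive their own
#'   streams at fixed offsets (+1 genotypes, +2 annotations, +3
#'   phenotypes)
#' @return an object of class `cohort_truth`
#' @export
simulate_truth <- function(config = cohort_config(), seed = 1) {
  set.seed(seed)
  n <- config$n_individuals
  two_n <- 2L * n
  ns <- config$n_sites

  # gene table
  n_acmg <- config$n_acmg_genes
  acmg <- head(acmg_panel_genes, n_acmg)
  n_extra <- config$n_genes - n_acmg
  extra <- c(head(extra_panel_genes, min(length(extra_panel_genes), n_extra)),
             sprintf("GENE%03d", seq_len(max(0, n_extra - length(extra_panel_genes)))))
  inh_extra <- sample(names(config$inheritance_probs), n_extra, replace = TRUE,
                      prob = config$inheritance_probs)
  inh_extra[extra == "DMD"] <- "XL"
  genes <- data.frame(
    gene = c(acmg, extra),
    inheritance = c(rep("AD", n_acmg), inh_extra),
    is_acmg59 = c(rep(TRUE, n_acmg), rep(FALSE, n_extra)),
    stringsAsFactors = FALSE)
  genes$chrom <- ifelse(genes$inheritance == "XL", "chrX",
                        paste0("chr", sample(1:22, nrow(genes), replace = TRUE)))

  # site allele frequencies: calibrated mixture
  theta <- solve_sfs_theta(two_n, config$singleton_doubleton_target,
                           config$tail_af_max)
  pm <- runif(ns) < theta
  af <- numeric(ns)
  af[pm] <- ifelse(runif(sum(pm)) < 2 / 3, 1 / two_n, 2 / two_n)
  af[!pm] <- 10^runif(sum(!pm), log10(3 / two_n), log10(config$tail_af_max))

  # gene assignment with variable gene sizes
  gsize <- rgamma(nrow(genes), shape = 2, rate = 1) + 0.2
  gidx <- sample.int(nrow(genes), ns, replace = TRUE, prob = gsize)
  gene <- genes$gene[gidx]
  chrom <- genes$chrom[gidx]
  pos <- ave(seq_len(ns), gidx, FUN = seq_along) * 37L +
    1000000L * gidx

  # consequences and alleles
  csq <- sample(names(config$consequence_probs), ns, replace = TRUE,
                prob = config$consequence_probs)
  coding <- csq %in% c("missense", "synonymous", "stop_gained")
  ref <- alt <- character(ns)
  snv <- !(csq %in% c("frameshift", "inframe_indel"))
  al_c <- sample_snv_alleles(sum(snv & coding), config$titv_odds_coding)
  al_n <- sample_snv_alleles(sum(snv & !coding), config$titv_odds_noncoding)
  ref[snv & coding] <- al_c[, 1]; alt[snv & coding] <- al_c[, 2]
  ref[snv & !coding] <- al_n[, 1]; alt[snv & !coding] <- al_n[, 2]
  n_fs <- sum(csq == "frameshift")
  ref[csq == "frameshift"] <- paste0("A", strrep("C", sample(1:2, n_fs, TRUE)))
  alt[csq == "frameshift"] <- "A"
  n_if <- sum(csq == "inframe_indel")
  ref[csq == "inframe_indel"] <- "ATTG"
  alt[csq == "inframe_indel"] <- "A"

  # novelty: probability decays with expected allele count; planted
  # excess in a few enriched genes
  logit_nov <- qlogis(config$novel_rate_rarest) +
    config$novel_logit_slope * log10(af * two_n)
  enr_pool <- setdiff(genes$gene[!genes$is_acmg59 & genes$chrom != "chrX"], NULL)
  enriched_genes <- sample(enr_pool, config$n_enriched_genes)
  logit_nov[gene %in% enriched_genes] <-
    logit_nov[gene %in% enriched_genes] + log(config$enrichment_odds)
  novel <- runif(ns) < plogis(logit_nov)

  in_second <- logical(ns)
  in_second[novel] <- runif(sum(novel)) < config$novel_second_cohort_rate
  in_second[!novel] <- runif(sum(!novel)) <
    (1 - (1 - af[!novel])^config$second_cohort_an)

  # predictions: strictly damaging missense fraction decays with AF
  sift <- rep("absent", ns); polyphen <- rep("absent", ns)
  mis <- which(csq == "missense")
  lo <- log10(1 / two_n); hi <- log10(0.01)
  w <- pmin(pmax((hi - log10(af[mis])) / (hi - lo), 0), 1)
  p_sd <- config$sd_missense_common +
    (config$sd_missense_rare - config$sd_missense_common) * w
  sd_mis <- runif(length(mis)) < p_sd
  sift[mis[sd_mis]] <- "deleterious"
  polyphen[mis[sd_mis]] <- "probably_damaging"
  other_mis <- mis[!sd_mis]
  sift[other_mis] <- sample(c("deleterious", "tolerated"), length(other_mis),
                            TRUE, prob = c(0.25, 0.75))
  polyphen[other_mis] <- ifelse(sift[other_mis] == "deleterious", "benign",
                                sample(c("possibly_damaging", "benign", "absent"),
                                       length(other_mis), TRUE,
                                       prob = c(0.15, 0.7, 0.15)))
  is_ptv <- csq %in% ptv_consequences
  trunc_conf <- ifelse(is_ptv,
                       ifelse(runif(ns) < config$hc_ptv_rate, "high", "low"),
                       "not_applicable")

  # ClinVar plan: only known variants can be in ClinVar
  clinvar <- rep("absent", ns)
  known <- which(!novel)
  weight <- ifelse(is_ptv[known] | (csq[known] == "missense" & sift[known] == "deleterious"),
                   3, 0.5)
  p_kp <- pmin(1, config$kp_fraction * weight / mean(weight))
  is_kp_site <- runif(length(known)) < p_kp
  kp_sites <- known[is_kp_site]
  clinvar[kp_sites] <- sample(c("pathogenic", "likely_pathogenic"),
                              length(kp_sites), TRUE, prob = c(0.6, 0.4))
  rest <- setdiff(known, kp_sites)
  clinvar[rest] <- sample(c("VUS", "conflicting", "likely_benign", "benign", "absent"),
                          length(rest), TRUE,
                          prob = c(0.05, 0.02, 0.04, 0.04, 0.85))

  # planted overrepresentation: a few KP alleles frequent enough to be
  # screened (>= 3 expected carriers) with cohort AF a fixed multiple of
  # the reference AF; everything else sits at ratio 1 (null)
  ratio <- rep(1, ns)
  overrep_sites <- integer(0)
  if (config$n_overrep > 0 && length(kp_sites) > 0) {
    overrep_sites <- sample(kp_sites, min(config$n_overrep, length(kp_sites)))
    af[overrep_sites] <- runif(length(overrep_sites), 4 / two_n, 12 / two_n)
    ratio[overrep_sites] <- runif(length(overrep_sites),
                                  config$overrep_ratio_range[1],
                                  config$overrep_ratio_range[2])
  }
  ref_af <- ifelse(novel, 0, af / ratio)
  max_af <- ifelse(novel, NA_real_, pmin(1, ref_af * runif(ns, 0.8, 1.3)))

  sexes <- ifelse(runif(n) < config$male_fraction, "male", "female")
  sample_ids <- sprintf("S%05d", seq_len(n))

  # phenotype link: clinically flagged variants in genes with a default rule
  rules <- default_phenotype_rules()
  rule_genes <- unlist(lapply(rules, `[[`, "genes"))
  linked <- (clinvar %in% c("pathogenic", "likely_pathogenic") |
               (is_ptv & trunc_conf == "high")) & gene %in% rule_genes

  # planted relatedness pairs (females, to keep X ploidy diploid)
  fem <- which(sexes == "female")
  need <- 2 * (config$n_duplicate_pairs + config$n_parent_child_pairs)
  picked <- sample(fem, need)
  dup_pairs <- if (config$n_duplicate_pairs > 0)
    matrix(picked[seq_len(2 * config$n_duplicate_pairs)], ncol = 2) else
    matrix(integer(0), ncol = 2)
  pc_pairs <- if (config$n_parent_child_pairs > 0)
    matrix(picked[2 * config$n_duplicate_pairs + seq_len(2 * config$n_parent_child_pairs)],
           ncol = 2) else matrix(integer(0), ncol = 2)

  sites <- data.frame(
    key = variant_key(chrom, pos, ref, alt), chrom = chrom, pos = pos,
    ref = ref, alt = alt, gene = gene, consequence = csq,
    true_af = af, ref_af = ref_af, ratio = ratio, novel = novel,
    in_second_cohort = in_second, clinvar_class = clinvar,
    truncation_confidence = trunc_conf, sift = sift, polyphen = polyphen,
    max_af = max_af, phenotype_linked = linked, stringsAsFactors = FALSE)
  if (anyDuplicated(sites$key)) {
    sites <- sites[!duplicated(sites$key), , drop = FALSE]
  }
  structure(list(
    config = config, seed = seed, theta = theta, genes = genes,
    sites = sites, sample_ids = sample_ids, sexes = sexes,
    enriched_genes = enriched_genes,
    overrep_keys = sites$key[match(overrep_sites, seq_len(ns))],
    duplicate_pairs = dup_pairs, parent_child_pairs = pc_pairs
  ), class = "cohort_truth")
}

#' @export
print.cohort_truth <- function(x, ...) {
  cat(sprintf("<cohort_truth> %d individuals, %d sites, seed %d\n",
              x$config$n_individuals, nrow(x$sites), x$seed))
  invisible(x)
}

#' Draw genotypes from a cohort truth
#'
#' Genotypes are drawn per site under Hardy-Weinberg at the true allele
#' frequency (hemizygous draws for males on chromosome X). Planted
#' duplicate pairs copy genotypes; planted parent-child pairs transmit
#' one parental allele per site. Sites never observed with an alternate
#' allele are dropped (a cohort callset only contains discovered
#' variants). A configured fraction of sites receives a non-PASS status
#' in one build and a fraction gets one sub-maximal non-reference GQ, to
#' exercise the consensus filter.
#'
#' @param truth a [simulate_truth()] object
#' @param seed defaults to the truth's master seed + 1
#' @return list `callset`, `emitted` (logical over truth sites),
#'   `pairs` (planted relationships)
#' @export
simulate_genotypes <- function(truth, seed = truth$seed + 1L) {
  set.seed(seed)
  cfg <- truth$config
  n <- cfg$n_individuals
  st <- truth$sites
  ns <- nrow(st)
  male <- truth$sexes == "male"
  xs <- is_chrx(st$chrom)

  dosage <- matrix(rbinom(ns * n, 2L, rep(st$true_af, n)), ns, n)
  ploidy <- matrix(2L, ns, n)
  if (any(xs) && any(male)) {
    dosage[xs, male] <- rbinom(sum(xs) * sum(male), 1L,
                               rep(st$true_af[xs], sum(male)))
    ploidy[xs, male] <- 1L
  }

  plant_pair <- function(d, pair, type) {
    a <- pair[1]; b <- pair[2]
    if (type == "dup") {
      d[, b] <- d[, a]
    } else {
      transmitted <- rbinom(ns, 1L, d[, a] / 2)
      d[, b] <- transmitted + rbinom(ns, 1L, st$true_af)
    }
    d
  }
  pair_rows <- list()
  for (r in seq_len(nrow(truth$duplicate_pairs))) {
    dosage <- plant_pair(dosage, truth$duplicate_pairs[r, ], "dup")
    pair_rows[[length(pair_rows) + 1L]] <- data.frame(
      sample_a = truth$sample_ids[truth$duplicate_pairs[r, 1]],
      sample_b = truth$sample_ids[truth$duplicate_pairs[r, 2]],
      relation = "duplicate", stringsAsFactors = FALSE)
  }
  for (r in seq_len(nrow(truth$parent_child_pairs))) {
    dosage <- plant_pair(dosage, truth$parent_child_pairs[r, ], "pc")
    pair_rows[[length(pair_rows) + 1L]] <- data.frame(
      sample_a = truth$sample_ids[truth$parent_child_pairs[r, 1]],
      sample_b = truth$sample_ids[truth$parent_child_pairs[r, 2]],
      relation = "parent_child", stringsAsFactors = FALSE)
  }

  if (cfg$missing_rate > 0) {
    miss <- matrix(runif(ns * n) < cfg$missing_rate, ns, n)
    dosage[miss] <- NA_integer_
  }

  emitted <- rowSums(dosage, na.rm = TRUE) >= 1L
  dosage <- dosage[emitted, , drop = FALSE]
  ploidy <- ploidy[emitted, , drop = FALSE]
  se <- st[emitted, , drop = FALSE]
  ne <- nrow(se)

  gq <- matrix(99L, ne, n)
  low_sites <- which(runif(ne) < cfg$frac_low_gq)
  for (i in low_sites) {
    nonref <- which(!is.na(dosage[i, ]) & dosage[i, ] >= 1L)
    if (length(nonref)) {
      gq[i, nonref[sample.int(length(nonref), 1)]] <- sample(40:98, 1)
    }
  }
  gq[is.na(dosage)] <- NA_integer_  # no call, no genotype quality
  filt_a <- ifelse(runif(ne) < cfg$frac_nonpass_a,
                   "VQSRTrancheSNP99.00to99.90", "PASS")
  filt_b <- ifelse(runif(ne) < cfg$frac_nonpass_b,
                   "VQSRTrancheSNP99.00to99.90", "PASS")

  variants <- data.frame(
    key = se$key, chrom = se$chrom, pos = se$pos, ref = se$ref, alt = se$alt,
    filter_build_a = filt_a, filter_build_b = filt_b, stringsAsFactors = FALSE)
  cs <- new_callset(variants, dosage, gq, ploidy, truth$sample_ids)
  list(callset = cs, emitted = emitted,
       pairs = if (length(pair_rows)) do.call(rbind, pair_rows) else
         data.frame(sample_a = character(0), sample_b = character(0),
                    relation = character(0)))
}

#' Emit the annotation snapshot for a cohort truth
#'
#' Reference-population allele counts are drawn binomially from the true
#' reference frequency at the configured allele number; consequence,
#' prediction, ClinVar and novelty fields mirror the truth plan exactly
#' (an rsid is present iff the variant is planned known).
#'
#' @param truth a [simulate_truth()] object
#' @param seed defaults to the master seed + 2
#' @return annotation data.frame in the dialect of [read_annotations()]
#' @export
simulate_annotations <- function(truth, seed = truth$seed + 2L) {
  set.seed(seed)
  st <- truth$sites
  ref_an <- rep(truth$config$ref_an, nrow(st))
  ref_ac <- rbinom(nrow(st), ref_an, pmin(st$ref_af, 1))
  data.frame(
    variant_key = st$key, gene = st$gene, consequence = st$consequence,
    truncation_confidence = st$truncation_confidence,
    sift = st$sift, polyphen = st$polyphen,
    rsid = ifelse(st$novel, "", sprintf("rs1%08d", seq_len(nrow(st)))),
    in_second_cohort = st$in_second_cohort,
    clinvar_class = st$clinvar_class,
    max_af = st$max_af,
    ref_nfe_ac = ref_ac, ref_nfe_an = ref_an, stringsAsFactors = FALSE)
}

#' Emit the sample phenotype table for a cohort truth
#'
#' Background phenotypes are drawn at population-plausible rates (QT
#' interval ~ N(410, 18) ms, LDL-C ~ N(3.6, 0.9) mmol/l, TG log-normal,
#' sparse background clinical flags). Carriers of phenotype-linked
#' planted variants receive the matching measurement or flag with
#' probability equal to the configured penetrance.
#'
#' @param truth a [simulate_truth()] object
#' @param callset from [simulate_genotypes()] (defines who carries what)
#' @param seed defaults to the master seed + 3
#' @param penetrance match probability per carrier (default from config)
#' @return sample data.frame in the dialect of [read_samples()]
#' @export
simulate_phenotypes <- function(truth, callset, seed = truth$seed + 3L,
                                penetrance = truth$config$penetrance) {
  set.seed(seed)
  n <- truth$config$n_individuals
  samples <- data.frame(
    sample_id = truth$sample_ids, sex = truth$sexes,
    age = sample(25:64, n, replace = TRUE),
    qt_ms = round(rnorm(n, 410, 18)),
    ldl_c = round(pmax(0.3, rnorm(n, 3.6, 0.9)), 2),
    tg = round(rlnorm(n, log(1.2), 0.5), 2), stringsAsFactors = FALSE)
  flags <- lapply(seq_len(n), function(i) {
    f <- character(0)
    if (runif(1) < 0.08) f <- c(f, "CAD")
    if (runif(1) < 0.004) f <- c(f, "myopathy")
    if (runif(1) < 0.004) f <- c(f, "hypertrophic-cardiomyopathy")
    if (runif(1) < 0.01) f <- c(f, "cerebral-infarction")
    f
  })

  rules <- default_phenotype_rules()
  linked_keys <- truth$sites$key[truth$sites$phenotype_linked]
  idx <- match(intersect(linked_keys, callset$variants$key), callset$variants$key)
  for (i in idx) {
    g <- truth$sites$gene[truth$sites$key == callset$variants$key[i]]
    rule <- Filter(function(r) g %in% r$genes, rules)[[1]]
    carriers <- which(!is.na(callset$dosage[i, ]) & callset$dosage[i, ] >= 1L)
    for (ci in carriers) {
      if (runif(1) >= penetrance) next
      if (!is.null(rule$field)) {
        samples[[rule$field]][ci] <- switch(rule$field,
          qt_ms = round(runif(1, 452, 470)),
          ldl_c = round(runif(1, 0.6, 1.5), 2),
          tg = round(runif(1, 10.5, 15), 2))
      } else {
        flags[[ci]] <- unique(c(flags[[ci]], rule$flag))
      }
    }
  }
  samples$clinical_flags <- flags
  samples
}

#' Generate a complete synthetic cohort
#'
#' Orchestrates [simulate_truth()], [simulate_genotypes()],
#' [simulate_annotations()] and [simulate_phenotypes()]; optionally
#' writes the full input bundle (VCF + filter sidecar + annotation,
#' sample and gene TSVs + truth JSON) to a directory in exactly the
#' dialect the readers consume.
#'
#' @param config a [cohort_config()]
#' @param seed master seed
#' @param dir optional output directory
#' @return list `truth`, `callset`, `annotations`, `samples`, `genes`,
#'   `pairs`, and (when written) `paths`
#' @export
simulate_cohort <- function(config = cohort_config(), seed = 1, dir = NULL) {
  truth <- simulate_truth(config, seed)
  gt <- simulate_genotypes(truth)
  ann <- simulate_annotations(truth)
  samples <- simulate_phenotypes(truth, gt$callset)
  genes <- truth$genes[, c("gene", "inheritance", "is_acmg59")]
  out <- list(truth = truth, callset = gt$callset, annotations = ann,
              samples = samples, genes = genes, pairs = gt$pairs)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      vcf = file.path(dir, "cohort.vcf"),
      filters = file.path(dir, "filters.tsv"),
      annotations = file.path(dir, "annotations.tsv"),
      samples = file.path(dir, "samples.tsv"),
      genes = file.path(dir, "genes.tsv"),
      truth = file.path(dir, "truth.json"))
    write_callset(gt$callset, paths$vcf, paths$filters)
    write_tsv(ann, paths$annotations)
    write_tsv(samples, paths$samples)
    write_tsv(genes, paths$genes)
    jsonlite::write_json(
      list(seed = seed, config = unclass(config), theta = truth$theta,
           enriched_genes = truth$enriched_genes,
           overrep_keys = truth$overrep_keys,
           pairs = gt$pairs, sites = truth$sites),
      paths$truth, auto_unbox = TRUE, digits = NA, na = "null")
    out$paths <- paths
  }
  out
}
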