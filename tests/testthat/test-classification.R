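test_that("classify_impact follows the five-class precedence", {
  # PTV consequences dominate regardless of predictions
  for (csq in c("stop_gained", "frameshift", "splice_acceptor", "splice_donor")) {
    expect_equal(classify_impact(csq, "tolerated", "benign"), "PTV")
  }
  # strictly damaging missense needs SIFT deleterious AND PolyPhen damaging
  expect_equal(classify_impact("missense", "deleterious", "probably_damaging"),
               "strictly_damaging_missense")
  expect_equal(classify_impact("missense", "deleterious", "possibly_damaging"),
               "strictly_damaging_missense")
  expect_equal(classify_impact("missense", "tolerated", "probably_damaging"),
               "other_missense")
  expect_equal(classify_impact("missense", "deleterious", "benign"),
               "other_missense")
  expect_equal(classify_impact("missense", "absent", "absent"),
               "other_missense")
  expect_equal(classify_impact("inframe_indel", "absent", "absent"),
               "inframe_indel")
  for (csq in c("synonymous", "intron", "UTR", "splice_region", "other")) {
    expect_equal(classify_impact(csq, "absent", "absent"), "other")
  }
  # strict PolyPhen mode excludes possibly_damaging
  expect_equal(classify_impact("missense", "deleterious", "possibly_damaging",
                               polyphen_strict = TRUE), "other_missense")
  # vectorized
  expect_equal(classify_impact(c("stop_gained", "missense"),
                               c("absent", "deleterious"),
                               c("absent", "probably_damaging")),
               c("PTV", "strictly_damaging_missense"))
})

test_that("novelty and AC tiers follow their definitions", {
  nov <- assign_novelty(c("rs123", "", NA, ""),
                        c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(nov$novelty, c("known", "novel", "novel", "novel"))
  expect_equal(nov$in_second_cohort, c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(assign_ac_tier(c(1L, 2L, 3L, 50L)),
               c("singleton", "doubleton", "AC>=3", "AC>=3"))
})

test_that("clinical flags: KP, high-confidence PTV, and rare PTV", {
  fl <- flag_clinical(
    clinvar_class = c("pathogenic", "likely_pathogenic", "VUS",
                      "absent", "absent"),
    truncation_confidence = c("not_applicable", "not_applicable", "high",
                              "high", "low"),
    max_af = c(0.01, 0.01, NA, 0.0005, 0.0005),
    impact_class = c("other_missense", "other_missense", "PTV", "PTV", "PTV"),
    novelty = c("known", "known", "novel", "known", "known"))
  expect_equal(fl$is_kp, c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(fl$is_hc_ptv, c(FALSE, FALSE, TRUE, TRUE, FALSE))
  # rare PTV: known high-confidence PTV with max_af strictly below cutoff
  # (novel PTVs form their own clinical group, so they are excluded here)
  expect_equal(fl$is_rare_ptv, c(FALSE, FALSE, FALSE, TRUE, FALSE))
  # boundary: max_af exactly at the cutoff is not rare
  fl2 <- flag_clinical("absent", "high", 0.001, "PTV", "known")
  expect_false(fl2$is_rare_ptv)
  # unobserved worldwide frequency counts as rare
  fl3 <- flag_clinical("absent", "high", NA, "PTV", "known")
  expect_true(fl3$is_rare_ptv)
})

test_that("Ti/Tv counts transitions and transversions correctly", {
  # the four transitions
  r <- titv_ratio(c("A", "G", "C", "T"), c("G", "A", "T", "C"))
  expect_equal(r$transitions, 4L)
  expect_equal(r$transversions, 0L)
  # balanced toy set: 2 transitions, 2 transversions
  r2 <- titv_ratio(c("A", "C", "A", "C"), c("G", "T", "C", "G"))
  expect_equal(r2$titv, 1.0)
  # non-SNV alleles are excluded from both counts
  r3 <- titv_ratio(c("A", "AT"), c("G", "A"))
  expect_equal(r3$transitions, 1L)
  expect_equal(r3$transversions, 0L)
  expect_false(titv_ratio("AT", "A")$defined)
})

test_that("classify_variants assembles per-variant labels from a simulated cohort", {
  sim <- small_sim()
  flt <- apply_consensus_filter(sim$callset)
  cls <- classify_variants(flt$callset, sim$annotations, sim$samples)
  expect_equal(nrow(cls), n_variants(flt$callset))
  # AC/AN/AF consistency
  expect_true(all(cls$ac >= 1))
  expect_true(all(cls$ac <= cls$an))
  expect_equal(cls$af, cls$ac / cls$an)
  # novelty matches the generator plan
  truth <- sim$truth$sites[match(cls$key, sim$truth$sites$key), ]
  expect_equal(cls$novelty == "known", !truth$novel)
  # impact classes only take the five allowed values
  expect_true(all(cls$impact_class %in%
                  c("PTV", "strictly_damaging_missense", "other_missense",
                    "inframe_indel", "other")))
  # carrier lists have the advertised cardinality vs the dosage matrix
  i <- which(cls$ac >= 2)[1]
  row <- match(cls$key[i], flt$callset$variants$key)
  carriers <- flt$callset$samples[
    !is.na(flt$callset$dosage[row, ]) & flt$callset$dosage[row, ] >= 1]
  expect_setequal(cls$carriers[[i]], carriers)
})

test_that("variant_overview conserves totals across its class x tier cells", {
  sim <- small_sim()
  flt <- apply_consensus_filter(sim$callset)
  cls <- classify_variants(flt$callset, sim$annotations, sim$samples)
  ov <- variant_overview(cls)
  body <- ov[ov$impact_class != "total", ]
  tot <- ov[ov$impact_class == "total", ]
  num <- setdiff(names(ov), "impact_class")
  for (col in num) expect_equal(sum(body[[col]]), tot[[col]])
  # every classified variant lands in exactly one known/novel x tier cell
  expect_equal(tot$known_ac_lt3 + tot$novel_ac_lt3 +
                 tot$known_ac_ge3 + tot$novel_ac_ge3, sum(cls$annotated))
  # novel-not-in-second-cohort is a subset of novel
  expect_true(all(body$novel_not_second_ac_lt3 <= body$novel_ac_lt3))
  expect_true(all(body$novel_not_second_ac_ge3 <= body$novel_ac_ge3))
})
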