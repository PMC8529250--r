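test_that("fisher_exact_2x2 matches the exhaustive enumeration oracle on all small tables", {
  # every 2x2 table with total n <= 30 and no all-zero margin
  n_max <- 30
  checked <- 0L
  for (a in 0:8) for (b in 0:8) for (cc in 0:8) for (d in 0:8) {
    if (a + b + cc + d > n_max) next
    if ((a + b) == 0 || (cc + d) == 0 || (a + cc) == 0 || (b + d) == 0) next
    expect_equal(fisher_exact_2x2(a, b, cc, d),
                 fisher_oracle_two_sided(a, b, cc, d),
                 tolerance = 1e-12,
                 label = sprintf("table (%d,%d;%d,%d)", a, b, cc, d))
    checked <- checked + 1L
  }
  expect_gt(checked, 1000)
})

test_that("fisher_exact_2x2 agrees with stats::fisher.test on random tables", {
  set.seed(42)
  for (i in 1:200) {
    tab <- matrix(rpois(4, lambda = sample(c(2, 10, 50), 1)), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact_2x2(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]),
                 stats::fisher.test(tab)$p.value, tolerance = 1e-9)
    expect_equal(
      fisher_exact_2x2(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2], "greater"),
      stats::fisher.test(tab, alternative = "greater")$p.value,
      tolerance = 1e-9)
    expect_equal(
      fisher_exact_2x2(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2], "less"),
      stats::fisher.test(tab, alternative = "less")$p.value,
      tolerance = 1e-9)
  }
})

test_that("fisher_exact_2x2 trivial cases", {
  # identical row proportions -> no association
  expect_equal(fisher_exact_2x2(5, 5, 50, 50), 1.0, tolerance = 1e-9)
  # empty margin -> 1 by convention
  expect_equal(fisher_exact_2x2(0, 0, 3, 4), 1)
  # monotone: p shrinks as the focal cell grows with the rest fixed
  ps <- vapply(1:15, function(a) fisher_exact_2x2(a, 20, 100, 1000), 0)
  expect_true(all(diff(ps) < 1e-12))
})

test_that("bh_adjust matches p.adjust and an independent step-up oracle", {
  set.seed(7)
  for (i in 1:100) {
    m <- sample(1:60, 1)
    p <- runif(m)^sample(1:3, 1)
    q <- bh_adjust(p)
    expect_equal(q, stats::p.adjust(p, method = "BH"), tolerance = 1e-12)
    expect_lt(max(abs(q - bh_oracle(p))), 1e-12)
  }
  # trivial cases
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  # NA handling: NAs returned as NA and excluded from m
  q <- bh_adjust(c(0.01, NA, 0.04))
  expect_true(is.na(q[2]))
  expect_equal(q[c(1, 3)], stats::p.adjust(c(0.01, 0.04), "BH"))
})

test_that("clopper_pearson_ci matches binom.test and has exact coverage", {
  set.seed(11)
  for (i in 1:50) {
    n <- sample(5:5000, 1)
    x <- sample(0:n, 1)
    ci <- clopper_pearson_ci(x, n)
    ref <- stats::binom.test(x, n)$conf.int
    expect_equal(unname(ci), as.numeric(ref), tolerance = 1e-10)
  }
  # boundary conventions
  expect_equal(unname(clopper_pearson_ci(0, 10)[1]), 0)
  expect_equal(unname(clopper_pearson_ci(10, 10)[2]), 1)
  # coverage at a rare-event operating point: p = 0.001, n = 3370
  set.seed(12)
  p_true <- 0.001; n <- 3370
  x <- rbinom(5000, n, p_true)
  cover <- vapply(x, function(k) {
    ci <- clopper_pearson_ci(k, n)
    ci["low"] <= p_true && p_true <= ci["high"]
  }, NA)
  # exact interval is conservative: coverage >= nominal (allow 3 SE slack
  # below nominal from the Monte Carlo itself)
  expect_gte(mean(cover), 0.95 - 3 * sqrt(0.95 * 0.05 / 5000))
})

test_that("gene_novelty_enrichment computes per-gene Fisher tests with BH across genes", {
  per_gene <- data.frame(gene = c("G1", "G2", "G3"),
                         novel = c(13, 2, 0), known = c(21, 40, 30))
  res <- gene_novelty_enrichment(per_gene, total_novel = 1356,
                                 total_known = 10520)
  expect_equal(res$p_value[1], fisher_exact_2x2(13, 21, 1356, 10520))
  expect_equal(res$q_value, bh_adjust(res$p_value))
  # null gene (novel fraction equals panel-wide fraction) -> p near 1
  null_gene <- data.frame(gene = "N", novel = 13, known = 101)
  p_null <- gene_novelty_enrichment(null_gene, 1300, 10100)$p_value
  expect_gt(p_null, 0.8)
  # exclusive background subtracts the focal gene from the comparison cells
  res_ex <- gene_novelty_enrichment(per_gene, 1356, 10520,
                                    background = "exclusive")
  expect_equal(res_ex$novel_rest, 1356 - per_gene$novel)
  expect_equal(res_ex$p_value[1], fisher_exact_2x2(13, 21, 1343, 10499))
})

test_that("af_overrepresentation screens, adjusts, and skips correctly", {
  v <- data.frame(
    key = c("a", "b", "c", "d"),
    cohort_ac = c(8, 4, 5, 9), cohort_an = rep(3370, 4),
    n_carriers = c(8, 4, 2, 9),
    ref_ac = c(10, 400, 5, NA), ref_an = c(100000, 100000, 100000, NA))
  res <- af_overrepresentation(v)
  # variant c dropped (2 carriers < 3), d skipped (missing reference)
  expect_setequal(res$key, c("a", "b"))
  expect_equal(attr(res, "skipped"), "d")
  expect_equal(res$p_value[res$key == "a"],
               fisher_exact_2x2(8, 3362, 10, 99990))
  expect_equal(res$q_value, bh_adjust(res$p_value))
  expect_equal(res$ratio, res$cohort_af / res$ref_af)
  a <- res[res$key == "a", ]
  expect_true(a$overrepresented)
  b <- res[res$key == "b", ]
  expect_false(b$overrepresented)  # ratio < 1 even if p small
  ci <- clopper_pearson_ci(8, 3370)
  expect_equal(a$ci_low, unname(ci["low"]))
  expect_equal(a$ci_high, unname(ci["high"]))
})

test_that("overrepresentation screen is calibrated under the null", {
  # cohort and reference drawn from the same AF: the fraction of tests
  # with p <= 0.05 must be at most ~0.05 (exact tests are conservative)
  set.seed(99)
  n_rep <- 200
  hits <- 0L; tests <- 0L
  for (r in seq_len(n_rep)) {
    af <- runif(8, 0.001, 0.01)
    v <- data.frame(
      key = sprintf("v%d", seq_along(af)),
      cohort_ac = rbinom(length(af), 3370, af), cohort_an = 3370,
      n_carriers = 3L,
      ref_ac = rbinom(length(af), 100000, af), ref_an = 100000)
    res <- af_overrepresentation(v)
    hits <- hits + sum(res$p_value <= 0.05)
    tests <- tests + nrow(res)
  }
  rate <- hits / tests
  expect_lte(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / tests))
})

test_that("af_correlation restricts to AC >= min_ac and usable pairs", {
  set.seed(3)
  af <- runif(100, 0.001, 0.2)
  ref <- af * exp(rnorm(100, 0, 0.05))
  ac <- rbinom(100, 3370, af)
  r <- af_correlation(af, ref, ac, min_ac = 3)
  use <- ac >= 3
  expect_equal(r, cor(af[use], ref[use]))
  expect_gt(r, 0.9)
  expect_true(is.na(af_correlation(af[1], ref[1], ac[1])))
})
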