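test_that("compute_ibs matches per-site brute force and handles missingness", {
  set.seed(21)
  a <- sample(c(0:2, NA), 500, replace = TRUE, prob = c(.5, .3, .15, .05))
  b <- sample(c(0:2, NA), 500, replace = TRUE, prob = c(.5, .3, .15, .05))
  got <- compute_ibs(a, b)
  # brute force: enumerate shared alleles site by site
  ok <- !is.na(a) & !is.na(b)
  brute <- table(factor(2 - abs(a[ok] - b[ok]), levels = 0:2))
  expect_equal(unname(got), as.integer(brute))
  expect_equal(sum(got), sum(ok))
  # trivial cases
  expect_equal(unname(compute_ibs(c(0, 1, 2), c(0, 1, 2))),
               c(0L, 0L, 3L))
  expect_equal(unname(compute_ibs(0L, 2L)), c(1L, 0L, 0L))
  expect_error(compute_ibs(1:3, 1:2), "length")
})

test_that("estimate_pi_hat recovers duplicate, unrelated, and parent-offspring pairs", {
  set.seed(31)
  n_sites <- 2000
  p <- runif(n_sites, 0.05, 0.5)
  draw <- function() rbinom(n_sites, 2, p)

  # duplicate: a sample against itself
  g <- draw()
  pi_dup <- estimate_pi_hat(compute_ibs(g, g), p)
  expect_gte(pi_dup, 0.95)

  # unrelated pairs at known AFs: mean pi_hat within +/- 0.03 of 0
  pis <- replicate(200, estimate_pi_hat(compute_ibs(draw(), draw()), p))
  expect_lt(abs(mean(pis)), 0.03)

  # parent-offspring: child inherits one parental allele, one from the pool
  parent <- draw()
  transmitted <- rbinom(n_sites, 1, parent / 2)
  child <- transmitted + rbinom(n_sites, 1, p)
  pi_po <- estimate_pi_hat(compute_ibs(parent, child), p)
  expect_lt(abs(pi_po - 0.5), 0.05)

  # degenerate AF set -> flagged missing
  expect_true(is.na(estimate_pi_hat(c(0, 0, 5), rep(0, 5))))
  # clamped into [0, 1] even for extreme counts
  expect_lte(estimate_pi_hat(c(0, 0, n_sites), p), 1)
  expect_gte(estimate_pi_hat(c(n_sites, 0, 0), p), 0)
})

test_that("pairwise_relatedness is symmetric, complete, and matches the per-pair path", {
  set.seed(41)
  n_sites <- 300; n_samp <- 12
  p <- runif(n_sites, 0.05, 0.5)
  d <- sapply(seq_len(n_samp), function(i) rbinom(n_sites, 2, p))
  colnames(d) <- sprintf("S%02d", seq_len(n_samp))
  d[sample(length(d), 50)] <- NA
  res <- pairwise_relatedness(d, p, min_af = 0.01)
  expect_equal(nrow(res), n_samp * (n_samp - 1) / 2)
  # IBS triples and pi_hat agree with the single-pair implementation
  for (r in sample(nrow(res), 10)) {
    a <- d[, res$sample_a[r]]; b <- d[, res$sample_b[r]]
    ibs <- compute_ibs(a, b)
    expect_equal(c(res$ibs0[r], res$ibs1[r], res$ibs2[r]), unname(ibs))
    expect_equal(sum(ibs), sum(!is.na(a) & !is.na(b)))
  }
  # symmetry: reversing the column order permutes but preserves values
  res_rev <- pairwise_relatedness(d[, rev(seq_len(n_samp))], p)
  key <- function(x) paste(pmin(x$sample_a, x$sample_b),
                           pmax(x$sample_a, x$sample_b))
  m <- match(key(res), key(res_rev))
  expect_equal(res$pi_hat, res_rev$pi_hat[m], tolerance = 1e-12)
  expect_true(all(res$pi_hat >= 0 & res$pi_hat <= 1, na.rm = TRUE))
})

test_that("planted duplicate and parent-child pairs are recovered from the generator", {
  sim <- small_sim()
  cs <- sim$callset
  cnt <- compute_site_counts(cs, sim$samples)
  auto <- !is_chrx(cs$variants$chrom)
  pairs <- pairwise_relatedness(cs$dosage[auto, , drop = FALSE],
                                cnt$af[auto], min_af = 0.01, cnt$an[auto])
  lookup <- function(a, b) {
    hit <- (pairs$sample_a == a & pairs$sample_b == b) |
           (pairs$sample_a == b & pairs$sample_b == a)
    pairs$pi_hat[hit]
  }
  planted <- sim$pairs
  expect_gte(nrow(planted), 2L)
  for (r in seq_len(nrow(planted))) {
    got <- lookup(planted$sample_a[r], planted$sample_b[r])
    if (planted$relation[r] == "duplicate") {
      expect_gte(got, 0.9)
    } else {
      expect_lt(abs(got - 0.5), 0.2)
    }
  }
})

test_that("prune_related greedily removes max-degree individuals with deterministic ties", {
  pairs <- data.frame(
    sample_a = c("A", "A", "A", "B", "X"),
    sample_b = c("B", "C", "D", "C", "Y"),
    pi_hat = c(0.9, 0.8, 0.6, 0.5, 0.1))
  res <- prune_related(pairs, threshold = 0.33,
                       samples = c("A", "B", "C", "D", "X", "Y"))
  # A has degree 3 -> removed first; remaining hot pair B-C, tie broken to B
  expect_equal(res$removed$sample, c("A", "B"))
  expect_equal(res$removed$n_pairs, c(3L, 1L))
  expect_setequal(res$retained, c("C", "D", "X", "Y"))
  # no pair above threshold -> all retained
  res2 <- prune_related(pairs[5, ], threshold = 0.33,
                        samples = c("X", "Y"))
  expect_setequal(res2$retained, c("X", "Y"))
  # one duplicate pair -> exactly one of the two removed
  res3 <- prune_related(data.frame(sample_a = "P", sample_b = "Q",
                                   pi_hat = 1.0), 0.33)
  expect_equal(nrow(res3$removed), 1L)
  expect_equal(length(res3$retained), 1L)
  # invariant: after pruning no retained pair exceeds the threshold
  left <- pairs[pairs$sample_a %in% res$retained &
                pairs$sample_b %in% res$retained, ]
  expect_true(all(left$pi_hat <= 0.33))
})

test_that("pair count is n(n-1)/2 for the cohort scale quoted for this design", {
  # 1,685 individuals give 1,418,770 pairs
  n <- 1685
  expect_equal(n * (n - 1) / 2, 1418770)
})
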