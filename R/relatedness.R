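#' Identity-by-state counts for one sample pair
#'
#' Counts sites at which two diploid dosage vectors share 0, 1 or 2
#' alleles identical by state. Sites missing in either sample are
#' excluded. Per site, IBS = 2 - |dosage_a - dosage_b| (opposite
#' homozygotes differ by 2 and score IBS0).
#'
#' @param genotypes_a,genotypes_b equal-length alt-dosage vectors
#'   (0/1/2, NA = missing)
#' @return named integer vector `c(ibs0, ibs1, ibs2)`
#' @export
compute_ibs <- function(genotypes_a, genotypes_b) {
  if (length(genotypes_a) != length(genotypes_b)) {
    stop("genotype vectors differ in length")
  }
  ok <- !is.na(genotypes_a) & !is.na(genotypes_b)
  ibs <- 2L - abs(genotypes_a[ok] - genotypes_b[ok])
  c(ibs0 = sum(ibs == 0L), ibs1 = sum(ibs == 1L), ibs2 = sum(ibs == 2L))
}

# Per-site expected IBS-class probabilities under IBD state 0/1, given
# allele frequencies p (HWE). Returns component sums over sites. When the
# allele number `an` used to estimate p is supplied, plug-in powers of p
# are replaced by unbiased factorial moments (allele counts drawn without
# replacement), the finite-sample correction of the standard toolkit
# estimator; without it rare sites bias the moments upward.
ibs_expectation_sums <- function(p, an = NULL) {
  q <- 1 - p
  if (is.null(an)) {
    m2x <- p^2; m2y <- q^2; m3x <- p^3; m3y <- q^3; m4x <- p^4; m4y <- q^4
    m2x2y <- p^2 * q^2; m3x1y <- p^3 * q; m1x3y <- p * q^3
    m2x1y <- p^2 * q; m1x2y <- p * q^2
  } else {
    t <- an; x <- p * an; y <- q * an
    ff <- function(v, k) {
      out <- rep(1, length(v))
      for (i in 0:(k - 1)) out <- out * pmax(v - i, 0)
      out
    }
    m2x <- ff(x, 2) / ff(t, 2); m2y <- ff(y, 2) / ff(t, 2)
    m3x <- ff(x, 3) / ff(t, 3); m3y <- ff(y, 3) / ff(t, 3)
    m4x <- ff(x, 4) / ff(t, 4); m4y <- ff(y, 4) / ff(t, 4)
    m2x2y <- ff(x, 2) * ff(y, 2) / ff(t, 4)
    m3x1y <- ff(x, 3) * y / ff(t, 4)
    m1x3y <- x * ff(y, 3) / ff(t, 4)
    m2x1y <- ff(x, 2) * y / ff(t, 3)
    m1x2y <- x * ff(y, 2) / ff(t, 3)
  }
  list(
    e0_ibd0 = sum(2 * m2x2y),
    e1_ibd0 = sum(4 * m3x1y + 4 * m1x3y),
    e2_ibd0 = sum(m4x + m4y + 4 * m2x2y),
    e1_ibd1 = sum(2 * m2x1y + 2 * m1x2y),
    e2_ibd1 = sum(m3x + m3y + m2x1y + m1x2y),
    n = length(p)
  )
}

# Method-of-moments IBD solve; all arguments may be vectors (one pair per
# element). Class probabilities are constrained to the simplex in the
# order used by the standard toolkit estimator: a probability above 1
# takes all the mass; a negative probability is zeroed and the remaining
# two renormalized. Clamping only the offending component (rather than
# all three at once) keeps the estimator nearly unbiased for unrelated
# pairs.
pihat_from_moments <- function(ibs0, ibs1, ibs2, e) {
  ok <- e$e0_ibd0 > 0 & e$e1_ibd1 > 0
  p0 <- ifelse(ok, ibs0 / e$e0_ibd0, NA_real_)
  p1 <- (ibs1 - p0 * e$e1_ibd0) / e$e1_ibd1
  p2 <- (ibs2 - p0 * e$e2_ibd0 - p1 * e$e2_ibd1) / e$n
  sel <- !is.na(p0) & p0 > 1; p0[sel] <- 1; p1[sel] <- 0; p2[sel] <- 0
  sel <- !is.na(p1) & p1 > 1; p1[sel] <- 1; p0[sel] <- 0; p2[sel] <- 0
  sel <- !is.na(p2) & p2 > 1; p2[sel] <- 1; p0[sel] <- 0; p1[sel] <- 0
  sel <- !is.na(p0) & p0 < 0; s <- p1 + p2
  p1[sel] <- p1[sel] / s[sel]; p2[sel] <- p2[sel] / s[sel]; p0[sel] <- 0
  sel <- !is.na(p1) & p1 < 0; s <- p0 + p2
  p0[sel] <- p0[sel] / s[sel]; p2[sel] <- p2[sel] / s[sel]; p1[sel] <- 0
  sel <- !is.na(p2) & p2 < 0; s <- p0 + p1
  p0[sel] <- p0[sel] / s[sel]; p1[sel] <- p1[sel] / s[sel]; p2[sel] <- 0
  pi_hat <- p2 + p1 / 2
  pi_hat[!is.finite(pi_hat)] <- NA_real_
  pmin(pmax(pi_hat, 0), 1)
}

#' Method-of-moments PI_HAT estimate for one pair
#'
#' Estimates the proportion of the genome shared identical by descent
#' from observed identity-by-state class counts and the cohort allele
#' frequencies of the co-called sites. Expected IBS-class counts under
#' IBD states 0/1/2 (HWE) are inverted by the method of moments; the
#' three class probabilities are clamped to `[0, 1]` and renormalized,
#' and PI_HAT = P(IBD=2) + P(IBD=1)/2, the estimator used by standard
#' genetics toolkits.
#'
#' @param ibs_counts integer vector `c(ibs0, ibs1, ibs2)` from
#'   [compute_ibs()]
#' @param site_afs allele frequencies of the sites entering the IBS
#'   counts (length must equal `sum(ibs_counts)`)
#' @param site_an optional allele numbers behind each AF estimate,
#'   enabling the finite-sample moment correction (recommended whenever
#'   the AFs come from the cohort itself)
#' @return PI_HAT in `[0, 1]`, or NA when all sites are monomorphic
#' @export
estimate_pi_hat <- function(ibs_counts, site_afs, site_an = NULL) {
  stopifnot(length(ibs_counts) == 3L, all(ibs_counts >= 0))
  if (sum(ibs_counts) != length(site_afs)) {
    stop("site_afs must cover exactly the sites counted in ibs_counts")
  }
  e <- ibs_expectation_sums(site_afs, site_an)
  if (e$e0_ibd0 <= 0 || e$e1_ibd1 <= 0) return(NA_real_)
  pihat_from_moments(ibs_counts[1], ibs_counts[2], ibs_counts[3], e)
}

#' All-pairs relatedness over a dosage matrix
#'
#' Computes IBS0/IBS1/IBS2 and method-of-moments PI_HAT for every sample
#' pair using indicator-matrix cross-products. Sites with minor allele
#' frequency below `min_af` are excluded by default: rare alleles carry
#' almost no IBS information and destabilize the moments. Missingness is
#' handled by scaling the expected-count sums by each pair's co-called
#' fraction.
#'
#' @param dosage sites x samples integer matrix (0/1/2, NA missing)
#' @param afs per-site cohort allele frequencies (same row order)
#' @param min_af minimum minor allele frequency for inclusion
#' @param an optional per-site allele numbers for the finite-sample
#'   moment correction (defaults to twice the sample count)
#' @return data.frame `sample_a`, `sample_b`, `ibs0`, `ibs1`, `ibs2`,
#'   `pi_hat`, one row per unordered pair (n(n-1)/2 rows)
#' @export
pairwise_relatedness <- function(dosage, afs, min_af = 0.01,
                                 an = rep(2L * ncol(dosage), nrow(dosage))) {
  stopifnot(nrow(dosage) == length(afs), length(an) == nrow(dosage))
  use <- !is.na(afs) & pmin(afs, 1 - afs) >= min_af
  if (!any(use)) stop("no sites left after the allele-frequency filter")
  d <- dosage[use, , drop = FALSE]
  p <- afs[use]
  an_use <- an[use]
  samples <- colnames(d)
  if (is.null(samples)) samples <- sprintf("S%04d", seq_len(ncol(d)))

  a0 <- !is.na(d) & d == 0L; storage.mode(a0) <- "double"
  a1 <- !is.na(d) & d == 1L; storage.mode(a1) <- "double"
  a2 <- !is.na(d) & d == 2L; storage.mode(a2) <- "double"
  m <- !is.na(d); storage.mode(m) <- "double"

  n02 <- crossprod(a0, a2)
  ibs0 <- n02 + t(n02)
  ibs2 <- crossprod(a0) + crossprod(a1) + crossprod(a2)
  tot <- crossprod(m)
  ibs1 <- tot - ibs0 - ibs2

  ut <- upper.tri(tot)
  idx <- which(ut, arr.ind = TRUE)
  e <- ibs_expectation_sums(p, an_use)
  scale <- tot[ut] / nrow(d)
  e_pair <- list(e0_ibd0 = e$e0_ibd0 * scale, e1_ibd0 = e$e1_ibd0 * scale,
                 e2_ibd0 = e$e2_ibd0 * scale, e1_ibd1 = e$e1_ibd1 * scale,
                 e2_ibd1 = e$e2_ibd1 * scale, n = tot[ut])
  pi_hat <- pihat_from_moments(ibs0[ut], ibs1[ut], ibs2[ut], e_pair)
  data.frame(sample_a = samples[idx[, 1]], sample_b = samples[idx[, 2]],
             ibs0 = as.integer(ibs0[ut]), ibs1 = as.integer(ibs1[ut]),
             ibs2 = as.integer(ibs2[ut]), pi_hat = pi_hat,
             stringsAsFactors = FALSE)
}

#' Greedily prune related samples
#'
#' Removes individuals until no remaining pair exceeds the PI_HAT
#' threshold. At each step the individual participating in the most
#' unresolved above-threshold pairs is dropped (ties broken by
#' lexicographically smallest sample id, for reproducibility).
#'
#' @param pairs data.frame with `sample_a`, `sample_b`, `pi_hat`
#' @param threshold pairs with `pi_hat` strictly above this are resolved
#' @param samples full sample universe (defaults to ids seen in `pairs`)
#' @return list with `retained` (character vector) and `removed`
#'   (data.frame `sample`, `n_pairs` at removal time)
#' @export
prune_related <- function(pairs, threshold = 0.33,
                          samples = sort(unique(c(pairs$sample_a, pairs$sample_b)))) {
  hot <- pairs[!is.na(pairs$pi_hat) & pairs$pi_hat > threshold,
               c("sample_a", "sample_b")]
  removed <- character(0); removed_deg <- integer(0)
  while (nrow(hot) > 0) {
    deg <- sort(table(c(hot$sample_a, hot$sample_b)), decreasing = TRUE)
    top <- names(deg)[deg == max(deg)]
    victim <- sort(top)[1]
    removed <- c(removed, victim)
    removed_deg <- c(removed_deg, max(deg))
    hot <- hot[hot$sample_a != victim & hot$sample_b != victim, , drop = FALSE]
  }
  list(retained = setdiff(samples, removed),
       removed = data.frame(sample = removed, n_pairs = removed_deg,
                            stringsAsFactors = FALSE))
}
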