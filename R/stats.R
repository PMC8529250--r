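#' Fisher's exact test for a 2x2 table
#'
#' Exact hypergeometric test on the table `(a, b; c, d)` with rows as
#' groups and columns as outcomes. The two-sided p-value sums the
#' probabilities of all tables with the observed margins whose point
#' probability does not exceed that of the observed table (ties within a
#' relative tolerance of 1e-7). One-sided alternatives refer to the odds
#' ratio of the first row.
#'
#' @param a,b,c,d non-negative integer cell counts
#' @param sidedness `"two_sided"` (default), `"greater"` or `"less"`
#' @return the p-value; a table with an all-zero margin returns 1 by
#'   convention
#' @examples
#' fisher_exact_2x2(8, 3362, 3, 4477)             # two-sided
#' fisher_exact_2x2(8, 3362, 3, 4477, "greater")  # directional
#' @export
fisher_exact_2x2 <- function(a, b, c, d,
                             sidedness = c("two_sided", "greater", "less")) {
  sidedness <- match.arg(sidedness)
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  if (r1 == 0 || r2 == 0 || c1 == 0 || (b + d) == 0) return(1)
  support <- max(0, c1 - r2):min(c1, r1)
  pr <- dhyper(support, r1, r2, c1)
  obs <- dhyper(a, r1, r2, c1)
  min(1, switch(sidedness,
    two_sided = sum(pr[pr <= obs * (1 + 1e-7)]),
    greater = phyper(a - 1, r1, r2, c1, lower.tail = FALSE),
    less = phyper(a, r1, r2, c1)))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard FDR step-up: for sorted p-values, q_(i) = min over j >= i of
#' m * p_(j) / j, clamped at 1, returned in the input order.
#'
#' @param p numeric vector of p-values in `[0, 1]` (NA allowed, returned
#'   as NA and excluded from m)
#' @return q-values, same length and order
#' @export
bh_adjust <- function(p) {
  stopifnot(all(is.na(p) | (p >= 0 & p <= 1)))
  q <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  m <- length(ok)
  if (m == 0) return(q)
  o <- ok[order(p[ok])]
  q[o] <- pmin(1, rev(cummin(rev(p[o] * m / seq_len(m)))))
  q
}

#' Clopper-Pearson exact binomial confidence interval
#'
#' Exact interval from beta-distribution quantiles; the lower margin is 0
#' when no successes are observed and the upper margin 1 when all trials
#' succeed.
#'
#' @param successes,trials binomial counts, `0 <= successes <= trials`
#' @param level confidence level (default 0.95)
#' @return named numeric vector `c(low, high)`
#' @examples
#' clopper_pearson_ci(3, 3370)  # c(0.00018, 0.0026)
#' @export
clopper_pearson_ci <- function(successes, trials, level = 0.95) {
  stopifnot(trials > 0, successes >= 0, successes <= trials)
  alpha <- 1 - level
  low <- if (successes == 0) 0 else qbeta(alpha / 2, successes, trials - successes + 1)
  high <- if (successes == trials) 1 else
    qbeta(1 - alpha / 2, successes + 1, trials - successes)
  c(low = low, high = high)
}

#' Per-gene novel-variant enrichment
#'
#' For each gene, tests whether its novel/known variant split differs
#' from the panel-wide split by Fisher's exact test, with BH correction
#' across genes. The default background keeps the focal gene inside the
#' panel totals (`"inclusive"`); `"exclusive"` subtracts the focal gene's
#' counts so the comparison cells are disjoint.
#'
#' @param per_gene data.frame with `gene`, `novel`, `known` counts
#' @param total_novel,total_known panel-wide totals (default: column sums)
#' @param background `"inclusive"` or `"exclusive"`
#' @param sidedness passed to [fisher_exact_2x2()]
#' @return data.frame `gene`, `novel_in_gene`, `known_in_gene`,
#'   `novel_rest`, `known_rest`, `p_value`, `q_value`
#' @export
gene_novelty_enrichment <- function(per_gene,
                                    total_novel = sum(per_gene$novel),
                                    total_known = sum(per_gene$known),
                                    background = c("inclusive", "exclusive"),
                                    sidedness = "two_sided") {
  background <- match.arg(background)
  stopifnot(all(per_gene$novel <= total_novel),
            all(per_gene$known <= total_known))
  rest_novel <- if (background == "exclusive") total_novel - per_gene$novel
                else rep(total_novel, nrow(per_gene))
  rest_known <- if (background == "exclusive") total_known - per_gene$known
                else rep(total_known, nrow(per_gene))
  p <- mapply(fisher_exact_2x2, per_gene$novel, per_gene$known,
              rest_novel, rest_known, MoreArgs = list(sidedness = sidedness))
  data.frame(gene = per_gene$gene,
             novel_in_gene = per_gene$novel, known_in_gene = per_gene$known,
             novel_rest = rest_novel, known_rest = rest_known,
             p_value = p, q_value = bh_adjust(p), stringsAsFactors = FALSE)
}

#' Allele-frequency overrepresentation screen against a reference
#'
#' For each tested variant, compares cohort allele counts against
#' reference-population counts by Fisher's exact test on direct allele
#' counts, computes the cohort/reference allele-frequency ratio and the
#' Clopper-Pearson interval on the cohort frequency, and adjusts p-values
#' by BH across the tested set. Variants carried by fewer than
#' `min_carriers` individuals are excluded before testing (their cohort
#' frequencies are too unstable to interpret); variants with `ref_an`
#' of zero or missing are skipped with a log attribute.
#'
#' @param variants data.frame with `key`, `cohort_ac`, `cohort_an`,
#'   `n_carriers`, `ref_ac`, `ref_an`
#' @param min_carriers minimum distinct carriers (default 3)
#' @param level CI level
#' @param sidedness passed to [fisher_exact_2x2()]
#' @param alpha BH significance level for the `overrepresented` verdict
#' @return data.frame with counts, `cohort_af`, `ci_low`, `ci_high`,
#'   `ref_af`, `ratio`, `p_value`, `q_value`, `overrepresented`;
#'   attribute `skipped` lists keys dropped for missing reference counts
#' @export
af_overrepresentation <- function(variants, min_carriers = 3, level = 0.95,
                                  sidedness = "two_sided", alpha = 0.05) {
  v <- variants[variants$n_carriers >= min_carriers, , drop = FALSE]
  skipped <- v$key[is.na(v$ref_an) | v$ref_an == 0]
  v <- v[!(is.na(v$ref_an) | v$ref_an == 0), , drop = FALSE]
  if (nrow(v) == 0) {
    out <- data.frame(key = character(0))
    attr(out, "skipped") <- skipped
    return(out)
  }
  p <- mapply(fisher_exact_2x2,
              v$cohort_ac, v$cohort_an - v$cohort_ac,
              v$ref_ac, v$ref_an - v$ref_ac,
              MoreArgs = list(sidedness = sidedness))
  ci <- t(mapply(clopper_pearson_ci, v$cohort_ac, v$cohort_an,
                 MoreArgs = list(level = level)))
  cohort_af <- v$cohort_ac / v$cohort_an
  ref_af <- v$ref_ac / v$ref_an
  q <- bh_adjust(p)
  ratio <- ifelse(ref_af > 0, cohort_af / ref_af, Inf)
  out <- data.frame(
    key = v$key, cohort_ac = v$cohort_ac, cohort_an = v$cohort_an,
    ref_ac = v$ref_ac, ref_an = v$ref_an,
    cohort_af = cohort_af, ci_low = ci[, "low"], ci_high = ci[, "high"],
    ref_af = ref_af, ratio = ratio, p_value = p, q_value = q,
    overrepresented = q <= alpha & ratio > 1, stringsAsFactors = FALSE)
  attr(out, "skipped") <- skipped
  out
}

#' Cohort vs reference allele-frequency correlation
#'
#' Pearson correlation between cohort and reference allele frequencies
#' over variants with cohort AC of at least `min_ac` and a reference
#' frequency available.
#'
#' @param cohort_af,ref_af paired frequency vectors
#' @param ac cohort allele counts (same order)
#' @param min_ac minimum AC for inclusion
#' @return Pearson R (NA with fewer than 2 usable variants)
#' @export
af_correlation <- function(cohort_af, ref_af, ac, min_ac = 3) {
  use <- !is.na(ref_af) & !is.na(cohort_af) & ac >= min_ac
  if (sum(use) < 2) return(NA_real_)
  cor(cohort_af[use], ref_af[use])
}
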