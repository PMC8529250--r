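# Shared lazily-built fixtures so expensive simulations run once per
# test session.
.fixtures <- new.env(parent = emptyenv())

small_sim <- function(seed = 101) {
  key <- paste0("small_", seed)
  if (is.null(.fixtures[[key]])) {
    .fixtures[[key]] <- simulate_cohort(cohort_config("small"), seed = seed)
  }
  .fixtures[[key]]
}

small_run <- function(seed = 101) {
  key <- paste0("run_", seed)
  if (is.null(.fixtures[[key]])) {
    .fixtures[[key]] <- suppressWarnings(
      run_pipeline(pipeline_config(inputs = small_sim(seed))))
  }
  .fixtures[[key]]
}

# Study-scale cohort: used by the parameter-recovery tests that need the
# default profile's statistical power.
default_sim <- function(seed = 202) {
  key <- paste0("default_", seed)
  if (is.null(.fixtures[[key]])) {
    .fixtures[[key]] <- simulate_cohort(cohort_config(), seed = seed)
  }
  .fixtures[[key]]
}

default_run <- function(seed = 202) {
  key <- paste0("default_run_", seed)
  if (is.null(.fixtures[[key]])) {
    .fixtures[[key]] <- suppressMessages(
      run_pipeline(pipeline_config(inputs = default_sim(seed))))
  }
  .fixtures[[key]]
}

# Exhaustive oracle for the two-sided Fisher p-value: enumerate every
# table with the observed margins and sum the probabilities of tables no
# more likely than the observed one. Independent of dhyper-based
# shortcuts in the implementation under test (uses choose() directly).
fisher_oracle_two_sided <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  support <- max(0, c1 - r2):min(c1, r1)
  pr <- vapply(support, function(x) {
    exp(lchoose(r1, x) + lchoose(r2, c1 - x) - lchoose(n, c1))
  }, 0)
  obs <- pr[support == a]
  sum(pr[pr <= obs * (1 + 1e-7)])
}

# Independent BH step-up (straight from the definition, no cummin trick).
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    j <- o[i]
    rank_i <- i
    q[j] <- min(1, min(p[o[rank_i:m]] * m / (rank_i:m)))
  }
  q
}
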