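# Shared fixtures: small cohorts and state-injection helpers built in code.

# 99% normal-approximation half-width for a binomial proportion
binom99 <- function(p, n) stats::qnorm(0.995) * sqrt(p * (1 - p) / n)

# cohort of n persons, optionally with history recording
tiny_cohort <- function(n, seed = 1, start_year = 2023, record_history = FALSE,
                        age_distribution = default_age_distribution()) {
  build_cohort(demography_config(total_eligible_population = n,
                                 age_distribution = age_distribution),
               start_year, seed = seed, record_history = record_history)
}

# inject adenomas directly into a cohort (bypasses onset sampling)
give_adenomas <- function(cohort, pid, sizes, villous = FALSE, dysplasia = FALSE,
                          year = cohort$start_year) {
  k <- max(length(pid), length(sizes))
  cohort$adenoma$pid <- c(cohort$adenoma$pid, rep_len(as.integer(pid), k))
  cohort$adenoma$size <- c(cohort$adenoma$size, rep_len(as.integer(sizes), k))
  cohort$adenoma$villous <- c(cohort$adenoma$villous, rep_len(villous, k))
  cohort$adenoma$dysplasia <- c(cohort$adenoma$dysplasia, rep_len(dysplasia, k))
  cohort$adenoma$onset_year <- c(cohort$adenoma$onset_year, rep(as.integer(year), k))
  cohort
}

give_preclinical <- function(cohort, pid, sojourn = 5L) {
  cohort$cancer_phase[pid] <- 1L
  cohort$sojourn_left[pid] <- as.integer(sojourn)
  cohort
}

# a natural-history config with effectively inert dynamics (validator requires
# strictly positive, ordered progression probabilities)
inert_nh <- function(...) {
  natural_history_config(onset_base = 0, grow_prob = c(0, 0, 0),
                         revert_prob = c(0, 0, 0),
                         progress_prob = c(1e-12, 1e-12, 2e-12), ...)
}

# desk-scale config for fast end-to-end runs
small_sim_config <- function(n = 3000, ...) {
  sim_config(demography = demography_config(total_eligible_population = n), ...)
}
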