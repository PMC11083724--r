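# Synthetic screening-eligible population.
#
# A cohort is a list of parallel per-person vectors plus an adenoma table
# (itself parallel vectors keyed by person id). All simulation operations are
# vectorized over these; a "Person" in the single-individual sense is a
# cohort of size 1.

new_history <- function() {
  env <- new.env(parent = emptyenv())
  env$events <- vector("list", 64L)
  env$n <- 0L
  env
}

record_event <- function(cohort, pid, year, event, detail = "") {
  h <- cohort$history
  if (is.null(h) || length(pid) == 0) return(invisible(NULL))
  h$n <- h$n + 1L
  if (h$n > length(h$events)) length(h$events) <- 2L * length(h$events)
  h$events[[h$n]] <- data.frame(pid = pid, year = year, event = event,
                                detail = detail, stringsAsFactors = FALSE)
  invisible(NULL)
}

#' Extract the recorded event history of a cohort
#'
#' Only populated when the cohort was built with `record_history = TRUE`.
#'
#' @param cohort A cohort created by [build_cohort()].
#' @return A data.frame with columns `pid`, `year`, `event`, `detail`,
#'   ordered as events occurred.
#' @export
cohort_history <- function(cohort) {
  h <- cohort$history
  if (is.null(h) || h$n == 0L)
    return(data.frame(pid = integer(), year = integer(),
                      event = character(), detail = character()))
  do.call(rbind, h$events[seq_len(h$n)])
}

#' Build a synthetic screening-eligible cohort
#'
#' Creates `round(total_eligible_population * scale_factor)` persons with ages
#' sampled from the configured age distribution over 50-74. The result is
#' deterministic for a fixed seed.
#'
#' @param config A [demography_config()].
#' @param start_year First simulated calendar year (the screening program is
#'   assumed to have existed since 2008, so `start_year >= 2008`).
#' @param seed Optional integer seed; when supplied the global RNG is seeded.
#' @param record_history If `TRUE`, every FIT, colonoscopy, diagnosis and
#'   death event is appended to a retrievable per-person log (intended for
#'   small cohorts; see [cohort_history()]).
#' @return An object of class `lrasim_cohort`.
#' @export
#' @examples
#' coh <- build_cohort(demography_config(total_eligible_population = 1000),
#'                     start_year = 2023, seed = 1)
#' n_alive(coh)
build_cohort <- function(config, start_year, seed = NULL, record_history = FALSE) {
  if (!inherits(config, "lrasim_demography"))
    stop_config("config must be a demography_config()")
  if (start_year < 2008)
    stop_config("start_year must be >= 2008 (screening program in place since 2008)")
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(round(config$total_eligible_population * config$scale_factor))
  if (n < 1) stop_config("scaled population size rounds to zero persons")
  ages <- sample(50:74, n, replace = TRUE, prob = config$age_distribution)
  cohort <- list(
    id = seq_len(n),
    birth_year = as.integer(start_year) - ages,
    alive = rep(TRUE, n),
    death_year = rep(NA_integer_, n),
    death_cause = rep(NA_character_, n),
    # screening profile
    participant = rep(FALSE, n),
    freq_years = rep(NA_integer_, n),       # 1 annual, 2 biennial
    last_fit_year = rep(NA_integer_, n),
    in_surveillance = rep(FALSE, n),
    # scheduled follow-up (0 none, 1 colonoscopy, 2 fit)
    next_modality = rep(0L, n),
    next_year = rep(NA_integer_, n),
    next_reason = rep(NA_integer_, n),      # index into FINDINGS_LEVELS
    next_phase = rep(0L, n),                # 0 none, 1 first_3y, 2 second_5y
    # cancer state (0 none, 1 preclinical, 2 clinical)
    cancer_phase = rep(0L, n),
    sojourn_left = rep(NA_integer_, n),
    cancer_dx_year = rep(NA_integer_, n),
    cancer_detected_by = rep(NA_character_, n),
    cancer_surv_left = rep(0L, n),
    # adenoma table: parallel vectors keyed by person id
    adenoma = list(pid = integer(), size = integer(), villous = logical(),
                   dysplasia = logical(), onset_year = integer()),
    start_year = as.integer(start_year),
    initial_size = n,
    history = if (record_history) new_history() else NULL
  )
  class(cohort) <- "lrasim_cohort"
  cohort
}

#' Number of persons currently alive
#' @param cohort A `lrasim_cohort`.
#' @return Integer count.
#' @export
n_alive <- function(cohort) sum(cohort$alive)

person_age <- function(cohort, year, idx = NULL) {
  if (is.null(idx)) year - cohort$birth_year else year - cohort$birth_year[idx]
}

n_adenomas_per_person <- function(cohort) {
  tabulate(cohort$adenoma$pid, nbins = length(cohort$id))
}

#' Snapshot a cohort as a data.frame
#'
#' @param x A `lrasim_cohort`.
#' @param year Calendar year at which to report ages; defaults to the
#'   cohort's start year.
#' @param ... Unused.
#' @return A data.frame with columns `id`, `age`, `alive`, `n_adenomas`,
#'   `cancer_status`.
#' @export
as.data.frame.lrasim_cohort <- function(x, year = x$start_year, ...) {
  data.frame(
    id = x$id,
    age = person_age(x, year),
    alive = x$alive,
    n_adenomas = n_adenomas_per_person(x),
    cancer_status = c("none", "preclinical", "clinical")[x$cancer_phase + 1L])
}

#' Write a cohort snapshot to CSV
#'
#' @inheritParams as.data.frame.lrasim_cohort
#' @param cohort A `lrasim_cohort`.
#' @param path Output CSV path.
#' @return Invisibly, the snapshot data.frame.
#' @export
write_cohort_snapshot <- function(cohort, path, year = cohort$start_year) {
  df <- as.data.frame(cohort, year = year)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' @export
print.lrasim_cohort <- function(x, ...) {
  cat(sprintf("<lrasim_cohort> %d persons (%d alive), %d adenomas, start year %d\n",
              length(x$id), n_alive(x), length(x$adenoma$pid), x$start_year))
  invisible(x)
}

# Look up annual non-CRC death probability for attained ages; ages beyond the
# table are treated as certain death.
mortality_prob <- function(ages, mortality_table) {
  idx <- ages - 49L
  q <- rep(1, length(ages))
  ok <- idx >= 1L & idx <= length(mortality_table)
  q[ok] <- mortality_table[idx[ok]]
  q[ages < 50L] <- 0
  q
}

#' Apply one year of all-cause (non-CRC) mortality
#'
#' Each alive person dies during `year` with the mortality-table probability
#' at their attained age (`year - birth_year`); ages beyond the end of the
#' table are treated as probability 1 (forced death). Deaths are recorded
#' with cause `"other"`. Dead persons accrue no further events.
#'
#' @param cohort A `lrasim_cohort`.
#' @param year Calendar year being simulated.
#' @param mortality_table Named per-age annual death probabilities starting
#'   at age 50 (see [default_mortality_table()]).
#' @return The updated cohort.
#' @export
advance_year <- function(cohort, year, mortality_table = default_mortality_table()) {
  alive <- which(cohort$alive)
  if (length(alive) == 0) return(cohort)
  ages <- person_age(cohort, year, alive)
  q <- mortality_prob(ages, mortality_table)
  dies <- alive[stats::runif(length(alive)) < q]
  if (length(dies)) {
    cohort$alive[dies] <- FALSE
    cohort$death_year[dies] <- as.integer(year)
    cohort$death_cause[dies] <- "other"
    record_event(cohort, dies, year, "death", "other")
  }
  cohort
}

# Append newly eligible 50-year-olds and assign their screening profiles with
# the same participation / frequency draws as the initial cohort.
add_entrants <- function(cohort, year, n_new, fit_cfg, frequency_mix) {
  if (n_new <= 0) return(cohort)
  n0 <- length(cohort$id)
  ids <- n0 + seq_len(n_new)
  grow <- function(x, fill) c(x, rep(fill, n_new))
  cohort$id <- c(cohort$id, ids)
  cohort$birth_year <- c(cohort$birth_year, rep(as.integer(year) - 50L, n_new))
  cohort$alive <- grow(cohort$alive, TRUE)
  cohort$death_year <- grow(cohort$death_year, NA_integer_)
  cohort$death_cause <- grow(cohort$death_cause, NA_character_)
  cohort$participant <- grow(cohort$participant, FALSE)
  cohort$freq_years <- grow(cohort$freq_years, NA_integer_)
  cohort$last_fit_year <- grow(cohort$last_fit_year, NA_integer_)
  cohort$in_surveillance <- grow(cohort$in_surveillance, FALSE)
  cohort$next_modality <- grow(cohort$next_modality, 0L)
  cohort$next_year <- grow(cohort$next_year, NA_integer_)
  cohort$next_reason <- grow(cohort$next_reason, NA_integer_)
  cohort$next_phase <- grow(cohort$next_phase, 0L)
  cohort$cancer_phase <- grow(cohort$cancer_phase, 0L)
  cohort$sojourn_left <- grow(cohort$sojourn_left, NA_integer_)
  cohort$cancer_dx_year <- grow(cohort$cancer_dx_year, NA_integer_)
  cohort$cancer_detected_by <- grow(cohort$cancer_detected_by, NA_character_)
  cohort$cancer_surv_left <- grow(cohort$cancer_surv_left, 0L)
  assign_profiles_idx(cohort, ids, fit_cfg, frequency_mix, year)
}
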