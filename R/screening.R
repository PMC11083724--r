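# Routine FIT screening: participation, annual/biennial frequency mix,
# threshold-dependent positivity keyed to the most advanced lesion.

# Assign participation / frequency / stagger to a subset of persons.
assign_profiles_idx <- function(cohort, idx, fit_cfg, frequency_mix, ref_year) {
  n <- length(idx)
  if (n == 0) return(cohort)
  part <- if (fit_cfg$participation_mode == "lifetime") {
    stats::runif(n) < fit_cfg$participation_rate
  } else {
    rep(TRUE, n)  # per-round attendance drawn at each due round instead
  }
  cohort$participant[idx] <- part
  freq <- ifelse(stats::runif(n) < frequency_mix[["annual"]], 1L, 2L)
  cohort$freq_years[idx] <- ifelse(part, freq, NA_integer_)
  # stagger first screens uniformly over the screening interval
  off <- ifelse(freq == 2L, sample(0:1, n, replace = TRUE), 0L)
  cohort$last_fit_year[idx] <- ifelse(part, as.integer(ref_year) - 1L - off,
                                      NA_integer_)
  cohort
}

#' Assign screening profiles to a cohort
#'
#' Each person independently becomes a lifetime screening participant with
#' the configured participation rate (default 0.42); each participant is an
#' annual or biennial screener per `frequency_mix` (default 50/50). Biennial
#' participants' screening years are staggered uniformly at random.
#' Deterministic under a fixed seed.
#'
#' @param cohort A `lrasim_cohort`.
#' @param fit_cfg A [fit_config()].
#' @param frequency_mix Named fractions `c(annual = , biennial = )`, summing
#'   to 1.
#' @param seed Optional integer seed.
#' @return The updated cohort.
#' @export
assign_screening_profiles <- function(cohort, fit_cfg = fit_preset("fit75"),
                                      frequency_mix = c(annual = 0.5, biennial = 0.5),
                                      seed = NULL) {
  if (!identical(sort(names(frequency_mix)), c("annual", "biennial")))
    stop_config("frequency_mix must be named c(annual=, biennial=)")
  if (abs(sum(frequency_mix) - 1) > 1e-9)
    stop_config("frequency_mix fractions must sum to 1")
  if (!is.null(seed)) set.seed(seed)
  assign_profiles_idx(cohort, seq_along(cohort$id), fit_cfg, frequency_mix,
                      cohort$start_year)
}

#' Perform FIT tests for a set of persons
#'
#' The probability of a positive result is the configured sensitivity for the
#' person's most advanced lesion, or the false-positive rate when no lesion
#' is present. `last_fit_year` is updated and the test is logged when history
#' recording is on. A positive result obliges a same-year colonoscopy
#' (100% compliance), which the simulation loop performs; callers using this
#' function directly receive the positivity vector and schedule that
#' colonoscopy themselves.
#'
#' @param cohort A `lrasim_cohort`.
#' @param idx Person indices due for a FIT this year.
#' @param year Calendar year.
#' @param fit_cfg A [fit_config()].
#' @param scheduled `TRUE` when these are surveillance-scheduled FITs (e.g.
#'   the return-to-FIT follow-up), which are performed regardless of routine
#'   participation status. Calling with `scheduled = FALSE` for a
#'   non-participant is a logic error.
#' @return A list with `cohort` (updated) and `positive` (logical vector
#'   along `idx`).
#' @export
perform_fit <- function(cohort, idx, year, fit_cfg = fit_preset("fit75"),
                        scheduled = FALSE) {
  if (length(idx) == 0)
    return(list(cohort = cohort, positive = logical(0)))
  if (!scheduled && any(!cohort$participant[idx]))
    stop_logic("routine FIT requested for a non-participant")
  if (any(!cohort$alive[idx]))
    stop_logic("FIT requested for a dead person")
  code <- lesion_code(cohort)[idx]
  p <- c(fit_cfg$false_positive_rate, fit_cfg$sensitivity_by_lesion)[code + 1L]
  positive <- stats::runif(length(idx)) < p
  cohort$last_fit_year[idx] <- as.integer(year)
  record_event(cohort, idx, year, "fit", ifelse(positive, "positive", "negative"))
  list(cohort = cohort, positive = positive)
}
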