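# Adenoma-carcinoma natural history.
#
# Each adenoma sits in one of three size classes (0-5, 6-9, >=10 mm) and each
# year either grows one class, reverts to normal mucosa, progresses to
# preclinical cancer, or stays. Preclinical cancer becomes clinical when its
# geometric sojourn elapses; clinical cancer carries an annual CRC death
# hazard. FIT positivity elsewhere is keyed to the most advanced lesion.

sample_sojourn <- function(n, mean_years) {
  # geometric on support 1, 2, ... with mean `mean_years`
  stats::rgeom(n, prob = 1 / mean_years) + 1L
}

#' Most advanced lesion per person
#'
#' Returns, for each requested person, the top of the ordered lesion
#' hierarchy none < adenoma 0-5 mm < adenoma 6-9 mm < adenoma >= 10 mm <
#' preclinical CRC. Persons with (pre)clinical cancer report
#' `"preclinical_crc"`.
#'
#' @param cohort A `lrasim_cohort`.
#' @param idx Person indices (default: everyone).
#' @return A factor with levels `none`, `adenoma_0_5`, `adenoma_6_9`,
#'   `adenoma_ge10`, `preclinical_crc`.
#' @export
#' @examples
#' coh <- build_cohort(demography_config(total_eligible_population = 1),
#'                     2023, seed = 1)
#' most_advanced_lesion(coh)  # "none"
most_advanced_lesion <- function(cohort, idx = seq_along(cohort$id)) {
  lev <- rep(0L, length(cohort$id))  # 0 none, 1..3 adenoma classes, 4 cancer
  ad <- cohort$adenoma
  if (length(ad$pid)) {
    mx <- rep(0L, length(cohort$id))
    agg <- tapply(ad$size, ad$pid, max)
    mx[as.integer(names(agg))] <- as.integer(agg)
    lev <- pmax(lev, mx)
  }
  lev[cohort$cancer_phase >= 1L] <- 4L
  factor(LESION_LEVELS[lev[idx] + 1L], levels = LESION_LEVELS)
}

# integer lesion codes (0..4) for internal vectorized use
lesion_code <- function(cohort) {
  lev <- rep(0L, length(cohort$id))
  ad <- cohort$adenoma
  if (length(ad$pid)) {
    agg <- tapply(ad$size, ad$pid, max)
    lev[as.integer(names(agg))] <- as.integer(agg)
  }
  lev[cohort$cancer_phase >= 1L] <- 4L
  lev
}

#' Advance the adenoma-carcinoma natural history by one year
#'
#' For every alive person: at most one new 0-5 mm adenoma arises with the
#' age-dependent onset probability; each existing adenoma independently grows
#' one size class, reverts to normal mucosa (leaving the adenoma set),
#' progresses to preclinical cancer (leaving the set and starting a sojourn
#' clock if none is running), or stays; a preclinical cancer whose sojourn
#' elapses is marked for symptomatic presentation this year; persons in the
#' clinical phase die of CRC with the configured annual probability.
#'
#' @param cohort A `lrasim_cohort`.
#' @param year Calendar year being simulated.
#' @param config A [natural_history_config()].
#' @return The updated cohort, with attribute fields
#'   `cohort$pending_symptomatic` (person indices newly presenting with
#'   symptoms this year) and `cohort$crc_deaths_this_year`.
#' @export
step_natural_history <- function(cohort, year, config = natural_history_config()) {
  nh <- config
  # 1. CRC deaths among clinical-phase persons
  clin <- which(cohort$alive & cohort$cancer_phase == 2L)
  crc_deaths <- integer(0)
  if (length(clin)) {
    dies <- clin[stats::runif(length(clin)) < nh$crc_death_prob]
    if (length(dies)) {
      cohort$alive[dies] <- FALSE
      cohort$death_year[dies] <- as.integer(year)
      cohort$death_cause[dies] <- "crc"
      record_event(cohort, dies, year, "death", "crc")
      crc_deaths <- dies
    }
  }
  cohort$crc_deaths_this_year <- length(crc_deaths)

  alive_mask <- cohort$alive

  # 2. preclinical sojourn countdown -> symptomatic presentation
  pre <- which(alive_mask & cohort$cancer_phase == 1L)
  pending <- integer(0)
  if (length(pre)) {
    cohort$sojourn_left[pre] <- cohort$sojourn_left[pre] - 1L
    pending <- pre[cohort$sojourn_left[pre] <= 0L]
  }
  cohort$pending_symptomatic <- pending

  # 3. adenoma transitions (existing adenomas of alive persons)
  ad <- cohort$adenoma
  if (length(ad$pid)) {
    live_row <- alive_mask[ad$pid]
    u <- stats::runif(length(ad$pid))
    g <- nh$grow_prob[ad$size]
    r <- nh$revert_prob[ad$size]
    p <- nh$progress_prob[ad$size]
    grow <- live_row & u < g
    revert <- live_row & !grow & u < g + r
    progress <- live_row & !grow & !revert & u < g + r + p
    if (any(grow)) ad$size[grow] <- ad$size[grow] + 1L
    prog_pids <- unique(ad$pid[progress])
    if (length(prog_pids)) {
      newpre <- prog_pids[cohort$cancer_phase[prog_pids] == 0L]
      if (length(newpre)) {
        cohort$cancer_phase[newpre] <- 1L
        cohort$sojourn_left[newpre] <- sample_sojourn(length(newpre),
                                                     nh$sojourn_mean_years)
        record_event(cohort, newpre, year, "preclinical_onset")
      }
      # a progression into an existing (pre)clinical cancer augments it: no-op
    }
    keep <- !(revert | progress)
    if (!all(keep)) {
      ad <- lapply(ad, function(v) v[keep])
    }
    cohort$adenoma <- ad
  }

  # 4. new adenoma onsets (cap max_new_per_year, default one per person-year)
  cand <- which(alive_mask & cohort$cancer_phase < 2L)
  if (length(cand)) {
    pr <- onset_rate(person_age(cohort, year, cand), nh)
    new_pid <- cand[stats::runif(length(cand)) < pr]
    if (length(new_pid)) {
      nn <- length(new_pid)
      vill <- stats::runif(nn) < nh$villous_fraction
      dysp <- stats::runif(nn) < nh$dysplasia_fraction
      cohort$adenoma$pid <- c(cohort$adenoma$pid, new_pid)
      cohort$adenoma$size <- c(cohort$adenoma$size, rep(1L, nn))
      cohort$adenoma$villous <- c(cohort$adenoma$villous, vill)
      cohort$adenoma$dysplasia <- c(cohort$adenoma$dysplasia, dysp)
      cohort$adenoma$onset_year <- c(cohort$adenoma$onset_year,
                                     rep(as.integer(year), nn))
    }
  }
  cohort
}
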