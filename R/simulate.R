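# One-strategy simulation over calendar years.
#
# Within-year event order is fixed:
#   (1) natural-history update (adenoma onset/transitions, sojourn countdown,
#       CRC death),
#   (2) scheduled follow-up events (symptomatic presentation, surveillance
#       colonoscopies, post-cancer surveillance, scheduled FITs),
#   (3) routine screening (FIT, and primary screening colonoscopies without
#       FIT),
#   (4) non-CRC mortality, then entry of newly eligible 50-year-olds.

# Apply follow-up scheduling to a batch of colonoscopy records (non-cancer
# findings only; diagnosis handling lives in perform_colonoscopy).
apply_followup_schedule <- function(cohort, records, strategy, prior_phase = NULL) {
  if (nrow(records) == 0) return(cohort)
  keep <- records$findings != "cancer"
  if (!any(keep)) return(cohort)
  rec <- records[keep, , drop = FALSE]
  pp <- if (is.null(prior_phase)) rep(0L, nrow(rec)) else prior_phase[keep]
  code <- match(rec$findings, FINDINGS_LEVELS)
  s <- schedule_followup_code(code, rec$year[1], strategy, pp)
  pid <- rec$pid
  cohort$next_modality[pid] <- s$modality
  cohort$next_year[pid] <- s$due
  cohort$next_reason[pid] <- s$reason
  cohort$next_phase[pid] <- s$phase
  cohort$in_surveillance[pid] <- s$modality != 0L
  cohort
}

annual_row_names <- function() {
  c("year", "n_alive", "n_eligible", "fit_screens", "fit_positives",
    paste0("colo_", COLO_CATEGORIES), "colo_total", "operative_colonoscopies",
    "major_bleeds", "perforations", "lra_findings_after_positive_fit",
    "crc_cases", "crc_deaths", "deaths_other", "cancer_mgmt_person_years",
    "cost_screening", "cost_clinical_diagnosis", "cost_cancer_management",
    "cost_total")
}

#' Run one screening strategy over a span of calendar years
#'
#' Simulates the cohort year by year under a single follow-up strategy,
#' accumulating annual outcome rows: FIT screens, colonoscopies in the five
#' reporting categories, complications, CRC cases and deaths, and
#' undiscounted costs in the three reporting groups.
#'
#' @param cohort A `lrasim_cohort` with screening profiles assigned (see
#'   [assign_screening_profiles()]).
#' @param strategy A [strategy_config()].
#' @param config A [sim_config()].
#' @param years Integer vector of consecutive calendar years to simulate
#'   (typically a burn-in from 2008 followed by the 2023-2042 reporting
#'   horizon).
#' @param seed Optional integer seed set before the loop.
#' @return A list with `annual` (data.frame, one row per simulated year) and
#'   `cohort` (final state).
#' @export
run_strategy <- function(cohort, strategy, config, years, seed = NULL) {
  stopifnot(inherits(cohort, "lrasim_cohort"),
            inherits(strategy, "lrasim_strategy"),
            inherits(config, "lrasim_config"))
  if (!is.null(seed)) set.seed(seed)
  years <- as.integer(years)
  nh <- config$natural_history
  fit_cfg <- config$fit
  comp <- config$complications
  det <- config$colonoscopy_sensitivity
  csens <- config$cancer_detection_sensitivity
  csy <- strategy$cancer_surveillance_years
  n_entrants <- as.integer(round(config$demography$entry_rate * cohort$initial_size))

  out <- matrix(0, nrow = length(years), ncol = length(annual_row_names()),
                dimnames = list(NULL, annual_row_names()))

  for (yi in seq_along(years)) {
    y <- years[yi]
    cat_n <- stats::setNames(numeric(5), COLO_CATEGORIES)
    cat_oper <- cat_n; cat_bleed <- cat_n; cat_perf <- cat_n
    fit_n <- 0; fit_pos <- 0; lra_pos_fit <- 0
    dx_before <- sum(!is.na(cohort$cancer_dx_year))
    had_colo <- rep(FALSE, length(cohort$id))

    do_colo <- function(idx, category) {
      res <- perform_colonoscopy(cohort, idx, y, category,
                                 detection_sensitivity = det,
                                 complications = comp, cancer_sens = csens,
                                 cancer_surveillance_years = csy)
      cat_n[category] <<- cat_n[category] + nrow(res$records)
      cat_oper[category] <<- cat_oper[category] + sum(res$records$operative)
      cat_bleed[category] <<- cat_bleed[category] + sum(res$records$major_bleed)
      cat_perf[category] <<- cat_perf[category] + sum(res$records$perforation)
      had_colo[idx] <<- TRUE
      cohort <<- res$cohort
      res$records
    }

    # (1) natural history
    cohort <- step_natural_history(cohort, y, nh)
    crc_deaths <- cohort$crc_deaths_this_year

    # (2a) symptomatic presentation -> diagnostic colonoscopy
    sym <- cohort$pending_symptomatic
    sym <- sym[cohort$alive[sym]]
    if (length(sym)) do_colo(sym, "symptomatic_diagnostic")

    # (2b) scheduled surveillance colonoscopies
    due_c <- which(cohort$alive & cohort$next_modality == 1L &
                     !is.na(cohort$next_year) & cohort$next_year == y)
    if (length(due_c)) {
      pp <- cohort$next_phase[due_c]
      cohort$next_modality[due_c] <- 0L
      cohort$next_year[due_c] <- NA_integer_
      cohort$in_surveillance[due_c] <- FALSE
      rec <- do_colo(due_c, "surveillance_after_adenoma")
      cohort <- apply_followup_schedule(cohort, rec, strategy, prior_phase = pp)
    }

    # (2c) post-cancer surveillance colonoscopies (annual series)
    due_cs <- which(cohort$alive & cohort$cancer_phase == 2L &
                      cohort$cancer_surv_left > 0L & cohort$cancer_dx_year < y)
    if (length(due_cs)) {
      do_colo(due_cs, "surveillance_after_cancer")
      cohort$cancer_surv_left[due_cs] <- cohort$cancer_surv_left[due_cs] - 1L
    }

    # (2d) scheduled FITs (normal-colonoscopy return and return-to-FIT rule)
    due_f <- which(cohort$alive & cohort$next_modality == 2L &
                     !is.na(cohort$next_year) & cohort$next_year == y)
    if (length(due_f)) {
      cohort$next_modality[due_f] <- 0L
      cohort$next_year[due_f] <- NA_integer_
      cohort$in_surveillance[due_f] <- FALSE
      ages <- person_age(cohort, y, due_f)
      takers <- due_f[ages >= 50L & ages <= 74L]   # FIT only within 50-74
      if (length(takers)) {
        res <- perform_fit(cohort, takers, y, fit_cfg, scheduled = TRUE)
        cohort <- res$cohort
        fit_n <- fit_n + length(takers)
        pos <- takers[res$positive]
        fit_pos <- fit_pos + length(pos)
        if (length(pos)) {
          rec <- do_colo(pos, "after_positive_fit")
          lra_pos_fit <- lra_pos_fit + sum(rec$findings == "lra_1_2")
          cohort <- apply_followup_schedule(cohort, rec, strategy)
        }
      }
    }

    # (3) routine FIT screening
    ages <- person_age(cohort, y)
    eligible <- cohort$alive & ages >= 50L & ages <= 74L
    due_r <- which(eligible & cohort$participant &
                     cohort$next_modality == 0L & cohort$cancer_phase < 2L &
                     !had_colo &
                     (y - cohort$last_fit_year) >= cohort$freq_years)
    if (length(due_r)) {
      if (fit_cfg$participation_mode == "per_round") {
        attend <- stats::runif(length(due_r)) < fit_cfg$participation_rate
        cohort$last_fit_year[due_r[!attend]] <- y   # round skipped
        due_r <- due_r[attend]
      }
      if (length(due_r)) {
        res <- perform_fit(cohort, due_r, y, fit_cfg, scheduled = FALSE)
        cohort <- res$cohort
        fit_n <- fit_n + length(due_r)
        pos <- due_r[res$positive]
        fit_pos <- fit_pos + length(pos)
        if (length(pos)) {
          rec <- do_colo(pos, "after_positive_fit")
          lra_pos_fit <- lra_pos_fit + sum(rec$findings == "lra_1_2")
          cohort <- apply_followup_schedule(cohort, rec, strategy)
        }
      }
    }

    # (3b) primary screening colonoscopies without FIT (family history)
    if (config$screening_colonoscopy_rate > 0) {
      cand <- which(eligible & cohort$next_modality == 0L &
                      cohort$cancer_phase < 2L & !had_colo)
      pick <- cand[stats::runif(length(cand)) < config$screening_colonoscopy_rate]
      if (length(pick)) {
        rec <- do_colo(pick, "screening_no_fit")
        cohort <- apply_followup_schedule(cohort, rec, strategy)
      }
    }

    # (4) cancer-management person-years, then non-CRC mortality and entry
    mgmt <- sum(cohort$alive & cohort$cancer_phase == 2L &
                  !is.na(cohort$cancer_dx_year) &
                  y - cohort$cancer_dx_year < nh$cancer_mgmt_years)
    alive_before <- sum(cohort$alive)
    cohort <- advance_year(cohort, y, config$demography$mortality_table)
    deaths_other <- alive_before - sum(cohort$alive)
    if (yi < length(years) && n_entrants > 0)
      cohort <- add_entrants(cohort, y + 1L, n_entrants, fit_cfg,
                             config$frequency_mix)

    crc_cases <- sum(!is.na(cohort$cancer_dx_year)) - dx_before
    ledger <- ledger_from_counts(
      list(fit_n = fit_n, n_colo = cat_n, n_operative = cat_oper,
           n_bleed = cat_bleed, n_perf = cat_perf,
           cancer_mgmt_person_years = mgmt),
      config$costs)
    ages_end <- person_age(cohort, y)
    out[yi, ] <- c(y, sum(cohort$alive),
                   sum(cohort$alive & ages_end >= 50L & ages_end <= 74L),
                   fit_n, fit_pos, cat_n, sum(cat_n), sum(cat_oper),
                   sum(cat_bleed), sum(cat_perf), lra_pos_fit,
                   crc_cases, crc_deaths, deaths_other, mgmt,
                   ledger[["screening"]], ledger[["clinical_diagnosis"]],
                   ledger[["cancer_management"]], ledger[["total"]])
  }
  list(annual = as.data.frame(out), cohort = cohort)
}
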