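# Undiscounted 2021-CAD cost accounting in the three reporting groups:
#   screening          - all FIT costs, positive-test consults, and
#                        {screening_no_fit, after_positive_fit} colonoscopies
#   clinical_diagnosis - {symptomatic_diagnostic, surveillance_after_adenoma}
#   cancer_management  - {surveillance_after_cancer} colonoscopies plus the
#                        annual cancer-management cost per person-year

COST_GROUP_OF_CATEGORY <- c(
  screening_no_fit = "screening",
  after_positive_fit = "screening",
  symptomatic_diagnostic = "clinical_diagnosis",
  surveillance_after_adenoma = "clinical_diagnosis",
  surveillance_after_cancer = "cancer_management")

#' Cost of one FIT screen
#'
#' Kit-and-processing cost plus the physician extra visit to discuss results
#' (both per screen), plus any per-screen recruitment cost (default 0).
#'
#' @param config A [cost_config()].
#' @return Cost in 2021 CAD.
#' @export
#' @examples
#' cost_of_fit(cost_config())  # 26.13 + 38.03 = 64.16
cost_of_fit <- function(config = cost_config()) {
  config$fit_kit + config$fit_extra_visit + config$recruitment_cost
}

#' Cost of colonoscopy procedures
#'
#' Base cost is the operative rate when any polypectomy was performed, else
#' the diagnostic rate; complication costs are added per event, and the
#' positive-test consultation fee is attached to colonoscopies following a
#' positive FIT.
#'
#' @param record A data.frame of colonoscopy records (as returned by
#'   [perform_colonoscopy()]) with columns `category`, `operative`,
#'   `major_bleed`, `perforation`.
#' @param config A [cost_config()].
#' @return Numeric vector of per-procedure costs in 2021 CAD.
#' @export
#' @examples
#' rec <- data.frame(category = "surveillance_after_adenoma", operative = FALSE,
#'                   major_bleed = FALSE, perforation = FALSE)
#' cost_of_colonoscopy(rec)  # 866.43
cost_of_colonoscopy <- function(record, config = cost_config()) {
  base <- ifelse(record$operative, config$operative_colonoscopy,
                 config$diagnostic_colonoscopy)
  base +
    as.numeric(record$major_bleed) * config$bleed_cost +
    as.numeric(record$perforation) * config$perforation_cost +
    (record$category == "after_positive_fit") * config$positive_consult
}

# Single source of truth for ledger arithmetic, from per-year event counts.
# counts: list with fit_n, and per-category vectors (named by COLO_CATEGORIES)
# n_colo, n_operative, n_bleed, n_perf, plus cancer_mgmt_person_years.
ledger_from_counts <- function(counts, config) {
  cat_cost <- counts$n_operative * config$operative_colonoscopy +
    (counts$n_colo - counts$n_operative) * config$diagnostic_colonoscopy +
    counts$n_bleed * config$bleed_cost +
    counts$n_perf * config$perforation_cost
  cat_cost[["after_positive_fit"]] <- cat_cost[["after_positive_fit"]] +
    counts$n_colo[["after_positive_fit"]] * config$positive_consult
  grp <- function(g) sum(cat_cost[COST_GROUP_OF_CATEGORY == g])
  screening <- counts$fit_n * cost_of_fit(config) + grp("screening")
  clinical <- grp("clinical_diagnosis")
  cancer <- grp("cancer_management") +
    counts$cancer_mgmt_person_years * config$cancer_mgmt_annual
  c(screening = screening, clinical_diagnosis = clinical,
    cancer_management = cancer, total = screening + clinical + cancer)
}

counts_from_events <- function(events) {
  fit_n <- sum(events$type == "fit")
  mgmt <- sum(events$type == "cancer_mgmt_year")
  colo <- events[events$type == "colonoscopy", , drop = FALSE]
  if (nrow(colo) && !all(colo$category %in% COLO_CATEGORIES))
    stop_logic("unknown colonoscopy category in event stream")
  per_cat <- function(x) {
    v <- tapply(x, factor(colo$category, levels = COLO_CATEGORIES), sum,
                default = 0)
    stats::setNames(as.numeric(v), COLO_CATEGORIES)
  }
  if (nrow(colo) == 0) {
    z <- stats::setNames(numeric(5), COLO_CATEGORIES)
    return(list(fit_n = fit_n, n_colo = z, n_operative = z, n_bleed = z,
                n_perf = z, cancer_mgmt_person_years = mgmt))
  }
  list(fit_n = fit_n,
       n_colo = per_cat(rep(1, nrow(colo))),
       n_operative = per_cat(as.numeric(colo$operative)),
       n_bleed = per_cat(as.numeric(colo$major_bleed)),
       n_perf = per_cat(as.numeric(colo$perforation)),
       cancer_mgmt_person_years = mgmt)
}

#' Aggregate an event stream into annual cost ledgers
#'
#' Sums per-event costs into the three reporting groups per calendar year.
#' The event stream has one row per costed event: FIT screens
#' (`type = "fit"`), colonoscopies (`type = "colonoscopy"`, with `category`,
#' `operative`, `major_bleed`, `perforation` columns), and cancer-management
#' person-years (`type = "cancer_mgmt_year"`).
#'
#' @param events A data.frame with at least columns `year` and `type`;
#'   colonoscopy rows additionally carry `category`, `operative`,
#'   `major_bleed`, `perforation`.
#' @param config A [cost_config()].
#' @return A data.frame with one row per year: `year`, `screening`,
#'   `clinical_diagnosis`, `cancer_management`, `total` (with
#'   `total = screening + clinical_diagnosis + cancer_management` exactly).
#' @export
aggregate_annual_costs <- function(events, config = cost_config()) {
  if (nrow(events) == 0)
    return(data.frame(year = integer(), screening = numeric(),
                      clinical_diagnosis = numeric(),
                      cancer_management = numeric(), total = numeric()))
  known <- c("fit", "colonoscopy", "cancer_mgmt_year")
  if (!all(events$type %in% known))
    stop_logic("unknown event type in event stream")
  years <- sort(unique(events$year))
  rows <- lapply(years, function(y) {
    counts <- counts_from_events(events[events$year == y, , drop = FALSE])
    as.list(ledger_from_counts(counts, config))
  })
  out <- do.call(rbind, lapply(rows, as.data.frame))
  cbind(year = years, out)
}
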