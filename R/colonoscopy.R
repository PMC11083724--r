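# Colonoscopy execution, findings classification, and follow-up scheduling.
#
# Findings classes:
#   normal    - nothing removed, no cancer
#   lra_1_2   - 1-2 adenomas removed, all tubular < 10 mm without dysplasia
#   high_risk - any villous adenoma, any tubular adenoma >= 10 mm, any
#               dysplastic adenoma, or > 2 low-risk adenomas
#   cancer    - cancer found (overrides everything)
#
# A sub-10 mm tubular adenoma with dysplasia is not a low-risk adenoma; it is
# classified high_risk (advanced histology).

# vectorized core: all arguments parallel vectors
classify_findings_code <- function(n_removed, n_lra, any_nonlra, cancer_found) {
  out <- rep(1L, length(n_removed))                       # normal
  out[n_removed > 0 & (any_nonlra | n_lra > 2L)] <- 3L    # high_risk
  out[n_removed > 0 & !any_nonlra & n_lra >= 1L & n_lra <= 2L] <- 2L  # lra_1_2
  out[cancer_found] <- 4L                                 # cancer
  out
}

#' Classify the findings of one colonoscopy
#'
#' Deterministic classification of removed adenomas: `cancer` if cancer was
#' found; `high_risk` if any removed adenoma is villous, >= 10 mm, or
#' dysplastic, or if more than 2 low-risk adenomas (LRAs) were removed;
#' `lra_1_2` if 1-2 adenomas were removed and all are tubular < 10 mm with
#' no dysplasia; otherwise `normal`.
#'
#' @param removed A data.frame of removed adenomas with columns `size_class`
#'   (values `"0-5"`, `"6-9"`, `">=10"`), `villous`, `dysplasia`; zero rows
#'   for a clean colonoscopy. See [adenoma()].
#' @param cancer_found Logical flag.
#' @return One of `"normal"`, `"lra_1_2"`, `"high_risk"`, `"cancer"` as a
#'   factor with the full findings level set.
#' @export
#' @examples
#' classify_findings(adenoma(c("0-5", "6-9")))          # lra_1_2
#' classify_findings(adenoma("0-5", villous = TRUE))    # high_risk
#' classify_findings(adenoma(c("0-5", "0-5", "0-5")))   # high_risk (>2 LRAs)
classify_findings <- function(removed = adenoma(character(0)), cancer_found = FALSE) {
  stopifnot(is.data.frame(removed),
            all(c("size_class", "villous", "dysplasia") %in% names(removed)))
  size <- match(as.character(removed$size_class), SIZE_CLASSES)
  if (anyNA(size) && nrow(removed) > 0)
    stop_config("size_class values must be one of: ", paste(SIZE_CLASSES, collapse = ", "))
  is_lra <- !removed$villous & size < 3L & !removed$dysplasia
  code <- classify_findings_code(nrow(removed), sum(is_lra), any(!is_lra),
                                 isTRUE(cancer_found))
  factor(FINDINGS_LEVELS[code], levels = FINDINGS_LEVELS)
}

#' Construct adenoma rows
#'
#' Convenience constructor for the adenoma data.frame used by
#' [classify_findings()]: one row per lesion with a size class and histology
#' flags.
#'
#' @param size_class Character vector over `"0-5"`, `"6-9"`, `">=10"` (mm).
#' @param villous,dysplasia Logical vectors (recycled).
#' @return A data.frame with columns `size_class`, `villous`, `dysplasia`.
#' @export
adenoma <- function(size_class, villous = FALSE, dysplasia = FALSE) {
  n <- length(size_class)
  data.frame(size_class = as.character(size_class),
             villous = rep_len(villous, n),
             dysplasia = rep_len(dysplasia, n))
}

#' Perform colonoscopies for a set of persons
#'
#' Each adenoma carried by a person is independently detected with its
#' size-class sensitivity; detected adenomas are removed (polypectomy). A
#' preclinical cancer is detected with `cancer_sens` (symptomatic diagnostic
#' procedures always confirm), upon which it becomes clinical with
#' `detected_by` set from the procedure category and post-cancer surveillance
#' is initiated. Major bleeding and perforation are sampled independently at
#' the configured per-procedure probabilities. Findings are classified from
#' what was removed.
#'
#' @param cohort A `lrasim_cohort`.
#' @param idx Person indices undergoing colonoscopy.
#' @param year Calendar year.
#' @param category One of `"screening_no_fit"`, `"after_positive_fit"`,
#'   `"symptomatic_diagnostic"`, `"surveillance_after_adenoma"`,
#'   `"surveillance_after_cancer"`.
#' @param detection_sensitivity Length-3 per-size-class detection
#'   probability.
#' @param complications A [complication_config()].
#' @param cancer_sens Probability of detecting a preclinical cancer.
#' @param cancer_surveillance_years Annual post-cancer surveillance
#'   colonoscopies initiated on diagnosis.
#' @return A list with `cohort` (updated) and `records`, a data.frame with
#'   one row per procedure: `pid`, `year`, `category`, `findings`,
#'   `n_removed`, `operative`, `major_bleed`, `perforation`.
#' @export
perform_colonoscopy <- function(cohort, idx, year,
                                category = "after_positive_fit",
                                detection_sensitivity = c(0.85, 0.95, 1.0),
                                complications = complication_config(),
                                cancer_sens = 1.0,
                                cancer_surveillance_years = 5L) {
  if (!category %in% COLO_CATEGORIES)
    stop_logic("unknown colonoscopy category: ", category)
  if (length(idx) == 0) {
    return(list(cohort = cohort, records = empty_colo_records()))
  }
  if (any(!cohort$alive[idx])) stop_logic("colonoscopy requested for a dead person")
  m <- length(idx)

  # adenoma detection and removal
  ad <- cohort$adenoma
  n_removed <- integer(m); n_lra <- integer(m); any_nonlra <- logical(m)
  if (length(ad$pid)) {
    slot <- match(ad$pid, idx)           # NA for adenomas of other persons
    here <- !is.na(slot)
    det <- here & stats::runif(length(ad$pid)) < detection_sensitivity[ad$size]
    if (any(det)) {
      s <- slot[det]
      n_removed <- tabulate(s, m)
      is_lra <- !ad$villous[det] & ad$size[det] < 3L & !ad$dysplasia[det]
      n_lra <- tabulate(s[is_lra], m)
      any_nonlra <- tabulate(s[!is_lra], m) > 0L
      keep <- !det
      cohort$adenoma <- lapply(ad, function(v) v[keep])
    }
  }

  # cancer detection
  pre <- cohort$cancer_phase[idx] == 1L
  found <- pre & (category == "symptomatic_diagnostic" |
                    stats::runif(m) < cancer_sens)
  cancer_found <- found | cohort$cancer_phase[idx] == 2L &
    category == "symptomatic_diagnostic"
  dx <- idx[found]
  if (length(dx)) {
    cohort$cancer_phase[dx] <- 2L
    cohort$cancer_dx_year[dx] <- as.integer(year)
    cohort$cancer_detected_by[dx] <-
      switch(category,
             screening_no_fit = "screen", after_positive_fit = "screen",
             symptomatic_diagnostic = "symptoms",
             surveillance_after_adenoma = "surveillance",
             surveillance_after_cancer = "surveillance")
    cohort$cancer_surv_left[dx] <- as.integer(cancer_surveillance_years)
    # diagnosis supersedes any adenoma-pathway schedule and routine screening
    cohort$next_modality[dx] <- 0L
    cohort$next_year[dx] <- NA_integer_
    cohort$in_surveillance[dx] <- FALSE
    record_event(cohort, dx, year, "crc_diagnosis", cohort$cancer_detected_by[dx])
  }

  # complications, independent per procedure
  bleed <- stats::runif(m) < complications$major_bleed_per_1000 / 1000
  perf <- stats::runif(m) < complications$perforation_per_1000 / 1000
  if (complications$mortality_per_1000 > 0) {
    dies <- idx[stats::runif(m) < complications$mortality_per_1000 / 1000]
    if (length(dies)) {
      cohort$alive[dies] <- FALSE
      cohort$death_year[dies] <- as.integer(year)
      cohort$death_cause[dies] <- "colonoscopy"
      record_event(cohort, dies, year, "death", "colonoscopy")
    }
  }

  findings <- classify_findings_code(n_removed, n_lra, any_nonlra, found)
  records <- data.frame(
    pid = idx, year = as.integer(year), category = category,
    findings = FINDINGS_LEVELS[findings],
    n_removed = n_removed, operative = n_removed > 0L,
    major_bleed = bleed, perforation = perf)
  record_event(cohort, idx, year, "colonoscopy",
               paste0(category, ":", records$findings))
  list(cohort = cohort, records = records)
}

empty_colo_records <- function() {
  data.frame(pid = integer(), year = integer(), category = character(),
             findings = character(), n_removed = integer(),
             operative = logical(), major_bleed = logical(),
             perforation = logical())
}

# Vectorized follow-up scheduling rule. findings_code: 1 normal, 2 lra_1_2,
# 3 high_risk, 4 cancer. prior_phase: 0 none, 1 first_3y, 2 second_5y.
# Returns parallel vectors: modality (0 none/release, 1 colonoscopy, 2 fit),
# due (year), reason (findings code), phase.
schedule_followup_code <- function(findings_code, year, strategy, prior_phase) {
  n <- length(findings_code)
  modality <- integer(n); due <- rep(NA_integer_, n)
  reason <- findings_code; phase <- integer(n)
  year <- as.integer(year)

  hr <- findings_code == 3L
  modality[hr] <- 1L
  due[hr] <- year + strategy$high_risk_first_years
  phase[hr] <- 1L

  lra <- findings_code == 2L
  new_rule <- strategy$lra_followup == "fit_5y" & year >= strategy$policy_start_year
  modality[lra] <- if (new_rule) 2L else 1L
  due[lra] <- year + strategy$lra_years

  nrm <- findings_code == 1L
  # a normal result at the 3-year high-risk follow-up still gets the second
  # surveillance colonoscopy 5 years after; otherwise return to FIT in 10
  nrm1 <- nrm & prior_phase == 1L
  modality[nrm1] <- 1L
  due[nrm1] <- year + strategy$high_risk_second_years
  phase[nrm1] <- 2L
  nrm0 <- nrm & prior_phase != 1L
  modality[nrm0] <- 2L
  due[nrm0] <- year + strategy$normal_return_years

  ca <- findings_code == 4L
  modality[ca] <- 1L
  due[ca] <- year + 1L
  list(modality = modality, due = due, reason = reason, phase = phase)
}

#' Schedule follow-up after a colonoscopy
#'
#' Applies the pathway rules to one completed colonoscopy's findings:
#' \itemize{
#' \item `normal`: routine FIT resumes in 10 years (surveillance suspends
#'   routine screening until then) - unless this was the 3-year high-risk
#'   follow-up, in which case the second surveillance colonoscopy comes 5
#'   years after.
#' \item `lra_1_2`: per strategy - surveillance colonoscopy in 5 years
#'   (status quo) or routine FIT in 5 years (return to FIT). The return-to-FIT
#'   rule applies only when the index colonoscopy year is at or after
#'   `policy_start_year` (default 2023); earlier index colonoscopies follow
#'   the status quo.
#' \item `high_risk`: surveillance colonoscopy in 3 years (then 5 years
#'   after); repeated high-risk findings restart the 3-year interval.
#' \item `cancer`: annual post-cancer surveillance colonoscopy series,
#'   starting next year.
#' }
#'
#' @param findings One of `"normal"`, `"lra_1_2"`, `"high_risk"`, `"cancer"`.
#' @param year Calendar year of the completed colonoscopy.
#' @param strategy A [strategy_config()].
#' @param prior_phase For surveillance colonoscopies in the high-risk
#'   sequence, `"first_3y"` or `"second_5y"`; `NULL` otherwise.
#' @return A list with `modality` (`"colonoscopy"` or `"fit"`), `due_year`,
#'   `reason` (the findings class), and `phase` (`"first_3y"`, `"second_5y"`
#'   or `NA`).
#' @export
#' @examples
#' sq <- strategy_preset("status_quo"); rf <- strategy_preset("return_to_fit")
#' schedule_followup("lra_1_2", 2024, rf)$due_year    # FIT in 2029
#' schedule_followup("lra_1_2", 2024, sq)$modality    # "colonoscopy"
#' schedule_followup("normal", 2025, sq)$due_year     # FIT in 2035
schedule_followup <- function(findings, year, strategy, prior_phase = NULL) {
  code <- match(as.character(findings), FINDINGS_LEVELS)
  if (is.na(code)) stop_logic("unknown findings class: ", findings)
  pp <- if (is.null(prior_phase) || is.na(prior_phase)) 0L
        else match(as.character(prior_phase), c("first_3y", "second_5y"))
  if (is.na(pp)) stop_logic("unknown prior_phase: ", prior_phase)
  s <- schedule_followup_code(code, year, strategy, pp)
  list(modality = c("none", "colonoscopy", "fit")[s$modality + 1L],
       due_year = s$due[1],
       reason = FINDINGS_LEVELS[s$reason[1]],
       phase = c(NA, "first_3y", "second_5y")[s$phase[1] + 1L])
}
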