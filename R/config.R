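# Configuration objects for the screening microsimulation.
#
# Every tunable of the model lives in one of the small config constructors
# below; each validates its invariants on construction so that a bad value
# fails loudly at configuration time, not deep inside a simulation run.

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("lrasim_config_error", "error", "condition")))
}

stop_logic <- function(...) {
  stop(errorCondition(paste0(...), class = c("lrasim_logic_error", "error", "condition")))
}

#' Default annual probability of non-colorectal-cancer death, ages 50-110
#'
#' A Gompertz-shaped synthetic life table: `q(a) = min(1, A * exp(B * (a - 50)))`
#' with `A = 0.004`, `B = 0.085`. It is a configurable stand-in for a national
#' life table; any named vector over ages 50-110 with probabilities in
#' \[0, 1\] can replace it in [demography_config()].
#'
#' @return Named numeric vector of annual death probabilities for ages 50-110.
#' @export
#' @examples
#' qx <- default_mortality_table()
#' qx[c("50", "74", "90")]
default_mortality_table <- function() {
  ages <- 50:110
  q <- pmin(1, 0.004 * exp(0.085 * (ages - 50)))
  names(q) <- ages
  q
}

#' Default age distribution of the screening-eligible population
#'
#' Probability weights over integer ages 50-74, mildly declining with age
#' (weights proportional to `exp(-0.012 * (age - 50))`), approximating a
#' stationary age structure under steady entry at 50 and mortality attrition.
#'
#' @return Named numeric vector of weights over ages 50-74 summing to 1.
#' @export
default_age_distribution <- function() {
  ages <- 50:74
  w <- exp(-0.012 * (ages - 50))
  w <- w / sum(w)
  names(w) <- ages
  w
}

#' Demography configuration
#'
#' Describes the synthetic screening-eligible population: its size at
#' simulation start, a scale factor for desk-scale runs, the age structure
#' over ages 50-74, the annual inflow of people turning 50, and an all-cause
#' (non-CRC) mortality table.
#'
#' @param total_eligible_population Number of people aged 50-74 at full scale.
#'   Default 1,190,189, the modelled provincial screening-eligible population
#'   in 2023.
#' @param scale_factor Fraction in (0, 1\] applied to all population counts;
#'   the simulated cohort has `round(total_eligible_population * scale_factor)`
#'   persons.
#' @param age_distribution Named probability weights over integer ages 50-74.
#' @param entry_rate Annual number of people turning 50, as a fraction of the
#'   initial eligible population. Default 0.045, chosen to keep the 50-74 band
#'   approximately stationary against ageing out at 75.
#' @param mortality_table Named per-age annual probability of non-CRC death
#'   for ages 50-110; ages beyond the table are treated as certain death.
#' @return An object of class `lrasim_demography`.
#' @export
#' @examples
#' cfg <- demography_config(total_eligible_population = 10000, scale_factor = 0.5)
#' round(cfg$total_eligible_population * cfg$scale_factor)
demography_config <- function(total_eligible_population = 1190189,
                              scale_factor = 1,
                              age_distribution = default_age_distribution(),
                              entry_rate = 0.045,
                              mortality_table = default_mortality_table()) {
  if (!is.numeric(total_eligible_population) || total_eligible_population <= 0)
    stop_config("total_eligible_population must be a positive number")
  if (!is.numeric(scale_factor) || scale_factor <= 0 || scale_factor > 1)
    stop_config("scale_factor must lie in (0, 1]")
  if (round(total_eligible_population * scale_factor) < 1)
    stop_config("scaled population size rounds to zero persons")
  if (length(age_distribution) != 25 ||
      !identical(names(age_distribution), as.character(50:74)))
    stop_config("age_distribution must be named over integer ages 50:74")
  if (any(age_distribution < 0))
    stop_config("age_distribution weights must be non-negative")
  if (abs(sum(age_distribution) - 1) > 1e-9)
    stop_config("age_distribution weights must sum to 1 (within 1e-9)")
  if (!is.numeric(entry_rate) || entry_rate < 0)
    stop_config("entry_rate must be non-negative")
  if (is.null(names(mortality_table)) || names(mortality_table)[1] != "50")
    stop_config("mortality_table must be named starting at age 50")
  if (any(mortality_table < 0 | mortality_table > 1))
    stop_config("mortality probabilities must lie in [0, 1]")
  structure(
    list(total_eligible_population = total_eligible_population,
         scale_factor = scale_factor,
         age_distribution = age_distribution,
         entry_rate = entry_rate,
         mortality_table = mortality_table),
    class = "lrasim_demography")
}

# Adenoma size classes, in hierarchy order. Index 1..3 used internally.
SIZE_CLASSES <- c("0-5", "6-9", ">=10")

# Lesion hierarchy for FIT positivity (most advanced lesion).
LESION_LEVELS <- c("none", "adenoma_0_5", "adenoma_6_9", "adenoma_ge10", "preclinical_crc")

# Findings classes from a colonoscopy.
FINDINGS_LEVELS <- c("normal", "lra_1_2", "high_risk", "cancer")

# The five colonoscopy reporting categories.
COLO_CATEGORIES <- c("screening_no_fit", "after_positive_fit", "symptomatic_diagnostic",
                     "surveillance_after_adenoma", "surveillance_after_cancer")

#' Natural-history configuration for the adenoma-carcinoma pathway
#'
#' Annual per-adenoma transition probabilities across the three size classes
#' (0-5, 6-9, >=10 mm), adenoma onset as a function of age, histology mix,
#' preclinical sojourn, and post-diagnosis colorectal-cancer (CRC) mortality.
#' Each adenoma each year either grows one size class, reverts to normal
#' mucosa, progresses to preclinical cancer, or stays; the remainder
#' probability is "stay".
#'
#' Defaults are a synthetic parameter set: they are tuned so that (a) the
#' yield of 1-2 low-risk adenomas among colonoscopies following a positive
#' FIT is near 26 per 100 and (b) full-scale annual CRC case counts are of a
#' realistic provincial order. They are not a registry calibration and every
#' value is overridable.
#'
#' @param onset_base Annual probability of a new 0-5 mm adenoma at age 50.
#' @param onset_slope Exponential age slope of the onset probability:
#'   `onset(age) = min(onset_cap, onset_base * exp(onset_slope * (age - 50)))`.
#' @param onset_cap Upper bound on the annual onset probability.
#' @param grow_prob Length-3 probabilities of moving up one size class, by
#'   size class; the top class must have 0.
#' @param revert_prob Length-3 probabilities of reverting to normal mucosa.
#' @param progress_prob Length-3 probabilities of progressing to preclinical
#'   cancer; must satisfy `>=10mm > 6-9mm >= 0-5mm > 0` (all adenomas carry
#'   some malignant potential).
#' @param villous_fraction Probability a new adenoma has villous histology.
#' @param dysplasia_fraction Probability a new sub-10 mm adenoma carries
#'   dysplasia.
#' @param sojourn_mean_years Mean of the geometric preclinical sojourn
#'   (years from preclinical onset to symptomatic presentation), support 1, 2, ...
#' @param crc_death_prob Annual probability of CRC death while in the
#'   clinical phase.
#' @param max_new_per_year Cap on new adenoma onsets per person-year.
#' @param cancer_mgmt_years Years after diagnosis during which annual cancer
#'   management cost accrues (aligned with the surveillance window).
#' @return An object of class `lrasim_natural_history`.
#' @export
natural_history_config <- function(onset_base = 0.045,
                                   onset_slope = 0.035,
                                   onset_cap = 0.15,
                                   grow_prob = c(0.07, 0.07, 0),
                                   revert_prob = c(0.05, 0.03, 0.01),
                                   progress_prob = c(0.0005, 0.0030, 0.0310),
                                   villous_fraction = 0.08,
                                   dysplasia_fraction = 0.04,
                                   sojourn_mean_years = 4,
                                   crc_death_prob = 0.06,
                                   max_new_per_year = 1L,
                                   cancer_mgmt_years = 5L) {
  for (p in list(grow_prob, revert_prob, progress_prob)) {
    if (length(p) != 3 || any(p < 0 | p > 1))
      stop_config("size-class transition probabilities must be length-3 in [0, 1]")
  }
  tot <- grow_prob + revert_prob + progress_prob
  if (any(tot > 1))
    stop_config("grow + revert + progress must be <= 1 in every size class")
  if (grow_prob[3] != 0)
    stop_config("the >=10 mm class cannot grow further; grow_prob[3] must be 0")
  if (!(progress_prob[3] > progress_prob[2] &&
        progress_prob[2] >= progress_prob[1] && progress_prob[1] > 0))
    stop_config("progress_prob must satisfy >=10mm > 6-9mm >= 0-5mm > 0")
  for (p in c(onset_base, onset_cap, villous_fraction, dysplasia_fraction, crc_death_prob)) {
    if (p < 0 || p > 1) stop_config("probabilities must lie in [0, 1]")
  }
  if (sojourn_mean_years < 1) stop_config("sojourn_mean_years must be >= 1")
  structure(
    list(onset_base = onset_base, onset_slope = onset_slope, onset_cap = onset_cap,
         grow_prob = grow_prob, revert_prob = revert_prob, progress_prob = progress_prob,
         villous_fraction = villous_fraction, dysplasia_fraction = dysplasia_fraction,
         sojourn_mean_years = sojourn_mean_years, crc_death_prob = crc_death_prob,
         max_new_per_year = as.integer(max_new_per_year),
         cancer_mgmt_years = as.integer(cancer_mgmt_years)),
    class = "lrasim_natural_history")
}

onset_rate <- function(age, nh) {
  pmin(nh$onset_cap, nh$onset_base * exp(nh$onset_slope * (age - 50)))
}

#' FIT test configuration
#'
#' The probability of a positive fecal immunochemical test is keyed to a
#' person's most advanced lesion at test time; `false_positive_rate` applies
#' when no lesion is present. Sensitivities must be non-decreasing along the
#' lesion hierarchy (0-5 mm adenoma < 6-9 mm < >=10 mm < preclinical CRC).
#'
#' @param threshold_label Positivity threshold label, `"75 ng/mL"` (base
#'   case) or `"100 ng/mL"`.
#' @param sensitivity_by_lesion Named probabilities of a positive FIT for
#'   `adenoma_0_5`, `adenoma_6_9`, `adenoma_ge10`, `preclinical_crc`. The
#'   large-adenoma and CRC defaults follow systematic-review-scale values; the
#'   sub-10 mm defaults are synthetic stand-ins calibrated so the low-risk
#'   adenoma yield property holds.
#' @param false_positive_rate Probability of a positive FIT with no lesion.
#' @param participation_rate Fraction of the eligible population who are
#'   screening participants. Default 0.42.
#' @param participation_mode `"lifetime"` (default): participation is a fixed
#'   person-level attribute; `"per_round"`: every eligible person attends each
#'   due round independently with `participation_rate`.
#' @return An object of class `lrasim_fit`.
#' @seealso [fit_preset()] for the named 75 and 100 ng/mL presets.
#' @export
fit_config <- function(threshold_label = "75 ng/mL",
                       sensitivity_by_lesion = c(adenoma_0_5 = 0.07,
                                                 adenoma_6_9 = 0.18,
                                                 adenoma_ge10 = 0.50,
                                                 preclinical_crc = 0.85),
                       false_positive_rate = 0.075,
                       participation_rate = 0.42,
                       participation_mode = c("lifetime", "per_round")) {
  participation_mode <- match.arg(participation_mode)
  want <- c("adenoma_0_5", "adenoma_6_9", "adenoma_ge10", "preclinical_crc")
  if (!identical(names(sensitivity_by_lesion), want))
    stop_config("sensitivity_by_lesion must be named: ", paste(want, collapse = ", "))
  if (any(sensitivity_by_lesion < 0 | sensitivity_by_lesion > 1))
    stop_config("sensitivities must lie in [0, 1]")
  if (is.unsorted(sensitivity_by_lesion))
    stop_config("sensitivity_by_lesion must be non-decreasing along the lesion hierarchy")
  if (false_positive_rate < 0 || false_positive_rate > 1)
    stop_config("false_positive_rate must lie in [0, 1]")
  if (participation_rate < 0 || participation_rate > 1)
    stop_config("participation_rate must lie in [0, 1]")
  structure(
    list(threshold_label = threshold_label,
         sensitivity_by_lesion = sensitivity_by_lesion,
         false_positive_rate = false_positive_rate,
         participation_rate = participation_rate,
         participation_mode = participation_mode),
    class = "lrasim_fit")
}

#' Named FIT threshold presets
#'
#' `"fit75"` is the base-case 75 ng/mL threshold; `"fit100"` lowers the
#' sub-10 mm sensitivities (relative sensitivities applied to the 75 ng/mL
#' values) and the false-positive rate, reflecting a stricter positivity
#' threshold.
#'
#' @param name `"fit75"` or `"fit100"`.
#' @return An [fit_config()] object.
#' @export
fit_preset <- function(name = c("fit75", "fit100")) {
  name <- match.arg(name)
  switch(name,
    fit75 = fit_config(),
    fit100 = fit_config(
      threshold_label = "100 ng/mL",
      sensitivity_by_lesion = c(adenoma_0_5 = 0.050,
                                adenoma_6_9 = 0.13,
                                adenoma_ge10 = 0.45,
                                preclinical_crc = 0.82),
      false_positive_rate = 0.060))
}

#' Strategy configuration for post-colonoscopy follow-up
#'
#' Encodes the follow-up rule applied after a colonoscopy finding of 1-2
#' low-risk adenomas (LRAs) - surveillance colonoscopy at 5 years (status
#' quo) or return to routine FIT screening at 5 years (new strategy) -
#' together with the shared pathway intervals: normal colonoscopy returns to
#' FIT at 10 years; high-risk findings (any villous adenoma, any tubular
#' adenoma >= 10 mm, or more than 2 LRAs) get colonoscopy at 3 years then 5
#' years; diagnosed cancer gets annual surveillance colonoscopy for 5 years.
#' The new-strategy LRA rule applies only to index colonoscopies performed in
#' `policy_start_year` or later.
#'
#' @param lra_followup `"colonoscopy_5y"` (status quo) or `"fit_5y"` (return
#'   to FIT).
#' @param policy_start_year First calendar year the LRA rule change applies.
#' @param normal_return_years,high_risk_first_years,high_risk_second_years,lra_years
#'   Follow-up intervals in years.
#' @param cancer_surveillance_years Number of annual post-cancer surveillance
#'   colonoscopies.
#' @return An object of class `lrasim_strategy`.
#' @seealso [strategy_preset()]
#' @export
strategy_config <- function(lra_followup = c("colonoscopy_5y", "fit_5y"),
                            policy_start_year = 2023L,
                            normal_return_years = 10L,
                            high_risk_first_years = 3L,
                            high_risk_second_years = 5L,
                            lra_years = 5L,
                            cancer_surveillance_years = 5L) {
  lra_followup <- match.arg(lra_followup)
  iv <- c(normal_return_years, high_risk_first_years, high_risk_second_years,
          lra_years, cancer_surveillance_years)
  if (any(iv != round(iv)) || any(iv <= 0))
    stop_config("all follow-up intervals must be positive integers")
  structure(
    list(lra_followup = lra_followup,
         policy_start_year = as.integer(policy_start_year),
         normal_return_years = as.integer(normal_return_years),
         high_risk_first_years = as.integer(high_risk_first_years),
         high_risk_second_years = as.integer(high_risk_second_years),
         lra_years = as.integer(lra_years),
         cancer_surveillance_years = as.integer(cancer_surveillance_years)),
    class = "lrasim_strategy")
}

#' Named strategy presets
#'
#' `"status_quo"`: surveillance colonoscopy 5 years after removal of 1-2
#' low-risk adenomas. `"return_to_fit"`: routine FIT screening resumes 5
#' years after removal, for index colonoscopies in 2023 or later.
#'
#' @param name `"status_quo"` or `"return_to_fit"`.
#' @return A [strategy_config()] object.
#' @export
strategy_preset <- function(name = c("status_quo", "return_to_fit")) {
  name <- match.arg(name)
  switch(name,
    status_quo = strategy_config("colonoscopy_5y"),
    return_to_fit = strategy_config("fit_5y"))
}

#' Colonoscopy complication configuration
#'
#' Per-procedure complication incidence, expressed per 1000 colonoscopies.
#' Defaults: major bleeding 0.3, perforation 1.7, mortality 0.
#'
#' @param major_bleed_per_1000,perforation_per_1000,mortality_per_1000
#'   Non-negative rates per 1000 colonoscopies.
#' @return An object of class `lrasim_complications`.
#' @export
complication_config <- function(major_bleed_per_1000 = 0.3,
                                perforation_per_1000 = 1.7,
                                mortality_per_1000 = 0) {
  r <- c(major_bleed_per_1000, perforation_per_1000, mortality_per_1000)
  if (any(r < 0) || any(r > 1000)) stop_config("complication rates must lie in [0, 1000]")
  structure(
    list(major_bleed_per_1000 = major_bleed_per_1000,
         perforation_per_1000 = perforation_per_1000,
         mortality_per_1000 = mortality_per_1000),
    class = "lrasim_complications")
}

#' Unit-cost configuration (2021 CAD, undiscounted)
#'
#' All unit costs are in 2021 Canadian dollars and no discounting is applied
#' anywhere in the model. `cancer_mgmt_annual` is a synthetic stand-in for
#' per-person annual cancer-management cost (the three-group cost report needs
#' one; its absolute level is not reproducible from published unit costs).
#'
#' @param fit_kit FIT kit cost and processing, per screen.
#' @param fit_extra_visit Physician extra visit to discuss FIT results, per
#'   screen.
#' @param positive_consult Consultation fee for a positive test (attached to
#'   the resulting colonoscopy, screening cost group).
#' @param diagnostic_colonoscopy,operative_colonoscopy Colonoscopy unit costs
#'   without/with polypectomy.
#' @param bleed_cost,perforation_cost Cost per complication event.
#' @param recruitment_cost Physician recruitment to screening, per screen
#'   (default 0).
#' @param cancer_mgmt_annual Annual cancer-management cost per person-year in
#'   the management window (synthetic stand-in).
#' @return An object of class `lrasim_costs`.
#' @export
cost_config <- function(fit_kit = 26.13,
                        fit_extra_visit = 38.03,
                        positive_consult = 146.03,
                        diagnostic_colonoscopy = 866.43,
                        operative_colonoscopy = 1036.43,
                        bleed_cost = 3864.74,
                        perforation_cost = 37779.83,
                        recruitment_cost = 0,
                        cancer_mgmt_annual = 12000) {
  v <- c(fit_kit, fit_extra_visit, positive_consult, diagnostic_colonoscopy,
         operative_colonoscopy, bleed_cost, perforation_cost, recruitment_cost,
         cancer_mgmt_annual)
  if (any(v < 0)) stop_config("all unit costs must be non-negative")
  structure(
    list(fit_kit = fit_kit, fit_extra_visit = fit_extra_visit,
         positive_consult = positive_consult,
         diagnostic_colonoscopy = diagnostic_colonoscopy,
         operative_colonoscopy = operative_colonoscopy,
         bleed_cost = bleed_cost, perforation_cost = perforation_cost,
         recruitment_cost = recruitment_cost,
         cancer_mgmt_annual = cancer_mgmt_annual),
    class = "lrasim_costs")
}

#' Unit-cost presets for sensitivity analysis
#'
#' `"base"` uses the published fee-schedule values. `"low_colonoscopy_cost"`
#' and `"high_colonoscopy_cost"` are user-editable overlays that move the two
#' colonoscopy unit costs down or up for one-way sensitivity analysis.
#'
#' @param name One of `"base"`, `"low_colonoscopy_cost"`, `"high_colonoscopy_cost"`.
#' @return A [cost_config()] object.
#' @export
cost_preset <- function(name = c("base", "low_colonoscopy_cost", "high_colonoscopy_cost")) {
  name <- match.arg(name)
  switch(name,
    base = cost_config(),
    low_colonoscopy_cost = cost_config(diagnostic_colonoscopy = 650,
                                       operative_colonoscopy = 800),
    high_colonoscopy_cost = cost_config(diagnostic_colonoscopy = 1300,
                                        operative_colonoscopy = 1550))
}

#' Bundle all model configuration for a simulation run
#'
#' @param demography A [demography_config()].
#' @param natural_history A [natural_history_config()].
#' @param fit A [fit_config()] (see [fit_preset()]).
#' @param complications A [complication_config()].
#' @param costs A [cost_config()].
#' @param frequency_mix Named fractions `c(annual = , biennial = )` of
#'   participants screening every 1 vs 2 years; must sum to 1. Default 50/50.
#' @param screening_colonoscopy_rate Annual probability that an eligible
#'   person receives a primary screening colonoscopy without FIT (e.g. for
#'   significant family history). Default 0.0135 reproduces the reported
#'   volume of that category at full scale.
#' @param colonoscopy_sensitivity Length-3 per-size-class probability that an
#'   adenoma present is detected (and removed) at colonoscopy.
#' @param cancer_detection_sensitivity Probability a preclinical cancer is
#'   detected at colonoscopy.
#' @return An object of class `lrasim_config`.
#' @export
sim_config <- function(demography = demography_config(),
                       natural_history = natural_history_config(),
                       fit = fit_preset("fit75"),
                       complications = complication_config(),
                       costs = cost_config(),
                       frequency_mix = c(annual = 0.5, biennial = 0.5),
                       screening_colonoscopy_rate = 0.0135,
                       colonoscopy_sensitivity = c(0.85, 0.95, 1.0),
                       cancer_detection_sensitivity = 1.0) {
  if (!identical(sort(names(frequency_mix)), c("annual", "biennial")))
    stop_config("frequency_mix must be named c(annual=, biennial=)")
  if (abs(sum(frequency_mix) - 1) > 1e-9)
    stop_config("frequency_mix fractions must sum to 1")
  if (any(frequency_mix < 0)) stop_config("frequency_mix fractions must be non-negative")
  if (screening_colonoscopy_rate < 0 || screening_colonoscopy_rate > 1)
    stop_config("screening_colonoscopy_rate must lie in [0, 1]")
  if (length(colonoscopy_sensitivity) != 3 ||
      any(colonoscopy_sensitivity < 0 | colonoscopy_sensitivity > 1))
    stop_config("colonoscopy_sensitivity must be length-3 probabilities")
  if (cancer_detection_sensitivity < 0 || cancer_detection_sensitivity > 1)
    stop_config("cancer_detection_sensitivity must lie in [0, 1]")
  stopifnot(inherits(demography, "lrasim_demography"),
            inherits(natural_history, "lrasim_natural_history"),
            inherits(fit, "lrasim_fit"),
            inherits(complications, "lrasim_complications"),
            inherits(costs, "lrasim_costs"))
  structure(
    list(demography = demography, natural_history = natural_history, fit = fit,
         complications = complications, costs = costs,
         frequency_mix = frequency_mix[c("annual", "biennial")],
         screening_colonoscopy_rate = screening_colonoscopy_rate,
         colonoscopy_sensitivity = colonoscopy_sensitivity,
         cancer_detection_sensitivity = cancer_detection_sensitivity),
    class = "lrasim_config")
}

#' Read a simulation configuration from a YAML or JSON file
#'
#' The file may specify any subset of the constructor arguments of the
#' component configs under top-level keys `demography`, `natural_history`,
#' `fit`, `complications`, `costs`, plus the scalar [sim_config()] arguments;
#' missing entries take package defaults. `fit` and `costs` may alternatively
#' be a preset name string (e.g. `fit: fit100`).
#'
#' @param path Path to a `.yaml`/`.yml` (or JSON, which YAML parses) file.
#' @return An object of class `lrasim_config`.
#' @export
#' @examples
#' cfg <- read_sim_config(system.file("extdata", "example-config.yaml",
#'                                    package = "lrasim"))
#' cfg$fit$threshold_label
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  build <- function(entry, constructor, preset_fun = NULL) {
    if (is.null(entry)) return(constructor())
    if (is.character(entry) && length(entry) == 1 && !is.null(preset_fun))
      return(preset_fun(entry))
    args <- lapply(entry, function(x) if (is.list(x)) unlist(x) else x)
    do.call(constructor, args)
  }
  top <- raw[setdiff(names(raw),
                     c("demography", "natural_history", "fit", "complications", "costs"))]
  top <- lapply(top, function(x) if (is.list(x)) unlist(x) else x)
  do.call(sim_config, c(
    list(demography = build(raw$demography, demography_config),
         natural_history = build(raw$natural_history, natural_history_config),
         fit = build(raw$fit, fit_config, fit_preset),
         complications = build(raw$complications, complication_config),
         costs = build(raw$costs, cost_config, cost_preset)),
    top))
}
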