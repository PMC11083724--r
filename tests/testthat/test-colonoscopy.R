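test_that("findings classification implements the low-risk / high-risk rules", {
  expect_identical(as.character(classify_findings(adenoma(character(0)))), "normal")
  expect_identical(as.character(classify_findings(adenoma(c("0-5", "6-9")))),
                   "lra_1_2")  # two tubular sub-10 mm, no dysplasia
  expect_identical(as.character(classify_findings(adenoma(rep("0-5", 3)))),
                   "high_risk")  # more than 2 LRAs
  expect_identical(as.character(classify_findings(adenoma("0-5", villous = TRUE))),
                   "high_risk")  # any villous adenoma
  expect_identical(as.character(classify_findings(adenoma(">=10"))),
                   "high_risk")  # any tubular >= 10 mm
  expect_identical(as.character(classify_findings(adenoma("6-9", dysplasia = TRUE))),
                   "high_risk")  # dysplastic sub-10 mm adenoma is not low risk
  expect_identical(as.character(classify_findings(adenoma("0-5"), cancer_found = TRUE)),
                   "cancer")     # cancer overrides everything
})

test_that("follow-up scheduling honours strategy, intervals and the policy gate", {
  sq <- strategy_preset("status_quo")
  rf <- strategy_preset("return_to_fit")

  s <- schedule_followup("lra_1_2", 2024, rf)
  expect_identical(s$modality, "fit")
  expect_identical(s$due_year, 2029L)

  s <- schedule_followup("lra_1_2", 2022, rf)  # index before policy start
  expect_identical(s$modality, "colonoscopy")
  expect_identical(s$due_year, 2027L)

  s <- schedule_followup("lra_1_2", 2024, sq)
  expect_identical(s$modality, "colonoscopy")
  expect_identical(s$due_year, 2029L)

  s <- schedule_followup("normal", 2025, sq)
  expect_identical(s$modality, "fit")
  expect_identical(s$due_year, 2035L)

  s <- schedule_followup("high_risk", 2024, rf)
  expect_identical(s$modality, "colonoscopy")
  expect_identical(s$due_year, 2027L)
  expect_identical(s$phase, "first_3y")

  # normal result at the 3-year high-risk check: second colonoscopy 5y after
  s <- schedule_followup("normal", 2027, rf, prior_phase = "first_3y")
  expect_identical(s$modality, "colonoscopy")
  expect_identical(s$due_year, 2032L)
  expect_identical(s$phase, "second_5y")

  s <- schedule_followup("cancer", 2024, sq)
  expect_identical(s$modality, "colonoscopy")
  expect_identical(s$due_year, 2025L)

  expect_error(schedule_followup("bogus", 2024, sq), class = "lrasim_logic_error")
})

test_that("colonoscopy removes detected adenomas and classifies findings", {
  coh <- tiny_cohort(3, seed = 30)
  res <- perform_colonoscopy(coh, 1, 2023, "after_positive_fit",
                             detection_sensitivity = c(1, 1, 1))
  expect_identical(res$records$findings, "normal")
  expect_identical(res$records$n_removed, 0L)
  expect_false(res$records$operative)

  coh <- give_adenomas(coh, 2, c(2L, 2L))  # two tubular 6 mm adenomas
  res <- perform_colonoscopy(coh, 2, 2023, "after_positive_fit",
                             detection_sensitivity = c(1, 1, 1))
  expect_identical(res$records$findings, "lra_1_2")
  expect_identical(res$records$n_removed, 2L)
  expect_true(res$records$operative)
  expect_length(res$cohort$adenoma$pid, 0)  # removed from the person

  expect_error(perform_colonoscopy(coh, 1, 2023, "nonsense"),
               class = "lrasim_logic_error")
})

test_that("detected preclinical cancer becomes clinical with the right provenance", {
  coh <- tiny_cohort(2, seed = 31)
  coh <- give_preclinical(coh, 1)
  res <- perform_colonoscopy(coh, 1, 2024, "surveillance_after_adenoma",
                             cancer_sens = 1)
  expect_identical(res$records$findings, "cancer")
  expect_identical(res$cohort$cancer_phase[1], 2L)
  expect_identical(res$cohort$cancer_dx_year[1], 2024L)
  expect_identical(res$cohort$cancer_detected_by[1], "surveillance")
  expect_identical(res$cohort$cancer_surv_left[1], 5L)
})

test_that("complication incidence recovers the configured per-procedure rates", {
  n <- 100000
  coh <- tiny_cohort(n, seed = 32)
  set.seed(33)
  res <- perform_colonoscopy(coh, seq_len(n), 2023, "after_positive_fit")
  perf_rate <- mean(res$records$perforation)
  bleed_rate <- mean(res$records$major_bleed)
  expect_lt(abs(perf_rate - 0.0017), binom99(0.0017, n))
  expect_lt(abs(bleed_rate - 0.0003), binom99(0.0003, n))
})

test_that("under the status quo no routine FIT precedes the 5-year surveillance colonoscopy", {
  cfg <- small_sim_config(4000)
  coh <- build_cohort(cfg$demography, 2015, seed = 34, record_history = TRUE)
  coh <- assign_screening_profiles(coh, cfg$fit, cfg$frequency_mix)
  res <- run_strategy(coh, strategy_preset("status_quo"), cfg, 2015:2030, seed = 35)
  h <- cohort_history(res$cohort)
  lra <- h[h$event == "colonoscopy" & endsWith(h$detail, ":lra_1_2"), ]
  expect_gt(nrow(lra), 0)
  fits <- h[h$event == "fit", ]
  for (k in seq_len(nrow(lra))) {
    gap <- fits$pid == lra$pid[k] &
      fits$year > lra$year[k] & fits$year < lra$year[k] + 5
    expect_identical(sum(gap), 0L)
  }
})

test_that("the five reporting categories partition all colonoscopies", {
  cfg <- small_sim_config(3000)
  coh <- build_cohort(cfg$demography, 2018, seed = 36)
  coh <- assign_screening_profiles(coh, cfg$fit, cfg$frequency_mix)
  res <- run_strategy(coh, strategy_preset("return_to_fit"), cfg, 2018:2030, seed = 37)
  an <- res$annual
  cats <- an$colo_screening_no_fit + an$colo_after_positive_fit +
    an$colo_symptomatic_diagnostic + an$colo_surveillance_after_adenoma +
    an$colo_surveillance_after_cancer
  expect_equal(cats, an$colo_total)
})
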