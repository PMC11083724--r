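test_that("build_cohort returns the scaled person count with ages in 50-74", {
  coh <- build_cohort(demography_config(total_eligible_population = 100000,
                                        scale_factor = 0.5),
                      2023, seed = 11)
  expect_length(coh$id, 50000)
  ages <- person_age(coh, 2023)
  expect_true(all(ages >= 50 & ages <= 74))

  full <- build_cohort(demography_config(), 2023, seed = 1)
  expect_length(full$id, 1190189)
  rm(full)
})

test_that("cohort construction is deterministic under a fixed seed", {
  a <- build_cohort(demography_config(total_eligible_population = 5000), 2023, seed = 7)
  b <- build_cohort(demography_config(total_eligible_population = 5000), 2023, seed = 7)
  expect_identical(a$birth_year, b$birth_year)
  c <- build_cohort(demography_config(total_eligible_population = 5000), 2023, seed = 8)
  expect_false(identical(a$birth_year, c$birth_year))
})

test_that("degenerate demography configurations are rejected", {
  expect_error(demography_config(scale_factor = 0), class = "lrasim_config_error")
  expect_error(demography_config(total_eligible_population = 0),
               class = "lrasim_config_error")
  bad_w <- default_age_distribution() * 2
  expect_error(demography_config(age_distribution = bad_w),
               class = "lrasim_config_error")
  expect_error(build_cohort(demography_config(), 2000, seed = 1),
               class = "lrasim_config_error")
})

test_that("sampled age structure matches the configured weights", {
  w <- stats::setNames(rep(1 / 25, 25), 50:74)
  coh <- build_cohort(demography_config(total_eligible_population = 50000,
                                        age_distribution = w),
                      2023, seed = 3)
  tab <- table(factor(person_age(coh, 2023), levels = 50:74))
  p <- stats::chisq.test(tab, p = w)$p.value
  expect_gt(p, 0.01)
})

test_that("annual mortality honours the configured table at the extremes", {
  coh <- tiny_cohort(500, seed = 2)
  none <- advance_year(coh, 2023, stats::setNames(rep(0, 61), 50:110))
  expect_true(all(none$alive))
  all_die <- advance_year(coh, 2023, stats::setNames(rep(1, 61), 50:110))
  expect_false(any(all_die$alive))
  expect_true(all(all_die$death_cause == "other"))
  expect_true(all(all_die$death_year == 2023))
  # a dead person accrues nothing further
  again <- advance_year(all_die, 2024, stats::setNames(rep(1, 61), 50:110))
  expect_identical(again$death_year, all_die$death_year)
})

test_that("death fraction recovers the configured annual probability", {
  coh <- tiny_cohort(100000, seed = 5)
  set.seed(99)
  out <- advance_year(coh, 2023, stats::setNames(rep(0.02, 61), 50:110))
  frac <- mean(!out$alive)
  expect_lt(abs(frac - 0.02), binom99(0.02, 100000))
})

test_that("ages beyond the mortality table force death", {
  coh <- tiny_cohort(10, seed = 1)
  coh$birth_year[] <- 2023L - 111L  # age 111, past the table
  out <- advance_year(coh, 2023)
  expect_false(any(out$alive))
})

test_that("population is conserved and runs are seed-reproducible", {
  cfg <- small_sim_config(2000)
  coh <- build_cohort(cfg$demography, 2015, seed = 21)
  coh <- assign_screening_profiles(coh, cfg$fit, cfg$frequency_mix)
  run1 <- run_strategy(coh, strategy_preset("status_quo"), cfg, 2015:2026, seed = 31)
  run2 <- run_strategy(coh, strategy_preset("status_quo"), cfg, 2015:2026, seed = 31)
  expect_identical(run1$annual, run2$annual)

  fin <- run1$cohort
  expect_identical(sum(fin$alive) + sum(!fin$alive), length(fin$id))
  n_entrants <- round(cfg$demography$entry_rate * coh$initial_size)
  expect_identical(length(fin$id),
                   coh$initial_size + as.integer(n_entrants * 11))
  deaths <- sum(run1$annual$crc_deaths + run1$annual$deaths_other)
  expect_identical(sum(!fin$alive), as.integer(deaths))
})

test_that("event counts scale approximately linearly with cohort size", {
  run_at <- function(n, seed) {
    cfg <- small_sim_config(n)
    coh <- build_cohort(cfg$demography, 2020, seed = seed)
    coh <- assign_screening_profiles(coh, cfg$fit, cfg$frequency_mix)
    res <- run_strategy(coh, strategy_preset("status_quo"), cfg, 2020:2029,
                        seed = seed + 1)
    mean(res$annual$fit_screens)
  }
  small <- run_at(4000, 41)
  large <- run_at(16000, 42)
  expect_lt(abs(large / small - 4), 4 * 0.15)
})

test_that("cohort snapshots expose id, age, vitality, lesions and cancer state", {
  coh <- tiny_cohort(50, seed = 4)
  coh <- give_adenomas(coh, 1, c(1L, 3L))
  coh <- give_preclinical(coh, 2)
  df <- as.data.frame(coh, year = 2023)
  expect_named(df, c("id", "age", "alive", "n_adenomas", "cancer_status"))
  expect_identical(df$n_adenomas[1], 2L)
  expect_identical(df$cancer_status[2], "preclinical")
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_cohort_snapshot(coh, path)
  expect_identical(nrow(utils::read.csv(path)), 50L)
})
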