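colo_event <- function(year, category, operative = FALSE, bleed = FALSE,
                       perf = FALSE) {
  data.frame(year = year, type = "colonoscopy", category = category,
             operative = operative, major_bleed = bleed, perforation = perf)
}
fit_event <- function(year) {
  data.frame(year = year, type = "fit", category = NA, operative = NA,
             major_bleed = NA, perforation = NA)
}
mgmt_event <- function(year) {
  data.frame(year = year, type = "cancer_mgmt_year", category = NA,
             operative = NA, major_bleed = NA, perforation = NA)
}

test_that("per-event unit costs follow the fee schedule", {
  expect_equal(cost_of_fit(cost_config()), 64.16)          # 26.13 + 38.03
  expect_equal(cost_of_fit(cost_config(fit_extra_visit = 0)), 26.13)
  expect_equal(cost_of_fit(cost_config(fit_kit = 0, fit_extra_visit = 0)), 0)

  rec <- colo_event(2023, "surveillance_after_adenoma")
  expect_equal(cost_of_colonoscopy(rec, cost_config()), 866.43)
  rec2 <- colo_event(2023, "surveillance_after_adenoma", operative = TRUE,
                     perf = TRUE)
  expect_equal(cost_of_colonoscopy(rec2, cost_config()), 38816.26)
  zero <- cost_config(fit_kit = 0, fit_extra_visit = 0, positive_consult = 0,
                      diagnostic_colonoscopy = 0, operative_colonoscopy = 0,
                      bleed_cost = 0, perforation_cost = 0,
                      cancer_mgmt_annual = 0)
  expect_equal(cost_of_colonoscopy(rec2, zero), 0)
  # the positive-test consultation applies only after a positive FIT
  rec3 <- colo_event(2023, "after_positive_fit")
  expect_equal(cost_of_colonoscopy(rec3, cost_config()), 866.43 + 146.03)
})

test_that("annual ledgers assign events to the three reporting groups", {
  expect_equal(sum(aggregate_annual_costs(fit_event(2023)[0, ])$total), 0)

  ev <- rbind(fit_event(2023), colo_event(2023, "after_positive_fit"))
  led <- aggregate_annual_costs(ev, cost_config())
  expect_equal(led$screening, 64.16 + 146.03 + 866.43)  # 1076.62
  expect_equal(led$clinical_diagnosis, 0)
  expect_equal(led$cancer_management, 0)

  ev2 <- rbind(colo_event(2024, "symptomatic_diagnostic"),
               colo_event(2024, "surveillance_after_adenoma", operative = TRUE),
               colo_event(2024, "surveillance_after_cancer"),
               mgmt_event(2024))
  led2 <- aggregate_annual_costs(ev2, cost_config())
  expect_equal(led2$clinical_diagnosis, 866.43 + 1036.43)
  expect_equal(led2$cancer_management, 866.43 + 12000)
  expect_equal(led2$total,
               led2$screening + led2$clinical_diagnosis + led2$cancer_management)

  bad <- colo_event(2024, "unknown_category")
  expect_error(aggregate_annual_costs(bad), class = "lrasim_logic_error")
})

random_events <- function(n, seed) {
  set.seed(seed)
  type <- sample(c("fit", "colonoscopy", "cancer_mgmt_year"), n, replace = TRUE)
  data.frame(
    year = sample(2023:2027, n, replace = TRUE), type = type,
    category = ifelse(type == "colonoscopy",
                      sample(c("screening_no_fit", "after_positive_fit",
                               "symptomatic_diagnostic",
                               "surveillance_after_adenoma",
                               "surveillance_after_cancer"), n, replace = TRUE),
                      NA),
    operative = sample(c(TRUE, FALSE), n, replace = TRUE),
    major_bleed = stats::runif(n) < 0.05,
    perforation = stats::runif(n) < 0.05)
}

test_that("ledger totals equal brute-force per-event summation", {
  ev <- random_events(500, seed = 44)
  cfg <- cost_config()
  led <- aggregate_annual_costs(ev, cfg)
  # independent oracle: cost every event on its own and sum by group
  group_of <- c(screening_no_fit = "screening", after_positive_fit = "screening",
                symptomatic_diagnostic = "clinical_diagnosis",
                surveillance_after_adenoma = "clinical_diagnosis",
                surveillance_after_cancer = "cancer_management")
  per_event <- numeric(nrow(ev)); grp <- character(nrow(ev))
  for (i in seq_len(nrow(ev))) {
    if (ev$type[i] == "fit") {
      per_event[i] <- cost_of_fit(cfg); grp[i] <- "screening"
    } else if (ev$type[i] == "cancer_mgmt_year") {
      per_event[i] <- cfg$cancer_mgmt_annual; grp[i] <- "cancer_management"
    } else {
      per_event[i] <- cost_of_colonoscopy(ev[i, ], cfg)
      grp[i] <- group_of[[ev$category[i]]]
    }
  }
  for (y in sort(unique(ev$year))) {
    row <- led[led$year == y, ]
    for (g in c("screening", "clinical_diagnosis", "cancer_management")) {
      expect_equal(row[[g]], sum(per_event[ev$year == y & grp == g]))
    }
  }
  expect_equal(led$total,
               led$screening + led$clinical_diagnosis + led$cancer_management)
})

test_that("ledgers are additive over disjoint event sets", {
  ev <- random_events(400, seed = 45)
  split_at <- seq_len(200)
  a <- aggregate_annual_costs(ev[split_at, ])
  b <- aggregate_annual_costs(ev[-split_at, ])
  whole <- aggregate_annual_costs(ev)
  for (y in whole$year) {
    ga <- a[a$year == y, -1]; gb <- b[b$year == y, -1]
    if (nrow(ga) == 0) ga[1, ] <- 0
    if (nrow(gb) == 0) gb[1, ] <- 0
    expect_equal(unlist(whole[whole$year == y, -1]), unlist(ga + gb))
  }
})

test_that("zero unit costs give a zero ledger and raising any cost never lowers a group", {
  ev <- random_events(300, seed = 46)
  zero <- cost_config(fit_kit = 0, fit_extra_visit = 0, positive_consult = 0,
                      diagnostic_colonoscopy = 0, operative_colonoscopy = 0,
                      bleed_cost = 0, perforation_cost = 0,
                      cancer_mgmt_annual = 0)
  expect_equal(sum(aggregate_annual_costs(ev, zero)$total), 0)

  base <- aggregate_annual_costs(ev, cost_config())
  fields <- c("fit_kit", "fit_extra_visit", "positive_consult",
              "diagnostic_colonoscopy", "operative_colonoscopy", "bleed_cost",
              "perforation_cost", "cancer_mgmt_annual")
  for (f in fields) {
    args <- stats::setNames(list(cost_config()[[f]] + 500), f)
    up <- aggregate_annual_costs(ev, do.call(cost_config, args))
    for (g in c("screening", "clinical_diagnosis", "cancer_management", "total"))
      expect_true(all(up[[g]] >= base[[g]] - 1e-9))
  }
})
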