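# Paired strategy experiments: replicate runs, incremental outcomes,
# t-based Monte Carlo confidence intervals, and report tables.

OUTCOME_COLS <- c("fit_screens", paste0("colo_", COLO_CATEGORIES), "colo_total",
                  "major_bleeds", "perforations", "crc_cases", "crc_deaths",
                  "cost_screening", "cost_clinical_diagnosis",
                  "cost_cancer_management", "cost_total")

#' Two-sided 95% t-interval for replicate mean differences
#'
#' Computes `mean(x) +/- t(0.975, n - 1) * sd(x) / sqrt(n)` over the
#' per-replicate incremental outcomes. A zero-variance input yields the
#' degenerate interval `(mean, mean)`.
#'
#' @param diffs Numeric vector of per-replicate differences, length >= 2.
#' @return Named numeric vector `c(mean, ci_low, ci_high)`.
#' @export
#' @examples
#' incremental_ci(1:12)
incremental_ci <- function(diffs) {
  n <- length(diffs)
  if (n < 2) stop_logic("at least 2 replicates are required for a confidence interval")
  m <- mean(diffs)
  s <- stats::sd(diffs)
  if (s == 0) return(c(mean = m, ci_low = m, ci_high = m))
  half <- stats::qt(0.975, df = n - 1) * s / sqrt(n)
  c(mean = m, ci_low = m - half, ci_high = m + half)
}

#' Derived complication increments from a colonoscopy increment
#'
#' Incremental major bleeds and perforations are obtained by multiplying the
#' incremental number of colonoscopies by the per-colonoscopy incidence
#' rates, reported both raw and rounded to the nearest integer for display.
#'
#' @param colonoscopy_diff Incremental annual colonoscopy count (new minus
#'   status quo).
#' @param rates A [complication_config()].
#' @return A list with `major_bleed`, `perforation` (raw) and
#'   `major_bleed_rounded`, `perforation_rounded`.
#' @export
#' @examples
#' complication_increment(-3892)  # -1.17 -> -1 bleeds, -6.62 -> -7 perforations
complication_increment <- function(colonoscopy_diff, rates = complication_config()) {
  b <- colonoscopy_diff * rates$major_bleed_per_1000 / 1000
  p <- colonoscopy_diff * rates$perforation_per_1000 / 1000
  list(major_bleed = b, perforation = p,
       major_bleed_rounded = round(b), perforation_rounded = round(p))
}

#' Percent change of an increment relative to the status quo
#'
#' @param diff Incremental value (new minus status quo).
#' @param baseline Status-quo value.
#' @return `diff / baseline * 100` (unrounded; reports display one decimal).
#' @export
percent_change <- function(diff, baseline) {
  ifelse(baseline == 0, ifelse(diff == 0, 0, NA_real_), diff / baseline * 100)
}

#' Run paired replicate simulations of the two strategies
#'
#' For each replicate, a fresh synthetic cohort is built and both strategies
#' are run on it over a burn-in period plus the reporting horizon. Under
#' common random numbers (the default) the two arms of a replicate share one
#' random stream, so outcome differences before the strategies behaviourally
#' diverge are exactly zero; with `common_random_numbers = FALSE` each arm
#' uses an independent stream. Outcomes are averaged over the horizon years
#' per run.
#'
#' @param config A [sim_config()].
#' @param n_replicates Number of replicate pairs (>= 2; default 12).
#' @param seed Integer master seed; all replicate and arm seeds derive from
#'   it, so a fixed seed reproduces the experiment bitwise.
#' @param strategies Named list of two [strategy_config()]s,
#'   `status_quo` and `new`.
#' @param burnin_start First simulated year (screening program history;
#'   default 2008).
#' @param horizon Reporting years (default 2023:2042).
#' @param common_random_numbers Share one stream per replicate pair.
#' @return An object of class `lrasim_replicates`: a list with `per_run`
#'   (average-annual outcomes per replicate and strategy), `annual`
#'   (full per-year outcome rows over the horizon for every run), `horizon`,
#'   `n_replicates`, and the configs used.
#' @export
run_replicates <- function(config,
                           n_replicates = 12,
                           seed = 1,
                           strategies = list(status_quo = strategy_preset("status_quo"),
                                             new = strategy_preset("return_to_fit")),
                           burnin_start = 2008,
                           horizon = 2023:2042,
                           common_random_numbers = TRUE) {
  if (n_replicates < 2)
    stop_config("n_replicates must be >= 2 to form confidence intervals")
  if (!identical(names(strategies), c("status_quo", "new")))
    stop_config("strategies must be a named list: status_quo, new")
  years <- seq(as.integer(burnin_start), max(horizon))
  set.seed(seed)
  build_seeds <- sample.int(.Machine$integer.max - 1L, n_replicates)
  arm_seeds <- matrix(sample.int(.Machine$integer.max - 1L, 2 * n_replicates),
                      nrow = n_replicates)
  per_run <- list(); annual <- list()
  for (r in seq_len(n_replicates)) {
    cohort0 <- build_cohort(config$demography, burnin_start,
                            seed = build_seeds[r])
    cohort0 <- assign_screening_profiles(cohort0, config$fit,
                                         config$frequency_mix)
    for (arm in c("status_quo", "new")) {
      arm_seed <- if (common_random_numbers) arm_seeds[r, 1]
                  else arm_seeds[r, if (arm == "status_quo") 1 else 2]
      res <- run_strategy(cohort0, strategies[[arm]], config, years,
                          seed = arm_seed)
      hz <- res$annual[res$annual$year %in% horizon, , drop = FALSE]
      per_run[[length(per_run) + 1L]] <- cbind(
        data.frame(replicate = r, strategy = arm),
        as.data.frame(t(colMeans(hz[, OUTCOME_COLS]))))
      annual[[length(annual) + 1L]] <- cbind(
        data.frame(replicate = r, strategy = arm), hz)
    }
  }
  structure(
    list(per_run = do.call(rbind, per_run),
         annual = do.call(rbind, annual),
         horizon = horizon, n_replicates = n_replicates,
         config = config, strategies = strategies,
         common_random_numbers = common_random_numbers, seed = seed),
    class = "lrasim_replicates")
}

#' Incremental outcome report with Monte Carlo confidence intervals
#'
#' For every outcome, pairs the two arms of each replicate, computes the mean
#' difference (new minus status quo) of the average-annual values, a
#' two-sided 95% t-interval over the replicate differences, and the percent
#' change relative to the status-quo mean. Derived complication increments
#' (incremental colonoscopies times the per-colonoscopy incidence rates) are
#' attached alongside.
#'
#' @param reps A `lrasim_replicates` object from [run_replicates()].
#' @param rates A [complication_config()] for the derived complication
#'   increments (defaults to the configuration the replicates were run with).
#' @return An object of class `lrasim_report`: a list with `outcomes` (a
#'   data.frame with columns `outcome`, `status_quo`, `new`, `diff`,
#'   `ci_low`, `ci_high`, `pct_change`) and `derived_complications`.
#' @export
incremental_report <- function(reps, rates = reps$config$complications) {
  stopifnot(inherits(reps, "lrasim_replicates"))
  pr <- reps$per_run
  sq <- pr[pr$strategy == "status_quo", ]
  nw <- pr[pr$strategy == "new", ]
  sq <- sq[order(sq$replicate), ]; nw <- nw[order(nw$replicate), ]
  rows <- lapply(OUTCOME_COLS, function(col) {
    d <- nw[[col]] - sq[[col]]
    ci <- incremental_ci(d)
    data.frame(outcome = col, status_quo = mean(sq[[col]]), new = mean(nw[[col]]),
               diff = ci[["mean"]], ci_low = ci[["ci_low"]],
               ci_high = ci[["ci_high"]],
               pct_change = percent_change(ci[["mean"]], mean(sq[[col]])))
  })
  outcomes <- do.call(rbind, rows)
  colo_diff <- outcomes$diff[outcomes$outcome == "colo_total"]
  structure(
    list(outcomes = outcomes,
         derived_complications = complication_increment(colo_diff, rates)),
    class = "lrasim_report")
}

#' @export
print.lrasim_report <- function(x, ...) {
  df <- x$outcomes
  df[, -1] <- lapply(df[, -1], function(v) round(v, 2))
  print(df, row.names = FALSE)
  dc <- x$derived_complications
  cat(sprintf("derived increments: major bleeds %.2f (%d), perforations %.2f (%d)\n",
              dc$major_bleed, dc$major_bleed_rounded,
              dc$perforation, dc$perforation_rounded))
  invisible(x)
}

report_row <- function(outcomes, col, label) {
  r <- outcomes[outcomes$outcome == col, ]
  data.frame(row = label, status_quo = r$status_quo, new = r$new,
             difference = r$diff, pct_change = round(r$pct_change, 1))
}

#' Write the report tables to CSV
#'
#' Emits four files into `dir`: `outcomes.csv` (CRC cases and deaths with
#' 95% confidence intervals, plus derived complication increments),
#' `volumes.csv` (FIT screens and the five colonoscopy categories with the
#' total), `costs.csv` (the three cost groups and the two totals), and
#' `timeseries.csv` (per-year mean incremental colonoscopies and costs across
#' replicates, supporting the check that savings begin once the first
#' deferred surveillance colonoscopies fall due).
#'
#' @param report A `lrasim_report` from [incremental_report()].
#' @param reps The `lrasim_replicates` object the report came from.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the list of written data.frames.
#' @export
write_reports <- function(report, reps, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  oc <- report$outcomes
  dc <- report$derived_complications

  ci_row <- function(col, label) {
    r <- oc[oc$outcome == col, ]
    data.frame(row = label, status_quo = r$status_quo, new = r$new,
               difference = r$diff, ci_low = r$ci_low, ci_high = r$ci_high)
  }
  tab3 <- rbind(ci_row("crc_cases", "CRC cases"),
                ci_row("crc_deaths", "CRC deaths"))
  comp <- data.frame(
    row = c("Major bleed from colonoscopy", "Perforation from colonoscopy"),
    status_quo = oc$status_quo[match(c("major_bleeds", "perforations"), oc$outcome)],
    new = NA, difference = c(dc$major_bleed_rounded, dc$perforation_rounded),
    ci_low = NA, ci_high = NA)
  comp$new <- comp$status_quo + comp$difference
  tab3 <- rbind(tab3, comp)

  vol_labels <- c(
    fit_screens = "FIT screens",
    colo_screening_no_fit = "Screening colonoscopies without FIT",
    colo_after_positive_fit = "Colonoscopies after a positive FIT",
    colo_symptomatic_diagnostic = "Colonoscopies for symptomatic patients",
    colo_surveillance_after_adenoma = "Surveillance colonoscopies after adenoma detection",
    colo_surveillance_after_cancer = "Surveillance colonoscopies after cancer detection",
    colo_total = "Total number of colonoscopies")
  tab4 <- do.call(rbind, Map(report_row, list(oc), names(vol_labels), vol_labels))

  cost_labels <- c(cost_screening = "Cost of screening",
                   cost_clinical_diagnosis = "Cost of clinical diagnosis",
                   cost_cancer_management = "Cost of cancer management")
  tab5 <- do.call(rbind, Map(report_row, list(oc), names(cost_labels), cost_labels))
  sub <- oc[oc$outcome %in% c("cost_screening", "cost_clinical_diagnosis"), ]
  tot <- oc[oc$outcome == "cost_total", ]
  tab5 <- rbind(tab5,
    data.frame(row = "Total cost (screening and diagnostics)",
               status_quo = sum(sub$status_quo), new = sum(sub$new),
               difference = sum(sub$diff),
               pct_change = round(percent_change(sum(sub$diff), sum(sub$status_quo)), 1)),
    data.frame(row = "Total cost (all categories)",
               status_quo = tot$status_quo, new = tot$new, difference = tot$diff,
               pct_change = round(tot$pct_change, 1)))

  an <- reps$annual
  sq <- an[an$strategy == "status_quo", ]; nw <- an[an$strategy == "new", ]
  key <- function(d) paste(d$replicate, d$year)
  nw <- nw[match(key(sq), key(nw)), ]
  diffs <- data.frame(year = sq$year,
                      d_colo = nw$colo_total - sq$colo_total,
                      d_cost = nw$cost_total - sq$cost_total)
  ts <- do.call(rbind, lapply(split(diffs, diffs$year), function(d) {
    data.frame(year = d$year[1],
               incremental_colonoscopies = mean(d$d_colo),
               incremental_total_cost = mean(d$d_cost))
  }))

  tables <- list(outcomes = tab3, volumes = tab4, costs = tab5, timeseries = ts)
  for (nm in names(tables))
    utils::write.csv(tables[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  invisible(tables)
}
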