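# Reproduction of the published simulation tables.
#
# Each builder generates (or accepts) one calibrated cohort per age-group
# column and runs the Monte-Carlo regimen engine over the published dose /
# interval menu, returning a long-form data.frame that
# write_summary_tables() can lay out like the printed tables.

.default_group_n <- c("<6" = 12, "6-<12" = 15, "12-<18" = 5,
                      ">=12" = 86, ">=18" = 81)

#' Calibrated cohorts for each age-group column
#'
#' One single-group cohort per requested age group, each calibrated to its
#' published per-kg clearance median. `n_scale` multiplies the study-like
#' group sizes, which stabilizes table cells at the cost of runtime.
#'
#' @param groups Age-group labels (columns of the printed tables).
#' @param n_scale Multiplier on the study-like group sizes.
#' @param theta,omega Model parameters.
#' @param seed Optional integer seed (per-group seeds are derived from it).
#' @return Named list of [generate_cohort()] cohorts.
#' @export
age_group_cohorts <- function(groups = c("<6", "6-<12", "12-<18",
                                         ">=12", ">=18"),
                              n_scale = 1,
                              theta = fix_fixed_effects(),
                              omega = fix_iiv(), seed = NULL) {
  .assert(all(groups %in% .age_groups), "unknown age-group label")
  out <- lapply(seq_along(groups), function(i) {
    g <- groups[i]
    n <- stats::setNames(max(1L, round(.default_group_n[[g]] * n_scale)), g)
    generate_cohort(n, theta = theta, omega = omega,
                    seed = if (is.null(seed)) NULL else seed + i)
  })
  stats::setNames(out, groups)
}

#' Single-dose durations above activity thresholds, by age group
#'
#' Long-form version of the published single-dose table: for each dose and
#' threshold, the pooled median and 25th percentile (days, half-day grid)
#' of the time exogenous activity stays above the threshold.
#'
#' @param cohorts Named list from [age_group_cohorts()].
#' @param doses Single doses, IU/kg.
#' @param thresholds Cutoffs, IU/dL.
#' @param n_replicates Monte-Carlo replicates per scenario.
#' @param theta,omega Model parameters.
#' @param seed Optional integer seed.
#' @return data.frame with columns `dose_per_kg`, `threshold`, `group`,
#'   `median`, `p25`.
#' @export
simulate_duration_table <- function(cohorts,
                                    doses = c(25, 40, 50, 75, 100),
                                    thresholds = c(1, 3, 5),
                                    n_replicates = 1000,
                                    theta = fix_fixed_effects(),
                                    omega = fix_iiv(), seed = NULL) {
  rows <- list()
  for (d in doses) {
    reg <- fix_regimen(d, mode = "single")
    for (g in names(cohorts)) {
      s <- summarize_regimen(cohorts[[g]], reg, n_replicates, thresholds,
                             theta, omega, seed = seed)
      rows[[length(rows) + 1L]] <- data.frame(
        dose_per_kg = d, threshold = thresholds, group = g,
        median = s$duration_days[, "median"], p25 = s$duration_days[, "p25"])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# the published steady-state regimen menu (dose IU/kg, interval days)
.steady_menu <- data.frame(
  dose_per_kg = c(25, 40, 50, 50, 50, 75, 75, 100),
  interval_days = c(7, 7, 7, 10, 14, 14, 21, 21))

#' Steady-state trough activity, by age group
#'
#' Pooled median and 90% prediction interval of the trough exogenous
#' activity for the published regimen menu.
#'
#' @inheritParams simulate_duration_table
#' @param regimens data.frame with columns `dose_per_kg`, `interval_days`.
#' @return data.frame with columns `dose_per_kg`, `interval_days`, `group`,
#'   `median`, `lo`, `hi`.
#' @export
simulate_trough_table <- function(cohorts, regimens = .steady_menu,
                                  n_replicates = 1000,
                                  theta = fix_fixed_effects(),
                                  omega = fix_iiv(), seed = NULL) {
  rows <- list()
  for (i in seq_len(nrow(regimens))) {
    reg <- fix_regimen(regimens$dose_per_kg[i], regimens$interval_days[i])
    for (g in names(cohorts)) {
      s <- summarize_regimen(cohorts[[g]], reg, n_replicates, theta = theta,
                             omega = omega, seed = seed)
      rows[[length(rows) + 1L]] <- data.frame(
        dose_per_kg = regimens$dose_per_kg[i],
        interval_days = regimens$interval_days[i], group = g,
        median = s$trough[["median"]], lo = s$trough[["lo"]],
        hi = s$trough[["hi"]])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Percent of simulated patients above trough cutoffs, by age group
#'
#' @inheritParams simulate_trough_table
#' @param thresholds Cutoffs, IU/dL.
#' @param percent_method Passed to [summarize_regimen()].
#' @return data.frame with columns `dose_per_kg`, `interval_days`,
#'   `threshold`, `group`, `percent`.
#' @export
simulate_percent_table <- function(cohorts, regimens = .steady_menu,
                                   thresholds = c(1, 3, 5),
                                   n_replicates = 1000,
                                   theta = fix_fixed_effects(),
                                   omega = fix_iiv(),
                                   percent_method = "pooled", seed = NULL) {
  rows <- list()
  for (i in seq_len(nrow(regimens))) {
    reg <- fix_regimen(regimens$dose_per_kg[i], regimens$interval_days[i])
    for (g in names(cohorts)) {
      s <- summarize_regimen(cohorts[[g]], reg, n_replicates, thresholds,
                             theta, omega, percent_method = percent_method,
                             seed = seed)
      rows[[length(rows) + 1L]] <- data.frame(
        dose_per_kg = regimens$dose_per_kg[i],
        interval_days = regimens$interval_days[i],
        threshold = thresholds, group = g,
        percent = unname(s$percent_above))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
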