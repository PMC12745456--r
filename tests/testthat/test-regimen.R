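# Regimen analysis: durations, troughs, cohort summaries.

theta <- fix_fixed_effects()

test_that("typical-adult weekly trough matches the accumulation closed form", {
  pk <- typical_parameters(theta, 70, 50)
  tr <- steady_trough(pk, 3500, interval_days = 7)
  expect_equal(tr, 19.1, tolerance = 5e-3)
  # independent route: trough after a 40-dose train (> 15 terminal t1/2)
  doses <- lapply(0:39, function(k) dose_event(3500, time = k * 168))
  train <- superpose(pk, doses, 40 * 168)
  expect_equal(tr, train, tolerance = 5e-3)
})

test_that("washout: trough vanishes as the interval grows", {
  pk <- typical_parameters(theta, 70, 50)
  expect_lt(steady_trough(pk, 3500, interval_days = 365), 1e-4)
})

test_that("trough is strictly increasing in dose at fixed interval", {
  pk <- typical_parameters(theta, 70, 50)
  tr <- vapply(c(25, 40, 50, 75, 100) * 70, function(amt)
    steady_trough(pk, amt, interval_days = 14), numeric(1))
  expect_true(all(diff(tr) > 0))
})

test_that("single-dose durations match the crossing of the biexponential", {
  pk <- typical_parameters(theta, 70, 100)
  exact <- duration_above(pk, 7000, thresholds = 5, grid = NULL)
  # independent check: profile is above the threshold just before the
  # crossing and below just after
  t_cross <- exact[[1]] * 24
  prof <- single_dose_profile(pk, dose_event(7000),
                              c(t_cross - 0.5, t_cross + 0.5))
  expect_gt(prof[1], 5)
  expect_lt(prof[2], 5)
  # half-day grid floors
  expect_equal(duration_above(pk, 7000, thresholds = 5)[[1]],
               floor(exact[[1]] / 0.5) * 0.5)
})

test_that("durations are ordered in threshold and monotone in dose", {
  pk50 <- typical_parameters(theta, 70, 50)
  d <- duration_above(pk50, 3500)
  expect_true(d[">1"] >= d[">3"] && d[">3"] >= d[">5"])
  per_dose <- vapply(c(25, 40, 50, 75, 100), function(dpk) {
    pk <- typical_parameters(theta, 70, dpk)
    duration_above(pk, dpk * 70, thresholds = 5, grid = NULL)[[1]]
  }, numeric(1))
  expect_true(all(diff(per_dose) > 0))
})

test_that("unreachable thresholds give zero duration", {
  pk <- typical_parameters(theta, 70, 50)
  expect_equal(duration_above(pk, 3500, thresholds = 1000)[[1]], 0)
})

test_that("a single patient with no IIV gives degenerate summaries", {
  coh <- generate_cohort(c(">=18" = 1), omega = fix_iiv(0, 0, 0), seed = 1)
  s <- summarize_regimen(coh, fix_regimen(50, 7), n_replicates = 8,
                         omega = fix_iiv(0, 0, 0), seed = 2)
  expect_equal(s$trough[["lo"]], s$trough[["median"]])
  expect_equal(s$trough[["hi"]], s$trough[["median"]])
  pk <- pk_parameters(coh$cl, coh$vc, coh$q, coh$vp)
  expect_equal(s$trough[["median"]], steady_trough(pk, 50 * coh$weight, 7))
  expect_true(all(s$percent_above %in% c(0, 100)))
})

test_that("median over IIV replicates stays near the typical value", {
  coh <- generate_cohort(c(">=18" = 300), seed = 31)
  s <- summarize_regimen(coh, fix_regimen(50, 7), n_replicates = 30,
                         seed = 32)
  w_med <- weight_for_per_kg_cl(theta, per_kg_cl_medians()[[">=18"]])
  pk <- typical_parameters(theta, w_med, 50)
  expect_equal(s$trough[["median"]], steady_trough(pk, 50 * w_med, 7),
               tolerance = 0.05)
})

test_that("summaries are reproducible under a fixed seed", {
  coh <- generate_cohort(c("12-<18" = 20), seed = 41)
  a <- summarize_regimen(coh, fix_regimen(75, 14), n_replicates = 10,
                         seed = 5)
  b <- summarize_regimen(coh, fix_regimen(75, 14), n_replicates = 10,
                         seed = 5)
  expect_identical(a[c("trough", "cmax", "auc_ss", "percent_above")],
                   b[c("trough", "cmax", "auc_ss", "percent_above")])
})

test_that("percent-above is ordered across cutoffs both ways it is counted", {
  coh <- generate_cohort(c(">=18" = 150), seed = 51)
  s <- summarize_regimen(coh, fix_regimen(50, 14), n_replicates = 40,
                         seed = 52)
  expect_true(all(diff(s$percent_above_pooled) <= 0))
  expect_true(all(diff(s$percent_above_per_patient) <= 0))
  expect_true(all(s$percent_above >= 0 & s$percent_above <= 100))
})

test_that("age groups order troughs by per-kg clearance", {
  groups <- c("<6", "6-<12", "12-<18", ">=18")
  troughs <- vapply(groups, function(g) {
    w <- weight_for_per_kg_cl(theta, per_kg_cl_medians()[[g]])
    steady_trough(typical_parameters(theta, w, 50), 50 * w, 7)
  }, numeric(1))
  expect_true(all(diff(troughs) > 0))
})

test_that("identical cohorts under one seed give identical comparisons", {
  coh <- generate_cohort(c(">=18" = 30), seed = 61)
  cmp <- ethnicity_comparison(coh, coh, fix_regimen(100, 21),
                              labels = c("Japanese", "non-Japanese"),
                              n_replicates = 10, seed = 62)
  expect_identical(cmp$table$Japanese, cmp$table$`non-Japanese`)
  expect_equal(cmp$summaries[[1]]$auc_ss[["median"]],
               cmp$summaries[[2]]$auc_ss[["median"]])
})

test_that("single-dose summaries report half-day medians and 25th percentiles", {
  coh <- generate_cohort(c("6-<12" = 40), seed = 71)
  s <- summarize_regimen(coh, fix_regimen(50, mode = "single"),
                         n_replicates = 10, seed = 72)
  expect_true(all(s$duration_days %% 0.5 == 0))
  expect_true(all(s$duration_days[, "p25"] <= s$duration_days[, "median"]))
})

test_that("regimen validation rejects bad inputs", {
  expect_error(fix_regimen(50, interval_days = -7), "invalid regimen")
  expect_error(fix_regimen(50), "interval_days")
  coh <- generate_cohort(c(">=18" = 2), seed = 1)
  expect_error(summarize_regimen(coh, fix_regimen(50, 7), n_replicates = 0),
               "config error")
})
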