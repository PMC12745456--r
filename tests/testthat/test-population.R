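# Virtual-cohort generator: log-normal IIV, calibration, residual error.

theta <- fix_fixed_effects()
omega <- fix_iiv()

test_that("zero variances return the typical values exactly", {
  ip <- sample_individual(theta, fix_iiv(0, 0, 0), weight = 70, seed = 1)
  expect_equal(ip$cl, 0.550)
  expect_equal(ip$vc, 65.7)
  expect_equal(ip$base, 0.992)
})

test_that("log-normal IIV reproduces the typical median and the CV", {
  ip <- sample_individual(theta, omega, weight = 70, n = 10000, seed = 42)
  expect_equal(median(ip$cl), 0.550, tolerance = 0.02)
  cv <- sd(ip$cl) / mean(ip$cl)
  expect_equal(cv, 0.196, tolerance = 0.05)
  # Q and Vp carry no IIV
  expect_identical(unique(ip$q), 0.208)
  expect_identical(unique(ip$vp), 19.5)
})

test_that("cohort weights are calibrated to the per-kg clearance medians", {
  for (g in c("<6", ">=18")) {
    coh <- generate_cohort(setNames(600, g), seed = 7)
    med <- median(per_kg_clearance(theta, coh$weight))
    expect_equal(med, per_kg_cl_medians()[[g]], tolerance = 0.03)
  }
})

test_that("generated baselines respect the 2 IU/dL bound", {
  coh <- generate_cohort(c("<6" = 100, ">=18" = 300), seed = 3)
  expect_true(all(coh$base <= 2))
  expect_true(all(coh$base > 0))
})

test_that("cohort generation is deterministic under a fixed seed", {
  a <- generate_cohort(c("6-<12" = 40, ">=18" = 60), seed = 99)
  b <- generate_cohort(c("6-<12" = 40, ">=18" = 60), seed = 99)
  expect_identical(a, b)
  c2 <- generate_cohort(c("6-<12" = 40, ">=18" = 60), seed = 100)
  expect_false(identical(a$weight, c2$weight))
})

test_that("group sizes and age bounds are honoured", {
  coh <- generate_cohort(c("<6" = 12, "6-<12" = 15, "12-<18" = 5,
                           ">=18" = 81), seed = 5)
  expect_equal(as.vector(table(coh$age_group)[c("<6", "6-<12", "12-<18",
                                                ">=18")]),
               c(12, 15, 5, 81))
  expect_true(all(coh$age[coh$age_group == "<6"] < 6))
  expect_true(all(coh$age[coh$age_group == ">=18"] >= 18))
})

test_that("unattainable calibration raises a config error", {
  expect_error(generate_cohort(c(">=18" = 5),
                               calibration = c(">=18" = -1), seed = 1),
               "config error")
  expect_error(generate_cohort(c("adults" = 5), seed = 1), "config error")
})

test_that("residual error has the published magnitude (natural form)", {
  obs <- add_residual_error(rep(50, 20000), group = "3001/3002/3003",
                            form = "natural", seed = 11)
  expect_equal(sd(obs), sqrt((0.371 * 50)^2 + 1.20^2), tolerance = 0.03)
  expect_equal(sd(obs), 18.6, tolerance = 0.04)
  # zero-sigma passthrough
  none <- add_residual_error(c(0, 5, 50), sigma = fix_residual(0, 0, 0, 0),
                             form = "natural", seed = 1)
  expect_equal(as.numeric(none), c(0, 5, 50))
})

test_that("log-scale residual form has variance prop^2 + (add/pred)^2", {
  obs <- add_residual_error(rep(50, 20000), form = "lognormal", seed = 12)
  expect_equal(sd(log(obs / 50)), sqrt(0.371^2 + (1.2 / 50)^2),
               tolerance = 0.03)
  expect_true(all(obs > 0))
})

test_that("natural-form draws below zero are floored and flagged", {
  obs <- add_residual_error(rep(0.5, 5000), form = "natural", seed = 13)
  fl <- attr(obs, "floored")
  expect_true(any(fl))
  expect_true(all(obs[fl] == 0))
  expect_true(all(obs >= 0))
})

test_that("noiseless datasets round-trip the model prediction", {
  coh <- generate_cohort(c(">=18" = 1), seed = 21)
  tt <- c(1, 24, 168, 336)
  ds <- simulate_dataset(coh, fix_regimen(50, mode = "single"), tt,
                         sigma = NULL)
  obs <- ds[ds$EVID == 0, ]
  pk <- pk_parameters(coh$cl, coh$vc, coh$q, coh$vp)
  fex <- single_dose_profile(pk, dose_event(50 * coh$weight), tt)
  expect_equal(obs$DV, fex + coh$base, tolerance = 1e-12)
})

test_that("dataset bookkeeping: one record per dose and per sample", {
  coh <- generate_cohort(c("6-<12" = 4, ">=18" = 3), seed = 22)
  tt <- c(1, 24, 96, 168)
  ds <- simulate_dataset(coh, fix_regimen(25, interval_days = 7), tt,
                         seed = 23)
  n_doses <- 2 # doses at 0 and 168 within the horizon
  expect_equal(nrow(ds), nrow(coh) * (n_doses + length(tt)))
  expect_true(all(ds$TIME[ds$EVID == 1] %in% c(0, 168)))
  # deterministic under the seed
  ds2 <- simulate_dataset(coh, fix_regimen(25, interval_days = 7), tt,
                          seed = 23)
  expect_identical(ds, ds2)
})

test_that("observations below 0.25 IU/dL are flagged but retained", {
  coh <- generate_cohort(c(">=18" = 1), seed = 31)
  coh$base <- 0.1; coh$screening <- 0.1
  ds <- simulate_dataset(coh, fix_regimen(50, mode = "single"),
                         sampling_times = c(0, 24), sigma = NULL)
  obs <- ds[ds$EVID == 0, ]
  expect_equal(obs$BLQ, c(1L, 0L))
  expect_equal(obs$DV[1], 0.1)
})
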