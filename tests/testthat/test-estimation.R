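# Mixed-effects estimation: objective, fit, LRT, pcVPC.

theta <- fix_fixed_effects()

# small dataset shared across objective tests
tiny_ds <- function(sigma = NULL, n = 2, seed = 91) {
  coh <- generate_cohort(setNames(n, ">=18"), seed = seed)
  simulate_dataset(coh, fix_regimen(50, mode = "single"),
                   sampling_times = c(0, 1, 24, 96, 168, 336, 504),
                   sigma = sigma, seed = seed + 1)
}

test_that("with no IIV the OFV reduces to the weighted log-scale deviance", {
  ds <- tiny_ds()
  sig <- fix_residual(0, 0.8, 0, 0.8)   # additive-only error
  ofv <- as.numeric(poppk_objective(ds, theta, fix_iiv(0, 0, 0), sig))
  # independent computation from public building blocks
  dev <- 0
  for (id in unique(ds$ID)) {
    rec <- ds[ds$ID == id, ]
    obs <- rec[rec$EVID == 0, ]
    wt <- rec$WT[1]
    pk <- typical_parameters(theta, wt, 50)
    f <- single_dose_profile(pk, dose_event(50 * wt), obs$TIME) + theta$base
    v <- (0.8 / f)^2
    r <- log(obs$DV) - log(f)
    dev <- dev + sum(r^2 / v + log(2 * pi * v))
  }
  expect_equal(ofv, dev, tolerance = 1e-8)
})

test_that("duplicating every individual doubles the OFV", {
  ds <- tiny_ds(sigma = fix_residual(), n = 3)
  dup <- ds
  dup$ID <- dup$ID + max(ds$ID)
  both <- rbind(ds, dup)
  class(both) <- class(ds)
  o1 <- as.numeric(poppk_objective(ds))
  o2 <- as.numeric(poppk_objective(both))
  expect_equal(o2, 2 * o1, tolerance = 1e-6)
})

test_that("the OFV is lower at the generating parameters than off them", {
  coh <- generate_cohort(c("<6" = 20, "6-<12" = 20, ">=18" = 160,
                           "12-<18" = 10), seed = 93)
  ds <- simulate_dataset(coh, fix_regimen(50, mode = "single"),
                         c(0, 1, 24, 96, 168, 336, 504), seed = 94)
  at_truth <- as.numeric(poppk_objective(ds))
  shifted <- fix_fixed_effects(cl = 0.550 * 1.3)
  off <- as.numeric(poppk_objective(ds, theta = shifted))
  expect_lt(at_truth, off)
})

test_that("a noiseless individual curve fit recovers CL, Vc, Q, Vp", {
  coh <- generate_cohort(c(">=18" = 1), omega = fix_iiv(0, 0, 0), seed = 95)
  tt <- c(0, 0.5, 1, 2, 4, 8, 16, 24, 48, 96, 168, 240, 336, 420, 504)
  ds <- simulate_dataset(coh, fix_regimen(50, mode = "single"), tt,
                         sigma = NULL)
  init <- list(theta = fix_fixed_effects(cl = 0.4, vc = 50, q = 0.3,
                                         vp = 30, base = 0.8),
               omega = fix_iiv(0, 0, 0),
               sigma = fix_residual(prop_3001 = 0.05, add_3001 = 0))
  fit <- poppk_fit(ds, init = init,
                   fixed = c("exp_wt_cl", "exp_wt_v", "exp_dose_vc",
                             "om2_cl", "om2_vc", "om2_base",
                             "sig_prop_2", "sig_add_2"),
                   se = FALSE)
  pk_true <- typical_parameters(theta, coh$weight, 50)
  est <- typical_parameters(fit$theta, coh$weight, 50)
  expect_equal(est$cl, pk_true$cl, tolerance = 5e-3)
  expect_equal(est$vc, pk_true$vc, tolerance = 5e-3)
  expect_equal(est$q, pk_true$q, tolerance = 5e-3)
  expect_equal(est$vp, pk_true$vp, tolerance = 5e-3)
  expect_equal(fit$theta$base, coh$base, tolerance = 5e-3)
})

test_that("LRT cutoffs equal the chi-squared quantiles used in selection", {
  back <- lrt_decision(1011, 1000, df = 1, stage = "backward")
  expect_equal(back$cutoff, 10.8276, tolerance = 1e-4)
  expect_true(back$significant)           # delta 11.0 > 10.83
  expect_false(lrt_decision(1010, 1000, df = 1,
                            stage = "backward")$significant)  # delta 10.0
  fwd <- lrt_decision(1007, 1000, df = 1, stage = "forward")
  expect_equal(fwd$cutoff, 6.6349, tolerance = 1e-4)
  expect_true(fwd$significant)
  # multi-df cutoffs follow the chi-squared family
  expect_equal(lrt_decision(10, 0, df = 3, stage = "forward")$cutoff,
               qchisq(0.99, 3))
})

test_that("a negative OFV difference warns and is not significant", {
  expect_warning(res <- lrt_decision(999, 1000, df = 1, stage = "forward"),
                 "noise")
  expect_false(res$significant)
})

test_that("prediction correction is the identity for homogeneous cohorts", {
  # identical weights and doses -> identical population predictions within
  # each bin -> correction factor exactly 1
  coh <- generate_cohort(c(">=18" = 6), omega = fix_iiv(0, 0, 0), seed = 96)
  coh$weight <- rep(70, 6)
  coh$base <- rep(0.992, 6); coh$screening <- coh$base
  coh$cl <- rep(0.550, 6); coh$vc <- rep(61.04, 6); coh$vp <- rep(19.5, 6)
  ds <- simulate_dataset(coh, fix_regimen(50, mode = "single"),
                         c(1, 24, 96, 168, 336), seed = 97)
  v <- pcvpc(ds, n_sim = 40, bins = 5, seed = 98)
  obs <- ds[ds$EVID == 0, ]
  brk <- unique(quantile(obs$TIME, seq(0, 1, length.out = 6)))
  grp <- cut(obs$TIME, brk, include.lowest = TRUE)
  raw_median <- tapply(obs$DV, grp, median)
  expect_equal(unname(v$obs_p50), as.numeric(raw_median), tolerance = 1e-10)
})

test_that("the pcVPC reports 5th/50th/95th percentile series per bin", {
  ds <- tiny_ds(sigma = fix_residual(), n = 8, seed = 99)
  v <- pcvpc(ds, n_sim = 30, bins = 4, seed = 100)
  expect_true(all(c("obs_p5", "obs_p50", "obs_p95", "sim_p5_med",
                    "sim_p50_med", "sim_p95_med", "sim_p50_lo",
                    "sim_p50_hi") %in% names(v)))
  expect_equal(nrow(v), 4)
  expect_true(all(v$obs_p5 <= v$obs_p50 & v$obs_p50 <= v$obs_p95))
  expect_true(all(v$sim_p50_lo <= v$sim_p50_med &
                    v$sim_p50_med <= v$sim_p50_hi))
})
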