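# Closed-form two-compartment kinetics against independent oracles.

ref_pk <- pk_parameters(cl = 0.550, vc = 65.7, q = 0.208, vp = 19.5)

test_that("macro rate constants match the eigenvalues of the rate matrix", {
  d <- disposition_constants(ref_pk)
  k10 <- ref_pk$cl / ref_pk$vc
  k12 <- ref_pk$q / ref_pk$vc
  k21 <- ref_pk$q / ref_pk$vp
  A <- matrix(c(-(k10 + k12), k12, k21, -k21), 2, 2)
  ev <- sort(-Re(eigen(A)$values))
  expect_equal(d$lambda2, ev[1], tolerance = 1e-10)
  expect_equal(d$lambda1, ev[2], tolerance = 1e-10)
  expect_equal(d$lambda2, 0.00527, tolerance = 1e-2)
})

test_that("q = 0 degenerates to the one-compartment limit, not an error", {
  d <- disposition_constants(pk_parameters(cl = 0.5, vc = 50, q = 0))
  expect_equal(d$lambda1, 0.01)
  expect_equal(d$lambda2, 0)
  expect_equal(d$coef_b, 0)
  expect_equal(d$coef_a, 1 / 50)
})

test_that("disposition invariants hold on random parameter sets", {
  for (pk in random_pk(25, seed = 101)) {
    d <- disposition_constants(pk)
    expect_gt(d$lambda1, d$lambda2)
    expect_gte(d$lambda2, 0)
    expect_equal(d$coef_a + d$coef_b, 1 / pk$vc, tolerance = 1e-12)
  }
})

test_that("invalid disposition parameters are rejected", {
  expect_error(pk_parameters(cl = -1, vc = 50), "positive")
  expect_error(pk_parameters(cl = 0.5, vc = 0), "positive")
  expect_error(pk_parameters(cl = 0.5, vc = 50, q = 0.2, vp = 0), "vp")
})

test_that("short-infusion profile approaches the bolus limit dose/Vc", {
  pk <- pk_parameters(cl = 0.550, vc = 79.9, q = 0.208, vp = 19.5)
  prof <- single_dose_profile(pk, dose_event(7000, duration = 1e-6),
                              times = 1e-6)
  expect_equal(prof, 7000 / 79.9, tolerance = 1e-3)
  expect_equal(prof, 87.6, tolerance = 1e-3)
})

test_that("activity is zero before the dose (causality)", {
  prof <- single_dose_profile(ref_pk, dose_event(3500, time = 24),
                              times = c(0, 12, 23.9, 25))
  expect_identical(prof[1:3], rep(0, 3))
  expect_gt(prof[4], 0)
})

test_that("closed-form profiles match the ODE oracle within 0.1%", {
  skip_if_not_installed("deSolve")
  times <- c(0.05, 0.1, 1 / 6, 0.5, 2, 8, 24, 72, 168, 336, 504)
  for (pk in c(list(ref_pk), random_pk(5, seed = 202))) {
    dose <- dose_event(5000)
    ana <- single_dose_profile(pk, dose, times)
    num <- ode_profile(pk, list(dose), times)
    expect_lt(max(abs(ana - num) / pmax(num, 1e-9)), 1e-3)
  }
})

test_that("superposition equals the sum of shifted single-dose profiles", {
  doses <- list(dose_event(3500, time = 0), dose_event(3500, time = 168))
  times <- seq(0, 504, by = 12)
  sup <- superpose(ref_pk, doses, times)
  by_hand <- single_dose_profile(ref_pk, doses[[1]], times) +
    single_dose_profile(ref_pk, doses[[2]], times)
  expect_equal(sup, by_hand, tolerance = 1e-12)
  expect_equal(superpose(ref_pk, doses[1], times),
               single_dose_profile(ref_pk, doses[[1]], times))
  expect_identical(superpose(ref_pk, list(), times), rep(0, length(times)))
})

test_that("multi-dose superposition matches the ODE oracle within 0.1%", {
  skip_if_not_installed("deSolve")
  doses <- lapply(0:6, function(k) dose_event(3500, time = k * 168))
  times <- c(1, 24, 167, 169, 400, 800, 1100)
  ana <- superpose(ref_pk, doses, times)
  num <- ode_profile(ref_pk, doses, times)
  expect_lt(max(abs(ana - num) / pmax(num, 1e-9)), 1e-3)
})

test_that("steady state by accumulation factors matches a long dose train", {
  # 30 weekly doses cover > 15 terminal half-lives for the reference adult
  tau <- 168
  times_in <- c(1 / 6, 1, 24, 96, 168)
  ss <- steady_state_profile(ref_pk, 3500, tau, times = times_in)
  doses <- lapply(0:29, function(k) dose_event(3500, time = k * tau))
  train <- superpose(ref_pk, doses, 29 * tau + times_in)
  expect_lt(max(abs(ss - train) / train), 5e-3)
})

test_that("tau -> infinity reduces steady state to the single dose profile", {
  times <- c(1, 24, 168)
  ss <- steady_state_profile(ref_pk, 3500, tau = 1e7, times = times)
  sd <- single_dose_profile(ref_pk, dose_event(3500), times)
  expect_equal(ss, sd, tolerance = 1e-10)
})

test_that("steady-state AUC over one interval equals dose/CL", {
  tau <- 504
  tt <- seq(0, tau, length.out = 20001)
  prof <- steady_state_profile(ref_pk, 7000, tau, times = tt)
  auc_trap <- sum(diff(tt) * (head(prof, -1) + tail(prof, -1)) / 2)
  expect_equal(auc_trap, 7000 / 0.550, tolerance = 1e-4)
  expect_equal(exposure_metrics(ref_pk, 7000, tau)$auc_ss, 12727.27,
               tolerance = 1e-4)
})

test_that("exposure metrics are ordered and troughs wash out", {
  for (pk in random_pk(10, seed = 303)) {
    m <- exposure_metrics(pk, 3000, tau = 240)
    expect_gte(m$cmax, m$ctrough)
  }
  m_long <- exposure_metrics(ref_pk, 3500, tau = 24 * 365)
  expect_lt(m_long$ctrough, 1e-4)
})

test_that("profiles are non-negative and decay monotonically post-infusion", {
  times <- seq(1 / 6, 504, length.out = 400)
  for (pk in random_pk(8, seed = 404)) {
    prof <- single_dose_profile(pk, dose_event(4000), times)
    expect_true(all(prof >= 0))
    expect_true(all(diff(prof) <= 1e-12))
  }
})

test_that("degenerate regimens are rejected", {
  expect_error(steady_state_profile(ref_pk, 3500, tau = 0, times = 0),
               "invalid regimen")
  expect_error(steady_state_profile(ref_pk, 3500, tau = 0.1, times = 0),
               "invalid regimen")
})
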