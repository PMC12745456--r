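# Independent numerical oracle: adaptive ODE integration of the
# two-compartment infusion system. Used only to cross-check the closed-form
# evaluators; the package itself never integrates ODEs.
#
# Integration is restarted at every infusion switch point: a multistep
# solver's dense output would otherwise interpolate straight across a
# 10-minute infusion without ever evaluating the rate inside it.

ode_profile <- function(pk, doses, times) {
  stopifnot(requireNamespace("deSolve", quietly = TRUE))
  k10 <- pk$cl / pk$vc
  k12 <- if (pk$q > 0) pk$q / pk$vc else 0
  k21 <- if (pk$q > 0) pk$q / pk$vp else 0
  dose_df <- data.frame(
    t0 = vapply(doses, `[[`, numeric(1), "time"),
    t1 = vapply(doses, function(d) d$time + d$duration, numeric(1)),
    rate = vapply(doses, function(d) d$amount / d$duration, numeric(1)))
  rhs <- function(t, y, rate)
    list(c(rate - (k10 + k12) * y[1] + k21 * y[2],
           k12 * y[1] - k21 * y[2]))
  switches <- sort(unique(c(0, dose_df$t0, dose_df$t1, times)))
  y <- c(0, 0)
  central <- numeric(length(switches))
  for (i in seq_len(length(switches) - 1L)) {
    a <- switches[i]; b <- switches[i + 1L]
    rate <- sum(dose_df$rate[dose_df$t0 <= a & a < dose_df$t1])
    sol <- deSolve::lsoda(y, c(a, b), rhs, rate, rtol = 1e-11, atol = 1e-11)
    y <- sol[nrow(sol), 2:3]
    central[i + 1L] <- y[1]
  }
  central[match(times, switches)] / pk$vc
}

# random but physiological parameter sets for property tests
random_pk <- function(n, seed) {
  set.seed(seed)
  lapply(seq_len(n), function(i)
    pk_parameters(cl = runif(1, 0.1, 2), vc = runif(1, 10, 120),
                  q = runif(1, 0.02, 1), vp = runif(1, 2, 60)))
}
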