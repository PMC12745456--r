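# Closed-form two-compartment IV-infusion kinetics.
#
# The model is linear, so the package evaluates profiles from the
# biexponential macro-constant form (disposition eigenvalues lambda1 >=
# lambda2) rather than by numerical integration: every dose contributes a
# shifted copy of the single-dose solution, and steady state follows by
# multiplying each exponential term by its accumulation factor
# 1/(1 - exp(-lambda * tau)).

# Vectorized disposition solve. Arguments are equal-length vectors (or
# scalars); returns list of vectors lambda1, lambda2, coef_a, coef_b with
# coef_a + coef_b = 1/vc (unit-bolus normalization, C(0) = 1/Vc).
.disposition <- function(cl, vc, q, vp) {
  n <- max(length(cl), length(vc), length(q), length(vp))
  cl <- rep_len(cl, n); vc <- rep_len(vc, n)
  q <- rep_len(q, n); vp <- rep_len(vp, n)
  k10 <- cl / vc
  k12 <- ifelse(q > 0, q / vc, 0)
  k21 <- ifelse(q > 0, q / vp, 0)
  s <- k10 + k12 + k21
  r <- sqrt(pmax(s^2 - 4 * k10 * k21, 0))
  l1 <- (s + r) / 2
  l2 <- (s - r) / 2
  # near-repeated roots are numerically fragile: collapse to a
  # one-compartment model with pooled volume
  degen <- q <= 0 | (l1 - l2) < 1e-10 * l1
  vpool <- vc + ifelse(q > 0, vp, 0)
  l1 <- ifelse(degen, cl / vpool, l1)
  l2 <- ifelse(degen, 0, l2)
  ca <- ifelse(degen, 1 / vpool, (l1 - k21) / ((l1 - l2) * vc))
  cb <- ifelse(degen, 0, (k21 - l2) / ((l1 - l2) * vc))
  list(lambda1 = l1, lambda2 = l2, coef_a = ca, coef_b = cb)
}

#' Disposition macro-constants
#'
#' Eigen-decomposition of the two-compartment rate matrix: the macro rate
#' constants `lambda1 >= lambda2` are the roots of
#' \eqn{\lambda^2 - (k_{10}+k_{12}+k_{21})\lambda + k_{10}k_{21} = 0}
#' with \eqn{k_{10} = CL/V_c}, \eqn{k_{12} = Q/V_c}, \eqn{k_{21} = Q/V_p},
#' and the coefficients partition a unit bolus so that
#' `coef_a + coef_b = 1/vc`.
#'
#' `q = 0` is not an error: it returns the one-compartment limit
#' (`lambda2 = 0`, `coef_b = 0`). Nearly repeated roots (relative gap below
#' 1e-10) are likewise collapsed to a one-compartment model with pooled
#' volume, which keeps profile evaluation stable on random parameter draws.
#'
#' @param pk A [pk_parameters()] object.
#' @return A list of class `fix_disposition` with elements `lambda1`,
#'   `lambda2` (1/h) and `coef_a`, `coef_b` (1/dL).
#' @examples
#' disposition_constants(pk_parameters(0.550, 65.7, 0.208, 19.5))
#' @export
disposition_constants <- function(pk) {
  .assert(inherits(pk, "pk_parameters"), "'pk' must be a pk_parameters object")
  d <- .disposition(pk$cl, pk$vc, pk$q, pk$vp)
  structure(lapply(d, unname), class = "fix_disposition")
}

#' @export
print.fix_disposition <- function(x, ...) {
  t_half <- ifelse(x$lambda2 > 0, log(2) / x$lambda2, log(2) / x$lambda1)
  cat(sprintf("lambda1 = %.5g 1/h, lambda2 = %.5g 1/h (terminal t1/2 = %.3g h)\n",
              x$lambda1, x$lambda2, t_half))
  cat(sprintf("coef_a = %.5g, coef_b = %.5g 1/dL (sum = 1/Vc)\n",
              x$coef_a, x$coef_b))
  invisible(x)
}

# Profile of a single zero-order infusion starting at t = 0, vectorized over
# subjects (rows implied by the disposition vectors) x times. `d` is the
# output of .disposition; returns a matrix [n_subjects x n_times] when
# n_subjects > 1, else a vector.
.infusion_profile <- function(d, amount, duration, times) {
  rate <- amount / duration
  term <- function(coef, lam) {
    on <- lam > 0 & coef != 0
    out <- matrix(0, length(lam), length(times))
    if (!any(on)) return(out)
    lam_on <- lam[on]; c_on <- coef[on]; r_on <- rep_len(rate, length(lam))[on]
    tl <- outer(lam_on, times)                      # lambda * t
    during <- outer(rep(1, length(lam_on)), times <= duration)
    e_t <- exp(-tl)
    e_dur <- exp(-lam_on * duration)
    base <- (c_on / lam_on) * r_on
    prof <- during * (base * (1 - e_t)) +
      (1 - during) * (base * (1 - e_dur) * exp(-outer(lam_on, times - duration)))
    out[on, ] <- prof
    out
  }
  p <- term(d$coef_a, d$lambda1) + term(d$coef_b, d$lambda2)
  if (any(times < 0)) p[, times < 0] <- 0
  if (nrow(p) == 1L) drop(p) else p
}

#' Exogenous activity after a single infusion
#'
#' Closed-form concentration (FIX activity, IU/dL) of the exogenous
#' component after one zero-order infusion, evaluated at `times` (hours).
#' Times before the start of the infusion return 0.
#'
#' @param pk A [pk_parameters()] object.
#' @param dose A [dose_event()].
#' @param times Sorted, non-negative vector of times (h since time zero).
#' @return Numeric vector of activities, IU/dL.
#' @examples
#' pk <- pk_parameters(0.550, 79.9, 0.208, 19.5)
#' single_dose_profile(pk, dose_event(7000), times = c(1, 24, 168, 336))
#' @export
single_dose_profile <- function(pk, dose, times) {
  .assert(inherits(pk, "pk_parameters"), "'pk' must be a pk_parameters object")
  .assert(inherits(dose, "dose_event"), "'dose' must be a dose_event")
  .assert(is.numeric(times) && !is.unsorted(times),
          "'times' must be a sorted numeric vector")
  d <- .disposition(pk$cl, pk$vc, pk$q, pk$vp)
  .infusion_profile(d, dose$amount, dose$duration, times - dose$time)
}

#' Superposition of multiple infusions
#'
#' Because the kinetics are linear, the profile under any dosing history is
#' the sum of shifted single-dose profiles. An empty dose list gives an
#' all-zero profile.
#'
#' @param pk A [pk_parameters()] object.
#' @param doses A list of [dose_event()] objects, sorted by time.
#' @param times Sorted, non-negative numeric vector of times (h).
#' @return Numeric vector of activities, IU/dL.
#' @export
superpose <- function(pk, doses, times) {
  .assert(is.list(doses), "'doses' must be a list of dose_event objects")
  if (length(doses) == 0L) return(rep(0, length(times)))
  .assert(all(vapply(doses, inherits, logical(1), "dose_event")),
          "'doses' must be a list of dose_event objects")
  tms <- vapply(doses, `[[`, numeric(1), "time")
  .assert(!is.unsorted(tms), "'doses' must be sorted by time")
  Reduce(`+`, lapply(doses, function(dd) single_dose_profile(pk, dd, times)))
}

# steady-state within-interval profile, vectorized over subjects x times;
# `times` in [0, tau]. Accumulation factor 1/(1 - exp(-lambda tau)) applied
# per exponential term.
.steady_profile <- function(d, amount, tau, duration, times) {
  rate <- amount / duration
  term <- function(coef, lam) {
    on <- lam > 0 & coef != 0
    out <- matrix(0, length(lam), length(times))
    if (!any(on)) return(out)
    lam_on <- lam[on]; c_on <- coef[on]; r_on <- rep_len(rate, length(lam))[on]
    acc <- 1 / (1 - exp(-lam_on * tau))
    base <- (c_on / lam_on) * r_on
    e_dur <- exp(-lam_on * duration)
    during <- outer(rep(1, length(lam_on)), times <= duration)
    e_t <- exp(-outer(lam_on, times))
    e_shift <- exp(-outer(lam_on, times - duration))
    prof_in <- base * ((1 - e_t) + exp(-lam_on * tau) * (1 - e_dur) * e_shift * acc)
    prof_out <- base * (1 - e_dur) * e_shift * acc
    out[on, ] <- during * prof_in + (1 - during) * prof_out
    out
  }
  p <- term(d$coef_a, d$lambda1) + term(d$coef_b, d$lambda2)
  if (nrow(p) == 1L) drop(p) else p
}

#' Steady-state within-interval profile
#'
#' Exogenous activity over one dosing interval at steady state for repeated
#' infusions of `dose_amount` every `tau` hours. Each exponential term of
#' the single-dose solution is scaled by its accumulation factor
#' \eqn{1/(1 - e^{-\lambda\tau})}.
#'
#' @param pk A [pk_parameters()] object.
#' @param dose_amount Dose per administration, IU.
#' @param tau Dosing interval, hours. Must be > 0.
#' @param infusion_duration Infusion duration, hours (default 10 min).
#' @param times Times within the interval, `0 <= times <= tau`.
#' @return Numeric vector of steady-state activities, IU/dL.
#' @examples
#' pk <- pk_parameters(0.550, 65.7, 0.208, 19.5)
#' steady_state_profile(pk, 3500, tau = 168, times = c(1, 24, 96, 168))
#' @export
steady_state_profile <- function(pk, dose_amount, tau,
                                 infusion_duration = 1 / 6, times) {
  .assert(inherits(pk, "pk_parameters"), "'pk' must be a pk_parameters object")
  .assert_scalar_num(dose_amount, "dose_amount")
  .assert(is.numeric(tau) && length(tau) == 1L && is.finite(tau) && tau > 0,
          "invalid regimen: 'tau' must be a positive interval in hours")
  .assert_scalar_num(infusion_duration, "infusion_duration")
  .assert(infusion_duration < tau,
          "invalid regimen: infusion must be shorter than the interval")
  .assert(is.numeric(times) && all(times >= 0) && all(times <= tau),
          "'times' must lie within [0, tau]")
  d <- .disposition(pk$cl, pk$vc, pk$q, pk$vp)
  .steady_profile(d, dose_amount, tau, infusion_duration, times)
}

#' Steady-state exposure metrics
#'
#' Cmax is the steady-state activity at the end of the infusion, Ctrough the
#' activity at the end of the interval (`t = tau`), and AUCss follows from
#' the clearance identity `dose / CL`.
#'
#' @inheritParams steady_state_profile
#' @return A list with `cmax`, `ctrough` (IU/dL) and `auc_ss` (IU h/dL).
#' @examples
#' exposure_metrics(pk_parameters(0.550, 79.9, 0.208, 19.5), 7000, tau = 504)
#' @export
exposure_metrics <- function(pk, dose_amount, tau, infusion_duration = 1 / 6) {
  prof <- steady_state_profile(pk, dose_amount, tau, infusion_duration,
                               times = c(infusion_duration, tau))
  list(cmax = prof[[1]], ctrough = prof[[2]], auc_ss = dose_amount / pk$cl)
}
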