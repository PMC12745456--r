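# Parameter containers for the rIX-FP population PK model.
#
# Units are fixed throughout the package: clearances in dL/h, volumes in dL,
# times in hours, doses in IU, activities in IU/dL (identical to % of normal).
# Days appear only at the reporting layer (regimen intervals, durations).

.assert <- function(ok, ...) {
  if (!isTRUE(ok)) stop(..., call. = FALSE)
}

.assert_scalar_num <- function(x, name, positive = TRUE, nonneg = FALSE) {
  .assert(is.numeric(x) && length(x) == 1L && is.finite(x),
          sprintf("'%s' must be a finite numeric scalar", name))
  if (positive) .assert(x > 0, sprintf("'%s' must be strictly positive", name))
  if (nonneg) .assert(x >= 0, sprintf("'%s' must be non-negative", name))
  invisible(x)
}

#' Structural PK parameters of one subject
#'
#' Container for the four disposition parameters of the two-compartment
#' model: clearance `cl` (dL/h), central volume `vc` (dL), intercompartmental
#' clearance `q` (dL/h) and peripheral volume `vp` (dL).
#'
#' @param cl Clearance, dL/h. Strictly positive.
#' @param vc Central volume of distribution, dL. Strictly positive.
#' @param q Intercompartmental clearance, dL/h. Non-negative; `q = 0`
#'   degenerates to a one-compartment model.
#' @param vp Peripheral volume, dL. Must be strictly positive whenever
#'   `q > 0`.
#' @return An object of class `pk_parameters`.
#' @examples
#' pk_parameters(cl = 0.550, vc = 65.7, q = 0.208, vp = 19.5)
#' @export
pk_parameters <- function(cl, vc, q = 0, vp = 1) {
  .assert_scalar_num(cl, "cl")
  .assert_scalar_num(vc, "vc")
  .assert_scalar_num(q, "q", positive = FALSE, nonneg = TRUE)
  .assert_scalar_num(vp, "vp", positive = FALSE, nonneg = TRUE)
  if (q > 0) .assert(vp > 0, "'vp' must be > 0 when 'q' > 0")
  structure(list(cl = cl, vc = vc, q = q, vp = vp), class = "pk_parameters")
}

#' @export
print.pk_parameters <- function(x, ...) {
  cat("Two-compartment PK parameters\n")
  cat(sprintf("  CL = %.4g dL/h, Vc = %.4g dL, Q = %.4g dL/h, Vp = %.4g dL\n",
              x$cl, x$vc, x$q, x$vp))
  invisible(x)
}

#' Population fixed effects of the final covariate model
#'
#' Typical parameter values and covariate exponents. Defaults are the final
#' model point estimates: typical values refer to a 70-kg patient receiving
#' a weight-adjusted dose of 50 IU/kg.
#'
#' @param base Typical endogenous FIX activity, IU/dL.
#' @param cl Typical clearance at 70 kg, dL/h.
#' @param vc Typical central volume at 70 kg and 50 IU/kg, dL.
#' @param q Intercompartmental clearance, dL/h (no covariates).
#' @param vp Typical peripheral volume at 70 kg, dL.
#' @param exp_wt_cl Allometric exponent of body weight on CL.
#' @param exp_wt_v Allometric exponent of body weight on Vc and Vp.
#' @param exp_dose_vc Exponent of weight-adjusted dose on Vc.
#' @return An object of class `fix_fixed_effects`.
#' @seealso [typical_parameters()], [fix_iiv()], [fix_residual()]
#' @examples
#' theta <- fix_fixed_effects()
#' typical_parameters(theta, weight = 70, dose_per_kg = 50)
#' @export
fix_fixed_effects <- function(base = 0.992, cl = 0.550, vc = 65.7,
                              q = 0.208, vp = 19.5,
                              exp_wt_cl = 0.528, exp_wt_v = 0.771,
                              exp_dose_vc = 0.281) {
  for (nm in c("base", "cl", "vc", "q", "vp"))
    .assert_scalar_num(get(nm), nm)
  for (nm in c("exp_wt_cl", "exp_wt_v", "exp_dose_vc"))
    .assert_scalar_num(get(nm), nm, positive = FALSE)
  structure(list(base = base, cl = cl, vc = vc, q = q, vp = vp,
                 exp_wt_cl = exp_wt_cl, exp_wt_v = exp_wt_v,
                 exp_dose_vc = exp_dose_vc),
            class = "fix_fixed_effects")
}

#' @export
print.fix_fixed_effects <- function(x, ...) {
  cat("Population fixed effects (reference: 70 kg, 50 IU/kg)\n")
  cat(sprintf("  BASE = %.3g IU/dL; CL = %.3g dL/h; Vc = %.3g dL; Q = %.3g dL/h; Vp = %.3g dL\n",
              x$base, x$cl, x$vc, x$q, x$vp))
  cat(sprintf("  exponents: weight on CL %.3g; weight on Vc/Vp %.3g; dose on Vc %.3g\n",
              x$exp_wt_cl, x$exp_wt_v, x$exp_dose_vc))
  invisible(x)
}

#' Inter-individual variability (IIV) variances
#'
#' Variances of the log-normal random effects on CL, Vc and BASE. The final
#' model carries no IIV on Q or Vp. Values are variances of the random
#' effect (so the approximate coefficient of variation is `sqrt(omega2)`).
#'
#' @param cl Variance of the log-scale random effect on clearance.
#' @param vc Variance of the log-scale random effect on central volume.
#' @param base Variance of the log-scale random effect on endogenous
#'   baseline activity.
#' @return An object of class `fix_iiv`.
#' @export
fix_iiv <- function(cl = 0.0386, vc = 0.0562, base = 0.176) {
  for (nm in c("cl", "vc", "base"))
    .assert_scalar_num(get(nm), nm, positive = FALSE, nonneg = TRUE)
  structure(list(cl = cl, vc = vc, base = base), class = "fix_iiv")
}

#' @export
print.fix_iiv <- function(x, ...) {
  cat(sprintf("IIV variances: CL %.4g (CV %.1f%%), Vc %.4g (CV %.1f%%), BASE %.4g (CV %.1f%%)\n",
              x$cl, 100 * sqrt(x$cl), x$vc, 100 * sqrt(x$vc),
              x$base, 100 * sqrt(x$base)))
  invisible(x)
}

#' Residual error magnitudes by study group
#'
#' Combined proportional + additive residual error, estimated separately for
#' the earlier studies (2001/2004) and the later studies (3001/3002/3003).
#' Proportional components are standard deviations on the relative scale
#' (0.181 is an 18.1% CV); additive components are IU/dL.
#'
#' @param prop_2001,add_2001 Proportional SD and additive SD (IU/dL) for
#'   study group `"2001/2004"`.
#' @param prop_3001,add_3001 Proportional SD and additive SD (IU/dL) for
#'   study group `"3001/3002/3003"`.
#' @return An object of class `fix_residual`.
#' @export
fix_residual <- function(prop_2001 = 0.181, add_2001 = 0.683,
                         prop_3001 = 0.371, add_3001 = 1.20) {
  for (nm in c("prop_2001", "add_2001", "prop_3001", "add_3001"))
    .assert_scalar_num(get(nm), nm, positive = FALSE, nonneg = TRUE)
  structure(list(prop_2001 = prop_2001, add_2001 = add_2001,
                 prop_3001 = prop_3001, add_3001 = add_3001),
            class = "fix_residual")
}

#' @export
print.fix_residual <- function(x, ...) {
  cat("Residual error (combined proportional + additive)\n")
  cat(sprintf("  2001/2004:      prop SD %.3g, additive SD %.3g IU/dL\n",
              x$prop_2001, x$add_2001))
  cat(sprintf("  3001/3002/3003: prop SD %.3g, additive SD %.3g IU/dL\n",
              x$prop_3001, x$add_3001))
  invisible(x)
}

# map a study-group label to its (prop, add) sigma pair
.sigma_for_group <- function(sigma, group) {
  g <- as.character(group)
  ok <- g %in% c("2001/2004", "3001/3002/3003")
  .assert(all(ok), "study group must be \"2001/2004\" or \"3001/3002/3003\"")
  list(prop = ifelse(g == "2001/2004", sigma$prop_2001, sigma$prop_3001),
       add = ifelse(g == "2001/2004", sigma$add_2001, sigma$add_3001))
}

#' Single infusion event
#'
#' @param amount Dose amount, IU. Strictly positive.
#' @param time Start of the infusion, hours since time zero.
#' @param duration Infusion duration in hours; defaults to 10 minutes
#'   (`1/6` h), the duration assumed by the regimen simulations.
#' @return An object of class `dose_event`.
#' @export
dose_event <- function(amount, time = 0, duration = 1 / 6) {
  .assert_scalar_num(amount, "amount")
  .assert_scalar_num(time, "time", positive = FALSE, nonneg = TRUE)
  .assert_scalar_num(duration, "duration")
  structure(list(time = time, amount = amount, duration = duration),
            class = "dose_event")
}
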