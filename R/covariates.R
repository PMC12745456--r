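# Covariate laws of the final model.
#
# Body weight enters clearance and the volumes as power laws centred at
# 70 kg; the weight-adjusted dose (IU/kg) enters the central volume centred
# at 50 IU/kg. These are the natural-scale equivalents of linear covariate
# relationships on the log-transformed parameters. Age is deliberately not
# a covariate: after accounting for body weight it carried no additional
# information, so age acts only through the weight distribution of the
# cohort generator. Ethnicity has no parameter effect and is kept as a
# cohort label only.

#' Typical PK parameters for given covariates
#'
#' Applies the covariate model to the population fixed effects:
#' \deqn{CL = \theta_{CL} (W/70)^{0.528}}
#' \deqn{V_c = \theta_{Vc} (W/70)^{0.771} (D/50)^{0.281}}
#' \deqn{V_p = \theta_{Vp} (W/70)^{0.771}, \quad Q = \theta_Q}
#' where `W` is body weight (kg) and `D` the weight-adjusted dose (IU/kg).
#' At the reference covariates (70 kg, 50 IU/kg) the output equals the
#' typical values exactly.
#'
#' @param theta A [fix_fixed_effects()] object.
#' @param weight Body weight, kg. Strictly positive.
#' @param dose_per_kg Weight-adjusted dose, IU/kg. Strictly positive.
#' @return A [pk_parameters()] object.
#' @examples
#' typical_parameters(fix_fixed_effects(), weight = 35, dose_per_kg = 50)
#' @export
typical_parameters <- function(theta, weight, dose_per_kg = 50) {
  .assert(inherits(theta, "fix_fixed_effects"),
          "'theta' must be a fix_fixed_effects object")
  .assert(is.numeric(weight) && length(weight) == 1L && is.finite(weight) &&
            weight > 0, "invalid covariate: 'weight' must be > 0")
  .assert(is.numeric(dose_per_kg) && length(dose_per_kg) == 1L &&
            is.finite(dose_per_kg) && dose_per_kg > 0,
          "invalid covariate: 'dose_per_kg' must be > 0")
  p <- .typical_vec(theta, weight, dose_per_kg)
  pk_parameters(cl = p$cl, vc = p$vc, q = p$q, vp = p$vp)
}

# vectorized over weight / dose_per_kg / eta; returns plain list of vectors
.typical_vec <- function(theta, weight, dose_per_kg,
                         eta_cl = 0, eta_vc = 0) {
  wn <- weight / 70
  list(cl = theta$cl * wn^theta$exp_wt_cl * exp(eta_cl),
       vc = theta$vc * wn^theta$exp_wt_v *
         (dose_per_kg / 50)^theta$exp_dose_vc * exp(eta_vc),
       q = rep_len(theta$q, length(wn)),
       vp = theta$vp * wn^theta$exp_wt_v)
}

#' Typical clearance per kilogram of body weight
#'
#' `CL(W)/W`, in dL/h/kg. Because the allometric exponent on CL is below 1,
#' per-kg clearance decreases strictly with weight, which is why young
#' children clear the drug faster per kilogram than adults.
#'
#' @param theta A [fix_fixed_effects()] object.
#' @param weight Body weight, kg (vectorized).
#' @return Per-kg clearance, dL/h/kg.
#' @examples
#' per_kg_clearance(fix_fixed_effects(), weight = c(16.5, 70))
#' @export
per_kg_clearance <- function(theta, weight) {
  .assert(inherits(theta, "fix_fixed_effects"),
          "'theta' must be a fix_fixed_effects object")
  .assert(is.numeric(weight) && all(is.finite(weight)) && all(weight > 0),
          "invalid covariate: 'weight' must be > 0")
  theta$cl * (weight / 70)^theta$exp_wt_cl / weight
}

#' Body weight matching a target per-kg clearance
#'
#' Inverts [per_kg_clearance()] by 1-D root finding. Used to calibrate the
#' cohort generator: the median weight of each age group is back-solved so
#' that the group's median typical per-kg clearance equals the published
#' post-hoc median for that group.
#'
#' @param theta A [fix_fixed_effects()] object.
#' @param target Target per-kg clearance, dL/h/kg.
#' @return Body weight, kg.
#' @examples
#' weight_for_per_kg_cl(fix_fixed_effects(), 0.0155) # around 16.5 kg
#' @export
weight_for_per_kg_cl <- function(theta, target) {
  .assert(is.numeric(target) && length(target) == 1L && is.finite(target) &&
            target > 0, "config error: 'target' per-kg clearance must be > 0")
  f <- function(w) log(per_kg_clearance(theta, w)) - log(target)
  # per-kg CL is strictly decreasing, so bracket by expansion
  lo <- 1; hi <- 500
  while (f(lo) < 0 && lo > 1e-3) lo <- lo / 10
  while (f(hi) > 0 && hi < 1e6) hi <- hi * 10
  .assert(f(lo) >= 0 && f(hi) <= 0,
          "config error: target per-kg clearance is unattainable")
  stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
}
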