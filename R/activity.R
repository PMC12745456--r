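# Composition of observed FIX activity.
#
# The observed quantity is FTOT = FEX + BASE + FPP: exogenous drug activity,
# endogenous baseline, and a decaying residual from FIX products taken
# before the first study dose. The regimen simulation tables use FEX only;
# the prior-product component matters when fitting datasets whose early
# observations still carry pre-study drug.

#' Baseline activity state of a patient
#'
#' @param base Endogenous FIX activity, IU/dL. Patients in the moderate to
#'   severe range have `base <= 2` IU/dL; generated patients respect that
#'   bound.
#' @param bse Observed FIX activity immediately prior to the first study
#'   dose, IU/dL (initial value of the prior-product decay).
#' @param screening Screening FIX activity, IU/dL.
#' @return An object of class `baseline_state`.
#' @export
baseline_state <- function(base, bse = 0, screening = base) {
  for (nm in c("base", "bse", "screening"))
    .assert_scalar_num(get(nm), nm, positive = FALSE, nonneg = TRUE)
  structure(list(base = base, bse = bse, screening = screening),
            class = "baseline_state")
}

#' Decaying prior-product activity (FPP)
#'
#' The residual activity of pre-study FIX products decays
#' mono-exponentially from the pre-first-dose observation BSE with the same
#' `CL` and `Vc` as the study drug:
#' \deqn{FPP(t) = BSE \, e^{-(CL/V_c)\,t}.}
#' Once the value declines below the lowest of (1) BSE itself, (2) the
#' screening activity, and (3) 2 IU/dL (the approximate quantification
#' limit), FPP is set to zero and stays zero. The zeroing time is computed
#' analytically from the threshold, so evaluation is deterministic and
#' stateless.
#'
#' @param state A [baseline_state()] object.
#' @param cl,vc Clearance (dL/h) and central volume (dL) of the individual.
#' @param t Times since first dose, hours (vectorized, non-negative).
#' @return FPP activity, IU/dL.
#' @examples
#' st <- baseline_state(base = 1, bse = 10, screening = 1)
#' prior_product_activity(st, cl = 0.550, vc = 65.7, t = c(0, 168, 504))
#' @export
prior_product_activity <- function(state, cl, vc, t) {
  .assert(inherits(state, "baseline_state"),
          "'state' must be a baseline_state object")
  .assert_scalar_num(cl, "cl"); .assert_scalar_num(vc, "vc")
  .assert(is.numeric(t) && all(is.finite(t)), "'t' must be numeric")
  .assert(all(t >= 0), "'t' must be non-negative")
  if (state$bse <= 0) return(rep(0, length(t)))
  thr <- min(state$bse, state$screening, 2)
  fpp <- state$bse * exp(-(cl / vc) * t)
  ifelse(fpp >= thr, fpp, 0)
}

#' Total observed FIX activity
#'
#' `FTOT = FEX + BASE + FPP`. All components must be non-negative, so the
#' total is bounded below by each component.
#'
#' @param fex Exogenous drug activity, IU/dL (vectorized).
#' @param base Endogenous baseline activity, IU/dL.
#' @param fpp Prior-product activity, IU/dL.
#' @return Total activity, IU/dL.
#' @export
total_activity <- function(fex, base = 0, fpp = 0) {
  .assert(is.numeric(fex) && is.numeric(base) && is.numeric(fpp),
          "activity components must be numeric")
  .assert(all(fex >= 0) && all(base >= 0) && all(fpp >= 0),
          "activity components must be non-negative")
  fex + base + fpp
}
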