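---
title: "Methods: population PK simulation and estimation for rIX-FP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population PK simulation and estimation for rIX-FP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

rIX-FP is a recombinant factor IX–albumin fusion protein with an extended
half-life used for prophylaxis in hemophilia B. This vignette documents the
model implemented by `rixfp`, the assumptions behind the synthetic cohort
generator, the numerical choices, and what the package's tests do and do
not establish.

## The structural model

FIX activity (IU/dL, identical to % of normal) after intravenous infusion
follows linear two-compartment disposition. With clearance $CL$, central
volume $V_c$, intercompartmental clearance $Q$ and peripheral volume $V_p$,
the micro-constants are $k_{10} = CL/V_c$, $k_{12} = Q/V_c$,
$k_{21} = Q/V_p$, and the macro rate constants $\lambda_1 \ge \lambda_2$
solve

$$\lambda^2 - (k_{10}+k_{12}+k_{21})\,\lambda + k_{10}k_{21} = 0.$$

All profiles are evaluated in closed form from the biexponential solution
of a zero-order infusion. Because the kinetics are linear, multiple doses
superpose, and the steady-state profile over one interval $\tau$ follows by
scaling each exponential term with its accumulation factor
$1/(1-e^{-\lambda\tau})$. A numerical ODE integration exists in the test
suite only, as an independent oracle; the package itself never integrates
differential equations. This makes a Monte-Carlo replicate a handful of
vectorized arithmetic operations, which is what keeps cohort-level
simulation fast and exact.

Observed activity decomposes as $F_{TOT} = F_{EX} + BASE + F_{PP}$:
exogenous drug, endogenous baseline (at most 2 IU/dL in this moderate to
severe population), and a residual of FIX products taken before the first
study dose. The prior-product component decays as
$F_{PP}(t) = BSE\,e^{-(CL/V_c)t}$ from the observed pre-first-dose
activity, using the same $CL$ and $V_c$ as the study drug, and is zeroed —
analytically, so evaluation is stateless and deterministic — once it falls
below the smallest of $BSE$, the screening activity and 2 IU/dL. All
regimen summaries use the exogenous component only.

## Covariate model

Body weight enters as power laws centred at 70 kg, and the weight-adjusted
dose (IU/kg) enters the central volume centred at 50 IU/kg:

$$CL = \theta_{CL}\,(W/70)^{0.528},\qquad
V_c = \theta_{Vc}\,(W/70)^{0.771}\,(D/50)^{0.281},\qquad
V_p = \theta_{Vp}\,(W/70)^{0.771}.$$

These are the natural-scale equivalents of linear covariate effects on the
log-transformed parameters. The defaults of `fix_fixed_effects()` are the
final published estimates ($\theta_{CL} = 0.550$ dL/h, $\theta_{Vc} =
65.7$ dL, $\theta_Q = 0.208$ dL/h, $\theta_{Vp} = 19.5$ dL, $\theta_{BASE}
= 0.992$ IU/dL). One printed unit for $Q$ ("dh/h") is read as dL/h; it is
the only unit in its table block that would otherwise be dimensionally
inconsistent.

Two modelling facts matter downstream. Age is *not* a covariate: after
accounting for body weight it carried no information, so age acts only
through the weight distribution of the cohort generator. Ethnicity has no
parameter effect either and is carried as a cohort label only; the package
still provides `ethnicity_comparison()` because demonstrating the absence
of a difference was part of the original analysis.

Because the allometric exponent on clearance (0.528) is below 1, per-kg
clearance falls with weight — children clear the drug faster per kilogram,
which is the entire story of why extended intervals fail in the youngest
group.

## The virtual cohort generator

The clinical datasets are not public, so simulation operates on virtual
cohorts that emulate the study population: age groups <6, 6–<12, 12–<18
and ≥18 years with study-like sizes 12/15/5/81. The published evidence
about each group's kinetics is the median of the individual per-kg
clearance estimates (0.0155, 0.0114, 0.0103 and 0.00822 dL/h/kg, with
0.00836 for ≥12). The generator back-solves, by 1-D root finding on the
allometric law, the body weight whose *typical* per-kg clearance equals
each group median (about 16.6 kg for <6 and 63.6 kg for ≥18) and uses it
as the median of a log-normal weight distribution.

Choices not determined by published information, fixed once:

* **Weight spread.** Geometric CV of 20% within each age group. Only
  study-level weight medians and ranges were published; 20% is a realistic
  within-group spread for pediatric/adult weight strata and the calibrated
  medians, not the spread, carry the group signal.
* **Ages** are uniform within the group bounds (1–6, 6–12, 12–18, 18–63
  years). Ages are labels here: nothing downstream reads them.
* **Baseline activity** is log-normal around $\theta_{BASE}$ with the
  published variance, truncated at 2 IU/dL by rejection sampling rather
  than clipping, which preserves the log-normal shape below the bound.
* **IIV** is log-normal on CL, Vc and BASE with diagonal covariance
  (variances 0.0386, 0.0562, 0.176), matching the final model, which
  retained a diagonal structure; Q and Vp carry no IIV. In the parameter
  table the IIV entries are variances (footnoted as such), while the
  "proportional" residual entries (0.181, 0.371) are standard deviations —
  their CV% column prints 18.1 and 37.1, which is only consistent with the
  SD reading.
* **Randomness** flows from a single integer seed through R's default
  generator, with patients generated in a fixed order, so a cohort or
  dataset is bit-reproducible from (configuration, seed).

What the generator does *not* emulate: the actual 113 covariate vectors,
between-study heterogeneity in weights within an age group, correlation
between weight and baseline, or anti-drug antibodies (none were observed).
Consequences of the calibration choice are discussed under *Known
limitations*.

## Residual error

The combined proportional + additive residual error is study-group
specific (0.181/0.683 for the earlier studies, 0.371/1.20 IU/dL for the
later ones). The original model was fit to *log-transformed* activity, for
which the combined structure is the log-transform-both-sides form: the
log-scale observation variance is $\sigma_p^2 + (\sigma_a/F)^2$.
`add_residual_error()` therefore offers two forms. The `"lognormal"` form
perturbs predictions on the log scale with exactly that variance; it is
what `simulate_dataset()` uses by default so that estimation experiments
are internally consistent with the estimator (and with how the original
model treated the data). The `"natural"` form composes the error
arithmetically on the activity scale ($F(1+\varepsilon_p)+\varepsilon_a$,
floored at zero and flagged); it is the literal natural-scale reading and
is kept for sensitivity analyses. To first order the two agree; they
differ in the tails, where the natural-scale form can produce zero or
negative draws that the log-scale model never generates.

Regimen simulations (`summarize_regimen()` and the table builders) apply
IIV only, no residual error: the published tables summarize
model-predicted activity, and assay noise is not part of a dosing
recommendation.

## The regimen simulation study

`duration_above()` finds the last down-crossing of each threshold (1, 3,
5 IU/dL) on the post-infusion biexponential by a vectorized Newton
iteration on log-activity — log-activity is convex and decreasing in time,
so iterations starting at the end of infusion converge monotonically.
Durations are reported on a half-day grid (floored), the resolution of the
published table. Troughs are the steady-state activity at exactly
$t = \tau$; Cmax at the end of the 10-minute infusion; AUC$_{ss}$ is
dose/CL.

`summarize_regimen()` resamples the IIV of every patient per replicate and
summarizes **pooled over patients × replicates**: medians and 90%
prediction intervals for troughs/Cmax/AUC, median and 25th percentile for
single-dose durations. Pooling is a deliberate interpretation: the
original simulations ran on the study patients' individual (post-hoc)
parameters, so each simulated patient already carried one realized IIV
deviation, and a pooled summary over a large synthetic cohort is the
corresponding population statement. Two observations support it: the
published 90% prediction intervals are far wider than the between-patient
spread of replicate-median troughs (they match the pooled spread almost
exactly), and the published median trough for adults on 100 IU/kg every
21 days sits just above 5 IU/dL while the matching percent-above-5 sits
just below 50%, which is only coherent if both are read against the same
pooled distribution. The percent-above-cutoff summaries default to the
same pooled convention; `percent_method = "per_patient"` (classifying each
patient by the median of their replicate troughs) is available, but it
collapses IIV and therefore understates attainment spread relative to the
published figures.

With 1,000 replicates the pooled medians are stable to well under ±2%
across seeds; the table builders default to that but accept smaller
values, and the acceptance script uses 10–200 replicates per scenario on
cohorts of 1,000, which gives the same precision at a fraction of the
cost.

## Estimation

`poppk_fit()` maximizes a Laplace-approximated marginal likelihood, the
desk-scale stand-in for NONMEM's FOCEI: estimates, not likelihood
arithmetic, are the basis of comparison. Per individual, the random-effect
vector $\eta$ (log-scale CL, Vc, BASE) is driven to its empirical-Bayes
mode and the integral is corrected with local curvature:

$$-2\log L_i \approx 2g_i(\hat\eta) - q\log 2\pi + \log\det H_i ,$$

where $g_i$ is the negative log joint and $H_i$ a Gauss-Newton curvature.
Observations enter on the log scale with per-observation variance
$\sigma_p^2 + (\sigma_a/F)^2$. Numerical details that proved to matter:

* The inner mode search uses the **full** finite-difference gradient of
  the joint (the variance depends on the prediction, so dropping the
  interaction terms misplaces the mode for low-activity observations) with
  the Gauss-Newton cross-product, which is always positive definite, as
  the step metric, plus step-halving; convergence at gradient norm
  1e-8.
* The outer problem is log-parameterized for positivity and solved with
  `nlminb` using **central-difference gradients at step 1e-4**: the inner
  solves leave ~1e-8 noise on the objective, and machine-epsilon forward
  differences stall the line search on that noise. The optimizer restarts
  from its incumbent until the OFV is stationary; stationarity is also the
  reported convergence criterion.
* The covariate exponents are held fixed by default. They are identified
  by wide multi-study weight ranges, not by a 50-patient single-dose
  design; freeing them there trades bias for variance. `fixed =
  character(0)` frees everything.
* Below-quantification observations enter at their recorded values (the
  original analysis did not censor them); a floor of 0.125 IU/dL guards
  the log transform against zero records, which only the natural-scale
  error form can produce.
* Variances of random effects equal to zero drop the corresponding
  dimension rather than being estimated at a boundary.

Identifiability of $BASE$ deserves a note: it is informed mainly by
predose samples (the synthetic designs include one at $t=0$) and by late
washout, where the relative noise $\sigma_a/F$ is largest, so its
finite-sample estimates are noticeably more variable than clearance's.
The original analysis had multiple studies' predose and washout data for
this; a single-occasion synthetic design does not.

`lrt_decision()` encodes the covariate-selection rule: forward inclusion
at $p<0.01$ and backward elimination at $p<0.001$, i.e. OFV changes of
6.63 and 10.83 for one degree of freedom, with chi-squared quantiles at
matching $\alpha$ for more degrees of freedom.

`pcvpc()` implements the prediction-corrected visual predictive check:
observations and simulated replicates are scaled by bin-median over
individual population prediction, then per-bin 5th/50th/95th percentiles
of the corrected observations are compared with simulation bands. Bins are
equal-count over time; empty bins are dropped with a warning.

## What the tests show — and what they cannot

The test suite validates three layers: (1) the closed-form kinetics
against an independent adaptive ODE integration (≤0.1% relative error) and
against structural identities (superposition, accumulation, dose/CL); (2)
the simulation study against the published table values, using the
calibrated synthetic cohorts; (3) the estimator by parameter recovery on
synthetic datasets generated at the published parameters (population CL
within 10% at 50 patients; all fixed effects within 15% and IIV variances
within a factor of two at 100 patients, 12 samples over 504 h).

Passing (2) shows that the published dosing conclusions follow from the
published parameters plus a weight distribution consistent with the
published per-kg clearance medians — not that the synthetic cohort equals
the study population. Passing (3) shows the estimator recovers the truth
of its own generative model at realistic noise; it cannot validate against
the original fit, whose data and final OFV are unpublished.

## Known limitations

* Calibrating the adult weight median through the typical per-kg clearance
  law yields ~63.6 kg, lighter than the study's adult patients (the
  published post-hoc median mixes realized IIV into the numerator). The
  synthetic adult cohort therefore clears slightly faster per kg than the
  study cohort, and its simulated troughs and durations sit a few percent
  below the published adult cells — visible mostly in the 100 IU/kg
  every-21-days trough, the slowest-decaying scenario. A 70-kg typical
  adult reproduces those cells within published precision.
* Nonlinear (saturable) kinetics, absorption models and lag times are out
  of scope; so is any efficacy or bleeding-outcome modelling.
* The Laplace estimator is not NONMEM FOCEI; OFV values are not comparable
  across implementations, only differences within one implementation are.
* Steady-state summaries assume full adherence and exact intervals.

## Problem sizes used by the shipped checks

Cohorts of 400–1,000 patients with 10–200 replicates per scenario for the
simulation-study checks; 50- and 100-patient datasets with 12 samples per
patient for estimator recovery; 300 simulation replicates for the pcVPC
calibration check. These sizes hold every Monte-Carlo standard error well
inside the tolerance it is tested against.
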