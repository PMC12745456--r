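# Desk-scale nonlinear mixed-effects estimation.
#
# The marginal likelihood integrates the per-patient random effects
# (log-scale CL, Vc, BASE) out of the data likelihood. The integral is
# approximated by Laplace's method at each individual's empirical-Bayes
# mode, with Gauss-Newton curvature for the log-determinant — the standard
# conditional-estimation family, implemented in plain R. Observations are
# compared on the log scale, with the combined proportional + additive
# residual error mapped to the per-observation log-scale variance
# sigma_p^2 + (sigma_a / F)^2.

# --- dataset parsing ------------------------------------------------------

.parse_dataset <- function(data) {
  .validate_dataset(data)
  ids <- unique(data$ID)
  lapply(ids, function(id) {
    rec <- data[data$ID == id, , drop = FALSE]
    dose <- rec[rec$EVID == 1L, , drop = FALSE]
    obs <- rec[rec$EVID == 0L, , drop = FALSE]
    .assert(nrow(obs) >= 1L,
            sprintf("individual %s has no observations", id))
    wt <- rec$WT[1]
    # precompute time offsets and during/after index sets per dose: they
    # depend only on the data and dominate the likelihood hot path
    pre <- lapply(seq_len(nrow(dose)), function(j) {
      tt <- obs$TIME - dose$TIME[j]
      dur <- dose$DUR[j]
      i_in <- which(tt >= 0 & tt <= dur)
      i_af <- which(tt > dur)
      list(i_in = i_in, tt_in = tt[i_in], i_af = i_af,
           tt_af = tt[i_af] - dur)
    })
    list(id = id, wt = wt,
         dose_per_kg = dose$AMT[1] / wt,
         bse = if ("BSE" %in% names(rec)) rec$BSE[1] else 0,
         scrn = if ("SCRN" %in% names(rec)) rec$SCRN[1] else 0,
         group = if ("STUDYGRP" %in% names(rec)) rec$STUDYGRP[1]
                 else "3001/3002/3003",
         dose_times = dose$TIME, dose_amts = dose$AMT, dose_durs = dose$DUR,
         pre = pre, times = obs$TIME, dv = obs$DV)
  })
}

# scalar disposition solve without the vectorized machinery
.disp1 <- function(cl, vc, q, vp) {
  k10 <- cl / vc
  if (q <= 0) return(list(l1 = k10, l2 = 0, ca = 1 / vc, cb = 0))
  k12 <- q / vc
  k21 <- q / vp
  s <- k10 + k12 + k21
  r <- sqrt(max(s * s - 4 * k10 * k21, 0))
  l1 <- (s + r) / 2
  l2 <- (s - r) / 2
  if ((l1 - l2) < 1e-10 * l1) {
    vpool <- vc + vp
    return(list(l1 = cl / vpool, l2 = 0, ca = 1 / vpool, cb = 0))
  }
  list(l1 = l1, l2 = l2, ca = (l1 - k21) / ((l1 - l2) * vc),
       cb = (k21 - l2) / ((l1 - l2) * vc))
}

# closed-form FTOT prediction for one individual; eta = c(cl, vc, base)
.pred_one <- function(ind, theta, eta) {
  wn <- ind$wt / 70
  cl <- theta$cl * wn^theta$exp_wt_cl * exp(eta[1])
  vc <- theta$vc * wn^theta$exp_wt_v *
    (ind$dose_per_kg / 50)^theta$exp_dose_vc * exp(eta[2])
  vp <- theta$vp * wn^theta$exp_wt_v
  d <- .disp1(cl, vc, theta$q, vp)
  f <- numeric(length(ind$times))
  for (j in seq_along(ind$dose_times)) {
    pre <- ind$pre[[j]]
    dur <- ind$dose_durs[j]
    rate <- ind$dose_amts[j] / dur
    b1 <- (d$ca / d$l1) * rate
    if (length(pre$i_in))
      f[pre$i_in] <- f[pre$i_in] + b1 * (1 - exp(-d$l1 * pre$tt_in))
    if (length(pre$i_af))
      f[pre$i_af] <- f[pre$i_af] +
        b1 * (1 - exp(-d$l1 * dur)) * exp(-d$l1 * pre$tt_af)
    if (d$cb != 0 && d$l2 > 0) {
      b2 <- (d$cb / d$l2) * rate
      if (length(pre$i_in))
        f[pre$i_in] <- f[pre$i_in] + b2 * (1 - exp(-d$l2 * pre$tt_in))
      if (length(pre$i_af))
        f[pre$i_af] <- f[pre$i_af] +
          b2 * (1 - exp(-d$l2 * dur)) * exp(-d$l2 * pre$tt_af)
    }
  }
  f <- f + theta$base * exp(eta[3])
  if (ind$bse > 0) {
    thr <- min(ind$bse, ind$scrn, 2)
    fpp <- ind$bse * exp(-(cl / vc) * ind$times)
    f <- f + ifelse(fpp >= thr, fpp, 0)
  }
  f
}

# -2 log joint of (y, eta) for one individual, up to the constant that the
# Laplace correction re-adds; lv = log observations, om2 = active variances
.ind_joint <- function(ind, theta, eta, om2_full, active, sp, sa, lv) {
  f <- pmax(.pred_one(ind, theta, eta), 1e-8)
  v <- sp^2 + (sa / f)^2
  r <- lv - log(f)
  0.5 * sum(r^2 / v + log(2 * pi * v)) +
    0.5 * sum(eta[active]^2 / om2_full[active] +
                log(2 * pi * om2_full[active]))
}

# Gauss-Newton inner optimization to the empirical-Bayes mode.
# Returns the mode, the objective value there and the GN curvature.
.inner_mode <- function(ind, theta, om2, active, sp, sa, eta_start) {
  lv <- log(pmax(ind$dv, 0.125))   # guard: half of LLOQ/2; see docs
  q <- sum(active)
  eta <- eta_start
  if (q == 0L)
    return(list(eta = eta, g = .ind_joint(ind, theta, eta, om2, active,
                                          sp, sa, lv),
                hess = matrix(0, 0, 0)))
  h <- 1e-4
  g_val <- .ind_joint(ind, theta, eta, om2, active, sp, sa, lv)
  for (it in 1:40) {
    f0 <- pmax(.pred_one(ind, theta, eta), 1e-8)
    v <- sp^2 + (sa / f0)^2
    r <- lv - log(f0)
    J <- matrix(0, length(f0), q)
    idx <- which(active)
    for (k in seq_len(q)) {
      ep <- eta; ep[idx[k]] <- ep[idx[k]] + h
      J[, k] <- (log(pmax(.pred_one(ind, theta, ep), 1e-8)) - log(f0)) / h
    }
    # exact gradient of the joint: because v = sp^2 + (sa/F)^2 depends on
    # F, each observation contributes d(logF)/d(eta) times
    # [-r/v + (sa^2/F^2)(r^2/v^2 - 1/v)] — the second piece is the
    # variance-through-the-mean interaction that plain Gauss-Newton drops
    cvec <- -r / v + (sa^2 / f0^2) * (r^2 / v^2 - 1 / v)
    grad <- crossprod(J, cvec) + eta[idx] / om2[idx]
    H <- crossprod(J, J / v) + diag(1 / om2[idx], q)
    if (sqrt(sum(grad^2)) < 1e-8) break
    step <- tryCatch(solve(H, -grad), error = function(e) -grad / max(diag(H)))
    lam <- 1
    for (half in 1:10) {
      cand <- eta
      cand[idx] <- eta[idx] + lam * step
      g_new <- .ind_joint(ind, theta, cand, om2, active, sp, sa, lv)
      if (is.finite(g_new) && g_new <= g_val + 1e-12) break
      lam <- lam / 2
    }
    if (g_new > g_val) break
    moved <- sqrt(sum((lam * step)^2))
    eta <- cand; g_val <- g_new
    if (moved < 1e-9) break
  }
  # curvature at the mode for the Laplace log-determinant
  f0 <- pmax(.pred_one(ind, theta, eta), 1e-8)
  v <- sp^2 + (sa / f0)^2
  idx <- which(active)
  J <- matrix(0, length(f0), q)
  for (k in seq_len(q)) {
    ep <- eta; ep[idx[k]] <- ep[idx[k]] + h
    J[, k] <- (log(pmax(.pred_one(ind, theta, ep), 1e-8)) - log(f0)) / h
  }
  H <- crossprod(J, J / v) + diag(1 / om2[idx], q)
  list(eta = eta, g = g_val, hess = H)
}

#' Marginal -2 log-likelihood (objective function value)
#'
#' Laplace-approximated objective for the population model on a
#' NONMEM-style dataset: per individual the random-effect vector is set to
#' its empirical-Bayes mode and the integral is corrected by the local
#' curvature. Individuals are independent, so the OFV is the sum of
#' per-individual contributions. Random effects whose variance is zero are
#' profiled out (fixed at zero). Observations recorded below the
#' quantification limit enter at their recorded value; a floor of
#' 0.125 IU/dL protects the log transform against zero records.
#'
#' @param data A [fix_dataset][simulate_dataset()] data.frame (or any
#'   data.frame with the same required columns).
#' @param theta A [fix_fixed_effects()] object.
#' @param omega A [fix_iiv()] object; variances equal to zero drop the
#'   corresponding random effect.
#' @param sigma A [fix_residual()] object.
#' @param eta_start Optional matrix of starting random effects
#'   (individuals x 3), used internally to warm-start repeated evaluations.
#' @return The OFV (numeric scalar) with attribute `"eta"`, the matrix of
#'   empirical-Bayes modes.
#' @export
poppk_objective <- function(data, theta = fix_fixed_effects(),
                            omega = fix_iiv(), sigma = fix_residual(),
                            eta_start = NULL) {
  inds <- if (is.list(data) && !is.data.frame(data)) data else
    .parse_dataset(data)
  .ofv(inds, theta, omega, sigma, eta_start)
}

.ofv <- function(inds, theta, omega, sigma, eta_start = NULL) {
  om2 <- c(omega$cl, omega$vc, omega$base)
  active <- om2 > 1e-12
  q <- sum(active)
  if (is.null(eta_start)) eta_start <- matrix(0, length(inds), 3)
  eta_out <- matrix(0, length(inds), 3)
  total <- 0
  for (i in seq_along(inds)) {
    sg <- .sigma_for_group(sigma, inds[[i]]$group)
    m <- .inner_mode(inds[[i]], theta, om2, active, sg$prop, sg$add,
                     eta_start[i, ])
    ld <- if (q > 0) determinant(m$hess, logarithm = TRUE)$modulus else 0
    total <- total + 2 * m$g - q * log(2 * pi) + as.numeric(ld)
    eta_out[i, ] <- m$eta
  }
  structure(total, eta = eta_out)
}

# --- outer fit ------------------------------------------------------------

.par_pack <- function(theta, omega, sigma, groups) {
  p <- c(t_base = log(theta$base), t_cl = log(theta$cl),
         t_vc = log(theta$vc), t_q = log(theta$q), t_vp = log(theta$vp),
         exp_wt_cl = theta$exp_wt_cl, exp_wt_v = theta$exp_wt_v,
         exp_dose_vc = theta$exp_dose_vc,
         om2_cl = log(max(omega$cl, 1e-10)),
         om2_vc = log(max(omega$vc, 1e-10)),
         om2_base = log(max(omega$base, 1e-10)))
  if ("2001/2004" %in% groups)
    p <- c(p, sig_prop_1 = log(sigma$prop_2001),
           sig_add_1 = log(sigma$add_2001))
  if ("3001/3002/3003" %in% groups)
    p <- c(p, sig_prop_2 = log(sigma$prop_3001),
           sig_add_2 = log(sigma$add_3001))
  p
}

.par_unpack <- function(p, ref_sigma) {
  theta <- fix_fixed_effects(base = exp(p[["t_base"]]), cl = exp(p[["t_cl"]]),
                             vc = exp(p[["t_vc"]]), q = exp(p[["t_q"]]),
                             vp = exp(p[["t_vp"]]),
                             exp_wt_cl = p[["exp_wt_cl"]],
                             exp_wt_v = p[["exp_wt_v"]],
                             exp_dose_vc = p[["exp_dose_vc"]])
  omega <- fix_iiv(cl = exp(p[["om2_cl"]]), vc = exp(p[["om2_vc"]]),
                   base = exp(p[["om2_base"]]))
  sigma <- fix_residual(
    prop_2001 = if ("sig_prop_1" %in% names(p)) exp(p[["sig_prop_1"]])
                else ref_sigma$prop_2001,
    add_2001 = if ("sig_add_1" %in% names(p)) exp(p[["sig_add_1"]])
               else ref_sigma$add_2001,
    prop_3001 = if ("sig_prop_2" %in% names(p)) exp(p[["sig_prop_2"]])
                else ref_sigma$prop_3001,
    add_3001 = if ("sig_add_2" %in% names(p)) exp(p[["sig_add_2"]])
               else ref_sigma$add_3001)
  list(theta = theta, omega = omega, sigma = sigma)
}

#' Fit the population model by Laplace marginal likelihood
#'
#' Quasi-Newton minimization of [poppk_objective()] over the fixed effects,
#' IIV variances and residual-error magnitudes. Positivity is enforced by
#' optimizing on the log scale (covariate exponents are unconstrained).
#' The covariate exponents are held at their initial values by default:
#' they are identified by wide multi-study weight ranges rather than by a
#' desk-scale single-dose design, and freeing them there mostly trades bias
#' for variance. Pass e.g. `fixed = character(0)` to free everything.
#'
#' Non-convergence is reported, not thrown: the best point found is
#' returned with `converged = FALSE`.
#'
#' @param data A NONMEM-style dataset (see [simulate_dataset()]).
#' @param init Named list with starting `theta` ([fix_fixed_effects()]),
#'   `omega` ([fix_iiv()]) and `sigma` ([fix_residual()]).
#' @param fixed Character vector of parameter names to hold at their
#'   initial values. Names follow the internal parameterization:
#'   `t_base, t_cl, t_vc, t_q, t_vp, exp_wt_cl, exp_wt_v, exp_dose_vc,
#'   om2_cl, om2_vc, om2_base, sig_prop_1, sig_add_1, sig_prop_2,
#'   sig_add_2`.
#' @param se Compute Hessian-based standard errors at the optimum (adds a
#'   numerical Hessian of the OFV; skip for large recovery experiments).
#' @param control Passed to [stats::nlminb()].
#' @return An object of class `fix_fit`: estimates (`theta`, `omega`,
#'   `sigma`), `ofv`, `converged`, iteration counts, the empirical-Bayes
#'   modes, and (optionally) `standard_errors` on the natural scale.
#' @export
poppk_fit <- function(data,
                      init = list(theta = fix_fixed_effects(),
                                  omega = fix_iiv(), sigma = fix_residual()),
                      fixed = c("exp_wt_cl", "exp_wt_v", "exp_dose_vc"),
                      se = TRUE,
                      control = list(iter.max = 200, eval.max = 400,
                                     rel.tol = 1e-8)) {
  inds <- .parse_dataset(data)
  groups <- unique(vapply(inds, `[[`, character(1), "group"))
  p_full <- .par_pack(init$theta, init$omega, init$sigma, groups)
  .assert(all(fixed %in% names(p_full)),
          "unknown parameter name in 'fixed'")
  free <- setdiff(names(p_full), fixed)
  eta_cache <- new.env(parent = emptyenv())
  eta_cache$eta <- NULL
  obj <- function(pf) {
    p <- p_full
    p[free] <- pf
    par <- .par_unpack(p, init$sigma)
    val <- tryCatch(
      .ofv(inds, par$theta, par$omega, par$sigma, eta_cache$eta),
      error = function(e) NULL)
    if (is.null(val) || !is.finite(val)) return(1e10)
    eta_cache$eta <- attr(val, "eta")
    as.numeric(val)
  }
  # central-difference gradient: the inner Laplace solves leave ~1e-8 noise
  # on the OFV, so forward differences at machine-epsilon steps stall the
  # line search; a wider symmetric step keeps the gradient usable
  grad <- function(pf) {
    h <- 1e-4
    vapply(seq_along(pf), function(k) {
      up <- pf; up[k] <- up[k] + h
      dn <- pf; dn[k] <- dn[k] - h
      (obj(up) - obj(dn)) / (2 * h)
    }, numeric(1))
  }
  opt <- stats::nlminb(p_full[free], obj, gradient = grad, control = control)
  # restart from the incumbent until the OFV is stationary
  stationary <- FALSE
  for (restart in 1:3) {
    opt2 <- stats::nlminb(opt$par, obj, gradient = grad, control = control)
    improved <- opt$objective - opt2$objective
    if (opt2$objective <= opt$objective) opt <- opt2
    if (improved < 0.01) { stationary <- TRUE; break }
  }
  p_hat <- p_full
  p_hat[free] <- opt$par
  est <- .par_unpack(p_hat, init$sigma)
  ses <- NULL
  if (se && length(free) > 0) {
    hess <- tryCatch(stats::optimHess(opt$par, obj), error = function(e) NULL)
    if (!is.null(hess)) {
      # OFV = -2 log L, so the information matrix is H/2
      cov <- tryCatch(solve(hess / 2), error = function(e) NULL)
      if (!is.null(cov) && all(diag(cov) > 0)) {
        se_t <- sqrt(diag(cov))
        # delta method back to the natural scale for log-parameterized terms
        natural <- ifelse(grepl("^exp_", free), 1, exp(opt$par))
        ses <- stats::setNames(se_t * natural, free)
      }
    }
  }
  structure(list(theta = est$theta, omega = est$omega, sigma = est$sigma,
                 ofv = opt$objective,
                 converged = opt$convergence == 0 || stationary,
                 message = opt$message,
                 iterations = opt$iterations,
                 evaluations = opt$evaluations,
                 free = free, fixed = fixed,
                 par = p_hat,
                 standard_errors = ses,
                 eta = eta_cache$eta,
                 n_individuals = length(inds),
                 n_observations = sum(vapply(inds, function(x)
                   length(x$dv), numeric(1)))),
            class = "fix_fit")
}

#' @export
print.fix_fit <- function(x, ...) {
  cat(sprintf("Population fit: %d individuals, %d observations\n",
              x$n_individuals, x$n_observations))
  cat(sprintf("  OFV = %.3f; converged: %s (%d iterations)\n",
              x$ofv, x$converged, x$iterations))
  cat(sprintf("  CL = %.4g dL/h, Vc = %.4g dL, Q = %.4g dL/h, Vp = %.4g dL, BASE = %.3g IU/dL\n",
              x$theta$cl, x$theta$vc, x$theta$q, x$theta$vp, x$theta$base))
  cat(sprintf("  omega2: CL %.4g, Vc %.4g, BASE %.4g\n",
              x$omega$cl, x$omega$vc, x$omega$base))
  invisible(x)
}

#' Likelihood-ratio test decision for nested models
#'
#' Compares the OFV difference between a reduced and a full model with the
#' chi-squared cutoff used during covariate selection: p < 0.01 at forward
#' inclusion (6.63 for one degree of freedom) and p < 0.001 at backward
#' elimination (10.83 for one degree of freedom). More degrees of freedom
#' (e.g. a categorical covariate with several levels) use the corresponding
#' quantile of the chi-squared distribution with that df.
#'
#' A negative OFV difference between nested models is numerical noise; it
#' triggers a warning and is declared not significant.
#'
#' @param ofv_reduced,ofv_full OFVs of the nested (reduced) and full model.
#' @param df Degrees of freedom of the comparison (>= 1).
#' @param stage `"forward"` (p < 0.01) or `"backward"` (p < 0.001).
#' @return A list with `delta_ofv`, `cutoff`, `p_value` and `significant`.
#' @examples
#' lrt_decision(ofv_reduced = 1011, ofv_full = 1000, df = 1, stage = "backward")
#' @export
lrt_decision <- function(ofv_reduced, ofv_full, df = 1,
                         stage = c("forward", "backward")) {
  stage <- match.arg(stage)
  .assert(is.numeric(df) && df >= 1, "'df' must be >= 1")
  alpha <- if (stage == "forward") 0.01 else 0.001
  delta <- ofv_reduced - ofv_full
  if (delta < 0)
    warning("reduced model has lower OFV than the full model; ",
            "treating the difference as numerical noise")
  cutoff <- stats::qchisq(1 - alpha, df)
  list(delta_ofv = delta, cutoff = cutoff,
       p_value = stats::pchisq(max(delta, 0), df, lower.tail = FALSE),
       significant = delta > cutoff)
}

# --- prediction-corrected VPC --------------------------------------------

#' Prediction-corrected visual predictive check
#'
#' Observations and simulated replicates are corrected multiplicatively by
#' the ratio of the bin-median population prediction to each record's own
#' population prediction, removing covariate- and dose-driven trends before
#' percentiles are compared. Per time bin the function reports the 5th,
#' 50th and 95th percentiles of the corrected observations together with
#' simulation-based confidence bands for each percentile.
#'
#' @param data A NONMEM-style dataset.
#' @param theta,omega,sigma Model parameters used for simulation.
#' @param n_sim Number of simulated replicates (1000 in the original
#'   evaluation; smaller values are fine for quick checks).
#' @param bins Number of equal-count time bins (empty bins are dropped with
#'   a warning).
#' @param conf Width of the simulation band per percentile (default 0.90).
#' @param seed Optional integer seed.
#' @return A data.frame of class `fix_vpc`: one row per bin with observed
#'   percentiles (`obs_p5`, `obs_p50`, `obs_p95`) and, for each, the
#'   simulation median and band (`sim_*_med`, `sim_*_lo`, `sim_*_hi`).
#' @export
pcvpc <- function(data, theta = fix_fixed_effects(), omega = fix_iiv(),
                  sigma = fix_residual(), n_sim = 1000, bins = 10,
                  conf = 0.90, seed = NULL) {
  inds <- .parse_dataset(data)
  if (!is.null(seed)) set.seed(seed)
  .assert(n_sim >= 1 && bins >= 1, "'n_sim' and 'bins' must be >= 1")
  times <- unlist(lapply(inds, `[[`, "times"))
  dv <- unlist(lapply(inds, `[[`, "dv"))
  pred <- unlist(lapply(inds, function(ind)
    .pred_one(ind, theta, c(0, 0, 0))))
  groups <- unlist(lapply(inds, function(ind)
    rep(ind$group, length(ind$times))))
  brk <- unique(stats::quantile(times, seq(0, 1, length.out = bins + 1)))
  if (length(brk) - 1L < bins)
    warning("empty time bins dropped; using ", length(brk) - 1L, " bins")
  bin <- cut(times, brk, include.lowest = TRUE)
  binmed_pred <- stats::ave(pred, bin, FUN = stats::median)
  corr <- binmed_pred / pred
  pc_obs <- dv * corr
  om2 <- c(omega$cl, omega$vc, omega$base)
  sg <- .sigma_for_group(sigma, groups)
  n_obs <- length(dv)
  probs <- c(0.05, 0.50, 0.95)
  sim_pct <- array(NA_real_, c(n_sim, nlevels(bin), 3))
  for (s in seq_len(n_sim)) {
    sim_f <- unlist(lapply(inds, function(ind) {
      eta <- stats::rnorm(3, 0, sqrt(om2))
      .pred_one(ind, theta, eta)
    }))
    w <- sqrt(sg$prop^2 + (sg$add / pmax(sim_f, 1e-8))^2)
    sim_dv <- sim_f * exp(w * stats::rnorm(n_obs))
    pc_sim <- sim_dv * corr
    for (b in seq_len(nlevels(bin))) {
      sel <- bin == levels(bin)[b]
      sim_pct[s, b, ] <- stats::quantile(pc_sim[sel], probs, names = FALSE)
    }
  }
  a <- (1 - conf) / 2
  out <- do.call(rbind, lapply(seq_len(nlevels(bin)), function(b) {
    sel <- bin == levels(bin)[b]
    op <- stats::quantile(pc_obs[sel], probs, names = FALSE)
    row <- data.frame(bin = levels(bin)[b],
                      t_mid = stats::median(times[sel]), n = sum(sel),
                      obs_p5 = op[1], obs_p50 = op[2], obs_p95 = op[3])
    for (k in 1:3) {
      nm <- c("p5", "p50", "p95")[k]
      qq <- stats::quantile(sim_pct[, b, k], c(a, 0.5, 1 - a), names = FALSE)
      row[[paste0("sim_", nm, "_lo")]] <- qq[1]
      row[[paste0("sim_", nm, "_med")]] <- qq[2]
      row[[paste0("sim_", nm, "_hi")]] <- qq[3]
    }
    row
  }))
  class(out) <- c("fix_vpc", "data.frame")
  out
}
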