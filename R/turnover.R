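# Composite quadrature on a uniform grid: Simpson's rule, with a trapezoid
# closing panel when the number of intervals is odd. Returns 0 for < 2 points.
simpson_quad <- function(y, h) {
  n <- length(y)
  if (n < 2) return(0)
  if (n == 2) return(h * (y[1] + y[2]) / 2)
  nint <- n - 1
  if (nint %% 2 == 0) {
    w <- c(1, rep(c(4, 2), length.out = nint - 1), 1)
    sum(w * y) * h / 3
  } else {
    simpson_quad(y[seq_len(n - 1)], h) + h * (y[n - 1] + y[n]) / 2
  }
}

#' Cohort history of a turnover constituent
#'
#' Bookkeeping container for collagen or SMC turnover: all material present
#' at the start of a simulation is treated as a single initial pool
#' (referential density `rho0`, survival `q0`, deposited in the reference
#' configuration), and newly produced material is recorded as cohorts on a
#' uniform grid of deposition times with spacing `ds` (the G&R step). Each
#' cohort carries its production rate `mR`, survival fraction `q` and the
#' mixture circumferential stretch `lam_dep` at deposition.
#'
#' @param label Constituent label.
#' @param rho0 Initial pool referential mass density (`Phi0 * rho`).
#' @param mR0 Production rate at the first grid point, \eqn{\tau = 0}
#'   (homeostatic value `ko * rho0`).
#' @param ds Grid spacing in days (the G&R step, default 0.1).
#' @return List of class `"cohort_history"`.
#' @export
cohort_history <- function(label, rho0, mR0 = NULL, ds = 0.1) {
  stopifnot(rho0 >= 0, ds > 0)
  structure(list(
    label = label, ds = ds,
    rho0 = rho0, q0 = 1, lam_dep0 = 1, prehistory = rho0 > 0,
    tau = 0, mR = if (is.null(mR0)) 0 else mR0, q = 1, lam_dep = 1
  ), class = "cohort_history")
}

#' @export
print.cohort_history <- function(x, ...) {
  cat("<cohort_history> ", x$label, ": ", length(x$tau), " cohorts on [",
      x$tau[1], ", ", x$tau[length(x$tau)], "] days; pool q0 = ",
      signif(x$q0, 4), "\n", sep = "")
  invisible(x)
}

#' Stress-dependent degradation rate
#'
#' \eqn{k = k_o (1 + \Delta\sigma^2)}: turnover accelerates symmetrically
#' with any deviation of the intramural stress measure from its target.
#'
#' @param delta_sigma Relative intramural stress deviation (dimensionless).
#' @param ko Base degradation rate, 1/day.
#' @return Degradation rate, 1/day (always >= `ko`).
#' @export
degradation_rate <- function(delta_sigma, ko) {
  if (ko <= 0) stop("base degradation rate must be > 0", call. = FALSE)
  ko * (1 + delta_sigma^2)
}

#' Incremental survival update
#'
#' One step of the exponential survival function:
#' `q_new = q_prev * exp(-k_avg * dt)`, with `k_avg` the time-averaged
#' degradation rate over the step.
#'
#' @param q_prev Previous survival fraction(s) in (0, 1].
#' @param k_avg Time-averaged degradation rate, 1/day.
#' @param dt Step, days.
#' @return Updated survival fraction(s).
#' @export
survival_update <- function(q_prev, k_avg, dt) {
  stopifnot(all(q_prev > 0), all(q_prev <= 1), k_avg >= 0, dt > 0)
  q_prev * exp(-k_avg * dt)
}

#' Referential mass production rate
#'
#' \eqn{m_R = \max(0,\; k\, \rho_R\, \Upsilon)}: the nominal rate
#' \eqn{k \rho_R} (production balances removal at homeostasis) scaled by
#' the combined stimulus, floored at zero because the combined stimulus can
#' go negative while removal is handled solely by the survival function.
#'
#' @param k Degradation rate, 1/day.
#' @param rhoR Referential mass density.
#' @param upsilon Combined stimulus (dimensionless, 1 at homeostasis).
#' @return Production rate, mass density / day.
#' @export
mass_production <- function(k, rhoR, upsilon) {
  stopifnot(k >= 0, rhoR >= 0)
  max(0, k * rhoR * upsilon)
}

#' Referential mass density from a cohort history
#'
#' \eqn{\rho_R(s) = \rho_R(0) q(s,0) + \int_0^s m_R(\tau) q(s,\tau) d\tau},
#' the integral approximated with the composite Simpson rule on the cohort
#' grid.
#'
#' @param ch A [cohort_history()].
#' @return Referential mass density (same units as `rho0`).
#' @export
referential_density <- function(ch) {
  ch$rho0 * ch$q0 + simpson_quad(ch$mR * ch$q, ch$ds)
}

#' Scalar intramural stress measure
#'
#' Two hypotheses for the stress that drives the phenomenological stimuli:
#' `"TRACE"` uses \eqn{\tilde\sigma = \sigma_{\theta\theta} + \sigma_{zz}}
#' (plane-stress trace), `"CIRC"` uses the circumferential stress only.
#'
#' @param sigma_thth,sigma_zz Cauchy stresses, kPa.
#' @param hypothesis `"TRACE"` or `"CIRC"`.
#' @return Stress measure, kPa.
#' @export
stress_measure <- function(sigma_thth, sigma_zz, hypothesis) {
  switch(hypothesis,
         TRACE = sigma_thth + sigma_zz,
         CIRC = sigma_thth,
         stop("unknown stress hypothesis: ", hypothesis, call. = FALSE))
}

#' Relative intramural stress deviation
#'
#' @param sigma_tilde Current stress measure, kPa.
#' @param sigma_tilde_o Homeostatic target, kPa (> 0).
#' @return \eqn{(\tilde\sigma - \tilde\sigma_o)/\tilde\sigma_o}.
#' @export
delta_sigma <- function(sigma_tilde, sigma_tilde_o) {
  if (sigma_tilde_o <= 0)
    stop("homeostatic stress target must be > 0", call. = FALSE)
  (sigma_tilde - sigma_tilde_o) / sigma_tilde_o
}

#' Relative wall shear stress deviation
#'
#' Poiseuille scaling of wall shear stress with flow and radius:
#' \eqn{\Delta\tau_w = Q r_o^3 / (Q_o r^3) - 1}.
#'
#' @param Q,Qo Current and reference flow (any common unit).
#' @param r,ro Current and reference luminal radius, mm.
#' @return Dimensionless deviation (0 at reference).
#' @export
delta_tau <- function(Q, Qo, r, ro) {
  stopifnot(Qo > 0, r > 0, ro > 0)
  Q * ro^3 / (Qo * r^3) - 1
}

#' Notch stimulus on SMC proliferation
#'
#' In-vitro-fitted dependence of SMC proliferation on relative NICD content:
#' \eqn{\Upsilon_N^m = 47.21\, e^{-3.855 I}}, normalized so that the value
#' at homeostatic Notch activity (I = 1) is 1 to within fit rounding.
#' Lower Notch activity promotes proliferation.
#'
#' @param I_rel NICD content relative to its homeostatic mean (>= 0).
#' @return Dimensionless stimulus, strictly decreasing in `I_rel`.
#' @export
notch_stimulus_smc <- function(I_rel) {
  stopifnot(all(I_rel >= 0))
  47.21 * exp(-3.855 * I_rel)
}

#' Notch stimulus on collagen synthesis
#'
#' In-vitro-fitted dependence of collagen synthesis on relative NICD
#' content: \eqn{\Upsilon_N^c = 0.3161 (I - 1) + 1}, equal to 1 at
#' homeostatic Notch activity. Higher Notch activity promotes collagen
#' synthesis.
#'
#' @inheritParams notch_stimulus_smc
#' @return Dimensionless stimulus, strictly increasing in `I_rel`.
#' @export
notch_stimulus_collagen <- function(I_rel) {
  stopifnot(all(I_rel >= 0))
  0.3161 * (I_rel - 1) + 1
}

#' Combined production stimulus
#'
#' \eqn{\Upsilon = \Upsilon_N + \Upsilon_\sigma + \Upsilon_{\tau w} - 2},
#' with individual terms replaced by 1 under the model variants:
#' `"PHENOM_ONLY"` deactivates the Notch term, `"NOTCH_ONLY"` deactivates
#' both phenomenological terms. The result can be negative; it is floored
#' at zero only where it enters [mass_production()].
#'
#' @param ups_N Notch stimulus.
#' @param ups_sig Intramural stress stimulus \eqn{1 + K_\sigma \Delta\sigma}.
#' @param ups_tau Wall shear stimulus \eqn{1 - K_{\tau w} \Delta\tau_w}.
#' @param variant `"COMBINED"`, `"PHENOM_ONLY"` or `"NOTCH_ONLY"`.
#' @return Combined stimulus (dimensionless).
#' @export
combined_stimulus <- function(ups_N, ups_sig, ups_tau,
                              variant = c("COMBINED", "PHENOM_ONLY",
                                          "NOTCH_ONLY")) {
  variant <- match.arg(variant)
  if (variant == "PHENOM_ONLY") ups_N <- 1
  if (variant == "NOTCH_ONLY") { ups_sig <- 1; ups_tau <- 1 }
  ups_N + ups_sig + ups_tau - 2
}

# Survival update + truncation of negligible cohorts (q below qmin), applied
# in place on a cohort history. Truncation only drops from the old end so the
# grid stays uniform.
update_cohort_survival <- function(ch, k_avg, dt, qmin = 1e-6) {
  if (ch$rho0 > 0) {
    ch$q0 <- survival_update(ch$q0, k_avg, dt)
    if (ch$q0 < qmin) { ch$rho0 <- 0; ch$q0 <- 1 }
  }
  if (length(ch$tau)) {
    ch$q <- survival_update(ch$q, k_avg, dt)
    keep <- which(ch$q >= qmin)
    if (length(keep) && keep[1] > 1) {
      idx <- keep[1]:length(ch$tau)
      ch$tau <- ch$tau[idx]; ch$mR <- ch$mR[idx]
      ch$q <- ch$q[idx]; ch$lam_dep <- ch$lam_dep[idx]
    } else if (!length(keep)) {
      ch$tau <- numeric(0); ch$mR <- numeric(0)
      ch$q <- numeric(0); ch$lam_dep <- numeric(0)
    }
  }
  ch
}

# Append a newly deposited cohort at time tau.
append_cohort <- function(ch, tau, mR, lam_dep) {
  ch$tau <- c(ch$tau, tau)
  ch$mR <- c(ch$mR, mR)
  ch$q <- c(ch$q, 1)
  ch$lam_dep <- c(ch$lam_dep, lam_dep)
  ch
}
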