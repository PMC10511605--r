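#' Pressure protocol
#'
#' \eqn{P(s) = P_o [1 + (f - 1)(1 - e^{-s/T})]}: a smooth rise from the
#' homeostatic pressure to `fold` times it with rise time `rise_days`.
#'
#' @param s G&R time, days (vectorized).
#' @param P_o Homeostatic pressure, kPa.
#' @param fold Pressure fold (>= 1).
#' @param rise_days Exponential rise time, days.
#' @return Pressure, kPa.
#' @export
pressure_protocol <- function(s, P_o, fold, rise_days) {
  P_o * (1 + (fold - 1) * (1 - exp(-s / rise_days)))
}

#' Initialize the coupled model in homeostasis
#'
#' Builds the reference state at `F = identity`: all initial mass sits in
#' per-constituent pools deposited with their deposition stretches, the
#' mixture stress is assembled under plane stress, and the homeostatic
#' pressure is the one equilibrating that stress through the thin-wall
#' Laplace relation, \eqn{P_o = \sigma_{\theta\theta,o} h_o / r_o}
#' (about 14 kPa with the default parameters). The Notch lattice (16 cells
#' at the reference thickness) is relaxed to steady state at the
#' homeostatic strain \eqn{E_{\theta\theta,o} = ((G_\theta^m)^2 - 1)/2}
#' with no external ligands, and its mean NICD is captured as the
#' normalization reference; external ligands configured for the run act
#' from the first step onwards.
#'
#' @param config A [scenario_config()].
#' @return An environment of class `"gr_sim"` holding parameters, cohort
#'   histories, the lattice, homeostatic targets and the current state.
#' @export
initialize_homeostasis <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  params <- cmm_params(config$gains_preset, config$overrides)
  nparams <- do.call(notch_params,
                     c(list(J_sol = config$J_sol, J_im = config$J_im),
                       list(overrides = config$notch_overrides)))
  ds <- config$ds_days

  cohorts <- list(
    collagen = cohort_history("collagen", params$collagen$Phi0 * params$rho,
                              mR0 = params$collagen$ko * params$collagen$Phi0 *
                                params$rho, ds = ds),
    smc = cohort_history("smc", params$smc$Phi0 * params$rho,
                         mR0 = params$smc$ko * params$smc$Phi0 * params$rho,
                         ds = ds))

  sig <- mixture_cauchy(1, cohorts, params, J = 1)
  geo <- wall_geometry(1, 1, params)
  P_o <- sig$sigma_thth * geo$h / geo$r
  if (!is.finite(P_o) || P_o <= 0)
    stop("computed homeostatic pressure is not positive", call. = FALSE)
  f_z <- sig$sigma_zz * pi * geo$h * (2 * geo$r + geo$h)
  E_o <- (params$smc$G[["th"]]^2 - 1) / 2

  # Homeostatic lattice reference: relaxed without external ligands so that
  # configured interventions perturb NICD relative to the control.
  np_ctrl <- nparams; np_ctrl$J_sol <- 0; np_ctrl$J_im <- 0
  lattice <- notch_steady_state(np_ctrl, E_o, tol = 1e-9,
                                M = layer_count(geo$h, params$h_c))
  I_ref <- attr(lattice, "mean_NICD")

  targets <- list(
    P_o = P_o, sigma_tilde_o = stress_measure(sig$sigma_thth, sig$sigma_zz,
                                              config$stress_hypothesis),
    f_z_o = f_z, E_o = E_o, I_ref = I_ref, Q_o = 1, r_o = geo$r)

  sim <- new.env(parent = emptyenv())
  sim$config <- config
  sim$params <- params
  sim$nparams <- nparams
  sim$cohorts <- cohorts
  sim$lattice <- lattice
  sim$targets <- targets
  sim$s <- 0
  sim$lam_theta <- 1
  sim$J <- 1
  sim$h <- geo$h
  sim$r <- geo$r
  sim$P <- P_o
  sim$sigma_thth <- sig$sigma_thth
  sim$sigma_zz <- sig$sigma_zz
  sim$lagrange_p <- sig$lagrange_p
  sim$f_z <- f_z
  sim$delta_sig <- 0
  sim$delta_tau <- 0
  sim$k_prev <- c(collagen = params$collagen$ko, smc = params$smc$ko)
  sim$rhoR <- c(elastin = params$elastin$Phi0 * params$rho,
                collagen = referential_density(cohorts$collagen),
                smc = referential_density(cohorts$smc))
  sim$I_rel <- 1
  sim$ups <- c(N_m = notch_stimulus_smc(1), N_c = notch_stimulus_collagen(1),
               sig_m = 1, sig_c = 1, tau_m = 1, tau_c = 1,
               comb_m = NA_real_, comb_c = NA_real_)
  sim$ups[["comb_m"]] <- combined_stimulus(sim$ups[["N_m"]], 1, 1,
                                           config$variant)
  sim$ups[["comb_c"]] <- combined_stimulus(sim$ups[["N_c"]], 1, 1,
                                           config$variant)
  class(sim) <- "gr_sim"
  sim
}

#' @export
print.gr_sim <- function(x, ...) {
  cat("<gr_sim> s =", x$s, "days; lam_theta =", signif(x$lam_theta, 6),
      "; h =", signif(x$h, 4), "mm; M =", x$lattice$M, "\n")
  invisible(x)
}

#' Solve thin-wall mechanical equilibrium
#'
#' Finds the mixture circumferential stretch at which the assembled wall
#' stress balances the pressure load (root of [laplace_residual()]),
#' bracketing around the current stretch inside `[0.5, 2]` and refining
#' with Brent's method to a stretch tolerance of 1e-10. The axial stretch
#' is fixed at 1 and the radial stretch follows from
#' \eqn{\lambda_r^* = J/\lambda_\theta^*}; the axial force is an output,
#' \eqn{f_z = \sigma_{zz} \pi h (2r + h)}.
#'
#' @param sim A `"gr_sim"` environment.
#' @param P Imposed pressure, kPa.
#' @return List with `lam_theta`, `h`, `r`, `sigma_thth`, `sigma_zz`,
#'   `lagrange_p`, `f_z`. The simulation state is not modified.
#' @export
solve_equilibrium <- function(sim, P) {
  if (P <= 0) stop("pressure must be > 0", call. = FALSE)
  f <- function(l) laplace_residual(l, P, sim$cohorts, sim$params, sim$J)
  lo <- max(0.5, sim$lam_theta - 0.02)
  hi <- min(2.0, sim$lam_theta + 0.02)
  flo <- f(lo); fhi <- f(hi)
  while (flo * fhi > 0) {
    if (lo <= 0.5 && hi >= 2.0)
      stop("no equilibrium bracket in lam_theta [0.5, 2]; residuals ",
           signif(flo, 4), " / ", signif(fhi, 4), " at P = ", signif(P, 5),
           " kPa", call. = FALSE)
    lo <- max(0.5, lo - 0.1); hi <- min(2.0, hi + 0.1)
    flo <- f(lo); fhi <- f(hi)
  }
  root <- stats::uniroot(f, lower = lo, upper = hi, f.lower = flo,
                         f.upper = fhi, tol = 1e-10)$root
  geo <- wall_geometry(root, sim$J, sim$params)
  sig <- mixture_cauchy(root, sim$cohorts, sim$params, sim$J)
  list(lam_theta = root, h = geo$h, r = geo$r,
       sigma_thth = sig$sigma_thth, sigma_zz = sig$sigma_zz,
       lagrange_p = sig$lagrange_p,
       f_z = sig$sigma_zz * pi * geo$h * (2 * geo$r + geo$h))
}

#' Advance the coupled model by one G&R step
#'
#' One step of the coupled loop: impose the protocol pressure, solve
#' mechanical equilibrium, evaluate the stress and shear deviations, update
#' cohort survival with the time-averaged degradation rate, feed the
#' averaged SMC strain to the Notch lattice and advance (or relax) it,
#' resize the lattice to the new layer count, evaluate all stimulus
#' functions under the configured variant, deposit new collagen and SMC
#' cohorts, and recompute referential densities and the volume ratio.
#'
#' @param sim A `"gr_sim"` environment; modified in place.
#' @return `sim`, invisibly.
#' @export
gr_step <- function(sim) {
  cfg <- sim$config
  params <- sim$params
  ds <- cfg$ds_days
  s_new <- sim$s + ds

  P_new <- pressure_protocol(s_new, sim$targets$P_o, cfg$pressure_fold,
                             cfg$pressure_rise_days)
  eq <- solve_equilibrium(sim, P_new)

  sig_tilde <- stress_measure(eq$sigma_thth, eq$sigma_zz,
                              cfg$stress_hypothesis)
  dsig <- delta_sigma(sig_tilde, sim$targets$sigma_tilde_o)
  dtau <- delta_tau(cfg$Q_rel, sim$targets$Q_o, eq$r, sim$targets$r_o)

  k_new <- c(collagen = degradation_rate(dsig, params$collagen$ko),
             smc = degradation_rate(dsig, params$smc$ko))
  kbar <- (sim$k_prev + k_new) / 2
  sim$cohorts$collagen <- update_cohort_survival(sim$cohorts$collagen,
                                                 kbar[["collagen"]], ds)
  sim$cohorts$smc <- update_cohort_survival(sim$cohorts$smc,
                                            kbar[["smc"]], ds)

  E <- smc_strain(sim$cohorts$smc, eq$lam_theta, params$smc$G[["th"]],
                  cfg$lattice_window)
  if (cfg$coupling_mode == "REAL_TIME") {
    sim$lattice <- notch_advance(sim$lattice, sim$nparams, E, 24 * ds)
  } else {
    sim$lattice <- notch_steady_state(sim$nparams, E, tol = 1e-9,
                                      state = sim$lattice)
  }
  sim$lattice <- notch_resize(sim$lattice,
                              layer_count(eq$h, params$h_c))
  I_rel <- nicd_relative(mean(sim$lattice$I), sim$targets$I_ref)

  ups <- c(N_m = notch_stimulus_smc(I_rel),
           N_c = notch_stimulus_collagen(I_rel),
           sig_m = 1 + params$smc$Ksig * dsig,
           sig_c = 1 + params$collagen$Ksig * dsig,
           tau_m = 1 - params$smc$Ktau * dtau,
           tau_c = 1 - params$collagen$Ktau * dtau,
           comb_m = NA_real_, comb_c = NA_real_)
  ups[["comb_m"]] <- combined_stimulus(ups[["N_m"]], ups[["sig_m"]],
                                       ups[["tau_m"]], cfg$variant)
  ups[["comb_c"]] <- combined_stimulus(ups[["N_c"]], ups[["sig_c"]],
                                       ups[["tau_c"]], cfg$variant)

  # forward-Euler convention: production over the step is based on the
  # density at the start of the step (keeps homeostasis bias-free)
  mR_c <- mass_production(k_new[["collagen"]], sim$rhoR[["collagen"]],
                          ups[["comb_c"]])
  mR_m <- mass_production(k_new[["smc"]], sim$rhoR[["smc"]],
                          ups[["comb_m"]])
  sim$cohorts$collagen <- append_cohort(sim$cohorts$collagen, s_new, mR_c,
                                        eq$lam_theta)
  sim$cohorts$smc <- append_cohort(sim$cohorts$smc, s_new, mR_m,
                                   eq$lam_theta)

  sim$rhoR <- c(elastin = params$elastin$Phi0 * params$rho,
                collagen = referential_density(sim$cohorts$collagen),
                smc = referential_density(sim$cohorts$smc))
  sim$J <- sum(sim$rhoR) / params$rho

  sim$s <- s_new
  sim$P <- P_new
  sim$lam_theta <- eq$lam_theta
  sim$h <- eq$h
  sim$r <- eq$r
  sim$sigma_thth <- eq$sigma_thth
  sim$sigma_zz <- eq$sigma_zz
  sim$lagrange_p <- eq$lagrange_p
  sim$f_z <- eq$f_z
  sim$delta_sig <- dsig
  sim$delta_tau <- dtau
  sim$k_prev <- k_new
  sim$I_rel <- I_rel
  sim$ups <- ups
  invisible(sim)
}

record_row <- function(sim) {
  c(s_days = sim$s, P = sim$P, lam_theta = sim$lam_theta, h = sim$h,
    r = sim$r, sigma_thth = sim$sigma_thth, sigma_zz = sim$sigma_zz,
    delta_sigma = sim$delta_sig, delta_tau = sim$delta_tau,
    rhoR_c = sim$rhoR[["collagen"]], rhoR_m = sim$rhoR[["smc"]],
    rhoR_e = sim$rhoR[["elastin"]], NICD = mean(sim$lattice$I),
    ups_N_m = sim$ups[["N_m"]], ups_N_c = sim$ups[["N_c"]],
    ups_sig_m = sim$ups[["sig_m"]], ups_sig_c = sim$ups[["sig_c"]],
    ups_tau_m = sim$ups[["tau_m"]], ups_tau_c = sim$ups[["tau_c"]],
    M = sim$lattice$M, J = sim$J, f_z = sim$f_z)
}

#' Run a full G&R scenario
#'
#' Initializes the homeostatic state and advances the coupled model over
#' the configured horizon. The returned trajectory follows the figure
#' conventions: pressure, thickness, radius, constituent densities and
#' NICD are also reported normalized by their values at `s = 0`
#' (`*_norm` columns).
#'
#' @param config A [scenario_config()] (or the name of a [preset()]).
#' @return A data frame of class `"gr_run"` with one row per G&R step
#'   (including `s = 0`), carrying the resolved `config` and the
#'   homeostatic `targets` as attributes. If `config$output` is set the
#'   trajectory is also written with [write_run()].
#' @examples
#' \donttest{
#' run <- run_scenario(scenario_config(duration_days = 2))
#' tail(run[, c("s_days", "h_norm", "NICD_norm")], 3)
#' }
#' @export
run_scenario <- function(config) {
  if (is.character(config)) config <- preset(config)
  sim <- initialize_homeostasis(config)
  nsteps <- round(config$duration_days / config$ds_days)
  rec <- matrix(NA_real_, nrow = nsteps + 1, ncol = length(record_row(sim)))
  colnames(rec) <- names(record_row(sim))
  rec[1, ] <- record_row(sim)
  for (i in seq_len(nsteps)) {
    gr_step(sim)
    rec[i + 1, ] <- record_row(sim)
    if (config$verbose && (i %% round(10 / config$ds_days) == 0))
      message(sprintf("s = %6.1f d  h_norm %.4f  NICD_norm %.4f  dsig %+.4f",
                      sim$s, sim$h / rec[1, "h"],
                      mean(sim$lattice$I) / sim$targets$I_ref, sim$delta_sig))
  }
  df <- as.data.frame(rec)
  out <- data.frame(
    s_days = df$s_days,
    P_norm = df$P / df$P[1],
    lam_theta = df$lam_theta,
    h_norm = df$h / df$h[1],
    r_norm = df$r / df$r[1],
    sigma_thth = df$sigma_thth,
    sigma_zz = df$sigma_zz,
    delta_sigma = df$delta_sigma,
    delta_tau = df$delta_tau,
    rhoR_c_norm = df$rhoR_c / df$rhoR_c[1],
    rhoR_m_norm = df$rhoR_m / df$rhoR_m[1],
    rhoR_e_norm = df$rhoR_e / df$rhoR_e[1],
    NICD_norm = df$NICD / df$NICD[1],
    ups_N_m = df$ups_N_m, ups_N_c = df$ups_N_c,
    ups_sig_m = df$ups_sig_m, ups_sig_c = df$ups_sig_c,
    ups_tau_m = df$ups_tau_m, ups_tau_c = df$ups_tau_c,
    M = as.integer(df$M),
    P_kPa = df$P, h_mm = df$h, r_mm = df$r, J = df$J, f_z = df$f_z)
  attr(out, "config") <- config
  attr(out, "targets") <- sim$targets
  class(out) <- c("gr_run", "data.frame")
  if (!is.null(config$output)) write_run(out, config$output)
  out
}

#' Homeostatic fixed-point self-check
#'
#' Runs the default parameter set at constant pressure and reports the
#' largest relative drift of wall thickness, constituent densities and mean
#' NICD from their initial values — a numerical health check of the
#' homeostatic construction.
#'
#' @param duration_days Horizon of the check (default 100).
#' @return List with `max_drift` and the per-quantity drifts.
#' @export
homeostasis_check <- function(duration_days = 100) {
  run <- run_scenario(scenario_config(pressure_fold = 1,
                                      duration_days = duration_days))
  last <- run[nrow(run), ]
  drifts <- c(h = abs(last$h_norm - 1),
              rhoR_c = abs(last$rhoR_c_norm - 1),
              rhoR_m = abs(last$rhoR_m_norm - 1),
              NICD = abs(last$NICD_norm - 1))
  list(max_drift = max(drifts), drifts = drifts)
}
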