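# Shared builders for crafted states used across test files.

ref_params <- function(gains = "FIG3_6") cmm_params(gains)

# Reference cohort pair: all mass in the initial pools, one grid point at
# tau = 0 with homeostatic production (the state initialize_homeostasis builds).
ref_cohorts <- function(params = ref_params(), ds = 0.1) {
  list(
    collagen = cohort_history("collagen", params$collagen$Phi0 * params$rho,
                              mR0 = params$collagen$ko * params$collagen$Phi0 *
                                params$rho, ds = ds),
    smc = cohort_history("smc", params$smc$Phi0 * params$rho,
                         mR0 = params$smc$ko * params$smc$Phi0 * params$rho,
                         ds = ds))
}

# A cohort history with no initial pool (and hence no prehistory), with the
# given explicit cohorts.
bare_cohort <- function(label, tau, mR, q, lam_dep, ds = 0.1) {
  ch <- cohort_history(label, rho0 = 0, mR0 = mR[1], ds = ds)
  ch$tau <- tau; ch$mR <- mR; ch$q <- q; ch$lam_dep <- lam_dep
  ch
}

# Independent elastin oracle: Phi * c_e * (lam * G)^2 components.
elastin_oracle <- function(Phi, c_e, G, F_now = c(1, 1, 1), J = 1) {
  Phi * c_e / J * (F_now * G)^2
}
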