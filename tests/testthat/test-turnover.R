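test_that("degradation rate grows quadratically and symmetrically with stress deviation", {
  expect_equal(degradation_rate(0, 0.1), 0.1)
  expect_equal(degradation_rate(1, 0.1), 0.2)
  expect_equal(degradation_rate(-0.5, 0.1), 0.125)
  expect_equal(degradation_rate(0.5, 0.1), degradation_rate(-0.5, 0.1))
  for (d in seq(-2, 2, by = 0.5)) expect_gte(degradation_rate(d, 0.1), 0.1)
  expect_error(degradation_rate(0, 0), "> 0")
})

test_that("incremental survival reproduces the analytic exponential decay", {
  expect_equal(survival_update(0.7, 0, 0.1), 0.7)
  expect_equal(survival_update(1, 0.1, 0.1), exp(-0.01))
  # 100 steps of 0.1 day at k = 0.1/day equal e^-1
  q <- 1
  for (i in 1:100) q <- survival_update(q, 0.1, 0.1)
  expect_equal(q, exp(-1), tolerance = 1e-12)
})

test_that("mass production balances removal at upsilon = 1 and is floored at zero", {
  expect_equal(mass_production(0.1, 2, 1), 0.2)
  expect_equal(mass_production(0.1, 1, 1.5), 0.15)
  expect_equal(mass_production(0.1, 1, 0), 0)
  expect_equal(mass_production(0.1, 1, -3), 0)
})

test_that("referential density: initial value, steady turnover, pure decay", {
  params <- ref_params()
  ch <- ref_cohorts(params)$collagen
  expect_equal(referential_density(ch), params$collagen$Phi0 * params$rho)

  # pure decay: no production after tau = 0, k = 0.1/day over 10 days
  dec <- ch
  dec$mR <- 0
  for (i in 1:100) dec <- notchgr:::update_cohort_survival(dec, 0.1, 0.1)
  expect_equal(referential_density(dec),
               params$collagen$Phi0 * params$rho * exp(-1), tolerance = 1e-12)

  # steady turnover: homeostatic production for 50 days leaves the density flat
  st <- ch
  k <- params$collagen$ko
  for (i in 1:500) {
    rho_start <- referential_density(st)
    st <- notchgr:::update_cohort_survival(st, k, 0.1)
    st <- notchgr:::append_cohort(st, i * 0.1, k * rho_start, 1)
  }
  expect_equal(referential_density(st), params$collagen$Phi0 * params$rho,
               tolerance = 1e-6)
})

test_that("Simpson quadrature of the hereditary integral matches a dense trapezoid oracle", {
  # smoothly varying production and survival over a 50-day window
  s <- 50
  mR <- function(tau) 2 + sin(tau / 5)
  q <- function(tau) exp(-0.08 * (s - tau))
  ch <- bare_cohort("collagen", tau = seq(0, s, by = 0.1),
                    mR = mR(seq(0, s, by = 0.1)),
                    q = q(seq(0, s, by = 0.1)),
                    lam_dep = 1)
  tau_d <- seq(0, s, by = 0.05)
  y <- mR(tau_d) * q(tau_d)
  dense_trap <- sum((y[-1] + y[-length(y)]) / 2) * 0.05
  expect_equal(referential_density(ch), dense_trap, tolerance = 1e-6)
})

test_that("stress measure and deviations follow their definitions", {
  expect_equal(stress_measure(100, 50, "TRACE"), 150)
  expect_equal(stress_measure(100, 50, "CIRC"), 100)
  expect_equal(stress_measure(80, 0, "TRACE"), stress_measure(80, 0, "CIRC"))
  expect_error(stress_measure(1, 1, "BIAXIAL"), "unknown stress hypothesis")

  expect_equal(delta_sigma(426, 426), 0)
  expect_equal(delta_sigma(1.1 * 426, 426), 0.1)
  expect_equal(delta_sigma(0.5 * 426, 426), -0.5)
  expect_error(delta_sigma(1, 0), "> 0")

  expect_equal(delta_tau(1, 1, 0.417, 0.417), 0)
  expect_equal(delta_tau(1, 1, 0.417 * 2^(1 / 3), 0.417), -0.5)
  expect_equal(delta_tau(2, 1, 0.417, 0.417), 1)
})

test_that("Notch stimulus fits are normalized at homeostasis and monotone", {
  expect_equal(notch_stimulus_smc(1), 1, tolerance = 2e-3)   # 0.9988 from fit
  expect_equal(notch_stimulus_smc(0), 47.21)
  expect_equal(notch_stimulus_smc(2), 0.02116, tolerance = 1e-3)
  expect_equal(notch_stimulus_collagen(1), 1)
  expect_equal(notch_stimulus_collagen(0), 0.6839)
  expect_equal(notch_stimulus_collagen(2), 1.3161)
  I <- seq(0, 3, by = 0.1)
  expect_true(all(diff(notch_stimulus_smc(I)) < 0))
  expect_true(all(diff(notch_stimulus_collagen(I)) > 0))
})

test_that("combined stimulus sums terms and honors variant deactivation", {
  expect_equal(combined_stimulus(1, 1, 1, "COMBINED"), 1)
  expect_equal(combined_stimulus(1.2, 1.1, 0.9, "COMBINED"), 1.2)
  expect_equal(combined_stimulus(1.2, 1.7, 0.4, "NOTCH_ONLY"), 1.2)
  expect_equal(combined_stimulus(1.2, 1.1, 0.9, "PHENOM_ONLY"),
               combined_stimulus(1, 1.1, 0.9, "COMBINED"))
  expect_error(combined_stimulus(1, 1, 1, "ALL"), "should be one of")
})

test_that("cohort truncation drops only negligible old cohorts and keeps mass", {
  params <- ref_params()
  ch <- ref_cohorts(params)$collagen
  k <- params$collagen$ko
  for (i in 1:1500) {  # 150 days at k = 0.1/day: pool q0 ~ 3e-7 < 1e-6
    rho_start <- referential_density(ch)
    ch <- notchgr:::update_cohort_survival(ch, k, 0.1)
    ch <- notchgr:::append_cohort(ch, i * 0.1, k * rho_start, 1)
  }
  expect_equal(ch$rho0, 0)               # decayed pool dropped
  expect_true(all(ch$q >= 1e-6))
  expect_gt(ch$tau[1], 0)                # grid truncated from the old end only
  expect_equal(diff(range(diff(ch$tau))), 0, tolerance = 1e-9)  # still uniform
  expect_equal(referential_density(ch), params$collagen$Phi0 * params$rho,
               tolerance = 1e-4)
})
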