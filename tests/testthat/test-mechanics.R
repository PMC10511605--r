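test_that("constituent stretch reproduces hand-evaluated cases", {
  id <- c(1, 1, 1)
  # identity everywhere
  expect_equal(constituent_stretch(id, id, id, c(0, 1, 0)), 1)
  # at reference the SMC stretch equals its circumferential deposition stretch
  expect_equal(constituent_stretch(c(1, 1.17, 1), id, id, c(0, 1, 0)), 1.17)
  # diagonal collagen fiber: lam^2 = (G_th sin phi)^2 + (G_z cos phi)^2
  phi <- 30.7 * pi / 180
  a <- c(0, sin(phi), cos(phi))
  lam <- constituent_stretch(c(1, 1.17, 1.2), id, id, a)
  expect_equal(lam, sqrt((1.17 * sin(phi))^2 + (1.2 * cos(phi))^2))
  expect_equal(lam, 1.1923, tolerance = 1e-4)
  # non-positive components rejected
  expect_error(constituent_stretch(c(1, -1, 1), id, id, a), "must be > 0")
  expect_error(constituent_stretch(id, id, id, c(0, 2, 0)), "unit vector")
})

test_that("Fung fiber stress matches hand evaluations and is odd around lam = 1", {
  expect_equal(fiber_second_pk(1, 343, 1.23), 0)
  expect_equal(fiber_second_pk(1.17, 343, 1.23), 149.6, tolerance = 1e-3)
  expect_equal(fiber_second_pk(1.1923, 450, 3.51), 354.0, tolerance = 1e-3)
  expect_lt(fiber_second_pk(0.9, 450, 3.51), 0)  # compression
  expect_error(fiber_second_pk(0, 450, 3.51), "> 0")
})

test_that("elastin Cauchy stress matches the closed form", {
  G_e <- c(1 / (1.96 * 1.73), 1.96, 1.73)
  sig <- elastin_cauchy(c(1, 1, 1), G_e, 0.079 * 1050, 1050, 114, 1)
  expect_equal(sig, elastin_oracle(0.079, 114, G_e), tolerance = 1e-12)
  expect_equal(sig[2], 34.60, tolerance = 1e-3)
  expect_equal(sig[1], 0.783, tolerance = 1e-2)
  expect_equal(elastin_cauchy(c(1, 1, 1), G_e, 0, 1050, 114, 1), c(0, 0, 0))
  expect_error(elastin_cauchy(c(1, 1, 1), G_e, 1, 1050, 114, 0), "J must be > 0")
})

test_that("mixture stress: elastin-only, linearity in moduli, family symmetry", {
  params <- ref_params()
  # zero collagen/SMC mass: plane stress leaves the elastin deviator
  empty <- list(collagen = bare_cohort("collagen", 0, 0, 1, 1),
                smc = bare_cohort("smc", 0, 0, 1, 1))
  sig <- mixture_cauchy(1, empty, params, 1)
  expect_equal(sig$sigma_thth, 34.5965 - 0.7837, tolerance = 1e-3)
  expect_equal(sig$sigma_rr, 0)
  # doubling all moduli doubles both stresses at fixed deformation
  p2 <- cmm_params(overrides = list(
    elastin = list(c_e = 2 * 114),
    collagen = list(c1 = 2 * 450),
    smc = list(c1 = 2 * 343)))
  ch <- ref_cohorts()
  s1 <- mixture_cauchy(1.05, ch, params, 1)
  s2 <- mixture_cauchy(1.05, ch, p2, 1)
  expect_equal(s2$sigma_thth, 2 * s1$sigma_thth, tolerance = 1e-12)
  expect_equal(s2$sigma_zz, 2 * s1$sigma_zz, tolerance = 1e-12)
  # the +phi and -phi collagen families contribute identically
  expect_equal(s1$by_constituent$collagen_plus,
               s1$by_constituent$collagen_minus, tolerance = 1e-12)
  # empty turnover constituent rejected
  broken <- empty
  broken$smc$tau <- numeric(0)
  expect_error(mixture_cauchy(1, broken, params, 1), "empty cohort history")
})

test_that("single-cohort Simpson assembly equals the closed-form fiber stress", {
  params <- ref_params()
  phi <- 30.7 * pi / 180
  rho <- params$rho
  m <- 0.595 * rho            # all collagen mass in the pool, q = 1
  ch <- list(collagen = cohort_history("collagen", m, mR0 = 0),
             smc = bare_cohort("smc", 0, 0, 1, 1))
  for (lam in c(1, 1.04, 1.1)) {
    sig <- mixture_cauchy(lam, ch, params, 1)
    # independent closed form: (1/rho J) m S(lam_f) (Fn a) x (Fn a), 2 families
    cth <- lam * 1.17 * sin(phi); cz <- 1.2 * cos(phi)
    lam_f <- sqrt(cth^2 + cz^2)
    S <- 450 * (lam_f^2 - 1) * exp(3.51 * (lam_f^2 - 1)^2)
    p_el <- unname(elastin_oracle(0.079, 114, params$elastin$G,
                                  c(1 / lam, lam, 1)))
    expect_equal(sig$sigma_thth, m / rho * S * cth^2 + p_el[2] - p_el[1],
                 tolerance = 1e-12)
    expect_equal(sig$sigma_zz, m / rho * S * cz^2 + p_el[3] - p_el[1],
                 tolerance = 1e-12)
  }
})

test_that("mixture stress vanishes when every constituent sits at its natural state", {
  # deposition stretches of identity: at F = identity nothing is stretched
  p <- cmm_params(overrides = list(
    elastin = list(G = c(r = 1, th = 1, z = 1)),
    collagen = list(G = c(r = 1, th = 1, z = 1)),
    smc = list(G = c(r = 1, th = 1, z = 1))))
  sig <- mixture_cauchy(1, ref_cohorts(p), p, 1)
  expect_equal(sig$sigma_thth, 0, tolerance = 1e-10)
  expect_equal(sig$sigma_zz, 0, tolerance = 1e-10)
})

test_that("Laplace residual: zero at homeostasis, monotone, negative when underloaded", {
  params <- ref_params()
  ch <- ref_cohorts()
  sig <- mixture_cauchy(1, ch, params, 1)
  P_o <- sig$sigma_thth * params$h_o / params$r_o
  expect_equal(laplace_residual(1, P_o, ch, params, 1), 0, tolerance = 1e-9)
  # wall understressed relative to a 50% raised load at lam = 1
  expect_lt(laplace_residual(1, 1.5 * P_o, ch, params, 1), 0)
  # continuous and strictly increasing over the working range
  grid <- seq(0.8, 1.3, by = 0.01)
  res <- vapply(grid, laplace_residual, numeric(1),
                P = P_o, cohorts = ch, params = params, J = 1)
  expect_true(all(diff(res) > 0))
})
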