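#' Stretch of a constituent cohort along its fiber direction
#'
#' A constituent deposited at time \eqn{\tau} carries a constant deposition
#' (pre-)stretch \eqn{G} relative to its stress-free natural configuration.
#' Its current stretch along a material direction `a` is the norm of
#' \eqn{F(s) F^{-1}(\tau) G a}. All deformation gradients here are diagonal
#' (cylindrical symmetry), given as their `(r, th, z)` components.
#'
#' @param dep_stretch Diagonal deposition stretch, length-3 positive vector.
#' @param F_dep Mixture deformation gradient diagonal at deposition time.
#' @param F_now Current mixture deformation gradient diagonal.
#' @param a Unit fiber direction in `(r, th, z)` components.
#' @return The scalar fiber stretch (dimensionless).
#' @examples
#' constituent_stretch(c(1, 1.17, 1), c(1, 1, 1), c(1, 1, 1), c(0, 1, 0))
#' @export
constituent_stretch <- function(dep_stretch, F_dep, F_now, a) {
  stopifnot(length(dep_stretch) == 3, length(F_dep) == 3,
            length(F_now) == 3, length(a) == 3)
  if (any(dep_stretch <= 0) || any(F_dep <= 0) || any(F_now <= 0))
    stop("deformation and deposition stretch components must be > 0",
         call. = FALSE)
  if (abs(sum(a^2) - 1) > 1e-8)
    stop("direction must be a unit vector", call. = FALSE)
  sqrt(sum((F_now / F_dep * dep_stretch * a)^2))
}

#' Fung-type fiber second Piola-Kirchhoff stress
#'
#' Scalar constitutive law for collagen fibers and SMCs,
#' \eqn{\hat S = c_1 (\lambda^2 - 1) \exp[c_2 (\lambda^2 - 1)^2]},
#' negative under compression.
#'
#' @param lam Fiber stretch(es) relative to the natural configuration, > 0.
#' @param c1 Stiffness-like parameter, kPa.
#' @param c2 Dimensionless exponential parameter.
#' @return Stress in kPa, vectorized over `lam`.
#' @examples
#' fiber_second_pk(1.17, 343, 1.23)
#' @export
fiber_second_pk <- function(lam, c1, c2) {
  if (any(lam <= 0)) stop("stretch must be > 0", call. = FALSE)
  e <- lam^2 - 1
  c1 * e * exp(c2 * e^2)
}

#' Elastin Cauchy stress (diagonal components)
#'
#' Elastin does not turn over; its neo-Hookean Cauchy stress contribution is
#' \eqn{\sigma^e = (\rho_R^e c^e / \rho J)\, F G^e G^e F^T}, diagonal for
#' diagonal `F`.
#'
#' @param F_now Current mixture deformation gradient diagonal `(r, th, z)`.
#' @param G_e Elastin deposition stretch diagonal.
#' @param rhoR_e Referential mass density of elastin.
#' @param rho Mixture mass density (same units as `rhoR_e`).
#' @param c_e Shear modulus, kPa.
#' @param J Volume ratio (> 0).
#' @return Length-3 vector of diagonal Cauchy stress components, kPa.
#' @export
elastin_cauchy <- function(F_now, G_e, rhoR_e, rho, c_e, J) {
  if (J <= 0) stop("volume ratio J must be > 0", call. = FALSE)
  if (rhoR_e < 0) stop("referential density must be >= 0", call. = FALSE)
  (rhoR_e * c_e) / (rho * J) * (F_now * G_e)^2
}

# th/z components of the deformed fiber direction F_n a for every cohort of
# a fiber constituent, with lam_z* == 1 at all times.
fiber_components <- function(ch, lam_theta, a_th, a_z) {
  list(
    th0 = lam_theta / ch$lam_dep0 * a_th, z0 = a_z,
    th  = lam_theta / ch$lam_dep  * a_th, z  = a_z)
}

# Hereditary-integral Cauchy stress of one fiber family:
# (mass_frac / rho J) [ rho0 q0 S0 (Fn a)x(Fn a) + Simpson over cohorts ].
# Returns c(thth, zz) in kPa.
fiber_family_cauchy <- function(ch, c1, c2, a_th, a_z, lam_theta, rho, J,
                                mass_frac = 1) {
  cmp <- fiber_components(ch, lam_theta, a_th, a_z)
  pref <- mass_frac / (rho * J)
  s_th <- 0; s_zz <- 0
  if (ch$rho0 > 0) {
    lam0 <- sqrt(cmp$th0^2 + cmp$z0^2)
    S0 <- fiber_second_pk(lam0, c1, c2)
    s_th <- s_th + ch$rho0 * ch$q0 * S0 * cmp$th0^2
    s_zz <- s_zz + ch$rho0 * ch$q0 * S0 * cmp$z0^2
  }
  if (length(ch$tau) > 1) {
    lam <- sqrt(cmp$th^2 + cmp$z^2)
    S <- fiber_second_pk(lam, c1, c2)
    m <- ch$mR * ch$q
    s_th <- s_th + simpson_quad(m * S * cmp$th^2, ch$ds)
    s_zz <- s_zz + simpson_quad(m * S * cmp$z^2, ch$ds)
  }
  c(thth = pref * s_th, zz = pref * s_zz)
}

#' Mixture Cauchy stress under thin-wall plane stress
#'
#' Assembles the circumferential and axial Cauchy stress of the mixture at a
#' given circumferential stretch: a closed-form elastin contribution plus
#' Simpson-rule hereditary integrals over the collagen cohorts (two symmetric
#' fiber families at \eqn{\pm\phi} from axial, each carrying half the
#' collagen mass) and the circumferential SMC cohorts. The Lagrange
#' multiplier of transient incompressibility is fixed by the plane-stress
#' closure \eqn{\sigma_{rr} = 0}; only elastin contributes radially, so
#' \eqn{p} equals the radial elastin extra stress.
#'
#' @param lam_theta Current mixture circumferential stretch \eqn{\lambda_\theta^*}.
#' @param cohorts List with elements `collagen` and `smc`, each a
#'   [cohort_history()].
#' @param params A [cmm_params()] object.
#' @param J Volume ratio \eqn{J = \sum_\alpha \rho_R^\alpha / \rho}.
#' @return List with `sigma_thth`, `sigma_zz`, `sigma_rr` (identically 0),
#'   `lagrange_p` (kPa) and `by_constituent` (per-constituent, per-family
#'   contributions before subtracting `p`).
#' @export
mixture_cauchy <- function(lam_theta, cohorts, params, J) {
  if (J <= 0) stop("volume ratio J must be > 0", call. = FALSE)
  for (cn in c("collagen", "smc")) {
    ch <- cohorts[[cn]]
    if (is.null(ch) || (length(ch$tau) == 0 && ch$rho0 <= 0))
      stop("empty cohort history for turnover constituent '", cn, "'",
           call. = FALSE)
  }
  pe <- params$elastin
  lam_r <- J / lam_theta          # lam_z* == 1
  Fd <- c(lam_r, lam_theta, 1)
  sig_e <- elastin_cauchy(Fd, pe$G, pe$Phi0 * params$rho, params$rho,
                          pe$c_e, J)
  p <- sig_e[[1]]                 # plane stress: sigma_rr = sig_e_rr - p = 0

  pc <- params$collagen
  phi <- pc$phi_deg * pi / 180
  fam_plus <- fiber_family_cauchy(cohorts$collagen, pc$c1, pc$c2,
                                  a_th = pc$G[["th"]] * sin(phi),
                                  a_z  = pc$G[["z"]] * cos(phi),
                                  lam_theta, params$rho, J, mass_frac = 0.5)
  fam_minus <- fiber_family_cauchy(cohorts$collagen, pc$c1, pc$c2,
                                   a_th = pc$G[["th"]] * -sin(phi),
                                   a_z  = pc$G[["z"]] * cos(phi),
                                   lam_theta, params$rho, J, mass_frac = 0.5)
  pm <- params$smc
  smc <- fiber_family_cauchy(cohorts$smc, pm$c1, pm$c2,
                             a_th = pm$G[["th"]], a_z = 0,
                             lam_theta, params$rho, J)

  sigma_thth <- sig_e[[2]] + fam_plus[["thth"]] + fam_minus[["thth"]] +
    smc[["thth"]] - p
  sigma_zz <- sig_e[[3]] + fam_plus[["zz"]] + fam_minus[["zz"]] +
    smc[["zz"]] - p
  list(sigma_thth = sigma_thth, sigma_zz = sigma_zz, sigma_rr = 0,
       lagrange_p = p,
       by_constituent = list(elastin = sig_e, collagen_plus = fam_plus,
                             collagen_minus = fam_minus, smc = smc))
}

#' Thin-wall geometry at a given circumferential stretch
#'
#' Wall thickness \eqn{h = \lambda_r^* h_o} with
#' \eqn{\lambda_r^* = J / (\lambda_\theta^* \lambda_z^*)}, and luminal
#' radius \eqn{r = \lambda_\theta^* (r_o + h_o/2) - h/2}.
#'
#' @inheritParams mixture_cauchy
#' @return List with `h`, `r` (mm) and `lam_r`.
#' @export
wall_geometry <- function(lam_theta, J, params) {
  if (lam_theta <= 0) stop("circumferential stretch must be > 0", call. = FALSE)
  lam_r <- J / lam_theta
  h <- lam_r * params$h_o
  r <- lam_theta * (params$r_o + params$h_o / 2) - h / 2
  if (h <= 0) stop("non-positive wall thickness", call. = FALSE)
  list(h = h, r = r, lam_r = lam_r)
}

#' Laplace equilibrium residual
#'
#' Residual of the thin-wall circumferential equilibrium
#' \eqn{\sigma_{\theta\theta} = P r / h} as a function of the mixture
#' circumferential stretch, with the wall geometry following the stretch.
#' The equilibrium stretch at pressure `P` is its root.
#'
#' @inheritParams mixture_cauchy
#' @param P Luminal pressure, kPa.
#' @return Residual \eqn{\sigma_{\theta\theta}(\lambda_\theta) - P r/h}, kPa.
#' @export
laplace_residual <- function(lam_theta, P, cohorts, params, J) {
  geo <- wall_geometry(lam_theta, J, params)
  sig <- mixture_cauchy(lam_theta, cohorts, params, J)
  sig$sigma_thth - P * geo$r / geo$h
}
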