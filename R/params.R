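#' Constrained mixture parameters for the murine abdominal aorta
#'
#' Returns the reference parameter set of the constrained mixture model
#' (CMM): geometry, mixture mass density, and per-constituent material,
#' deposition-stretch, turnover and gain parameters for elastin, collagen
#' (two symmetric helical fiber families at \eqn{\pm\phi} from the axial
#' direction) and circumferentially oriented smooth muscle cells (SMCs).
#'
#' Two gain presets are available for the phenomenological stimulus
#' functions: `"FIG3_6"` (regression against in vivo hypertensive
#' remodeling; collagen \eqn{K_\sigma = 32.6}, \eqn{K_{\tau w} = 0};
#' SMC 50, 50) and `"FIG2"` (an earlier phenomenological fit; collagen
#' 0.55, 1.65; SMC 0.473, 1.41).
#'
#' Elastin does not turn over and so carries no degradation or gain
#' parameters; its radial deposition stretch is fixed by incompressible
#' deposition, \eqn{G_r^e = 1/(G_\theta^e G_z^e)}.
#'
#' @param gains Gain preset, `"FIG3_6"` (default) or `"FIG2"`.
#' @param overrides Named list of top-level or per-constituent overrides,
#'   e.g. `list(smc = list(Ksig = 0))`. Unknown names are an error.
#' @return A list of class `"cmm_params"` with elements `rho` (mixture mass
#'   density, kg/m^3), `h_o` and `r_o` (reference thickness and luminal
#'   radius, mm), `h_c` (SMC thickness, mm), and per-constituent lists
#'   `elastin`, `collagen`, `smc`.
#' @examples
#' p <- cmm_params()
#' p$collagen$c1      # Fung stiffness, kPa
#' p$elastin$G        # deposition stretch diag(G_r, G_th, G_z)
#' @export
cmm_params <- function(gains = c("FIG3_6", "FIG2"), overrides = list()) {
  gains <- match.arg(gains)
  g <- switch(gains,
    FIG3_6 = list(collagen = c(Ksig = 32.6, Ktau = 0),
                  smc      = c(Ksig = 50,   Ktau = 50)),
    FIG2   = list(collagen = c(Ksig = 0.55,  Ktau = 1.65),
                  smc      = c(Ksig = 0.473, Ktau = 1.41)))

  p <- list(
    rho = 1050,            # kg/m^3, constant true density of every constituent
    h_o = 0.032,           # mm
    r_o = 0.417,           # mm
    h_c = 0.002,           # mm, SMC thickness (16 layers at h_o)
    gains_preset = gains,
    elastin = list(
      label = "elastin",
      c_e   = 114,         # kPa, neo-Hookean shear modulus
      G     = c(r = 1 / (1.96 * 1.73), th = 1.96, z = 1.73),
      Phi0  = 0.079),
    collagen = list(
      label = "collagen",
      c1 = 450, c2 = 3.51, # kPa, -
      G  = c(r = 1, th = 1.17, z = 1.2),
      phi_deg = 30.7,      # fiber angle from the axial direction
      ko = 1 / 10,         # 1/day
      Ksig = unname(g$collagen["Ksig"]),
      Ktau = unname(g$collagen["Ktau"]),
      Phi0 = 0.595),
    smc = list(
      label = "smc",
      c1 = 343, c2 = 1.23,
      G  = c(r = 1, th = 1.17, z = 1),  # acts circumferentially only
      ko = 1 / 10,
      Ksig = unname(g$smc["Ksig"]),
      Ktau = unname(g$smc["Ktau"]),
      Phi0 = 0.326)
  )
  p <- apply_overrides(p, overrides)
  validate_cmm_params(p)
  class(p) <- "cmm_params"
  p
}

apply_overrides <- function(p, overrides) {
  stopifnot(is.list(overrides))
  for (nm in names(overrides)) {
    if (!nm %in% names(p))
      stop("unknown parameter override: ", nm, call. = FALSE)
    if (is.list(overrides[[nm]])) {
      for (sub in names(overrides[[nm]])) {
        if (!sub %in% names(p[[nm]]))
          stop("unknown parameter override: ", nm, "$", sub, call. = FALSE)
        p[[nm]][[sub]] <- overrides[[nm]][[sub]]
      }
    } else {
      p[[nm]] <- overrides[[nm]]
    }
  }
  p
}

validate_cmm_params <- function(p) {
  bad <- character(0)
  chk <- function(cond, msg) if (!isTRUE(cond)) bad <<- c(bad, msg)
  chk(p$rho > 0, "rho must be > 0")
  chk(p$h_o > 0 && p$r_o > 0 && p$h_c > 0, "geometry must be > 0")
  for (cn in c("collagen", "smc")) {
    cc <- p[[cn]]
    chk(cc$c1 > 0 && cc$c2 > 0, paste(cn, "Fung parameters must be > 0"))
    chk(cc$ko > 0, paste(cn, "base degradation rate must be > 0"))
    chk(all(cc$G > 0), paste(cn, "deposition stretches must be > 0"))
  }
  chk(all(p$elastin$G > 0) && p$elastin$c_e > 0, "elastin parameters must be > 0")
  chk(abs(p$elastin$G[["r"]] * p$elastin$G[["th"]] * p$elastin$G[["z"]] - 1) < 1e-10,
      "elastin deposition stretch must satisfy G_r = 1/(G_th * G_z)")
  phis <- c(p$elastin$Phi0, p$collagen$Phi0, p$smc$Phi0)
  chk(all(phis >= 0 & phis <= 1), "mass fractions must lie in [0, 1]")
  chk(abs(sum(phis) - 1) < 1e-8, "mass fractions must sum to 1")
  if (length(bad))
    stop("invalid mixture parameters:\n  ", paste(bad, collapse = "\n  "),
         call. = FALSE)
  invisible(p)
}

#' Notch-Jagged-Delta lattice parameters
#'
#' Reference parameter set for the juxtacrine signaling model on the radial
#' SMC array: production rates of Notch, Jagged and Delta, trans-activation
#' and cis-inhibition rates, degradation rates of free proteins and of the
#' Notch intracellular domain (NICD), the Hill autoregulation parameters,
#' the strain sensitivities of Notch and Jagged production, constant
#' external soluble/immobilized Jagged ligand contents, and the explicit
#' integration step.
#'
#' @param J_sol,J_im Constant number of external soluble / immobilized
#'   Jagged ligands available per SMC (default 0).
#' @param overrides Named list of overrides of any other field.
#' @return List of class `"notch_params"`.
#' @examples
#' np <- notch_params(J_im = 100)
#' np$A_N   # strain sensitivity of Notch production
#' @export
notch_params <- function(J_sol = 0, J_im = 0, overrides = list()) {
  p <- list(
    N_pr = 1400, J_pr = 1600, D_pr = 100,  # counts / h
    k_t = 2.5e-5, k_c = 5.0e-5,            # 1 / (count h)
    gamma = 0.1, gamma_I = 0.5,            # 1 / h
    I0 = 200,
    p_N = 2.0, p_J = 5.0, p_D = 2.0,
    Lam_N = 2.0, Lam_J = 2.0, Lam_D = 0.0,
    A_N = -5.79, A_J = -4.17,              # per unit Green-Lagrange strain
    J_sol = J_sol, J_im = J_im,
    dt = 0.05                              # h, explicit Euler step
  )
  p <- apply_overrides(p, overrides)
  bad <- character(0)
  rates <- c(p$N_pr, p$J_pr, p$D_pr, p$k_t, p$k_c, p$gamma, p$gamma_I)
  if (!all(rates >= 0)) bad <- c(bad, "rates must be >= 0")
  if (!(p$I0 > 0)) bad <- c(bad, "I0 must be > 0")
  if (!(p$dt > 0)) bad <- c(bad, "dt must be > 0")
  if (p$J_sol < 0 || p$J_im < 0) bad <- c(bad, "external ligand contents must be >= 0")
  if (length(bad))
    stop("invalid Notch parameters:\n  ", paste(bad, collapse = "\n  "),
         call. = FALSE)
  class(p) <- "notch_params"
  p
}
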