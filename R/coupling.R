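#' Circumferential Green-Lagrange strain of the SMCs
#'
#' The per-cohort circumferential SMC stretches
#' \eqn{\lambda^m_{n(\tau)}(s) = \lambda_\theta^*(s)/\lambda_\theta^*(\tau)
#' \cdot G_\theta^m} are averaged arithmetically over the most recent
#' `window` cohorts (the initial pool counting as one cohort), and the
#' strain formula \eqn{E_{\theta\theta} = (\lambda_\theta^2 - 1)/2} is then
#' applied to the averaged stretch. Older cohorts are excluded because most
#' of their material has been removed.
#'
#' The initial pool stands in for the homeostatic prehistory: cohorts
#' deposited before the start of the simulation, all in the reference
#' configuration. It therefore contributes `window - n` virtual cohorts at
#' the pool deposition stretch while fewer than `window` post-start cohorts
#' exist, so the averaging window fills gradually exactly as it would had
#' the prehistory been stored cohort by cohort. A history constructed with
#' `rho0 = 0` has no prehistory and only its explicit cohorts are averaged.
#'
#' @param ch SMC [cohort_history()].
#' @param lam_theta_now Current mixture circumferential stretch.
#' @param G_th Circumferential SMC deposition stretch.
#' @param window Number of most recent cohorts averaged (default 2000).
#' @return Green-Lagrange strain (dimensionless).
#' @export
smc_strain <- function(ch, lam_theta_now, G_th, window = 2000) {
  lams <- if (length(ch$tau)) lam_theta_now / ch$lam_dep * G_th else numeric(0)
  lams <- utils::tail(lams, window)
  n_pre <- if (isTRUE(ch$prehistory)) max(0, window - length(lams)) else 0
  n_tot <- n_pre + length(lams)
  if (n_tot == 0)
    stop("no SMC cohorts available for strain averaging", call. = FALSE)
  lam_pre <- lam_theta_now / ch$lam_dep0 * G_th
  lam_bar <- (n_pre * lam_pre + sum(lams)) / n_tot
  (lam_bar^2 - 1) / 2
}

#' Number of SMC layers across the wall
#'
#' `M = round(h / h_c)`, floored at one cell; `h_c` is the SMC thickness
#' (2 um by default), giving 16 layers at the reference thickness of
#' 0.032 mm.
#'
#' @param h Wall thickness, mm.
#' @param h_c SMC thickness, mm.
#' @return Integer cell count (>= 1).
#' @export
layer_count <- function(h, h_c = 0.002) {
  stopifnot(h > 0, h_c > 0)
  max(1L, as.integer(round(h / h_c)))
}

#' NICD content relative to its homeostatic mean
#'
#' The in-vitro-fitted Notch stimulus functions take relative expression as
#' input (value 1 at homeostasis), so the lattice mean NICD is normalized by
#' the homeostatic mean captured once at initialization.
#'
#' @param I_mean Current lattice mean NICD (count).
#' @param I_ref Homeostatic mean NICD (count, > 0).
#' @return Relative NICD content.
#' @export
nicd_relative <- function(I_mean, I_ref) {
  if (is.null(I_ref) || !is.finite(I_ref) || I_ref <= 0)
    stop("homeostatic NICD reference is unset; initialize first",
         call. = FALSE)
  I_mean / I_ref
}
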