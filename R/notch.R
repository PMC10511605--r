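#' Notch lattice state
#'
#' Per-cell contents of Notch receptors (`N`), Jagged ligands (`J`),
#' Delta ligands (`D`) and NICD (`I`) for a one-dimensional radial array of
#' `M` SMCs. Contents are molecule counts (dimensionless, >= 0).
#'
#' @param M Number of cells (>= 1).
#' @param N,J,D,I Initial contents, scalars or length-`M` vectors.
#' @return List of class `"notch_state"` with fields `N`, `J`, `D`, `I`, `M`.
#' @export
notch_state <- function(M, N = 0, J = 0, D = 0, I = 0) {
  M <- as.integer(M)
  stopifnot(M >= 1)
  st <- list(N = rep_len(N, M), J = rep_len(J, M),
             D = rep_len(D, M), I = rep_len(I, M), M = M)
  if (any(unlist(st[c("N", "J", "D", "I")]) < 0))
    stop("contents must be >= 0", call. = FALSE)
  structure(st, class = "notch_state")
}

#' @export
print.notch_state <- function(x, ...) {
  cat("<notch_state> M =", x$M, "cells; mean contents:",
      sprintf("N %.1f, J %.1f, D %.1f, NICD %.2f",
              mean(x$N), mean(x$J), mean(x$D), mean(x$I)), "\n")
  invisible(x)
}

#' Shifted Hill autoregulation function
#'
#' \eqn{H_S(I, \Lambda, p) = \Lambda + (1 - \Lambda) / (1 + (I/I_0)^p)}:
#' equals 1 at `I = 0` and tends to \eqn{\Lambda} as `I` grows, so
#' \eqn{\Lambda > 1} is trans-activation-driven upregulation and
#' \eqn{\Lambda < 1} downregulation.
#'
#' @param I NICD content (>= 0), vectorized.
#' @param Lambda Asymptotic fold change.
#' @param p Hill exponent (> 0).
#' @param I0 Transition NICD content (> 0).
#' @return Dimensionless factor between `min(1, Lambda)` and `max(1, Lambda)`.
#' @export
hill <- function(I, Lambda, p, I0) {
  stopifnot(all(I >= 0), I0 > 0, p > 0)
  Lambda + (1 - Lambda) / (1 + (I / I0)^p)
}

# Neighbor mean with mirror (zero-flux) boundaries: the missing neighbor of
# an end cell is replaced by its existing neighbor; a single cell sees itself.
neighbor_mean <- function(x) {
  M <- length(x)
  if (M == 1) return(x)
  left <- x[c(2L, seq_len(M - 1L))]    # x[j-1], mirrored at j = 1
  right <- x[c(seq_len(M - 1L) + 1L, M - 1L)]  # x[j+1], mirrored at j = M
  (left + right) / 2
}

#' Right-hand side of the Notch lattice ODEs
#'
#' Rate equations for Notch, Jagged, Delta and NICD in every cell:
#' strain-modulated production of Notch and Jagged
#' (\eqn{e^{A_N E_{\theta\theta}}}, \eqn{e^{A_J E_{\theta\theta}}};
#' Delta production is strain-independent), Hill autoregulation by NICD,
#' cis-inhibition between receptors and ligands of the same cell,
#' trans-interaction with the neighbor average of the adjacent cells, and
#' first-order degradation. External soluble Jagged ligands sequester Notch
#' without signaling; immobilized Jagged ligands bind Notch and release
#' NICD.
#'
#' @param state A [notch_state()].
#' @param params A [notch_params()].
#' @param E_thth Circumferential Green-Lagrange strain of the SMCs.
#' @return List with per-cell derivatives `N`, `J`, `D`, `I` (counts/h).
#' @export
notch_rhs <- function(state, params, E_thth) {
  stopifnot(is.finite(E_thth))
  p <- params
  N <- state$N; J <- state$J; D <- state$D; I <- state$I
  nbN <- neighbor_mean(N); nbJ <- neighbor_mean(J); nbD <- neighbor_mean(D)
  dN <- p$N_pr * exp(p$A_N * E_thth) * hill(I, p$Lam_N, p$p_N, p$I0) -
    p$k_c * N * (D + J) - p$k_t * N * (nbD + nbJ) -
    p$k_t * N * (p$J_sol + p$J_im) - p$gamma * N
  dJ <- p$J_pr * exp(p$A_J * E_thth) * hill(I, p$Lam_J, p$p_J, p$I0) -
    p$k_c * J * N - p$k_t * J * nbN - p$gamma * J
  dD <- p$D_pr * hill(I, p$Lam_D, p$p_D, p$I0) -
    p$k_c * D * N - p$k_t * D * nbN - p$gamma * D
  dI <- p$k_t * N * (nbD + nbJ) + p$k_t * N * p$J_im - p$gamma_I * I
  list(N = dN, J = dJ, D = dD, I = dI)
}

#' Advance the Notch lattice in time
#'
#' Forward-Euler integration with the fixed substep `params$dt` (0.05 h by
#' default) and the strain held constant; contents are clamped at zero after
#' every substep (Euler can overshoot; counts are non-negative).
#'
#' @inheritParams notch_rhs
#' @param duration Time to advance, hours; must be a non-negative multiple
#'   of `params$dt`.
#' @return The advanced [notch_state()].
#' @export
notch_advance <- function(state, params, E_thth, duration) {
  nsub <- duration / params$dt
  if (duration < 0 || abs(nsub - round(nsub)) > 1e-8)
    stop("duration must be a non-negative multiple of dt", call. = FALSE)
  nsub <- round(nsub)
  p <- params
  dt <- p$dt
  # inlined right-hand side (kept identical to notch_rhs; see tests)
  N <- state$N; J <- state$J; D <- state$D; I <- state$I
  M <- state$M
  li <- if (M > 1) c(2L, seq_len(M - 1L)) else 1L
  ri <- if (M > 1) c(seq_len(M - 1L) + 1L, M - 1L) else 1L
  prodN <- p$N_pr * exp(p$A_N * E_thth)
  prodJ <- p$J_pr * exp(p$A_J * E_thth)
  for (k in seq_len(nsub)) {
    nbN <- (N[li] + N[ri]) / 2
    nbJ <- (J[li] + J[ri]) / 2
    nbD <- (D[li] + D[ri]) / 2
    hN <- p$Lam_N + (1 - p$Lam_N) / (1 + (I / p$I0)^p$p_N)
    hJ <- p$Lam_J + (1 - p$Lam_J) / (1 + (I / p$I0)^p$p_J)
    hD <- p$Lam_D + (1 - p$Lam_D) / (1 + (I / p$I0)^p$p_D)
    dN <- prodN * hN - p$k_c * N * (D + J) - p$k_t * N * (nbD + nbJ) -
      p$k_t * N * (p$J_sol + p$J_im) - p$gamma * N
    dJ <- prodJ * hJ - p$k_c * J * N - p$k_t * J * nbN - p$gamma * J
    dD <- p$D_pr * hD - p$k_c * D * N - p$k_t * D * nbN - p$gamma * D
    dI <- p$k_t * N * (nbD + nbJ) + p$k_t * N * p$J_im - p$gamma_I * I
    N <- pmax.int(N + dt * dN, 0)
    J <- pmax.int(J + dt * dJ, 0)
    D <- pmax.int(D + dt * dD, 0)
    I <- pmax.int(I + dt * dI, 0)
  }
  for (sp in c("N", "J", "D", "I")) {
    x <- switch(sp, N = N, J = J, D = D, I = I)
    if (any(!is.finite(x)))
      stop("numeric instability in species ", sp, " at cell ",
           which(!is.finite(x))[1], call. = FALSE)
  }
  state$N <- N; state$J <- J; state$D <- D; state$I <- I
  state
}

#' Relax the Notch lattice to steady state
#'
#' Integrates at fixed strain until the scaled update
#' \eqn{|dX/dt|\, dt / \max(X, 1)} falls below `tol` for every cell and
#' species.
#'
#' @inheritParams notch_rhs
#' @param tol Convergence tolerance (default 1e-9).
#' @param state Optional warm-start state (defaults to an empty lattice of
#'   `M` cells).
#' @param M Lattice size used when `state` is not given.
#' @param max_hours Step budget; exceeded budget is an error.
#' @return Converged [notch_state()] with the mean NICD in attribute
#'   `"mean_NICD"`.
#' @export
notch_steady_state <- function(params, E_thth, tol = 1e-9, state = NULL,
                               M = 16, max_hours = 20000) {
  if (tol <= 0) stop("tol must be > 0", call. = FALSE)
  if (is.null(state)) state <- notch_state(M)
  dt <- params$dt
  chunk <- 20  # hours between convergence checks
  elapsed <- 0
  repeat {
    state <- notch_advance(state, params, E_thth, chunk)
    elapsed <- elapsed + chunk
    d <- notch_rhs(state, params, E_thth)
    crit <- max(vapply(c("N", "J", "D", "I"), function(sp)
      max(abs(d[[sp]]) * dt / pmax(state[[sp]], 1)), numeric(1)))
    if (crit < tol) break
    if (elapsed > max_hours)
      stop("Notch lattice failed to reach steady state within ",
           max_hours, " h (criterion ", signif(crit, 3), ")", call. = FALSE)
  }
  attr(state, "mean_NICD") <- mean(state$I)
  state
}

#' Resize the lattice as the wall thickens or thins
#'
#' New cells are appended at the outer end, initialized to the current
#' lattice mean of each species; on shrinkage, outer-end cells are removed.
#' Retained cells are untouched.
#'
#' @param state A [notch_state()].
#' @param M_new Target cell count (>= 1).
#' @return Resized [notch_state()].
#' @export
notch_resize <- function(state, M_new) {
  M_new <- as.integer(M_new)
  stopifnot(M_new >= 1)
  if (M_new == state$M) return(state)
  for (sp in c("N", "J", "D", "I")) {
    x <- state[[sp]]
    if (M_new > state$M) {
      state[[sp]] <- c(x, rep(mean(x), M_new - state$M))
    } else {
      state[[sp]] <- x[seq_len(M_new)]
    }
  }
  state$M <- M_new
  state
}
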