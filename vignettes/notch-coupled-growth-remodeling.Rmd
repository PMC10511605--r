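---
title: "Notch-coupled arterial growth and remodeling: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Notch-coupled arterial growth and remodeling: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`notchgr` simulates the slow adaptation of an artery to altered loading by
coupling two well-separated scales: a constrained mixture model (CMM) of the
wall, evolving over days to months, and a Notch–Jagged–Delta signaling model
among smooth muscle cells (SMCs), evolving over hours. This vignette is the
package's own account of the model, its assumptions, the numerical choices,
and what the shipped tests do and do not establish.

## Tissue scale: constrained mixture mechanics

The wall is a thin-walled cylinder made of elastin, collagen and SMCs that
deform together but are produced and removed individually, each with its own
stress-free (natural) configuration. The mixture deformation from the
homeostatic reference is `diag(lam_r*, lam_th*, lam_z*)` with the axial
stretch pinned at 1 (the vessel is tethered axially; the axial force is an
output, never a constraint). A constituent deposited at G&R time `tau`
carries a constant deposition prestretch `G` and is stretched at time `s` by
`lam = |F(s) F(tau)^-1 G a|` along its fiber direction `a`: collagen forms
two symmetric helical families at 30.7 degrees from the axial direction, the
total collagen mass split equally between them (the split is bookkeeping
only; the families contribute identically by symmetry), and SMCs act purely
circumferentially.

Elastin does not turn over and contributes a neo-Hookean stress; collagen
and SMC cohorts contribute through a Fung-type fiber law
`c1 (lam^2 - 1) exp[c2 (lam^2 - 1)^2]` weighted by production and survival
in a hereditary integral. Transient incompressibility closes under
plane stress: the Lagrange multiplier equals the radial elastin stress, so
the assembled radial stress is exactly zero at every solved state.

**Volume ratio.** Between G&R times the tissue is incompressible, but
across G&R times mass is added and removed at constant true density, so the
reference-volume ratio is `J(s) = sum(rhoR_alpha) / rho` and the radial
stretch follows as `lam_r* = J / (lam_th* lam_z*)`. A literal reading in
which `lam_r* = 1/(lam_th* lam_z*)` at all G&R times would freeze `J` at 1
and forbid any growth-driven thickening; we therefore apply that relation
only to the (instantaneous) transient response, which is what makes the
predicted wall thickening possible at all.

## Turnover kinetics

Survival decays as `q(s, tau) = exp(-int k dt)` with
`k = ko (1 + delta_sigma^2)`: any deviation of the intramural stress
measure from its homeostatic target accelerates removal symmetrically.
Production is `mR = k * rhoR * Upsilon`, so at `Upsilon = 1` production
exactly balances nominal removal. The combined stimulus

```
Upsilon = Upsilon_N + Upsilon_sigma + Upsilon_tauw - 2
```

adds a mechanistic Notch term to the two classical phenomenological terms
`1 + K_sigma * delta_sigma` and `1 - K_tauw * delta_tau`. Model variants
replace deactivated terms by 1 (`PHENOM_ONLY` forces `Upsilon_N = 1`;
`NOTCH_ONLY` forces both phenomenological terms to 1) so the remaining
terms keep their homeostatic normalization. `Upsilon` may go negative when
a large Notch term collides with strongly negative phenomenological terms;
production is floored at zero because removal is already handled by the
survival function, and negative deposition has no physical meaning.

Two intramural stress measures are supported: the plane-stress trace
(`TRACE`, circumferential plus axial) and the circumferential stress alone
(`CIRC`). Deviations are evaluated at the imposed (systolic) pressure of
each step. Wall shear stress follows Poiseuille scaling,
`delta_tau = Q r_o^3 / (Q_o r^3) - 1`, with flow held constant in all
presets so only the radius moves it.

## Cell scale: the Notch lattice

One radial column of `M` cells is tracked, `M = round(h / h_c)` with
`h_c = 2 um` (16 cells at the reference thickness). Per cell, four ODEs
govern Notch, Jagged, Delta and NICD: production with Hill-type
autoregulation by NICD, cis-inhibition within a cell, trans-activation with
the arithmetic mean of the two neighbors, first-order degradation, and
external Jagged ligands at constant content — soluble ligands bind Notch
without signaling (pure sink), immobilized ligands bind and release NICD.
Notch and Jagged production are modulated by `exp(A_N * E)` and
`exp(A_J * E)` with `E` the circumferential Green–Lagrange strain of the
SMCs and both sensitivities negative; Delta production is
strain-independent.

Boundary cells lack one neighbor; the missing neighbor's contribution is
replaced by the existing neighbor's (mirror, zero-flux), which preserves
each cell's interaction capacity. A consequence worth knowing: a uniform
lattice is exactly uniform at steady state, so the mean NICD is independent
of `M` for homogeneous strain — the lattice-size insensitivity asserted in
the tests is exact here, not approximate. Cells appended when the wall
thickens are initialized to the lattice mean of each species to avoid
injection transients; removal takes cells from the outer end.

## Coupling

Tissue to cell: the strain input is computed from the per-cohort SMC
stretches averaged *as stretches* (mean first, then
`E = (lam^2 - 1)/2`) over the 2000 most recently deposited cohorts. The
initial mass pool stands in for the homeostatic prehistory and contributes
`2000 - n` virtual cohorts at reference deposition until enough real
cohorts exist. This matters: if the pool counted as a single cohort, newly
deposited cohorts (laid down at the current, already-distended
configuration) would dominate the average within days, the strain signal
would renormalize almost immediately, and the sustained Notch response —
the mechanism behind both the SMC-driven thickening and the axial-stress
runaway under the `TRACE` hypothesis — could not develop.

Cell to tissue: the lattice mean NICD, normalized by its homeostatic mean
`I_ref`, feeds the fitted stimulus functions
`Upsilon_N^m = 47.21 exp(-3.855 I)` (SMC proliferation; lower Notch
activity promotes proliferation) and
`Upsilon_N^c = 0.3161 (I - 1) + 1` (collagen synthesis; higher Notch
activity promotes synthesis), both equal to 1 at `I = 1` up to fit
rounding. `I_ref` is captured once, at initialization, from a lattice
relaxed *without* external ligands, so that configured Jagged interventions
perturb NICD relative to the untreated control rather than being absorbed
into the normalization.

Each 0.1-day G&R step advances the lattice by 2.4 h of wall-clock time at
frozen strain (`REAL_TIME`, the default). Because the slowest lattice
relaxation time (~10 h, set by the degradation rate 0.1/h) is comparable to
the step, a `QUASI_STEADY` mode that relaxes the lattice fully each step is
also available and selectable in the configuration; the two modes differ
visibly only during fast transients.

## Numerics

* **G&R step** 0.1 days, fixed; adaptive stepping would change the cohort
  grid semantics. One step runs: protocol pressure, equilibrium solve,
  stress/shear deviations, survival update, lattice advance and resize,
  stimulus evaluation, cohort deposition, density and `J` update.
* **Equilibrium** is a bracketed scalar root of the Laplace residual
  `sigma_thth(lam) - P r(lam)/h(lam)` in `lam_th* in [0.5, 2]` (the
  residual is strictly increasing over the working range), warm-started at
  the previous solution and refined with Brent's method to a stretch
  tolerance of 1e-10. The axial force follows explicitly once the root is
  known, which is algebraically equivalent to solving the two equilibrium
  equations simultaneously.
* **Hereditary integrals** use the composite Simpson rule on the uniform
  cohort grid, with a trapezoid closing panel when the number of intervals
  is odd (the grid alternates parity every step).
* **Survival** is updated incrementally with the time-averaged degradation
  rate over the step (mean of the endpoint rates); cohorts whose survival
  falls below 1e-6 are dropped from the old end of the grid, bounding
  memory at roughly 1400 cohorts with the default turnover while keeping
  the grid uniform.
* **Production closure**: the density entering `mR` is the density at the
  start of the step (forward-Euler convention). Evaluating it after the
  survival update instead leaves a systematic O(ds) underproduction bias
  that accumulates to percent-level drift at homeostasis; with the
  start-of-step convention the homeostatic state drifts by about 1e-5 over
  100 days.
* **Lattice integration**: explicit Euler with a 0.05 h substep, contents
  clamped at zero after each substep (clamping never engages near
  homeostatic strains with the default rates; a test asserts this). The
  steady state is declared when `|dX| dt / max(X, 1)` falls below 1e-9 for
  every cell and species.

## Study conditions and scenario presets

Parameter defaults are the murine infrarenal abdominal aorta set shipped
with the package (`cmm_params()`, `notch_params()`), including both gain
presets for the phenomenological stimuli (`FIG2`: collagen 0.55/1.65, SMC
0.473/1.41; `FIG3_6`: collagen 32.6/0, SMC 50/50). The pressure protocol
`P = P_o (1 + (f - 1)(1 - exp(-s/T)))` with default fold 1.5 and rise time
4 days mimics the shape of experimentally observed hypertensive profiles;
the fold and rise time are configuration values, not measured quantities.
The homeostatic pressure is never imposed: it is computed from the
reference composition so the run starts in exact mechanical equilibrium
(13.5 kPa with the defaults, near the nominal 14.4 kPa for this vessel).

The Jagged intervention presets use doses of 150–300 immobilized and
1500–3000 soluble ligands per cell. These were chosen once so that the
lattice-scale NICD shifts (roughly 2–10%) are commensurate with the NICD
excursion hypertension itself produces, with the soluble doses an order of
magnitude above the immobilized ones in line with the much weaker per-ligand
effect of a pure receptor sink; they are model inputs, not measured
concentrations.

Default scenario horizons are 100 days (variant and intervention runs) and
200 days (stress-hypothesis runs, which need the longer window for the
collagen runaway to complete); the test suite uses these same horizons, and
the lattice sizes exercised are 8–32 cells.

## What the tests show — and what they do not

The suite verifies the homeostatic fixed point (sub-0.5% drift over 100
days at constant pressure), the signed chain pressure → stretch → lower
NICD → more SMC proliferation and less collagen synthesis, the qualitative
divergence of the two stress hypotheses (collagen runaway under `TRACE`,
compositional stability under `CIRC`), growth to a thicker plateau with a
transient Notch dip under the combined model, muscle-heavy growth under
`NOTCH_ONLY`, monotone and oppositely signed dose responses to the two
external ligand types, and agreement of the quadrature and integrators with
closed-form oracles.

These are statements about the model, not the animal. The wall is a single
thin-walled layer with no residual-stress analysis and no radial stress
gradient; SMC active (contractile) stress is not modeled; endothelial
shear-stress signaling to Notch, inflammation, and receptor subtypes are
absent; the lattice is one-dimensional and all cells feel the same
mixture-level strain. Within the model, radius regulation is weak — the
Notch drive pulls toward the original SMC stretch rather than toward a
shear-set radius — so predicted luminal radius changes should be read with
particular caution.

## Degenerate inputs and edge behavior

Non-positive stretches, volume ratios, thicknesses, rates or targets raise
immediate errors rather than propagating; an equilibrium bracket failure
reports the residuals at both bracket ends and the pressure; lattice
divergence names the offending cell and species; configuration validation
reports every violated field at once. A cohort history that loses its pool
and all cohorts to truncation is an invalid state for stress assembly and
is rejected.
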