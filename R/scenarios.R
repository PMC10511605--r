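#' Scenario configuration
#'
#' Builds and validates the full configuration of a G&R run: gain preset,
#' intramural stress hypothesis, model variant, pressure protocol, external
#' Jagged intervention, cell-tissue coupling mode, and numerics. All
#' violations are reported together with field-level messages.
#'
#' The pressure protocol is
#' \eqn{P(s) = P_o [1 + (f - 1)(1 - e^{-s/T})]} with fold `pressure_fold`
#' and rise time `pressure_rise_days`; the defaults (1.5, 4 days) mimic the
#' shape of an experimentally observed hypertensive profile but are not
#' measured values.
#'
#' @param stress_hypothesis `"CIRC"` (circumferential stress only, default)
#'   or `"TRACE"` (circumferential plus axial).
#' @param variant `"COMBINED"` (default), `"PHENOM_ONLY"` or `"NOTCH_ONLY"`.
#' @param gains_preset `"FIG3_6"` or `"FIG2"`; if `NULL`, resolved to
#'   `"FIG2"` under the TRACE hypothesis and `"FIG3_6"` otherwise.
#' @param pressure_fold Fold increase of pressure over baseline (>= 1;
#'   1 gives a constant-pressure run).
#' @param pressure_rise_days Exponential rise time of the protocol, days.
#' @param duration_days Simulated horizon, days (> 0).
#' @param J_sol,J_im Constant external soluble / immobilized Jagged ligands
#'   per SMC (>= 0).
#' @param coupling_mode `"REAL_TIME"` (lattice advanced by the wall-clock
#'   duration of each G&R step, default) or `"QUASI_STEADY"` (lattice
#'   relaxed to steady state every step).
#' @param Q_rel Flow relative to baseline (constant; default 1).
#' @param ds_days G&R step, days (default 0.1).
#' @param lattice_window Number of most recent SMC cohorts averaged for the
#'   strain input (default 2000).
#' @param overrides Named list of mixture parameter overrides passed to
#'   [cmm_params()].
#' @param notch_overrides Named list of overrides passed to [notch_params()].
#' @param output Optional output path stem for [write_run()].
#' @param verbose Log one line per simulated 10 days.
#' @return List of class `"scenario_config"`.
#' @export
scenario_config <- function(stress_hypothesis = "CIRC",
                            variant = "COMBINED",
                            gains_preset = NULL,
                            pressure_fold = 1.5,
                            pressure_rise_days = 4,
                            duration_days = 100,
                            J_sol = 0, J_im = 0,
                            coupling_mode = "REAL_TIME",
                            Q_rel = 1,
                            ds_days = 0.1,
                            lattice_window = 2000,
                            overrides = list(),
                            notch_overrides = list(),
                            output = NULL,
                            verbose = FALSE) {
  if (is.null(gains_preset))
    gains_preset <- if (identical(stress_hypothesis, "TRACE")) "FIG2" else "FIG3_6"
  cfg <- list(stress_hypothesis = stress_hypothesis, variant = variant,
              gains_preset = gains_preset, pressure_fold = pressure_fold,
              pressure_rise_days = pressure_rise_days,
              duration_days = duration_days, J_sol = J_sol, J_im = J_im,
              coupling_mode = coupling_mode, Q_rel = Q_rel,
              ds_days = ds_days, lattice_window = lattice_window,
              overrides = overrides, notch_overrides = notch_overrides,
              output = output, verbose = verbose)
  bad <- character(0)
  chk <- function(cond, msg) if (!isTRUE(cond)) bad <<- c(bad, msg)
  chk(stress_hypothesis %in% c("CIRC", "TRACE"),
      "stress_hypothesis: must be CIRC or TRACE")
  chk(variant %in% c("COMBINED", "PHENOM_ONLY", "NOTCH_ONLY"),
      "variant: must be COMBINED, PHENOM_ONLY or NOTCH_ONLY")
  chk(gains_preset %in% c("FIG2", "FIG3_6"),
      "gains_preset: must be FIG2 or FIG3_6")
  chk(is.numeric(pressure_fold) && pressure_fold >= 1,
      "pressure_fold: must be >= 1")
  chk(is.numeric(pressure_rise_days) && pressure_rise_days > 0,
      "pressure_rise_days: must be > 0")
  chk(is.numeric(duration_days) && duration_days >= 0,
      "duration_days: must be >= 0")
  chk(is.numeric(J_sol) && J_sol >= 0, "J_sol: must be >= 0")
  chk(is.numeric(J_im) && J_im >= 0, "J_im: must be >= 0")
  chk(coupling_mode %in% c("REAL_TIME", "QUASI_STEADY"),
      "coupling_mode: must be REAL_TIME or QUASI_STEADY")
  chk(is.numeric(Q_rel) && Q_rel > 0, "Q_rel: must be > 0")
  chk(is.numeric(ds_days) && ds_days > 0, "ds_days: must be > 0")
  chk(is.numeric(lattice_window) && lattice_window >= 1,
      "lattice_window: must be >= 1")
  if (length(bad))
    stop("invalid scenario configuration:\n  ",
         paste(bad, collapse = "\n  "), call. = FALSE)
  structure(cfg, class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("<scenario_config>\n",
      "  hypothesis ", x$stress_hypothesis, ", variant ", x$variant,
      ", gains ", x$gains_preset, "\n",
      "  pressure fold ", x$pressure_fold, " (rise ", x$pressure_rise_days,
      " d), duration ", x$duration_days, " d\n",
      "  J_sol ", x$J_sol, ", J_im ", x$J_im, ", coupling ",
      x$coupling_mode, "\n", sep = "")
  invisible(x)
}

config_fields <- function() {
  setdiff(names(formals(scenario_config)), character(0))
}

#' Load a scenario configuration from a YAML/JSON file
#'
#' Unset keys are filled with defaults (an empty file gives the default
#' hypertension scenario: CIRC hypothesis, COMBINED variant, FIG3_6 gains).
#' Unknown keys and out-of-range values are rejected with field-level
#' messages listing every violation.
#'
#' @param path Path to a YAML (or JSON, a YAML subset) file.
#' @return A validated [scenario_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  unknown <- setdiff(names(raw), config_fields())
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(scenario_config, raw)
}

#' Write a scenario configuration to YAML
#'
#' @param config A [scenario_config()].
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  x$output <- if (is.null(x$output)) NULL else x$output
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Preset scenarios
#'
#' Ready-made configurations for the four in silico experiments: the two
#' intramural stress hypotheses under hypertension (`fig2_trace`,
#' `fig2_circ`, with the earlier phenomenological gain set), the combined
#' hypertension model and its variants (`fig3_combined`, `fig4_phenom`,
#' `fig4_notch_only`), and hypertension with external Jagged ligands
#' (`fig5_jsol`, `fig6_jim`). The ligand presets carry a dose sweep in
#' attribute `"sweep"`; the printed doses are model inputs chosen to
#' produce clear dose separation at the lattice scale, not measured
#' concentrations.
#'
#' @param name Preset name; see Details.
#' @param ... Overrides forwarded to [scenario_config()] on top of the
#'   preset.
#' @return A [scenario_config()].
#' @export
preset <- function(name, ...) {
  args <- switch(name,
    fig2_trace = list(stress_hypothesis = "TRACE", gains_preset = "FIG2",
                      duration_days = 200),
    fig2_circ = list(stress_hypothesis = "CIRC", gains_preset = "FIG2",
                     duration_days = 200),
    fig3_combined = list(variant = "COMBINED"),
    fig4_phenom = list(variant = "PHENOM_ONLY"),
    fig4_notch_only = list(variant = "NOTCH_ONLY"),
    fig5_jsol = list(J_sol = 3000),
    fig6_jim = list(J_sol = 0, J_im = 300),
    stop("unknown preset '", name, "'; available: ",
         paste(preset_names(), collapse = ", "), call. = FALSE))
  dots <- list(...)
  cfg <- do.call(scenario_config, utils::modifyList(args, dots))
  if (name == "fig5_jsol") attr(cfg, "sweep") <-
    list(key = "J_sol", values = c(0, 1500, 3000))
  if (name == "fig6_jim") attr(cfg, "sweep") <-
    list(key = "J_im", values = c(0, 150, 300))
  cfg
}

#' @rdname preset
#' @export
preset_names <- function() {
  c("fig2_trace", "fig2_circ", "fig3_combined", "fig4_phenom",
    "fig4_notch_only", "fig5_jsol", "fig6_jim")
}

#' Write a run to CSV with a JSON metadata sidecar
#'
#' The CSV holds the tidy per-step trajectory of [run_scenario()]; the
#' sidecar records the resolved configuration and the homeostatic targets
#' so a run is reproducible from its outputs alone.
#'
#' @param run A `"gr_run"` data frame from [run_scenario()].
#' @param path Output CSV path; the sidecar gets the same name with
#'   `.json` appended.
#' @return `path`, invisibly.
#' @export
write_run <- function(run, path) {
  utils::write.csv(as.data.frame(run), path, row.names = FALSE)
  meta <- list(
    config = unclass(attr(run, "config")),
    targets = attr(run, "targets"),
    solver = list(lam_theta_tol = 1e-10, cohort_qmin = 1e-6),
    package = as.character(utils::packageVersion("notchgr")))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
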