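#' Model names understood by the fitting and comparison functions
#'
#' * `"standard"` - standard chemical-equilibrium two-state model
#'   ([vant_hoff_curves()]; heat capacity from [cp_two_state()])
#' * `"theta_weighted"` - extent-of-unfolding-weighted variant
#'   ([theta_weighted_curves()]; same heat capacity)
#' * `"stat_two_state"` - statistical-mechanical two-state model
#'   ([stat_two_state_lnZ()])
#' * `"zimm_bragg"` - multistate cooperative Zimm-Bragg model
#'   ([zimm_bragg_lnZ()])
#'
#' @return Character vector of the four model names.
#' @export
model_names <- function() {
  c("standard", "theta_weighted", "stat_two_state", "zimm_bragg")
}

default_params_class <- function(model) {
  switch(model,
    standard = ,
    theta_weighted = "equilibrium_params",
    stat_two_state = "stat_params",
    zimm_bragg = "zimm_bragg_params",
    abort(sprintf("unknown model '%s'", model))
  )
}

#' Model heat-capacity curve
#'
#' Evaluates the excess heat capacity predicted by a parameter record on a
#' temperature grid: the closed form for the chemical-equilibrium models,
#' and numerical differentiation of the partition function (via
#' [thermo_from_lnZ()]) for the statistical-mechanical and Zimm-Bragg
#' models. A list of parameter records is evaluated as the sum of
#' independent transitions (simultaneous two-transition analysis).
#'
#' @param params A parameter record, or a list of records for additive
#'   transitions.
#' @param temperature Kelvin grid (at least 5 points for the numerical
#'   models).
#' @param baseline Constant heat-capacity offset added to the curve
#'   (default 0; measured thermograms are baseline-corrected).
#' @return A tibble with columns `temperature`, `cp`.
#' @export
model_cp <- function(params, temperature, baseline = 0) {
  cp <- model_cp_vec(params, temperature) + baseline
  tibble(temperature = temperature, cp = cp)
}

model_cp_vec <- function(params, temperature) {
  if (is_param_list(params)) {
    return(Reduce(`+`, lapply(params, model_cp_vec, temperature = temperature)))
  }
  if (inherits(params, "equilibrium_params")) {
    return(cp_two_state(params, temperature)$cp)
  }
  lnZ <- params_lnZ(params, temperature)
  thermo_from_lnZ(lnZ, temperature)$Cv_curve
}

params_lnZ <- function(params, temperature) {
  if (inherits(params, "stat_params")) {
    stat_two_state_lnZ(params, temperature)
  } else if (inherits(params, "zimm_bragg_params")) {
    zimm_bragg_lnZ(params, temperature)
  } else {
    abort("params must be stat_params or zimm_bragg_params for a partition model")
  }
}

is_param_record <- function(x) {
  inherits(x, c("equilibrium_params", "stat_params", "zimm_bragg_params"))
}

is_param_list <- function(x) {
  is.list(x) && !is_param_record(x) && all(vapply(x, is_param_record, logical(1)))
}

#' Model thermodynamic profiles for comparison with DSC integration
#'
#' Evaluates the cumulative enthalpy, entropy and free-energy curves a model
#' predicts, on the same footing as the model-free profiles from
#' [integrate_profiles()]:
#' * `standard`: the raw van't Hoff functions (linear/logarithmic in T,
#'   parabolic free energy) - deliberately retained because their mismatch
#'   with the integrated profiles is the motivating diagnostic;
#' * `theta_weighted`: the van't Hoff functions weighted by the extent of
#'   unfolding;
#' * `stat_two_state`, `zimm_bragg`: inner energy, entropy and free energy
#'   from the partition function (volume effects being small, E, S_v and F
#'   are compared directly with the calorimetric dH, dS and dG).
#' For a list of parameter records the transitions are summed.
#'
#' @param params A parameter record or list of records.
#' @param temperature Kelvin grid.
#' @param model One of [model_names()]; decides how an
#'   [equilibrium_params()] record is turned into profiles.
#' @return A tibble with columns `temperature`, `dH`, `dS`, `dG`.
#' @export
model_profiles <- function(params, temperature, model) {
  model <- match.arg(model, model_names())
  if (is_param_list(params)) {
    parts <- lapply(params, model_profiles, temperature = temperature, model = model)
    return(tibble(
      temperature = temperature,
      dH = Reduce(`+`, lapply(parts, `[[`, "dH")),
      dS = Reduce(`+`, lapply(parts, `[[`, "dS")),
      dG = Reduce(`+`, lapply(parts, `[[`, "dG"))
    ))
  }
  if (model == "standard") {
    vh <- vant_hoff_curves(params, temperature)
    return(tibble(temperature = temperature, dH = vh$dH_NU, dS = vh$dS_NU,
                  dG = vh$dG_NU))
  }
  if (model == "theta_weighted") {
    tw <- theta_weighted_curves(params, temperature)
    return(tibble(temperature = temperature, dH = tw$dH_theta,
                  dS = tw$dS_theta, dG = tw$dG_theta))
  }
  th <- thermo_from_lnZ(params_lnZ(params, temperature), temperature)
  tibble(temperature = temperature, dH = th$E, dS = th$S, dG = th$F)
}
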