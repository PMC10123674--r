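#' van't Hoff curves of the standard chemical-equilibrium two-state model
#'
#' Evaluates, on a temperature grid, the standard two-state (N = U)
#' thermodynamics
#' \deqn{\Delta H_{NU}(T) = \Delta H_0 + \Delta C_p^0 (T - T_m)}
#' \deqn{\Delta S_{NU}(T) = \Delta H_0 / T_m + \Delta C_p^0 \ln(T / T_m)}
#' \deqn{\Delta G_{NU}(T) = \Delta H_{NU} - T\,\Delta S_{NU}}
#' together with the equilibrium constant
#' \eqn{K_{NU} = \exp(-\Delta G_{NU} / RT)} and the extent of unfolding
#' \eqn{\Theta_U = K_{NU} / (1 + K_{NU})}. The extent of unfolding is
#' evaluated in log space (a logistic in \eqn{-\Delta G_{NU}/RT}) so it stays
#' finite however large \eqn{|\Delta G_{NU}|} gets; `K_NU` itself may
#' overflow to `Inf` deep in the unfolded state.
#'
#' At \eqn{T = T_m}: \eqn{\Delta G_{NU} = 0}, \eqn{K_{NU} = 1},
#' \eqn{\Theta_U = 1/2}.
#'
#' @param params An [equilibrium_params()] record.
#' @param temperature Kelvin grid (all > 0).
#' @return A tibble with columns `temperature`, `dH_NU`, `dS_NU`, `dG_NU`,
#'   `K_NU`, `theta_U`.
#' @export
#' @examples
#' p <- equilibrium_params(107, 335, 2.27)
#' vant_hoff_curves(p, c(318, 335, 350))
vant_hoff_curves <- function(params, temperature) {
  check_temperature(temperature)
  dH <- params$dH0 + params$cp_step * (temperature - params$t_m)
  dS <- params$dH0 / params$t_m + params$cp_step * log(temperature / params$t_m)
  dG <- dH - temperature * dS
  x <- -dG / (.Rgas * temperature)
  tibble(
    temperature = temperature,
    dH_NU = dH, dS_NU = dS, dG_NU = dG,
    K_NU = exp(x),
    theta_U = plogis(x)
  )
}

#' Heat capacity of the chemical-equilibrium two-state model
#'
#' The model heat capacity is the temperature derivative of the
#' extent-weighted enthalpy \eqn{\Delta H_{NU}(T)\,\Theta_U(T)}:
#' \deqn{C_p(T) = \Theta_U \Delta C_p^0 +
#'   \Delta H_{NU}^2\,\Theta_U (1 - \Theta_U) / (R T^2).}
#' It reproduces the characteristic peak at the midpoint (height
#' \eqn{\Delta H_0^2 / 4 R T_m^2} when \eqn{\Delta C_p^0 = 0}) and tends to
#' zero in the native limit \eqn{\Theta_U \to 0}.
#'
#' @inheritParams vant_hoff_curves
#' @return A tibble with columns `temperature`, `cp` (kcal mol^-1 K^-1).
#' @export
cp_two_state <- function(params, temperature) {
  vh <- vant_hoff_curves(params, temperature)
  cp <- vh$theta_U * params$cp_step +
    vh$dH_NU^2 * vh$theta_U * (1 - vh$theta_U) / (.Rgas * temperature^2)
  tibble(temperature = temperature, cp = cp)
}

#' Extent-of-unfolding-weighted two-state curves
#'
#' The weighted variant of the chemical-equilibrium two-state model
#' multiplies each of the van't Hoff functions pointwise by the extent of
#' unfolding: \eqn{\Delta H_\Theta = \Theta_U \Delta H_{NU}},
#' \eqn{\Delta S_\Theta = \Theta_U \Delta S_{NU}},
#' \eqn{\Delta G_\Theta = \Theta_U \Delta G_{NU}}. All three vanish in the
#' deep native limit, and \eqn{\Delta G_\Theta(T_m) = 0} exactly. The free
#' energy retains a small positive lobe just on the native side of the
#' midpoint - the diagnostic this package's model comparison flags.
#'
#' @inheritParams vant_hoff_curves
#' @return A tibble with columns `temperature`, `dH_theta`, `dS_theta`,
#'   `dG_theta`, `theta_U`.
#' @export
theta_weighted_curves <- function(params, temperature) {
  vh <- vant_hoff_curves(params, temperature)
  tibble(
    temperature = temperature,
    dH_theta = vh$theta_U * vh$dH_NU,
    dS_theta = vh$theta_U * vh$dS_NU,
    dG_theta = vh$theta_U * vh$dG_NU,
    theta_U = vh$theta_U
  )
}

check_temperature <- function(temperature) {
  if (!is.numeric(temperature) || length(temperature) == 0 || anyNA(temperature)) {
    abort("temperature must be numeric without missing values")
  }
  if (any(temperature <= 0)) abort("all temperatures must be > 0 K")
  invisible(TRUE)
}
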