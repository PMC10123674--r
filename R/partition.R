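#' Log partition function of the statistical-mechanical two-state model
#'
#' The model assigns the native state weight 1 and the unfolded state a
#' Boltzmann weight referenced to the midpoint temperature:
#' \deqn{Z(T) = 1 + \exp\left[-\Delta E(T)\left(\frac{1}{RT} -
#'   \frac{1}{RT_m}\right)\right], \qquad
#'   \Delta E(T) = \Delta E_0 + C_v (T - T_m).}
#' At the midpoint \eqn{Z(T_m) = 2}, so the free energy there is
#' \eqn{-RT_m \ln 2} (about -0.46 kcal/mol at 335 K) - negative, unlike the
#' chemical-equilibrium prediction of zero. With \eqn{C_v > 0} the unfolded
#' weight exceeds 1 again below \eqn{T_{cold} = T_m - \Delta E_0 / C_v},
#' producing cold denaturation.
#'
#' @param params A [stat_params()] record.
#' @param temperature Kelvin grid (all > 0).
#' @return Numeric vector of \eqn{\ln Z \ge 0}, one per grid point.
#' @export
#' @examples
#' stat_two_state_lnZ(stat_params(110, 335, 1.05), 335) # log(2)
stat_two_state_lnZ <- function(params, temperature) {
  check_temperature(temperature)
  a <- stat_log_weight(params, temperature)
  log1p_exp(a)
}

stat_log_weight <- function(params, temperature) {
  dE <- params$dE0 + params$cv * (temperature - params$t_m)
  -dE * (1 / (.Rgas * temperature) - 1 / (.Rgas * params$t_m))
}

# log(1 + exp(a)) without overflow
log1p_exp <- function(a) {
  out <- numeric(length(a))
  big <- a > 35
  out[big] <- a[big] + log1p(exp(-a[big]))
  out[!big] <- log1p(exp(a[!big]))
  out
}

#' Cold-denaturation temperature of the statistical two-state model
#'
#' The unfolded-state energy \eqn{\Delta E(T) = \Delta E_0 + C_v (T - T_m)}
#' vanishes at \eqn{T_{cold} = T_m - \Delta E_0 / C_v}, where the extent of
#' unfolding crosses 1/2 a second time. The inner energy stabilizes the fold
#' (larger \eqn{\Delta E_0} pushes \eqn{T_{cold}} down) while the
#' fluctuation term \eqn{C_v} destabilizes it. The heat/cold separation is
#' \eqn{\Delta T = \Delta E_0 / C_v}.
#'
#' @param params A [stat_params()] record.
#' @return Temperature in kelvin; `NA_real_` when `cv == 0` (no cold
#'   denaturation within this model).
#' @export
#' @examples
#' cold_denaturation_temperature(stat_params(110, 335, 1.05)) # ~230 K
cold_denaturation_temperature <- function(params) {
  if (params$cv == 0) return(NA_real_)
  params$t_m - params$dE0 / params$cv
}

#' Log partition function of the multistate cooperative Zimm-Bragg model
#'
#' Transfer-matrix (largest eigenvalue) form of the Zimm-Bragg helix-coil
#' partition function for `n_res` residues:
#' \deqn{s(T) = \exp\left[-h(T)\left(\frac{1}{RT} - \frac{1}{RT_m}\right)
#'   \right], \quad h(T) = h_0 + c_v (T - T_m),}
#' \deqn{\lambda_1 = \frac{1 + s}{2} +
#'   \sqrt{\left(\frac{1 - s}{2}\right)^2 + \sigma s}, \qquad
#'   \ln Z = N \ln \lambda_1.}
#' At \eqn{\sigma = 1} (no cooperativity) \eqn{\lambda_1 = 1 + s}, and with
#' \eqn{N = 1} the model coincides with the statistical-mechanical two-state
#' partition function. Smaller \eqn{\sigma} sharpens the transition.
#'
#' @param params A [zimm_bragg_params()] record.
#' @param temperature Kelvin grid (all > 0).
#' @return Numeric vector of \eqn{\ln Z \ge 0}.
#' @export
zimm_bragg_lnZ <- function(params, temperature) {
  check_temperature(temperature)
  s <- zb_s(params, temperature)
  params$n_res * log(zb_lambda1(s, params$sigma))
}

zb_s <- function(params, temperature) {
  h <- params$h0 + params$cv_res * (temperature - params$t_m)
  exp(-h * (1 / (.Rgas * temperature) - 1 / (.Rgas * params$t_m)))
}

zb_lambda1 <- function(s, sigma) {
  (1 + s) / 2 + sqrt(((1 - s) / 2)^2 + sigma * s)
}

# d lambda1 / d s
zb_dlambda1_ds <- function(s, sigma) {
  0.5 + (sigma - (1 - s) / 2) / (2 * sqrt(((1 - s) / 2)^2 + sigma * s))
}

#' Thermodynamic functions from a log partition function
#'
#' Converts \eqn{\ln Z(T)} sampled on a temperature grid into
#' \deqn{E = R T^2 \frac{d\ln Z}{dT}, \quad F = -RT \ln Z, \quad
#'   S = (E - F)/T, \quad C_v = \frac{dE}{dT},}
#' using central differences on the grid (one-sided at the ends), so any
#' alternative partition function can be dropped in unchanged. Because
#' \eqn{Z \ge 1}, the free energy is zero or negative, never positive. A
#' grid spacing of 0.5 K or finer is recommended for stable derivatives.
#'
#' @param lnZ Numeric vector of log partition function values.
#' @param temperature Kelvin grid of the same length (at least 5 points).
#' @param theta_U Optional extent-of-unfolding vector to carry along (from
#'   [extent_unfolded()]).
#' @return A tibble of class `partition_thermo` with columns `temperature`,
#'   `lnZ`, `E` (kcal mol^-1), `S` (kcal mol^-1 K^-1), `F` (kcal mol^-1),
#'   `Cv_curve` (kcal mol^-1 K^-1) and, if supplied, `theta_U`.
#' @export
thermo_from_lnZ <- function(lnZ, temperature, theta_U = NULL) {
  if (length(temperature) < 5) {
    abort("need at least 5 grid points for stable differentiation")
  }
  if (length(lnZ) != length(temperature)) {
    abort("lnZ and temperature must have equal length")
  }
  check_temperature(temperature)
  E <- .Rgas * temperature^2 * pracma::gradient(lnZ, temperature)
  F_ <- -.Rgas * temperature * lnZ
  S <- (E - F_) / temperature
  Cv <- pracma::gradient(E, temperature)
  cols <- list(temperature = temperature, lnZ = lnZ, E = E, S = S, F = F_,
               Cv_curve = Cv)
  if (!is.null(theta_U)) cols$theta_U <- theta_U
  new_tibble(cols, nrow = length(temperature), class = "partition_thermo")
}

#' Extent of unfolding of a partition-function model
#'
#' For the statistical-mechanical two-state model the unfolded fraction is
#' \eqn{q/(1+q)} with \eqn{q = Z - 1}; for the Zimm-Bragg model it is the
#' standard helix-coil fraction
#' \eqn{\Theta_U = (s/N)\,\partial \ln Z / \partial s = s \lambda_1' /
#' \lambda_1}. Both equal 1/2 at the midpoint temperature. Also implemented
#' for [equilibrium_params()] (the logistic of the van't Hoff free energy)
#' so one generic serves every model in the package.
#'
#' @param params A parameter record ([stat_params()], [zimm_bragg_params()]
#'   or [equilibrium_params()]).
#' @param temperature Kelvin grid.
#' @return Numeric vector of unfolded fractions in \[0, 1\].
#' @export
extent_unfolded <- function(params, temperature) {
  UseMethod("extent_unfolded")
}

#' @export
extent_unfolded.stat_params <- function(params, temperature) {
  check_temperature(temperature)
  plogis(stat_log_weight(params, temperature))
}

#' @export
extent_unfolded.zimm_bragg_params <- function(params, temperature) {
  check_temperature(temperature)
  s <- zb_s(params, temperature)
  s * zb_dlambda1_ds(s, params$sigma) / zb_lambda1(s, params$sigma)
}

#' @export
extent_unfolded.equilibrium_params <- function(params, temperature) {
  vant_hoff_curves(params, temperature)$theta_U
}

#' Nucleation free energy from the cooperativity parameter
#'
#' The free energy needed to start a new folded stretch inside an unfolded
#' domain is \eqn{\Delta G_\sigma = -RT \ln \sigma}. It is a quantitative
#' stability measure: the two proteins in the worked examples have nearly
#' identical unfolding free energies but nucleation energies differing by
#' over 3 kcal/mol.
#'
#' @param sigma Cooperativity parameter, 0 < sigma <= 1.
#' @param temperature Temperature in kelvin (typically the midpoint).
#' @return Free energy in kcal mol^-1 (>= 0).
#' @export
#' @examples
#' nucleation_free_energy(5e-7, 335) # ~9.7 kcal/mol
nucleation_free_energy <- function(sigma, temperature) {
  if (any(sigma <= 0 | sigma > 1)) abort("sigma must be in (0, 1]")
  check_temperature(temperature)
  -.Rgas * temperature * log(sigma)
}
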