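#' Parameters of the chemical-equilibrium two-state models
#'
#' Holds the conformational (van't Hoff) enthalpy, the midpoint temperature
#' and the heat-capacity step between native and unfolded protein. Used both
#' by the standard chemical-equilibrium two-state model and by its
#' extent-of-unfolding-weighted variant.
#'
#' @param dH0 Conformational (van't Hoff) enthalpy, kcal mol^-1. Negative
#'   values are allowed and describe cold-denaturation-only transitions.
#' @param t_m Midpoint temperature, kelvin.
#' @param cp_step Heat-capacity step between unfolded and native protein,
#'   kcal mol^-1 K^-1.
#' @return A list of class `equilibrium_params`.
#' @export
#' @examples
#' equilibrium_params(dH0 = 107, t_m = 335, cp_step = 2.27)
equilibrium_params <- function(dH0, t_m, cp_step = 0) {
  stopifnot(is.numeric(dH0), is.numeric(t_m), is.numeric(cp_step))
  if (t_m <= 0) abort("t_m must be > 0 K")
  if (dH0 == 0) abort("dH0 must be non-zero")
  structure(list(dH0 = as.numeric(dH0), t_m = as.numeric(t_m),
                 cp_step = as.numeric(cp_step)),
            class = "equilibrium_params")
}

#' Parameters of the statistical-mechanical two-state model
#'
#' @param dE0 Difference in inner energy between native and unfolded protein,
#'   kcal mol^-1 (close to the van't Hoff enthalpy in practice).
#' @param t_m Midpoint temperature, kelvin.
#' @param cv Heat capacity of the inner energy, kcal mol^-1 K^-1; represents
#'   energy fluctuations and accounts for the heat-capacity increase upon
#'   unfolding.
#' @return A list of class `stat_params`.
#' @export
#' @examples
#' stat_params(dE0 = 110, t_m = 335, cv = 1.05)
stat_params <- function(dE0, t_m, cv = 0) {
  stopifnot(is.numeric(dE0), is.numeric(t_m), is.numeric(cv))
  if (t_m <= 0) abort("t_m must be > 0 K")
  if (cv < 0) abort("cv must be >= 0")
  structure(list(dE0 = as.numeric(dE0), t_m = as.numeric(t_m),
                 cv = as.numeric(cv)),
            class = "stat_params")
}

#' Parameters of the multistate cooperative Zimm-Bragg model
#'
#' @param h0 Unfolding energy per amino-acid residue, kcal mol^-1.
#' @param cv_res Heat capacity per residue, kcal mol^-1 K^-1 (note: papers in
#'   this field usually quote cal mol^-1 K^-1; divide by 1000).
#' @param sigma Cooperativity (nucleation) parameter, 0 < sigma <= 1; smaller
#'   sigma gives a sharper transition.
#' @param n_res Number of residues participating in the transition.
#' @param t_m Midpoint temperature, kelvin.
#' @return A list of class `zimm_bragg_params`.
#' @export
#' @examples
#' zimm_bragg_params(h0 = 0.91, cv_res = 0.007, sigma = 5e-7,
#'                   n_res = 129, t_m = 335)
zimm_bragg_params <- function(h0, cv_res, sigma, n_res, t_m) {
  stopifnot(is.numeric(h0), is.numeric(cv_res), is.numeric(sigma),
            is.numeric(n_res), is.numeric(t_m))
  if (!(sigma > 0 && sigma <= 1)) abort("sigma must be in (0, 1]")
  if (n_res < 1) abort("n_res must be >= 1")
  if (t_m <= 0) abort("t_m must be > 0 K")
  structure(list(h0 = as.numeric(h0), cv_res = as.numeric(cv_res),
                 sigma = as.numeric(sigma), n_res = as.numeric(n_res),
                 t_m = as.numeric(t_m)),
            class = "zimm_bragg_params")
}

#' @export
print.equilibrium_params <- function(x, ...) {
  cat(sprintf(
    "<equilibrium two-state>  dH0 = %g kcal/mol, Tm = %g K, dCp0 = %g kcal/(mol K)\n",
    x$dH0, x$t_m, x$cp_step))
  invisible(x)
}

#' @export
print.stat_params <- function(x, ...) {
  cat(sprintf(
    "<statistical two-state>  dE0 = %g kcal/mol, Tm = %g K, Cv = %g kcal/(mol K)\n",
    x$dE0, x$t_m, x$cv))
  invisible(x)
}

#' @export
print.zimm_bragg_params <- function(x, ...) {
  cat(sprintf(
    "<Zimm-Bragg>  h0 = %g kcal/mol, cv = %g kcal/(mol K), sigma = %g, N = %g, Tm = %g K\n",
    x$h0, x$cv_res, x$sigma, x$n_res, x$t_m))
  invisible(x)
}
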