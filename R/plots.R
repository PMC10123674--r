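#' Plot a DSC thermogram
#'
#' Heat capacity against temperature (degrees Celsius on the axis, as
#' calorimetry figures are conventionally drawn).
#'
#' @param object A `dsc_thermogram`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dsc_thermogram
#' @export
autoplot.dsc_thermogram <- function(object, ...) {
  df <- tibble(t_c = object$temperature - 273.15, cp = object$cp)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t_c, y = .data$cp)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::labs(
      x = "Temperature (°C)",
      y = expression(C[p] ~ "(kcal" ~ mol^-1 ~ K^-1 * ")"),
      title = attr(object, "label")
    ) +
    ggplot2::theme_minimal()
}

#' Plot model-free thermodynamic profiles
#'
#' Facets the cumulative enthalpy, entropy and free energy against
#' temperature; the sigmoidal dH/dS curves and the trapezoidal dG profile
#' are the visual signatures of a well-behaved unfolding scan.
#'
#' @param object A `dsc_profile` from [integrate_profiles()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dsc_profile
#' @export
autoplot.dsc_profile <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble(t_c = object$temperature - 273.15, dH = object$dH,
           dS = object$dS, dG = object$dG),
    cols = c("dH", "dS", "dG"), names_to = "quantity", values_to = "value"
  )
  long$quantity <- factor(long$quantity, levels = c("dH", "dS", "dG"),
                          labels = c("ΔH (kcal/mol)",
                                     "ΔS (kcal/mol/K)",
                                     "ΔG (kcal/mol)"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t_c, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::facet_wrap(~quantity, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "Temperature (°C)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a model fit over the data
#'
#' Measured heat capacity (points) with the fitted model curve (line).
#'
#' @param object A `dsc_fit` from [fit_model()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dsc_fit
#' @export
autoplot.dsc_fit <- function(object, ...) {
  df <- mutate(object$fitted, t_c = .data$temperature - 273.15)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t_c)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$cp_obs), size = 0.5,
                        alpha = 0.5) +
    ggplot2::geom_line(ggplot2::aes(y = .data$cp_fit), colour = "red") +
    ggplot2::labs(
      x = "Temperature (°C)",
      y = expression(C[p] ~ "(kcal" ~ mol^-1 ~ K^-1 * ")"),
      title = paste("Model:", object$model)
    ) +
    ggplot2::theme_minimal()
}

#' Compare model free-energy curves with the integrated free energy
#'
#' Overlays each fitted model's free-energy curve on the model-free
#' integrated dG(T) - the comparison that separates the partition-function
#' models (never-positive dG) from the chemical-equilibrium ones.
#'
#' @param thermogram The `dsc_thermogram` the fits share.
#' @param fits A list of `dsc_fit` objects.
#' @return A ggplot object.
#' @export
plot_free_energy_comparison <- function(thermogram, fits) {
  tt <- thermogram$temperature
  obs <- integrate_profiles(thermogram)
  layers <- bind_rows(c(
    list(tibble(t_c = tt - 273.15, dG = obs$dG, curve = "model-free DSC")),
    purrr::map(fits, function(f) {
      pl <- if (is_param_record(f$params)) list(f$params) else f$params
      tibble(t_c = tt - 273.15,
             dG = model_profiles(pl, tt, f$model)$dG,
             curve = f$model)
    })
  ))
  ggplot2::ggplot(layers,
                  ggplot2::aes(x = .data$t_c, y = .data$dG,
                               colour = .data$curve)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Temperature (°C)",
                  y = expression(Delta * G ~ "(kcal" ~ mol^-1 * ")"),
                  colour = NULL) +
    ggplot2::theme_minimal()
}
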