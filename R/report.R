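#' Protein stability report from a thermogram
#'
#' Runs the full pipeline on one thermogram: model-free integration,
#' transition detection, per-transition totals with the enthalpy/entropy
#' ratio midpoint, the enthalpy decomposition into conformational and
#' heat-capacity-step parts, and (optionally) a model fit from which the
#' model-specific stability measures follow - the cold-denaturation
#' temperature and heat/cold separation of the statistical two-state model,
#' and the nucleation free energy of the Zimm-Bragg model.
#'
#' @param thermogram A `dsc_thermogram`.
#' @param fit Optional `dsc_fit` from [fit_model()]; if `model` is given
#'   instead, the fit is performed here.
#' @param model Optional model name to fit (ignored when `fit` is given).
#' @param ... Passed to [fit_model()] (e.g. `n_res`, `seed`).
#' @return A list of class `dsc_report` with elements:
#'   * `transitions`: [detect_transitions()] tibble (with `width`);
#'   * `totals`: per-transition tibble adding `dH_total`, `dS_total`,
#'     `dG_total`, `tm_ratio` (the dH/dS midpoint), `cp_step`,
#'     `dH_cp_step`, `dH_conf`;
#'   * `fit`: the `dsc_fit` or `NULL`;
#'   * `stability`: one-row tibble with `t_m_peak`, `t_m_ratio`,
#'     `peak_width`, and where a fit provides them `t_cold`, `delta_T`,
#'     `dG_sigma` (all `NA` otherwise).
#' @export
stability_report <- function(thermogram, fit = NULL, model = NULL, ...) {
  transitions <- detect_transitions(thermogram)
  profile <- integrate_profiles(thermogram)

  totals <- if (nrow(transitions) > 0) {
    bind_rows(lapply(seq_len(nrow(transitions)), function(i) {
      w <- transitions[i, ]
      step <- tryCatch(estimate_cp_step(thermogram, w), error = function(e) NA_real_)
      tot <- total_changes(profile, w)
      dec <- if (is.na(step)) {
        tibble(dH_cp_step = NA_real_, dH_conf = NA_real_)
      } else {
        d <- enthalpy_decomposition(profile, w, step)
        tibble(dH_cp_step = d$dH_cp_step, dH_conf = d$dH_conf)
      }
      bind_cols(w, tot,
                tibble(tm_ratio = midpoint_from_ratio(tot$dH_total, tot$dS_total),
                       cp_step = step),
                dec)
    }))
  } else {
    tibble()
  }

  if (is.null(fit) && !is.null(model)) {
    fit <- fit_model(thermogram, model = model, ...)
  }

  t_cold <- delta_T <- dG_sigma <- NA_real_
  if (!is.null(fit)) {
    pl <- if (is_param_record(fit$params)) list(fit$params) else fit$params
    p1 <- pl[[1]]
    if (inherits(p1, "stat_params") && p1$cv > 0) {
      t_cold <- cold_denaturation_temperature(p1)
      delta_T <- p1$dE0 / p1$cv
    }
    if (inherits(p1, "zimm_bragg_params")) {
      dG_sigma <- nucleation_free_energy(p1$sigma, p1$t_m)
    }
  }

  stability <- tibble(
    t_m_peak = if (nrow(transitions) > 0) transitions$t_m[which.max(abs(transitions$peak_cp))] else NA_real_,
    t_m_ratio = if (nrow(totals) > 0) totals$tm_ratio[which.max(abs(totals$dH_total))] else NA_real_,
    peak_width = if (nrow(transitions) > 0) transitions$width[which.max(abs(transitions$peak_cp))] else NA_real_,
    t_cold = t_cold, delta_T = delta_T, dG_sigma = dG_sigma
  )

  structure(
    list(transitions = transitions, totals = totals, fit = fit,
         stability = stability, profile = profile),
    class = "dsc_report"
  )
}

#' @export
print.dsc_report <- function(x, ...) {
  cat("<DSC stability report>\n")
  s <- x$stability
  cat(sprintf("  transitions detected: %d\n", nrow(x$transitions)))
  if (!is.na(s$t_m_peak)) {
    cat(sprintf("  T_m (peak):   %.2f K (%.2f C)\n", s$t_m_peak, s$t_m_peak - 273.15))
  }
  if (!is.na(s$t_m_ratio)) {
    cat(sprintf("  T_m (dH/dS):  %.2f K (%.2f C)\n", s$t_m_ratio, s$t_m_ratio - 273.15))
  }
  if (!is.na(s$peak_width)) cat(sprintf("  peak width:   %.2f K\n", s$peak_width))
  if (!is.na(s$t_cold)) {
    cat(sprintf("  T_cold:       %.2f K,  delta T = %.2f K\n", s$t_cold, s$delta_T))
  }
  if (!is.na(s$dG_sigma)) {
    cat(sprintf("  dG_sigma:     %.2f kcal/mol\n", s$dG_sigma))
  }
  if (!is.null(x$fit)) print(x$fit)
  invisible(x)
}
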