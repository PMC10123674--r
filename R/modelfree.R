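#' Model-free thermodynamic profiles from a thermogram
#'
#' Converts the measured excess heat capacity into cumulative unfolding
#' enthalpy, entropy and Gibbs free energy by discrete integration,
#' \deqn{\Delta H(T_i) = \sum C_p(T_j)\,\Delta T_j, \qquad
#'       \Delta S(T_i) = \sum \frac{C_p(T_j)}{T_j}\,\Delta T_j, \qquad
#'       \Delta G = \Delta H - T\,\Delta S,}
#' starting at the native-state end of the scan (the first recorded point:
#' low-temperature end of a heating scan, high-temperature end of a cooling
#' scan), where all three functions are zero by construction. On a cooling
#' scan the temperature steps are negative, so an exothermic transition
#' accumulates negative enthalpy.
#'
#' @param thermogram A `dsc_thermogram`.
#' @param rule Integration rule. `"riemann"` (default) is the left-Riemann
#'   running sum in discrete temperature steps; `"trapezoid"` uses the
#'   trapezoid rule (both converge to the same integral as the grid is
#'   refined).
#' @return A tibble of class `dsc_profile` with columns `temperature` (K),
#'   `dH` (kcal mol^-1), `dS` (kcal mol^-1 K^-1) and `dG` (kcal mol^-1), in
#'   recorded scan order.
#' @export
#' @examples
#' tg <- as_thermogram(data.frame(temperature = seq(300, 310, 0.1), cp = 1))
#' integrate_profiles(tg)
integrate_profiles <- function(thermogram, rule = c("riemann", "trapezoid")) {
  rule <- match.arg(rule)
  validate_thermogram(thermogram$temperature, thermogram$cp)
  tt <- thermogram$temperature
  cp <- thermogram$cp
  dT <- diff(tt)
  if (any(dT == 0)) abort("zero-length temperature step in grid")

  if (rule == "riemann") {
    inc_H <- cp[-length(cp)] * dT
    inc_S <- (cp[-length(cp)] / tt[-length(tt)]) * dT
  } else {
    inc_H <- (cp[-length(cp)] + cp[-1]) / 2 * dT
    inc_S <- (cp[-length(cp)] / tt[-length(tt)] + cp[-1] / tt[-1]) / 2 * dT
  }
  dH <- c(0, cumsum(inc_H))
  dS <- c(0, cumsum(inc_S))
  new_profile(tt, dH, dS)
}

new_profile <- function(temperature, dH, dS) {
  new_tibble(
    list(temperature = temperature, dH = dH, dS = dS,
         dG = dH - temperature * dS),
    nrow = length(temperature), class = "dsc_profile"
  )
}

#' Total thermodynamic changes over a transition window
#'
#' Differences of the cumulative model-free profiles between `t_ini` and
#' `t_end` (values at the window ends are linearly interpolated on the grid).
#'
#' @param profile A [integrate_profiles()] result.
#' @param window A [transition_window()]; `t_ini` and `t_end` must both lie
#'   inside the profile grid. A zero-width window gives zero totals.
#' @return A one-row tibble with `dH_total` (kcal mol^-1), `dS_total`
#'   (kcal mol^-1 K^-1) and `dG_total` (kcal mol^-1).
#' @export
total_changes <- function(profile, window) {
  tt <- profile$temperature
  lo <- min(tt); hi <- max(tt)
  for (tp in c(window$t_ini, window$t_end)) {
    if (tp < lo || tp > hi) {
      abort(sprintf("window temperature %.6g K outside profile grid [%.6g, %.6g]",
                    tp, lo, hi))
    }
  }
  at <- function(col, x) approx(tt, profile[[col]], xout = x)$y
  tibble(
    dH_total = at("dH", window$t_end) - at("dH", window$t_ini),
    dS_total = at("dS", window$t_end) - at("dS", window$t_ini),
    dG_total = at("dG", window$t_end) - at("dG", window$t_ini)
  )
}

#' Enthalpy carried by the heat-capacity step
#'
#' The contribution of the heat-capacity increase upon unfolding to the total
#' calorimetric enthalpy is approximated by the area under the sigmoidal step
#' between the window ends,
#' \deqn{\Delta H_{\Delta C_p^0} = \Delta C_p^0\,(T_{end} - T_{ini})/3.}
#' The divisor 3 (rather than 2, the straight-line triangle) reflects the
#' sigmoidal hypotenuse of the step. The result is signed by the scan
#' direction: negative when `t_end < t_ini` (cooling).
#'
#' @param cp_step Heat-capacity step, kcal mol^-1 K^-1.
#' @param window A [transition_window()].
#' @return Enthalpy in kcal mol^-1.
#' @export
#' @examples
#' cp_step_enthalpy(2.269, transition_window(318, 335, 346)) # 21.2 kcal/mol
cp_step_enthalpy <- function(cp_step, window) {
  as.numeric(cp_step) * (window$t_end - window$t_ini) / 3
}

#' Midpoint temperature from the enthalpy/entropy ratio
#'
#' For a first-order transition the midpoint temperature is the ratio of the
#' total unfolding enthalpy to the total unfolding entropy,
#' \eqn{T_m = \Delta H / \Delta S}. The relation applies to heat and to cold
#' denaturation alike (both totals change sign together).
#'
#' @param dH_total Total enthalpy change, kcal mol^-1.
#' @param dS_total Total entropy change, kcal mol^-1 K^-1; must be non-zero.
#' @return Temperature in kelvin.
#' @export
#' @examples
#' midpoint_from_ratio(-69.5, -0.248) # cold denaturation, ~280 K
midpoint_from_ratio <- function(dH_total, dS_total) {
  if (any(dS_total == 0)) {
    abort("dS_total is zero: midpoint temperature dH/dS is undefined")
  }
  dH_total / dS_total
}

#' Detect unfolding transitions in a thermogram
#'
#' Finds local extrema of |C_p| above a noise threshold and brackets each
#' with begin/end temperatures where the baseline-corrected |C_p| first and
#' last exceeds a fraction of the peak height. The noise threshold is
#' `noise_mult` times the median absolute deviation of the flattest decile
#' of the trace (the contiguous tenth with the smallest detrended spread).
#' Peak flanks are referenced to local baselines (median C_p of the far
#' flank on each side), so a heat-capacity step between native and unfolded
#' plateaus does not inflate the window.
#'
#' @param thermogram A `dsc_thermogram`.
#' @param peak_frac Fraction of the baseline-corrected peak height defining
#'   `t_ini`/`t_end` (default 0.02).
#' @param noise_mult Multiplier on the flattest-decile MAD for the peak
#'   acceptance threshold (default 5).
#' @return A tibble with one row per transition in scan order: `t_ini`,
#'   `t_m`, `t_end` (kelvin), `peak_cp` (signed C_p at the extremum,
#'   kcal mol^-1 K^-1) and `width` (kelvin). Empty (zero-row) if no extremum
#'   exceeds the threshold.
#' @export
detect_transitions <- function(thermogram, peak_frac = 0.02, noise_mult = 5) {
  tt <- thermogram$temperature
  cp <- thermogram$cp
  n <- length(cp)
  a <- abs(cp)

  thr <- noise_mult * flattest_decile_mad(cp)
  thr <- max(thr, 1e-12)

  # interior local maxima of |cp| above threshold
  is_peak <- c(FALSE, a[2:(n - 1)] >= a[1:(n - 2)] & a[2:(n - 1)] >= a[3:n],
               FALSE) & a > thr
  idx <- which(is_peak)
  if (length(idx) == 0) {
    return(tibble(t_ini = numeric(), t_m = numeric(), t_end = numeric(),
                  peak_cp = numeric(), width = numeric()))
  }
  # collapse plateaus / ripples: keep one extremum per cluster separated by a
  # dip below half the smaller of the adjacent peaks
  keep <- idx[1]
  for (i in idx[-1]) {
    last <- keep[length(keep)]
    valley <- min(a[last:i])
    if (valley < 0.5 * min(a[last], a[i])) {
      keep <- c(keep, i)
    } else if (a[i] > a[last]) {
      keep[length(keep)] <- i
    }
  }

  segs <- segment_bounds(keep, n)
  out <- purrr::map2(keep, segs, function(pk, seg) {
    bracket_peak(tt, cp, pk, seg[1], seg[2], peak_frac)
  })
  bind_rows(out)
}

# contiguous decile of the trace with the smallest detrended spread
flattest_decile_mad <- function(cp) {
  n <- length(cp)
  w <- max(5L, floor(n / 10))
  starts <- unique(pmax(1L, floor(seq(1L, n - w + 1L, length.out = 20L))))
  spread <- vapply(starts, function(s) {
    seg <- cp[s:(s + w - 1L)]
    x <- seq_along(seg)
    res <- stats::residuals(stats::lm.fit(cbind(1, x), seg))
    mad(res)
  }, numeric(1))
  min(spread)
}

segment_bounds <- function(peaks, n) {
  k <- length(peaks)
  purrr::map(seq_len(k), function(j) {
    left <- if (j == 1) 1L else floor((peaks[j - 1] + peaks[j]) / 2)
    right <- if (j == k) n else ceiling((peaks[j] + peaks[j + 1]) / 2)
    c(left, right)
  })
}

bracket_peak <- function(tt, cp, pk, left, right, peak_frac) {
  s <- sign(cp[pk])
  y <- s * cp  # peak now positive
  # local baselines: median over the outer 10% of each flank of the segment
  bl_w <- max(3L, floor((pk - left + 1) / 10))
  br_w <- max(3L, floor((right - pk + 1) / 10))
  base_l <- median(y[left:min(left + bl_w - 1L, pk)])
  base_r <- median(y[max(right - br_w + 1L, pk):right])
  h_l <- y[pk] - base_l
  h_r <- y[pk] - base_r

  below_l <- which(y[left:pk] - base_l < peak_frac * h_l)
  i_ini <- if (length(below_l)) left + max(below_l) - 1L else left
  below_r <- which(y[pk:right] - base_r < peak_frac * h_r)
  i_end <- if (length(below_r)) pk + min(below_r) - 1L else right

  tibble(
    t_ini = tt[i_ini], t_m = tt[pk], t_end = tt[i_end],
    peak_cp = cp[pk], width = abs(tt[i_end] - tt[i_ini])
  )
}

#' Estimate the heat-capacity step from plateaus
#'
#' Mean excess heat capacity over the post-transition plateau minus the
#' pre-transition plateau, the plateaus being the outer `flank` fraction of
#' the window's flanks (grid points just outside the window, spanning
#' `flank * width` in temperature).
#'
#' @param thermogram A `dsc_thermogram`.
#' @param window A [transition_window()].
#' @param flank Plateau width as a fraction of the window width (default 0.1).
#' @return Estimated heat-capacity step, kcal mol^-1 K^-1 (sign: unfolded
#'   side minus native side, in scan order).
#' @export
estimate_cp_step <- function(thermogram, window, flank = 0.1) {
  tt <- thermogram$temperature
  cp <- thermogram$cp
  w <- abs(window$t_end - window$t_ini) * flank
  d <- sign(window$t_end - window$t_ini)  # +1 heating window, -1 cooling
  off_pre <- (window$t_ini - tt) * d      # >= 0 on the native side of t_ini
  off_post <- (tt - window$t_end) * d     # >= 0 beyond t_end
  pre <- cp[off_pre >= 0 & off_pre <= w]
  post <- cp[off_post >= 0 & off_post <= w]
  if (length(pre) == 0 || length(post) == 0) {
    abort("no grid points in the plateau flanks; widen the grid or the flank")
  }
  mean(post) - mean(pre)
}

#' Shift cumulative profiles to a new reference state
#'
#' Subtracts constant offsets from the cumulative enthalpy and entropy and
#' recomputes the free energy. Used to place the native state at zero when a
#' scan starts from the cold-denatured state: shifting by the totals of the
#' first (disorder-to-order) transition makes the native plateau read
#' dH = dS = 0 and turns the free energy into its trapezoidal shape.
#'
#' @param profile A `dsc_profile`.
#' @param dH_shift Enthalpy offset, kcal mol^-1.
#' @param dS_shift Entropy offset, kcal mol^-1 K^-1.
#' @return A `dsc_profile` with `dH`, `dS` shifted and `dG = dH - T dS`
#'   recomputed.
#' @export
rebase_profiles <- function(profile, dH_shift, dS_shift) {
  new_profile(profile$temperature, profile$dH - dH_shift,
              profile$dS - dS_shift)
}

#' Decompose the calorimetric enthalpy over a window
#'
#' Splits the total calorimetric enthalpy into the conformational part and
#' the part carried by the heat-capacity step:
#' dH_total = dH_conf + dH_cp_step, with dH_cp_step from
#' [cp_step_enthalpy()].
#'
#' @param profile A `dsc_profile`.
#' @param window A [transition_window()].
#' @param cp_step Heat-capacity step, kcal mol^-1 K^-1; if `NULL`, estimated
#'   from the source thermogram is not possible here, so it must be given.
#' @return A one-row tibble: `dH_total`, `dS_total`, `dG_total`,
#'   `dH_cp_step`, `dH_conf`, `cp_step`.
#' @export
enthalpy_decomposition <- function(profile, window, cp_step) {
  tot <- total_changes(profile, window)
  step <- cp_step_enthalpy(cp_step, window)
  mutate(tot, dH_cp_step = step, dH_conf = .data$dH_total - step,
         cp_step = as.numeric(cp_step))
}

#' @export
print.dsc_profile <- function(x, ...) {
  cat(sprintf("<DSC thermodynamic profile>  %d points, %.2f-%.2f K\n",
              nrow(x), min(x$temperature), max(x$temperature)))
  NextMethod()
}
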