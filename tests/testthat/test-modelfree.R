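test_that("constant heat capacity integrates to the closed forms", {
  tg <- flat_thermogram(300, 310, step = 0.01, cp = 1)
  pr <- integrate_profiles(tg)
  n <- nrow(pr)
  expect_equal(pr$dH[n], 10, tolerance = 1e-10)
  # closed form of the entropy integral for constant C_p
  expect_equal(pr$dS[n], log(310 / 300), tolerance = 1e-4)
  expect_equal(pr$dG, pr$dH - pr$temperature * pr$dS)

  zero <- flat_thermogram(cp = 0)
  przero <- integrate_profiles(zero)
  expect_true(all(przero$dH == 0 & przero$dS == 0 & przero$dG == 0))
})

test_that("profiles are zero at the native reference point", {
  sp <- noise_free_scenario("fig2_cold")
  pr <- integrate_profiles(generate_thermogram(sp)$thermogram)
  expect_equal(pr$dH[1], 0)
  expect_equal(pr$dS[1], 0)
  expect_equal(pr$dG[1], 0)
})

test_that("Riemann and trapezoid sums converge together under refinement", {
  p <- lysozyme_eq()
  errs <- sapply(c(0.5, 0.05), function(h) {
    tt <- seq(310, 360, by = h)
    tg <- as_thermogram(data.frame(temperature = tt,
                                   cp = cp_two_state(p, tt)$cp))
    r <- integrate_profiles(tg, rule = "riemann")
    t <- integrate_profiles(tg, rule = "trapezoid")
    max(abs(r$dH - t$dH))
  })
  expect_lt(errs[2], errs[1] / 5)  # O(dT) gap shrinks with the grid
  expect_lt(errs[2], 0.5)
})

test_that("cooling-scan integration accumulates negative enthalpy", {
  sp <- noise_free_scenario("fig2_cold")
  gen <- generate_thermogram(sp)
  pr <- integrate_profiles(gen$thermogram)
  expect_lt(pr$dH[nrow(pr)], -40)          # exothermic cold denaturation
  expect_lt(gen$ground_truth$dH_true, 0)
  expect_equal(pr$dH[nrow(pr)], gen$ground_truth$dH_true, tolerance = 1e-2)
})

test_that("windowed totals match the generator's analytic ground truth", {
  sp <- noise_free_scenario("fig1_lysozyme")
  gen <- generate_thermogram(sp)
  pr <- integrate_profiles(gen$thermogram, rule = "trapezoid")
  tt <- gen$thermogram$temperature
  w <- transition_window(tt[1], 335, tt[length(tt)])
  tot <- total_changes(pr, w)
  expect_equal(tot$dH_total, gen$ground_truth$dH_true, tolerance = 1e-3)

  wz <- list(t_ini = 320, t_end = 320)  # zero width
  expect_equal(total_changes(pr, wz)$dH_total, 0)
  expect_error(total_changes(pr, transition_window(200, 300, 340)),
               "outside")
})

test_that("cp-step enthalpy follows the triangle formula with sign", {
  expect_equal(cp_step_enthalpy(2.269, transition_window(318, 335, 346)),
               2.269 * 28 / 3, tolerance = 1e-12)
  expect_equal(cp_step_enthalpy(1.0, transition_window(300, 315, 330)), 10)
  expect_equal(cp_step_enthalpy(5, list(t_ini = 320, t_end = 320)), 0)
  # cooling window: negative contribution
  expect_lt(cp_step_enthalpy(0.86, transition_window(310, 279, 259)), 0)
})

test_that("midpoint from the enthalpy/entropy ratio works for both signs", {
  expect_equal(midpoint_from_ratio(-69.5, -0.248), 280.24, tolerance = 1e-3)
  expect_equal(midpoint_from_ratio(104.1, 0.313), 332.59, tolerance = 1e-3)
  expect_equal(midpoint_from_ratio(137, 0.409), 334.96, tolerance = 1e-3)
  expect_error(midpoint_from_ratio(100, 0), "zero")
})

test_that("midpoint ratio recovers the planted T_m of a symmetric peak", {
  p <- stat_params(dE0 = 110, t_m = 335, cv = 0)  # symmetric, no step
  sp <- synthetic_spec("stat_two_state", p, 305, 365, grid_step = 0.17)
  tg <- generate_thermogram(sp)$thermogram
  pr <- integrate_profiles(tg)
  tot <- total_changes(pr, transition_window(306, 335, 364))
  expect_equal(midpoint_from_ratio(tot$dH_total, tot$dS_total), 335,
               tolerance = 0.2 / 335)
})

test_that("transition detection finds planted single and double peaks", {
  sp1 <- noise_free_scenario("fig1_lysozyme")
  g1 <- generate_thermogram(sp1)$thermogram
  tr1 <- detect_transitions(g1)
  expect_equal(nrow(tr1), 1)
  # the detected extremum is the grid argmax of the model curve ...
  expect_equal(tr1$t_m, g1$temperature[which.max(g1$cp)])
  # ... which for this model sits within ~0.5 K of the planted midpoint
  expect_equal(tr1$t_m, 335, tolerance = 0.5 / 335)
  expect_gt(tr1$width, 5)

  sp3 <- noise_free_scenario("fig3_double")
  tr3 <- detect_transitions(generate_thermogram(sp3)$thermogram)
  expect_equal(nrow(tr3), 2)
  # within one grid step of the planted maxima (plus the sub-0.1 K shift of
  # the model's true extremum off the midpoint)
  expect_lt(max(abs(tr3$t_m - c(277.15, 330.15))), 0.27)

  flat <- flat_thermogram(cp = 0)
  expect_equal(nrow(detect_transitions(flat)), 0)
})

test_that("detection survives instrument noise", {
  sp <- scenario("fig1_lysozyme", seed = 7)  # noise_sd 0.05
  tr <- detect_transitions(generate_thermogram(sp)$thermogram)
  expect_equal(nrow(tr), 1)
  expect_equal(tr$t_m, 335, tolerance = 1 / 335)
})

test_that("cp-step estimate recovers the planted plateau difference", {
  p <- lysozyme_eq()  # dCp0 = 2.27 is the plateau difference by construction
  sp <- synthetic_spec("standard", p, 300, 363, grid_step = 0.17)
  tg <- generate_thermogram(sp)$thermogram
  w <- transition_window(318, 335, 352)
  expect_equal(estimate_cp_step(tg, w), 2.27, tolerance = 0.05)

  # statistical two-state: the unfolded branch has slope ~2 Cv T / Tm, so the
  # apparent heat-capacity step is roughly twice Cv - the published DSC step
  # (2.27) versus fitted Cv (1.05) shows the same ratio
  sps <- noise_free_scenario("fig1_lysozyme")
  tgs <- generate_thermogram(sps)$thermogram
  expect_equal(estimate_cp_step(tgs, w), 2 * 1.05 * 352 / 335,
               tolerance = 0.05)
})

test_that("rebasing moves the native plateau to zero and keeps dG identity", {
  sp <- noise_free_scenario("fig3_double")
  tg <- generate_thermogram(sp)$thermogram
  pr <- integrate_profiles(tg)
  expect_identical(rebase_profiles(pr, 0, 0)$dH, pr$dH)

  tr <- detect_transitions(tg)
  tot1 <- total_changes(pr, tr[1, ])
  reb <- rebase_profiles(pr, tot1$dH_total, tot1$dS_total)
  # native plateau between the two transitions
  plateau <- reb$temperature > 295 & reb$temperature < 310
  expect_lt(max(abs(reb$dH[plateau])), 1.5)
  expect_lt(max(abs(reb$dS[plateau])), 0.005)
  expect_equal(reb$dG, reb$dH - reb$temperature * reb$dS)
  # trapezoidal free energy: ~0 on the plateau, negative outside
  expect_lt(reb$dG[nrow(reb)], -1)
  expect_lt(reb$dG[1], 1e-6)
})

test_that("integrated dG of a noise-free heating scan never goes positive", {
  sp <- noise_free_scenario("fig1_lysozyme")
  pr <- integrate_profiles(generate_thermogram(sp)$thermogram)
  expect_lt(max(pr$dG), 1e-8)
})

test_that("enthalpy decomposition is self-consistent", {
  sp <- noise_free_scenario("fig1_lysozyme")
  pr <- integrate_profiles(generate_thermogram(sp)$thermogram)
  w <- transition_window(318, 335, 346)
  dec <- enthalpy_decomposition(pr, w, 1.05)
  expect_equal(dec$dH_total, dec$dH_conf + dec$dH_cp_step)
})
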