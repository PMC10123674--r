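test_that("statistical two-state partition function hits Z(Tm) = 2", {
  p <- lysozyme_stat()
  expect_equal(stat_two_state_lnZ(p, 335), log(2), tolerance = 1e-12)
  # free energy at the midpoint is -R Tm ln 2
  th <- thermo_from_lnZ(stat_two_state_lnZ(p, seq(333, 337, 0.1)),
                        seq(333, 337, 0.1))
  expect_equal(th$F[th$temperature == 335],
               -gas_constant_kcal() * 335 * log(2), tolerance = 1e-10)
})

test_that("single-state limit: Z -> 1 and all functions vanish", {
  p <- stat_params(dE0 = 110, t_m = 335, cv = 0)
  tt <- seq(250, 280, by = 0.5)
  lnZ <- stat_two_state_lnZ(p, tt)
  expect_lt(max(lnZ), 1e-8)
  th <- thermo_from_lnZ(lnZ, tt)
  expect_lt(max(abs(th$E)), 1e-6)
  expect_lt(max(abs(th$S)), 1e-8)
  expect_lt(max(abs(th$Cv_curve)), 1e-6)

  zero <- thermo_from_lnZ(rep(0, 11), seq(300, 310, 1))
  expect_true(all(zero$E == 0 & zero$S == 0 & zero$F == 0 & zero$Cv_curve == 0))
})

test_that("theta_U crosses 1/2 at both heat and cold midpoints", {
  p <- lysozyme_stat()
  tt <- seq(200, 400, by = 0.05)
  th <- extent_unfolded(p, tt)
  expect_equal(extent_unfolded(p, 335), 0.5, tolerance = 1e-12)
  t_cold <- cold_denaturation_temperature(p)
  expect_equal(t_cold, 335 - 110 / 1.05, tolerance = 1e-12)
  expect_equal(extent_unfolded(p, t_cold), 0.5, tolerance = 1e-12)
  # the separation between the two 1/2 crossings equals dE0 / Cv
  cross <- tt[abs(diff(th > 0.5)) == 1]
  expect_equal(diff(range(cross)), 110 / 1.05, tolerance = 0.1 / 100)
  # deep native limit between the crossings
  expect_lt(extent_unfolded(p, 280), 1e-4)
})

test_that("cold denaturation temperature handles edge cases", {
  expect_true(is.na(cold_denaturation_temperature(stat_params(110, 335, 0))))
  expect_equal(cold_denaturation_temperature(stat_params(1e-12, 335, 1.05)),
               335, tolerance = 1e-9)
  # printed parameter sets: lysozyme ~105 C separation, blg heat ~48 C
  expect_equal(335 - cold_denaturation_temperature(lysozyme_stat()),
               104.76, tolerance = 1e-3)
  expect_equal(328 - cold_denaturation_temperature(stat_params(60, 328, 1.25)),
               48, tolerance = 1e-12)
})

test_that("Zimm-Bragg reduces to the statistical two-state at sigma=1, N=1", {
  tt <- seq(200, 400, by = 1)
  zb <- zimm_bragg_params(h0 = 110, cv_res = 1.05, sigma = 1, n_res = 1,
                          t_m = 335)
  st <- lysozyme_stat()
  expect_lt(max(abs(zimm_bragg_lnZ(zb, tt) - stat_two_state_lnZ(st, tt))),
            1e-12)
})

test_that("smaller sigma sharpens the heat-capacity peak", {
  fwhm <- function(sigma) {
    tt <- seq(300, 370, by = 0.05)
    p <- zimm_bragg_params(h0 = 0.91, cv_res = 0, sigma = sigma,
                           n_res = 129, t_m = 335)
    cv <- thermo_from_lnZ(zimm_bragg_lnZ(p, tt), tt)$Cv_curve
    half <- max(cv) / 2
    diff(range(tt[cv >= half]))
  }
  expect_lt(fwhm(5e-7), fwhm(1e-2))
})

test_that("Zimm-Bragg theta_U matches the finite-difference s-derivative", {
  p <- lysozyme_zb()
  tt <- seq(320, 350, by = 0.5)
  th <- extent_unfolded(p, tt)
  expect_equal(extent_unfolded(p, 335), 0.5, tolerance = 1e-9)
  # (s/N) dlnZ/ds by central difference in ln s
  eps <- 1e-7
  s <- thermodsc:::zb_s(p, tt)
  lam <- function(s) thermodsc:::zb_lambda1(s, p$sigma)
  fd <- (log(lam(s * (1 + eps))) - log(lam(s * (1 - eps)))) / (2 * eps)
  expect_lt(max(abs(th - fd)), 1e-6)
  expect_true(all(th >= 0 & th <= 1))
})

test_that("free energy from a partition function is never positive", {
  tt <- seq(200, 400, by = 0.5)
  for (params in list(lysozyme_stat(), lysozyme_zb(),
                      stat_params(-42, 279, 0.45))) {
    lnZ <- if (inherits(params, "stat_params")) {
      stat_two_state_lnZ(params, tt)
    } else {
      zimm_bragg_lnZ(params, tt)
    }
    expect_true(all(lnZ >= 0))
    th <- thermo_from_lnZ(lnZ, tt)
    expect_true(all(th$F <= 1e-12))
    # construction identity S = (E - F)/T
    expect_lt(max(abs(th$S - (th$E - th$F) / th$temperature)), 1e-9)
  }
})

test_that("model Cv integrates back to the total rise of E (conservation)", {
  p <- lysozyme_stat()
  tt <- seq(300, 370, by = 0.02)
  th <- thermo_from_lnZ(stat_two_state_lnZ(p, tt), tt)
  expect_equal(pracma::trapz(tt, th$Cv_curve), th$E[length(tt)] - th$E[1],
               tolerance = 1e-6)
})

test_that("Cv matches the fluctuation identity for T-independent levels", {
  p <- stat_params(dE0 = 110, t_m = 335, cv = 0)
  tt <- seq(320, 350, by = 0.02)
  th <- thermo_from_lnZ(stat_two_state_lnZ(p, tt), tt)
  q <- exp(thermodsc:::stat_log_weight(p, tt))
  w <- q / (1 + q)
  fluct <- 110^2 * w * (1 - w) / (gas_constant_kcal() * tt^2)
  i <- 5:(length(tt) - 4)
  expect_lt(max(abs(th$Cv_curve[i] - fluct[i]) / max(fluct)), 1e-4)
})

test_that("numerical derivatives converge under grid refinement", {
  p <- lysozyme_stat()
  err <- sapply(c(0.5, 0.05), function(h) {
    tt <- seq(330, 340, by = h)
    th <- thermo_from_lnZ(stat_two_state_lnZ(p, tt), tt)
    # analytic E for the two-state form as the oracle
    a <- thermodsc:::stat_log_weight(p, tt)
    dE <- p$dE0 + p$cv * (tt - p$t_m)
    da <- -p$cv * (1 / (gas_constant_kcal() * tt) - 1 / (gas_constant_kcal() * p$t_m)) +
      dE / (gas_constant_kcal() * tt^2)
    E_exact <- gas_constant_kcal() * tt^2 * plogis(a) * da
    max(abs(th$E - E_exact))
  })
  expect_lt(err[2], err[1] / 10)
})

test_that("nucleation free energy follows -RT ln sigma", {
  expect_equal(nucleation_free_energy(5e-7, 335), 9.66, tolerance = 1e-2)
  expect_equal(nucleation_free_energy(7e-5, 326), 6.20, tolerance = 1e-2)
  expect_identical(nucleation_free_energy(1, 300), 0)
  expect_error(nucleation_free_energy(0, 300), "sigma")
  expect_error(nucleation_free_energy(1.5, 300), "sigma")
})

test_that("thermo_from_lnZ validates its grid", {
  expect_error(thermo_from_lnZ(rep(0, 4), c(300, 301, 302, 303)),
               "at least 5")
  expect_error(thermo_from_lnZ(rep(0, 6), seq(300, 304, 1)), "equal length")
})
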