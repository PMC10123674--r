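---
title: "Thermodynamics of protein unfolding from DSC thermograms: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thermodynamics of protein unfolding from DSC thermograms: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermodsc)
```

## Scope and assumptions

`thermodsc` analyses baseline-corrected molar excess heat capacities
$C_p(T)$ of protein unfolding measured by differential scanning
calorimetry. "Baseline-corrected" means the instrument baseline and the
buffer reference have been subtracted so that the native protein reads
$C_p = 0$; vendor-specific raw formats and buffer-scan subtraction are out
of scope. Temperatures are kelvin everywhere inside the package; degrees
Celsius appear only at I/O boundaries (`units = "celsius"`) and in
reporting, with the offset fixed at 273.15. All energies are
kcal mol^-1^ and the gas constant is $R = 1.987\times10^{-3}$
kcal mol^-1^ K^-1^ (`gas_constant_kcal()`).

Volume changes on unfolding are small, so the constant-volume quantities
delivered by the partition-function machinery ($\Delta E$, $\Delta S_v$,
$\Delta F$) are compared directly with the calorimetric constant-pressure
ones ($\Delta H$, $\Delta S_p$, $\Delta G$).

## Model-free evaluation

The cumulative profiles are running sums over the recorded grid,

$$\Delta H(T_i)=\sum_{j<i} C_p(T_j)\,\Delta T_j,\qquad
  \Delta S(T_i)=\sum_{j<i} \frac{C_p(T_j)}{T_j}\,\Delta T_j,\qquad
  \Delta G = \Delta H - T\,\Delta S,$$

started at the native end of the scan: the first recorded point of a
heating scan, the high-temperature first point of a cooling scan. On a
cooling scan the steps $\Delta T_j$ are negative, so an exothermic
transition accumulates negative enthalpy without any sign juggling. The
left-Riemann sum is the default because it is the natural discrete form
for instrument data sampled in steps; `rule = "trapezoid"` is available
and the two agree to $O(\Delta T)$ (asserted by a grid-refinement test).
For a non-negative heating peak the construction guarantees
$\Delta G \le 0$ — the experimental signature that the package's model
comparison is built around.

Two closed forms complete the model-free toolkit. The heat-capacity step
$\Delta C_p^0$ between unfolded and native plateaus contributes
$\Delta H_{\Delta C_p^0} = \Delta C_p^0\,(T_{end}-T_{ini})/3$ to the total
enthalpy; the divisor is 3 rather than the straight-line triangle's 2
because the step rises along the sigmoidal extent of unfolding. And the
ratio of windowed totals $\Delta H/\Delta S$ predicts the transition
midpoint, for heat and cold denaturation alike.

## The four models

**Standard chemical-equilibrium two-state model.** Linear van't Hoff
enthalpy $\Delta H_{NU}(T)=\Delta H_0+\Delta C_p^0 (T-T_m)$, entropy
$\Delta S_{NU}(T) = \Delta H_0/T_m + \Delta C_p^0 \ln(T/T_m)$, parabolic
$\Delta G_{NU}$, equilibrium constant $K_{NU}=e^{-\Delta G_{NU}/RT}$ and
$\Theta_U = K_{NU}/(1+K_{NU})$. Its heat capacity — the derivative of
$\Theta_U \Delta H_{NU}$ —

$$C_p = \Theta_U\,\Delta C_p^0 +
  \frac{\Delta H_{NU}^2\,\Theta_U(1-\Theta_U)}{R T^2}$$

fits DSC peaks well, but the model's thermodynamic functions do not: it
assigns the native protein a *positive* free energy and full enthalpy at
temperatures where the measured heat capacity (and hence every integrated
profile) is zero. The package deliberately retains and reports these
curves: their mismatch against the integrated profiles is the diagnostic
`compare_models()` quantifies.

**$\Theta_U$-weighted variant.** The same three functions multiplied
pointwise by $\Theta_U(T)$. All three now vanish in the native limit and
$\Delta G_\Theta(T_m)=0$ exactly, but a small positive free-energy lobe
survives just below $T_m$; `compare_models()` flags any model whose
free-energy curve exceeds `max(0.02, 3 * noise)` kcal/mol anywhere
(`positive_dG`).

**Statistical-mechanical two-state model.** A two-level canonical
partition function with a temperature-dependent level spacing,

$$Z(T) = 1+\exp\!\left[-\Delta E(T)\Big(\tfrac{1}{RT}-\tfrac{1}{RT_m}\Big)\right],
\qquad \Delta E(T)=\Delta E_0 + C_v\,(T-T_m).$$

Since $Z \ge 1$, $F = -RT\ln Z \le 0$ always, and $F(T_m) = -RT_m\ln 2$
($-0.46$ kcal/mol at 335 K). $\Delta E(T)$ vanishes at
$T_{cold}=T_m-\Delta E_0/C_v$, giving cold denaturation analytically;
$\Delta E_0$ stabilises the fold, the fluctuation term $C_v$ destabilises
it. A useful identity of this form: on the unfolded branch
$E(T) = \Delta E_0 - C_v T_m + C_v T^2/T_m$, so the *apparent*
heat-capacity step in a fitted thermogram is $\approx 2 C_v T/T_m$ —
about twice the parameter $C_v$. That factor is why a thermogram whose
measured step is $\sim$2.3 kcal/(mol K) is fitted by $C_v \approx 1.05$.

**Multistate cooperative Zimm–Bragg model.** Residue-level helix–coil
statistics via the largest transfer-matrix eigenvalue,

$$s(T)=\exp\!\left[-h(T)\Big(\tfrac{1}{RT}-\tfrac{1}{RT_m}\Big)\right],\quad
\lambda_1=\tfrac{1+s}{2}+\sqrt{\Big(\tfrac{1-s}{2}\Big)^2+\sigma s},\quad
\ln Z = N \ln \lambda_1,$$

with $h(T)=h_0+c_v (T-T_m)$ per residue. At $\sigma = 1$ and $N = 1$ this
collapses exactly onto the statistical two-state form (pinned by a test
at $10^{-12}$). Smaller $\sigma$ sharpens the transition; the nucleation
free energy $\Delta G_\sigma = -RT\ln\sigma$ is the package's
cooperativity-based stability measure, evaluated at $T_m$ by default
since no other convention fixes the temperature.

These algebraic forms are pinned by their printed consequences —
$Z(T_m)=2$, $\Theta_U(T_m)=1/2$ in every model, the
$\Delta T = \Delta E_0/C_v$ heat/cold separation, and the $\sigma=1$
reduction — each of which is an explicit test.

### Partition-function engine

`thermo_from_lnZ()` converts any $\ln Z(T)$ sampled on a grid into
$E = RT^2\,d\ln Z/dT$, $F=-RT\ln Z$, $S=(E-F)/T$ and $C_v = dE/dT$ using
central differences (one-sided at the ends). Derivatives are numerical
rather than symbolic so that any alternative partition function drops in
unchanged; a step-refinement test confirms the expected convergence and a
fluctuation-identity test checks $C_v$ against
$\langle E^2\rangle - \langle E\rangle^2$ for temperature-independent
levels. Grids of 0.5 K or finer are recommended (at least 5 points are
required); the identity $S=(E-F)/T$ holds to $10^{-9}$ by construction.
The extent of unfolding uses the analytic eigenvalue derivative,
$\Theta_U = s\,\lambda_1'/\lambda_1$, verified against a
finite-difference $\partial \ln Z/\partial \ln s$.

## Transition detection and initial values

Detection looks for interior local extrema of $|C_p|$ above
`noise_mult` (default 5) times the median absolute deviation of the
flattest contiguous decile of the (linearly detrended) trace. Window
edges $T_{ini}/T_{end}$ sit where the baseline-corrected $|C_p|$ first
and last exceeds `peak_frac` (default 2%) of the peak height, with the
local baseline taken as the median over the outer tenth of each flank, so
a $\Delta C_p^0$ step does not inflate the window. Ripples on a peak's
shoulder are merged unless separated by a dip below half the smaller
neighbour. Both thresholds are exposed as arguments because no standard
detection rule exists in the field; the defaults recover planted peak
positions to within one grid step on noise-free scans and within
$\sim$0.5 K at realistic noise. Note that a model's $C_p$ maximum is not
exactly its midpoint: temperature-dependent level spacing shifts the
extremum by a few tenths of a kelvin, which is visible in the tests'
tolerances.

Fit initialisation derives $T_m$ from the peak position, the step from
the plateau difference (`estimate_cp_step()`, outer-10%-flank means), and
the conformational enthalpy from the windowed enthalpy total minus the
step's triangle contribution.

## Fitting

The objective is always the $C_p$ residual — what the instrument
measures; profile residuals are diagnostics. Levenberg–Marquardt
(`minpack.lm::nls.lm`) with box bounds: $T_m$ within the data span
±20 K, enthalpies sign-free (cold-denaturation-only fits need negative
values), $C_v \ge 0$, and $\sigma$ log~10~-parameterised in
$[10^{-9}, 1]$ with the residue count $N$ held fixed (it is a structural
input, not an identifiable parameter alongside $h_0$). A seeded
multistart (default 8 launches, seed 0, recorded in the result) jitters
the auto-initial values; the best converged solution wins, making fits
bit-for-bit reproducible for a given data/seed pair. Two-transition scans
are fitted as the sum of two independent transitions, with an optional
shared constant baseline (default off, since inputs are
baseline-corrected). When windows are auto-detected the fit defaults to
the strongest single transition; passing two windows explicitly requests
the simultaneous fit — an explicit choice rather than a data-dependent
surprise.

Noise-free self-generated thermograms are recovered to within 0.1% for
all four models ($\sigma$ compared on its log scale); at a realistic
noise of 0.05 kcal/(mol K), 20 seeded replicates keep the enthalpy
within 2% and $T_m$ within 0.2 K, with bias below the replicate spread.

## The synthetic generator

`scenario()` encodes the three experimental situations the package is
designed around, with published fit parameters as the generating truth:

* `fig1_lysozyme` — heating scan, 298–363 K, statistical two-state
  $\Delta E_0 = 110$ kcal/mol, $C_v = 1.05$ kcal/(mol K), $T_m = 335$ K.
* `fig2_cold` — cooling scan recorded 310 K $\to$ 259 K, statistical
  two-state $\Delta E_0 = -42$ kcal/mol, $C_v = 0.45$ kcal/(mol K),
  $T_m = 279$ K; integration yields the negative (exothermic) enthalpy
  of cold denaturation.
* `fig3_double` — heating scan 264–344 K with a disorder$\to$order
  transition followed by heat unfolding. The published record gives
  per-transition totals but no single generating parameter set, so the
  preset uses two additive chemical-equilibrium transitions with
  conformational enthalpies of 56 kcal/mol each and midpoints at the
  published heat-capacity maxima, 277.15 K (4 °C) and 330.15 K (57 °C).
  The heat-capacity step is set to zero here so that the planted maxima
  coincide with the midpoints — the double-peak geometry, not the step,
  is what this scenario exercises.

Defaults shared by all scenarios: grid step 0.17 K (the stated
temperature resolution of the underlying instruments), i.i.d. Gaussian
noise with sd 0.05 kcal mol^-1^ K^-1^ (a realistic modern-instrument
noise floor; no published noise characterisation exists for these
traces), optional linear baseline drift (default 0), and a recorded seed
(`withr::with_seed`, so session RNG state is untouched). Ground truth
totals are computed by trapezoid quadrature of the noise-free model curve
on a 10× finer grid over the emitted span, making them independent of
the emitted grid's integration rule.

What the generator does *not* emulate — and therefore what passing tests
do not demonstrate about real data: autocorrelated instrument noise,
scan-rate effects and refolding hysteresis, aggregation exotherms,
residual structure in the "unfolded" state, and imperfect baseline
correction. Results on real thermograms inherit all of those caveats.

## Numerical choices and degenerate inputs

* $\Theta_U$ is evaluated as a logistic in $-\Delta G/RT$ (log-space), so
  it is finite for arbitrarily large $|\Delta G|$; $K_{NU}$ itself may
  overflow to `Inf` deep in the unfolded state, by design.
* `log1p`-style evaluation keeps $\ln(1+e^a)$ accurate for large $a$.
* Zero-width windows give zero totals; a window outside the grid, a
  non-monotone grid, fewer than 3 points, or a zero-length temperature
  step raise validation errors naming the offence; an undetectable
  transition yields an empty table, not an error; $C_v = 0$ makes
  `cold_denaturation_temperature()` return `NA` (no cold denaturation in
  that model) rather than throwing.
* Ties in `compare_models()` keep input order; ranking combines profile
  residuals with the entropy residual weighted by the mid-scan
  temperature to bring it to energy units.
* Thermogram CSVs are written at 17 significant digits so write/read
  round-trips are bit-identical.

Problem sizes throughout the test suite are chosen for sub-second
single-fit runtimes: synthetic scans of 300–500 points (0.17 K grids over
60–80 K spans), fine oracle grids up to $10^4$ points, and 20-replicate
noise studies.

## Known limitations

Two printed values in the source material are internally inconsistent
and are resolved as follows: a cold-unfolding step enthalpy reported as
−18.9 kcal/mol disagrees with the triangle formula evaluated from the
printed step and window (≈ −14.6); the package reports the formula value.
A cold-denaturation entropy appears both as 0.3283 and 0.283
kcal mol^-1^ K^-1^; only 0.283 is consistent with the printed 277 K
midpoint ratio, so that value is used where the ratio matters. For the
β-lactoglobulin double-transition data, the statistical and multistate
models' printed heat/cold separations (46/48 °C) are not all reproducible
from their own printed parameter ratios; the package reports the ratio
implied by the parameters and does not tune toward the printed values.

The multistate model's $N$ must be supplied, not fitted. The standard
model's parabolic free energy is reported, never "corrected". And the
package analyses equilibrium thermograms only — kinetic distortions are
invisible to it.
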