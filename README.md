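# thermodsc

Model-free and model-based analysis of protein unfolding thermograms from
differential scanning calorimetry (DSC).

DSC is the one technique that measures a thermodynamic quantity of protein
unfolding directly: the molar excess heat capacity C<sub>p</sub>(T). This
package is for calorimetrists and protein scientists who want to go beyond
fitting the C<sub>p</sub> peak: it converts a baseline-corrected thermogram
into full temperature profiles of unfolding enthalpy, entropy and free
energy without assuming any model, and then confronts those profiles with
four unfolding models, producing protein stability reports (melting and
cold-denaturation temperatures, transition widths, enthalpy decomposition,
cooperativity and nucleation free energy).

## What it computes

**Model-free profiles.** With temperatures sampled in discrete steps ΔT,

- ΔH(T) = Σ C<sub>p</sub>(T<sub>j</sub>) ΔT<sub>j</sub>
- ΔS(T) = Σ (C<sub>p</sub>(T<sub>j</sub>)/T<sub>j</sub>) ΔT<sub>j</sub>
- ΔG(T) = ΔH(T) − T·ΔS(T)

integrated from the native end of the scan. Enthalpy and entropy come out
sigmoidal; because of enthalpy–entropy compensation the free energy is
small and trapezoidal — approximately zero across the native plateau and
negative beyond both the heat- and cold-denaturation midpoints. The total
calorimetric enthalpy splits into a conformational part and the part
carried by the heat-capacity step ΔC<sub>p</sub>⁰ between native and
unfolded protein, ΔH<sub>ΔCp⁰</sub> = ΔC<sub>p</sub>⁰(T<sub>end</sub> −
T<sub>ini</sub>)/3, and the ratio ΔH/ΔS predicts the transition midpoint
T<sub>m</sub>.

**Four unfolding models**, all exposed through one fitting and comparison
interface:

| model | parameters | free energy at T<sub>m</sub> |
|---|---|---|
| standard chemical-equilibrium two-state | ΔH₀, T<sub>m</sub>, ΔC<sub>p</sub>⁰ | 0 (and positive for the native state) |
| Θ<sub>U</sub>-weighted two-state | ΔH₀, T<sub>m</sub>, ΔC<sub>p</sub>⁰ | exactly 0, small positive lobe nearby |
| statistical-mechanical two-state | ΔE₀, T<sub>m</sub>, C<sub>v</sub> | −RT<sub>m</sub> ln 2 (≈ −0.46 kcal/mol at 335 K) |
| multistate cooperative Zimm–Bragg | h₀, c<sub>v</sub>, σ, N, T<sub>m</sub> | ≤ 0 everywhere |

The two partition-function models are driven through a common engine
(E = RT² dlnZ/dT, F = −RT lnZ, S = (E − F)/T, C<sub>v</sub> = dE/dT), so
their free energy can never be positive — the key property the
model-free profiles show and the chemical-equilibrium models violate. The
statistical-mechanical model gives a closed form for cold denaturation,
T<sub>cold</sub> = T<sub>m</sub> − ΔE₀/C<sub>v</sub>, and the Zimm–Bragg
cooperativity parameter yields the nucleation free energy
ΔG<sub>σ</sub> = −RT ln σ.

Because public repositories carry no machine-readable DSC traces, the
package ships a seeded synthetic-thermogram generator
(`scenario()` / `generate_thermogram()`) that emulates the three canonical
experimental situations — a lysozyme-like heating scan, an exothermic
β-lactoglobulin-like cooling scan, and a double cold + heat transition —
with analytic ground truth for every simulated scan.

## Worked example

```r
library(thermodsc)

sp  <- scenario("fig1_lysozyme", seed = 42)   # 0.17 K grid, noise sd 0.05
gen <- generate_thermogram(sp)
tg  <- gen$thermogram

detect_transitions(tg)
#> # A tibble: 1 × 5
#>   t_ini   t_m t_end peak_cp width
#>   <dbl> <dbl> <dbl>   <dbl> <dbl>
#> 1  324.  335.  345.    14.8  20.7

fit <- fit_model(tg, model = "stat_two_state")
fit
#> <DSC model fit>  stat_two_state, rmsd(Cp) = 0.04843 kcal/(mol K), converged (15 iter, seed 0)
#> <statistical two-state>  dE0 = 109.995 kcal/mol, Tm = 335.001 K, Cv = 1.04965 kcal/(mol K)

stability_report(tg, fit = fit)
#> <DSC stability report>
#>   transitions detected: 1
#>   T_m (peak):   335.40 K (62.25 C)
#>   T_m (dH/dS):  335.82 K (62.67 C)
#>   peak width:   20.74 K
#>   T_cold:       230.21 K,  delta T = 104.79 K
```

Reading the output: the thermogram was generated from ΔE₀ = 110 kcal/mol,
C<sub>v</sub> = 1.05 kcal/(mol K), T<sub>m</sub> = 335 K with realistic
instrument noise, and the fit recovers all three to a fraction of a
percent (`rmsd(Cp)` ≈ the injected noise, as it should be). The
model-free midpoint estimates — the C<sub>p</sub> peak position and the
ΔH/ΔS ratio — agree with each other and with the generating midpoint to
well under a kelvin, and the fitted model predicts cold denaturation
about 105 K below the heat transition. `integrate_profiles(tg)`,
`autoplot()` on any result, `tidy(fit)`/`glance(fit)` and
`compare_models()` continue the pipeline.

A thin command line lives in `inst/cli/thermodsc.R` with subcommands
`simulate`, `integrate`, `fit` and `report` over CSV/JSON files.

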