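# isophys

Statistical-physics modelling of equilibrium adsorption isotherms, built for
quartz crystal microbalance (QCM) studies of metal-ion binding to porphyrin
films — and for any adsorption data where a grand-canonical site-occupation
model is the right description.

## The problem and the models

A QCM titration yields an isotherm: adsorbed quantity `Q_a` (µg/cm²) versus
equilibrium concentration `c` (mol/L) at fixed temperature, obtained from the
Sauerbrey relation `Δf_m = −C·Δm`. Classical empirical isotherms (Langmuir,
Freundlich) fit such curves but say little about mechanism. The
statistical-physics family used here derives `Q_a` from a per-site
grand-canonical partition function, so every fitted parameter has a physical
reading:

| model | closed form | saturates at |
|---|---|---|
| mono-layer, ideal gas | `Q_a = n·P_M / (1 + (c_half/c)^n)` | `n·P_M` |
| mono-layer, real gas  | `c_half → w_half·(1−bc)·e^{2βac}·e^{−bc/(1−bc)}` | `n·P_M` |
| double-layer, ideal gas | `Q_a = n·P_M·[(c/c1)^n + 2(c/c2)^{2n}] / [1 + (c/c1)^n + (c/c2)^{2n}]` | `2·n·P_M` |
| double-layer, real gas | double-layer with real-gas-corrected ratios | `2·n·P_M` |

`n` is the number of ions per receptor site (`n < 1`: multi-docking), `P_M`
the receptor-site density, `c_half`/`c1`/`c2` energetic concentrations that
encode adsorption energies via `|E| = R·T·ln(S/c_x)` (with `S` the adsorbate
solubility), and `a`, `b` van der Waals lateral-interaction parameters that
can bend an isotherm downward past its maximum. From the same partition
function the package derives configurational entropy and reduced free
enthalpy curves; the mono-layer entropy peaks exactly at `c_half`.

The workflow: reduce a QCM injection log (`reduce_trace()`), fit one model
(`isofit()`, multi-start Levenberg–Marquardt) or compare all four
(`select_model()`, scored by R², RMSE and AIC), fit across temperatures
(`fit_temperatures()`), classify the thermal character (`trend_report()`),
and compute thermodynamic curves (`thermo_curves()`, `entropy_peaks()`).
`run_pipeline()` chains everything and writes delimited-text reports. A
synthetic-data module (`published_fit_params()`, `generate_isotherm()`,
`generate_qcm_trace()`) provides generating truths and noise so every stage
is testable without laboratory data.

## Worked example

Generate a noisy mono-layer isotherm from a published zinc/porphyrin
parameter set and refit it:

```r
library(isophys)
fx  <- published_fit_params()
iso <- generate_isotherm(fx$ZnCl2$params[["300"]],
                         noise = noise_model("mult_gauss", 0.02, seed = 1),
                         T = 300)
fit <- isofit(iso, "mono_ideal", weights = "relative")
fit
#> <isofit> mono_ideal, T = 300 K, 50 points
#>   n       = 0.938213
#>   P_M     = 424.514
#>   c_half  = 0.00807085
#>   R2 = 0.999609, RMSE = 2.255, AIC = -405.2
```

The generating truth was `n = 0.94`, `P_M = 421.4`, `c_half = 0.008`: at 2%
multiplicative noise the fit recovers all three to well under 1%. Model
comparison confirms the mono-layer description:

```r
select_model(iso, c("mono_ideal", "double_ideal"), weights = "relative")
#> <iso_selection> T = 300 K; chosen model: mono_ideal
#>         model k_params     r2  rmse     aic converged
#>    mono_ideal        3 0.9996 2.255 -405.16      TRUE
#>  double_ideal        4 0.9996 2.257 -404.23      TRUE
#>   max relative residual 0.0488 -> 5% gap satisfied
```

The entropy maximum sits at the fitted half-saturation concentration, and a
user-supplied solubility converts it to an adsorption energy:

```r
entropy_peaks(thermo_curves(fit$params, T = 300))
#>            c S_over_kB
#> 1 0.00807085  294.2505
adsorption_energy(coef(fit)["c_half"], S = 31.7, T = 300)
#> [1] 20.64153   # kJ/mol: physisorption-range binding for this S
```

A command-line front end over the same functions lives at
`inst/scripts/isophys` (subcommands `simulate`, `reduce`, `fit`, `select`,
`thermo`, `run`).

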