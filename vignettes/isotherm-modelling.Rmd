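---
title: "Statistical-physics modelling of QCM adsorption isotherms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical-physics modelling of QCM adsorption isotherms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isophys)
```

## The physical model

`isophys` analyses equilibrium adsorption isotherms — adsorbed quantity
$Q_a$ (µg/cm²) versus bulk concentration $c$ (mol/L) at fixed temperature —
with a family of models derived from a grand-canonical partition function per
receptor site. A surface carries $P_M$ identical receptor sites (µg/cm²,
commensurate with $Q_a$); each site binds $n$ ions ($n < 1$ is read as
multi-docking, one ion shared across several sites). With the per-site
partition function $z_{gc}$ and chemical potential $\mu$, the occupancy is
$N_0 = (P_M/\beta)\,\partial \ln z_{gc}/\partial\mu$ and $Q_a = n N_0$.
Substituting the ideal-gas potential $\beta\mu = \ln(c/z_{tr})$ turns every
Boltzmann factor into a concentration ratio, giving four closed forms:

* **mono-layer, ideal gas** — $Q_a = n P_M \big/ \left(1 + (c_{1/2}/c)^n\right)$,
  with half-saturation concentration $c_{1/2}$;
* **mono-layer, real gas** — $c_{1/2}$ replaced by
  $w_{1/2}\,(1-bc)\,e^{2\beta a c}\,e^{-bc/(1-bc)}$, where $a$ (cohesion
  pressure) and $b$ (covolume) are van der Waals lateral-interaction
  parameters; the curve can rise and then decline when $2\beta a c$ and $bc$
  reach order one;
* **double-layer, ideal gas** —
  $Q_a = n P_M\,\frac{(c/c_1)^n + 2 (c/c_2)^{2n}}{1 + (c/c_1)^n + (c/c_2)^{2n}}$,
  two energetic concentrations $c_1, c_2$ for the two layers (layer-by-layer
  adsorption, e.g. a cation layer completed by an anion layer);
* **double-layer, real gas** — the same with real-gas-corrected ratios.

Mono-layer models saturate at $n P_M$, double-layer ones at $2 n P_M$.
The energetic concentrations encode adsorption energies through
$c_x = S\,e^{-E_x/(k_B T)}$ with $S$ the adsorbate solubility, so
$|E_x| = R T \ln(S/c_x)$ (reported in kJ/mol; `adsorption_energy()`).
Magnitudes above roughly 40 kJ/mol mark chemisorption; below, physisorption.
No default $S$ is shipped — it is adsorbate- and medium-specific, and
energies are only computed when the user supplies it.

Every closed form is cross-checked in the test suite against an independent
route: `q_partition_deriv()` differentiates $\ln z_{gc}$ numerically with
respect to $\beta\mu$ (each occupation ratio scales as $e^{kh}$ under a
shift $h$, $k$ the layer's adsorbate count), and must agree with the closed
form to $10^{-6}$ relative.

### Units and the $\beta$ convention

Published fitted values of $a$ and $b$ in this literature typically come
without units. In the default `units_mode("reduced")` the package therefore
takes $\beta \equiv 1$ and uses $a$, $b$ verbatim as dimensionless-group
scalars; `units_mode("physical")` sets $\beta = 1/(RT)$ for unit-explicit
work. Parameter recovery is unaffected by the convention; the convention is
stamped into every report. A consequence worth knowing: magnitudes of
$a \sim 10^{-9}$ and $b \sim 10^{-12}$ leave $2\beta a c$ and $bc$ around
$10^{-10}$ for $c \le 0.1$ mol/L, i.e. numerically inert — such values
cannot bend an isotherm downward, and fitting them freely is
ill-conditioned. `isofit()` therefore supports fixing them (`fixed =`), and
`nickel_like_params()` provides a synthetic set ($a = 30$, $b = 2$) whose
groups do reach order one inside the default grid, so the non-monotone
regime is testable.

## QCM reduction

A quartz crystal microbalance experiment titrates stock solution into a
measuring cell (volume $V_s$, default 150 mL) and records the resonance
frequency shift after each step. Under the standard assumptions — constant
temperature, polished crystal, negligible solution viscosity/density and
pressure effects, all flagged on `qcm_config()` — the shift from the
stabilised baseline is the Sauerbrey mass term alone,
$\Delta f_m = -C\,\Delta m$, with $C$ the crystal sensitivity factor
(Hz·cm²/µg; calibration-specific, no default). Matter conservation gives the
injected volume $V_{ad} = c_f V_s / c_0$ per target concentration; the added
volumes (≤ 2 mL against 150 mL) are by default not subtracted from $V_s$,
an approximation that `reduce_trace(account_added_volume = TRUE)` can undo
for sensitivity analysis. `generate_qcm_trace()` simulates exactly the
protocol `reduce_trace()` inverts, and the round trip is exact without
noise.

## Fitting, scoring, selection

`isofit()` minimises residuals by Levenberg–Marquardt (via \pkg{minpack.lm})
under box bounds ($n \in [0.05, 5]$, $P_M \in [10^{-3}, 10\max q]$,
energetic concentrations $\in [10^{-6}, 10]$ mol/L, $a, b \in [0, 10^{-6}]$
unless overridden). Besides the default start ($n = 1$, $P_M = \max q$ for
mono-layer or $\max q / 2$ for double-layer, concentrations at the grid
median), double-layer models get one deterministic layer-separated start
($P_M = \max q$, second concentration at the grid top): the symmetric
default start can funnel the optimiser into a merged-layer local minimum
when the second plateau is only partly developed. The remaining starts are
seeded log-uniform jitters (factor 20), so results are reproducible given
the seed.

Two objectives are available. `weights = "none"` (default) minimises raw
residuals; `weights = "relative"` divides residuals by the model prediction,
which is the maximum-likelihood choice when errors are multiplicative — the
natural error model for QCM-derived quantities spanning two decades, and the
model the synthetic generator implements. The replicate studies below use
relative weighting for that reason.

Fits are scored by $R^2 = 1 - RSS/TSS$, $RMSE = \sqrt{RSS/(N-k)}$
(residual-degrees-of-freedom convention; values below 2 are conventionally
flagged as descriptive) and the least-squares Akaike criterion
$AIC = N \ln(RSS/N) + 2k$. Only AIC differences matter for selection. Two
numerical choices: the RSS inside the logarithm is floored — at $10^{-30}$
in `goodness()`, and at the fit's numerical resolution
($N (10^{-11}\,\mathrm{scale})^2$) inside `isofit()` — so that numerically
perfect fits give finite AIC and, importantly, two nested models that both
reach machine-precision residuals score as an exact tie instead of an AIC
difference made of rounding dust.

`select_model()` picks the lowest-AIC converged candidate, with one
refinement: candidates within 2 AIC units of the minimum are treated as
statistically equivalent and the most parsimonious of them wins. This is the
standard equivalence reading of small AIC differences; without it, a
4-parameter model that is a superset of a 3-parameter truth is chosen in a
substantial fraction of noisy replicates purely by fitting noise
($\Delta RSS \sim \chi^2_1$ against a penalty of 2). Set
`delta_aic_tie = 0` for strict minimisation. The report also states whether
the maximum relative residual of the chosen fit is within 5% (computed on
points above 1% of the curve maximum, so near-zero observations do not
dominate the ratio) — the conventional 95%-confidence gap for a descriptive
fit.

`fit_temperatures()` assembles one fit per temperature into a
parameters-by-temperature table, and `trend_report()` classifies it:
monotone increase of both $n$ and $P_M$ with temperature is reported as
endothermic adsorption (heating exposes additional receptor sites), monotone
decrease as exothermic, anything else as mixed; the cohesion pressure's own
trend is reported separately.

## Thermodynamics

From the same partition function, the configurational entropy per unit area
is $S_a/k_B = P_M(\ln z_{gc} - \sum_i p_i \ln y_i)$ with $p_i$ the state
probabilities and $y_i$ the occupation ratios — for a mono-layer model
$P_M\left(\ln(1+x) - x\ln x/(1+x)\right)$, which vanishes at both
concentration extremes and is maximal exactly at $x = 1$, i.e. at
$c = c_{1/2}$: the half-filled surface is the most disordered. A
double-layer system with well-separated energetic concentrations shows one
peak near $c_1$ and a second near the layer-dominance crossover $c_2^2/c_1$.
One derivation detail: for the double-layer entropy the second-layer ratio
carries the exponent $2n$, as the partition function dictates; a published
variant uses $n$ there, which we believe to be typographical, and which is
available behind `as_printed = TRUE` for comparison. Entropy expressions are
implemented in overflow-safe log-sum-exp form.

The reduced free enthalpy is $G/(k_B T) = \beta\mu(c)\, Q_a(c)$, using the
real-gas potential
$\beta\mu_r = \ln(c/z_{tr}) - \ln(1-bc) + bc/(1-bc) - 2\beta a c$ for the
real-gas mono-layer model and the ideal potential otherwise. It is negative
wherever $c < z_{tr}$ and the surface is partly filled — adsorption
proceeds spontaneously toward saturation — a statement conditional on the
translational reference $z_{tr}$, for which no published value exists; the
package defaults to $z_{tr} = 1$ mol/L and records it in every output.
`entropy_peaks()` locates strict interior maxima by grid scan and refines
them with Brent search on the closed form in log-concentration (to about
$10^{-5}$ relative in $c$); plateaus with differences below $10^{-12}$ are
not counted.

## The synthetic-data generator

No raw isotherms from the motivating experiments are publicly tabulated, so
the package ships a generator that defines the study conditions under which
everything is tested:

* `published_fit_params()` — the published fitted parameter sets for the three
  metal-chloride/porphyrin systems (ZnCl₂ mono-layer ideal, NiCl₂ mono-layer
  real, CrCl₂ double-layer ideal) at 285–300 K, used verbatim as generating
  truths;
* `default_grid()` — 50 log-spaced concentrations on $[10^{-4}, 0.05]$
  mol/L, inside what 10⁻³–0.1 mol/L stocks diluted into 150 mL can reach;
* `noise_model("mult_gauss", sigma_rel = 0.02)` — multiplicative Gaussian
  noise, the relative-error model appropriate for quantities spanning two
  decades; 2% is a realistic QCM repeatability figure. Negative noisy values
  are clipped at zero with a warning (rare at 2%).

What the generator does *not* emulate: baseline drift, viscoelastic
(non-Sauerbrey) film response, adsorbate speciation and ionic-strength
effects, porphyrin aggregation, and temperature errors. Passing tests
therefore demonstrate the *statistical machinery* — recovery, selection,
thermodynamic structure — under the assumed error model, not the fidelity of
these models to any particular laboratory system.

## Verification summary and problem sizes

The test suite (all sizes chosen to keep each study at seconds on one CPU):

* noiseless 50-point curves from all 12 published parameter columns are
  refit to better than $10^{-4}$ relative error (real-gas $a$, $b$ fixed at
  truth — see the ill-conditioning note above);
* with 2% noise, 20 replicates per generating model, the signed median
  relative bias of $n$ and $P_M$ stays below 2% and the generating model is
  selected in at least 95% of replicates (mono-ideal truth vs a
  well-separated double-ideal truth, $c_1 = 5\times10^{-4}$,
  $c_2 = 0.015$ mol/L — the regime where the two hypotheses are genuinely
  distinguishable on the default grid);
* the mono-layer entropy maximum is located at $c_{1/2}$ to $10^{-5}$
  relative; double-layer peaks match an independent dense-grid brute force;
* generator → reducer → fitter round trips are exact without noise;
  mole bookkeeping conserves matter to $10^{-12}$.

## Known limitations

* Free fitting of $a$ and $b$ is supported but ill-conditioned whenever
  their dimensionless groups are small; fix them when independent values
  exist.
* Published criterion tables and energy tables for the motivating systems
  are not reproducible here: the raw isotherms and the solubilities behind
  them were never published. The package recomputes energies only from a
  user-supplied solubility.
* Whether a double-layer system with closely spaced $c_1, c_2$ (ratio ~10)
  resolves two entropy maxima is numerically delicate; the two-peak
  structure is asserted only for well-separated layers.
* The free-enthalpy sign statement depends on $z_{tr}$, which is a
  convention here, not a measurement.
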