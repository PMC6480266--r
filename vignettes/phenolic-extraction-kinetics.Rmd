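---
title: "Modelling phenolic extraction kinetics in red wine fermentation"
author: "phenolex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling phenolic extraction kinetics in red wine fermentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenolex)
```

## The model

Red wine gets its colour and mouthfeel from phenolics extracted out of grape
solids during fermentation: anthocyanins and tannins from the skins, tannins
from the seeds. `phenolex` pools these into three pseudo-species —
`anthocyanin`, `skin_tannin`, `seed_tannin` — and tracks, for each species
$i$ and per litre of must, five pools closed by a mass balance:

$$C_{i,G0} = C_{i,G} + C_{i,S} + C_{i,F} + C_{i,R} + C_{i,U}$$

where $C_{i,G0}$ is the initial reservoir in the grape, $C_{i,G}$ the
available-but-unreleased amount, $C_{i,S}$ the amount adsorbed on grape
cell-wall material, $C_{i,F}$ the amount free in solution (what a sampled
fermentation measures), $C_{i,R}$ the amount lost to reaction, and $C_{i,U}$
a temperature-dependent amount that can never be extracted.

Three processes move mass between pools:

1. **Release.** Skin phenolics leave the solids first order in the driving
   force, $dC_{i,G}/dt = -k_G (C_{i,G} - C_{i,F})$ — the signature of a
   diffusion-driven process. Seed tannins release at a constant (zero-order)
   rate, $dC_{G}/dt = -k_{G,seed}$, consistent with a diffusion path that
   shortens (the seed's outer layer ablating) as the concentration gradient
   relaxes; `ablation_flux_demo()` illustrates the algebra: if the Fickian
   path length $L$ shrinks in proportion to $\Delta C$, the flux
   $J = D\,\Delta C / L$ is exactly constant.
2. **Adsorption.** Free phenolics equilibrate with binding sites on grape
   cell-wall material through a competitive Langmuir isotherm sharing one
   site pool:
   $$q_i = \frac{C_{i,S}}{\Gamma\,\varphi} =
     \frac{q_{m,i} K_i C_{i,F}}{1 + \sum_j K_j C_{j,F}}$$
   Adsorption is assumed fast relative to release and reaction, so the
   partition is re-solved as an algebraic constraint at every instant rather
   than integrated as a rate. Ethanol affects the model *only* through the
   $(T, \text{ethanol})$ lookup of $K$ and $q_m$.
3. **Disappearance.** Anthocyanins disappear from solution (polymerisation,
   degradation) at a zero-order rate $k_R$; tannins do not, on fermentation
   time scales.

The model assumes a homogeneous must (no cap gradients, valid for small
pumped-over fermenters), pseudo-species rather than individual compounds,
and kinetic parameters that depend on temperature only.

## Parameters and defaults

Temperature enters through empirical regressions, evaluated in degrees
Celsius with `eval_temperature_polynomial()` and clamped at zero (a negative
rate constant or unavailable amount is physically meaningless; the clamp is
flagged). The defaults are:

| parameter | units | form | value at 20 °C |
|---|---|---|---|
| $k_{G,\text{anth}}$ | 1/h | quadratic in $T$ | 0.0096 |
| $k_{G,\text{tan,skin}}$ | 1/h | quadratic in $T$ | 0.0056 |
| $k_{G,\text{tan,seed}}$ | mg/L/h | quadratic in $T$ | 0.406 |
| $C_{U,\text{anth}}$ | mg/L | quadratic in $T$ | 193 (clamps to 0 at 35 °C) |
| $C_{U,\text{tan}}$ | mg/L | linear in $T$ | 577 |
| $k_{R,\text{anth}}$ | mg/L/h | Arrhenius, $A = 1.38\times10^{18}$ mg/L/h, $E_a = 107.3$ kJ/mol | 0.105 |

The Arrhenius law uses absolute temperature and $R = 8.314$ J/mol/K; at
35 °C it gives 0.89 mg/L/h. The calibrated range is 20–35 °C and 0–15 %
ethanol; anything outside is accepted but flagged as extrapolation.

Several quantities the temperature regressions do not determine were fixed
once, as follows:

* **Initial reservoirs** $C_{G0}$: 1200 mg/L (anthocyanin) and 1350 mg/L
  (skin tannin) — chosen so that the extractable amounts
  $C_{G0} - C_U$ at 20 °C are consistent with the worked release-fit
  amplitudes (≈ 492 and 379 mg/L, which estimate half the extractable pool
  under the no-adsorption closed form) and with typical Cabernet Sauvignon
  musts. The seed reservoir defaults to 1.2 × (336 h of zero-order release
  at 35 °C) ≈ 417 mg/L so the seed never runs dry within the calibrated
  range; seed totals are otherwise unconstrained by the data this model is
  built on.
* **Adsorbent phase**: $\varphi = 0.20$ (only ~20 % of cell-wall material is
  surface-exposed); $\Gamma = 0.05$ g cell wall per g grape (a realistic
  cell-wall mass fraction of crushed berry solids — never reported for this
  system, so it is a configuration input); grape load 1000 g/L (red
  fermentation is essentially crushed grapes).
* **Langmuir tables**: the shipped $K$ and $q_m$ tables over
  $\{20,25,30,35\}\,°C \times \{0,5,10,15\}\,\%$ ethanol are *synthetic*
  placeholders with plausible magnitudes ($K \sim 0.004$–$0.008$ L/mg,
  $q_m \sim 15$–$30$ mg/g) that weaken mildly with temperature and ethanol,
  as phenolic solubility rises. Measured isotherms, where available, should
  replace them via the YAML configuration (`read_config()` merges partial
  overrides onto the defaults).
* **Ethanol profile**: a logistic ramp from 0 to 13 % v/v with midpoint 72 h
  and scale 24 h — a generic healthy fermentation; a constant-ethanol
  override exists for calibration work.

## Numerical design

**Equilibrium partition.** At every derivative evaluation the liquid-
accessible total $M_i = C_{S,i} + C_{F,i}$ must be split consistently with
the competitive isotherm. `solve_partition()` reduces the $N$-species system
to one scalar equation in the saturation sum $S = \sum_j K_j C_{F,j}$: for
trial $S$, $C_{F,i} = M_i(1+S)/((1+S) + Q_i K_i)$ with
$Q_i = \Gamma \varphi\, (\text{grape load})\, q_{m,i}$ the capacity on the
must-volume basis. The map $g(S) = \sum K_i C_{F,i}(S)$ is increasing and
concave, so $g(S) - S$ has exactly one root in $[0, \sum K_i M_i]$; a
bracketing search polished by Newton steps lands at relative tolerance
$10^{-12}$. Conservation $C_F + C_S = M$ holds exactly by construction. An
independent damped fixed-point solver of the full $N$-dimensional system
(`partition_oracle()`) exists purely as a cross-check and is held to
$10^{-8}$ agreement in the tests.

**Integration.** The ODE state is deliberately minimal — $C_G$ per species
plus $C_R$ for anthocyanin — and $C_S, C_F$ are recovered algebraically
through the partition at every step, so the mass balance closes to machine
precision at all times (the standing test requires $< 10^{-6}$ mg/L).
`deSolve::lsoda` integrates with rtol = atol = $10^{-9}$; halving the
tolerances moves outputs by less than $10^{-6}$ relative.

Two smooth gates handle depletion without events or negative pools: the
zero-order anthocyanin sink is multiplied by $C_F/(C_F + 0.1\,\text{mg/L})$
so it shuts off as the free pool empties (a literal zero-order sink would
drive $C_F$ negative; the source model is silent on depletion), and the
zero-order seed release by $C_G/(C_G + 10^{-6}\,\text{mg/L})$, a transition
layer far below solver tolerance that stops release exactly at reservoir
exhaustion. Reservoirs below $10^{-9}$ mg/L are treated as empty rather than
integrated through the gate.

**Re-uptake is allowed.** The skin driving force $C_G - C_F$ is not clamped:
the release law is linear as written, and the free concentration *can*
exceed the depleted reservoir late in fermentation, because the seed's
zero-order release keeps loading the shared Langmuir pool and displaces skin
phenolics back into solution. This competitive displacement produces a mild,
genuine decrease (~0.1 mg/L per 6 h at 30 °C) of the extracted skin pools
near the end of a run; it is detected and flagged in the trajectory
diagnostics. Consequently "extraction is monotone when the reaction is off"
is only an invariant in the absence of a competing zero-order source, and
that is how the property is tested.

## Parameter estimation

`fit_study()` mirrors the classical stagewise procedure, then makes it
self-consistent.

**Stage 1 — window fits.** Early time points (from $t = 0$ until the series
first reaches 90 % of its median-smoothed peak) carry the release signal;
late points (from the peak onward) the disappearance signal. Both rules are
overridable. The gap to peak is fitted as $A e^{-kt}$ by Levenberg–Marquardt
from a log-linear start (`fit_release_first_order()`), and slopes by
ordinary least squares (`fit_zero_order_slope()`). Following the field's
convention the fitted decay constant is reported as-is — but note that under
the model's own no-adsorption closed form the gap decays at $2 k_G$ (release
fills the same solution it equilibrates against;
$C_F(t) = \tfrac{A_0}{2}(1 - e^{-2 k_G t})$), and with adsorption at a rate
between $k_G$ and $2 k_G$. These stage-1 fits are therefore kept as
diagnostics, with the convention caveat attached to each result.

**Stage 2 — mass-balance-integral estimates.** Because adsorption parameters
are configuration (not fitted), the adsorbed pool can be *reconstructed*
from the observed free concentrations of all three species: the isotherm is
explicit in $C_F$. With $M = C_F + C_S$ known, integrating each release law
turns estimation into regression:

* seed: $M_{seed}(t)$ is linear with slope $k_{G,seed}$ regardless of
  adsorption;
* skin tannin: $M(t) - M(0) = k_G A_0 t - k_G \int (M + C_F)\,dt$, linear in
  $(k_G A_0, k_G)$, with $C_U = C_{G0} - A_0$;
* anthocyanin: the same balance with the gated reacted pool
  $C_R = k_R \int C_F/(C_F + 0.1)\,dt$ substituted, leaving three parameters
  $(k_G, k_R, A_0)$ fitted by Levenberg–Marquardt.

Series are spline-interpolated onto an hourly grid before integration, and
the regressions are weighted as $1/\max(M, 300)^2$ — the multiplicative
error model of chromatographic quantification, floored where reconstruction
(not measurement) error dominates. On noiseless data the residuals vanish,
so these estimators recover the generating parameters essentially exactly;
the standing test requires every parameter within 2 % (unavailable amounts
scored as unavailable *fractions* $C_U/C_{G0}$, since the 35 °C truth is
exactly zero after clamping).

**Stage 3 — temperature models.** Across temperatures the recovered
disappearance rates are regressed in Arrhenius form ($\ln k$ on $1/T$,
$E_a = -R \cdot \text{slope}$) and the remaining parameters as polynomials
(quadratic, except linear for the unavailable skin tannin), reproducing the
default configuration's shape.

**Identifiability at realistic noise.** With 12 h sampling over 336 h and
5 % multiplicative noise, the anthocyanin triple $(k_G, k_R, C_U)$ has a
nearly flat likelihood at low temperature: a lower release constant, a
higher disappearance rate and a smaller unavailable fraction imitate one
another. A per-temperature maximum-likelihood fit of the full ODE — the
efficient estimator, kept out of the production path for cost — shows the
same ~15 % worst-case $k_G$ error on unlucky noise draws, confirming the
limit is informational, not algorithmic. Typical (median) release-constant
errors stay well under 10 %, which is what the seed-pinned noisy test
asserts; `run_recovery()` reports the full bias/RMSE picture per parameter
and temperature. The disappearance rate at 20 °C is the least identified
quantity (its whole 336 h signal is ~35 mg/L against ~25 mg/L of noise);
estimates of it at fermentation-relevant temperatures (30–35 °C) are much
tighter.

## The synthetic-data generator

`default_study()` emulates the kind of dataset the model was built against:
four constant-temperature fermentations at 20, 25, 30 and 35 °C, sampled
every 12 h over 336 h (14 days), with per-source liquid-phase concentrations
and 5 % multiplicative lognormal noise (the natural error model for
concentrations spanning two orders of magnitude; negative values cannot
occur, and post-noise clamping is recorded anyway). Every dataset stamps its
generating parameters, noise seed and ethanol profile into metadata — the
ground truth that recovery experiments score against — and round-trips
through tidy CSV plus a JSON sidecar.

What it does *not* emulate: yeast growth and sugar consumption, temperature
transients, cap heterogeneity and pump-over schedules, tannin speciation
(real assays measure total tannin; the pipeline requires skin and seed
series separately, which only synthetic data — or a speciated assay —
provides), and any systematic (non-multiplicative) measurement error.
Passing recovery tests therefore demonstrate that the estimation pipeline
correctly inverts the model under its own assumptions — not that the model
is true of any particular real fermentation.

## Problem sizes

The test suite and the acceptance script run the study at its native size:
29 time points per temperature, four temperatures, 20 noise replicates for
the recovery report, and 500 random instances for the equilibrium-solver
cross-check. A full noiseless generate–fit round trip takes about a second;
the 20-replicate recovery report under ten seconds, because the noiseless
trajectories are simulated once and shared across replicates.

## Known limitations

* Adsorption defaults are synthetic; conclusions about absolute adsorbed
  fractions should not be drawn from them.
* $C_{G0}$ and $C_U$ are confounded in the balance — data identify only the
  extractable amount $C_{G0} - C_U$. $C_{G0}$ is a configuration input and
  $C_U$ is derived against it.
* The skin/seed attribution of measured tannin is assumed given; real total
  tannin data cannot be fitted without an attribution model.
* Outside 20–35 °C and 0–15 % ethanol every parameter is an extrapolation,
  and the polynomial forms are unsafe far outside the range (the seed
  release quadratic, for instance, rises again below ~4 °C).
* Zero-order seed release with a finite reservoir implies a kink at
  depletion; the default reservoir avoids it in-range, but user
  configurations with small seed totals will see the (gated, smooth) stop.
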