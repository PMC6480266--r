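# phenolex

Mechanistic modelling of phenolic extraction kinetics during red wine
fermentation: simulation, stagewise parameter estimation, and synthetic
study generation for recovery experiments.

## The problem

Colour (anthocyanins) and mouthfeel (tannins) in red wine come from
phenolics extracted out of grape skins and seeds over a one-to-two-week
fermentation. Winemakers steer this extraction mainly through temperature,
but most available models are either empirical fits with no mechanism or
mechanistic treatments of a single compound class. `phenolex` implements a
compact mechanistic model for three pooled species — anthocyanins, skin
tannins, seed tannins — intended for kinetics work: fitting extraction data,
testing estimation procedures, and exploring temperature policy.

## The model

For each species *i*, per litre of must, a mass balance closes five pools:

    C_i,G0 = C_i,G + C_i,S + C_i,F + C_i,R + C_i,U

(initial reservoir = unreleased + adsorbed + free + reacted + unavailable).
Three processes connect them:

* **release** — first order in the driving force for skin phenolics,
  `dC_G/dt = -k_G (C_G - C_F)`; zero order for seed tannins,
  `dC_G/dt = -k_G,seed` (a constant rate, consistent with a diffusion path
  that shortens as the seed's outer layer ablates);
* **adsorption** — a competitive Langmuir equilibrium on one shared pool of
  grape cell-wall sites, `q_i = q_m,i K_i C_F,i / (1 + Σ_j K_j C_F,j)`,
  re-solved algebraically at every instant (adsorption is fast relative to
  release and reaction); ethanol enters the model only here;
* **disappearance** — a zero-order loss of anthocyanins from solution,
  `dC_R/dt = k_R`, gated off smoothly as the free pool empties.

Rate constants and unavailable amounts are empirical functions of
temperature (polynomials in °C); the disappearance rate follows an Arrhenius
law with A = 1.38×10¹⁸ mg/L/h and Ea = 107.3 kJ/mol (0.89 mg/L/h at 35 °C).
The estimation pipeline is stagewise: early-window exponential fits and
zero-order slopes per temperature, then a model-consistent
mass-balance-integral regression, then Arrhenius and polynomial regressions
across temperatures. See the methods vignette
(`vignettes/phenolic-extraction-kinetics.Rmd`) for the full account.

## Worked example

Simulate a 14-day fermentation at 28 °C, then run a full
generate-and-refit round trip on the four-temperature synthetic study:

```r
library(phenolex)

traj <- simulate_fermentation(conditions = fermentation_conditions(28),
                              times = seq(0, 336, by = 12))
traj
#> Phenolic extraction trajectory
#>   temperature: 28 C; 29 time points over 336 h
#>   final free concentrations (mg/L):
#> anthocyanin skin_tannin seed_tannin 
#>      467.66      446.79      196.20 
#>   mass-balance residual: 2.273737e-13 mg/L

study <- default_study(sigma = 0, seed = 1)   # noiseless, known ground truth
fit <- fit_study(study)
fit
#> Stagewise study fit over 4 temperature(s)
#>
#>        parameter          T20          T25          T30          T35
#>  k_G_anthocyanin 9.600960e-03   0.01337183   0.01674477   0.01971231
#>  k_G_skin_tannin 5.563973e-03   0.01018609   0.01411952   0.01737045
#>  k_G_seed_tannin 4.057013e-01   0.57079429   0.78036798   1.03442381
#>  k_R_anthocyanin 1.047331e-01   0.21849997   0.44624405   0.89126217
#>  C_U_anthocyanin 1.928505e+02 155.35494254  91.07766033   0.87147035
#>  C_U_skin_tannin 5.770358e+02 451.13726544 325.27276575 199.43386764
#>
#> Temperature models:
#>   k_G_anthocyanin: c0 = -0.00950547, c1 = 0.00111597, c2 = -8.03322e-06 (R^2 = 1)
#>   ...
#>   k_R_anthocyanin: A = 1.3333e+18, Ea = 107218 (R^2 = 1)
```

Reading the output: the final free concentrations are the liquid-phase
observables a winery lab would measure at pressing; the mass-balance
residual confirms the five pools close to machine precision. In the refit,
each per-temperature estimate reproduces the generating value — e.g.
`k_G_anthocyanin` at 20 °C returns 0.009601 1/h against a true 0.0096015,
and the cross-temperature Arrhenius stage recovers Ea = 107.2 kJ/mol against
the generating 107.3. At 5 % measurement noise, `run_recovery()` reports
bias and RMSE per parameter over seed-pinned replicates.

A thin command-line wrapper over the same functions is installed at
`inst/scripts/phenolex.R`:

```sh
Rscript inst/scripts/phenolex.R generate --out-dir study --sigma 0.05 --seed 101
Rscript inst/scripts/phenolex.R fit --manifest manifest.yaml --out-dir fits
```

## Configuration

All model constants live in a YAML configuration
(`inst/extdata/default_config.yaml`); `read_config()` merges partial user
files over the defaults. The shipped Langmuir adsorption tables are
synthetic placeholders with realistic magnitudes — substitute measured
isotherms for quantitative adsorption work.
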