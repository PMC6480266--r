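# Default phenolex model configuration.
#
# kinetics: empirical temperature regressions (polynomial coefficients are
#   intercept-first in T, degrees Celsius) for release constants (1/h for
#   first-order skin species, mg/L/h for the zero-order seed), unavailable
#   amounts (mg/L), the Arrhenius pair (A mg/L/h, Ea J/mol) for anthocyanin
#   disappearance, and total initial reservoirs C_G0 (mg/L of must).
# adsorption: SYNTHETIC placeholder Langmuir tables K (L/mg) and q_m (mg/g),
#   rows = temperature_grid (C), columns = ethanol_grid (% v/v); replace with
#   measured isotherms when available. Gamma: g cell-wall material per g
#   grape; phi: exposed fraction; grape_load: g grape per L must.
kinetics:
  anthocyanin:
    release:
      type: polynomial
      coefficients:
      - -0.0095045
      - 0.0011173
      - -8.1e-06
    unavailable:
      type: polynomial
      coefficients:
      - 75.7035
      - 16.57825
      - -0.53615
    reaction:
      type: arrhenius
      A: 1.38e+18
      Ea: 107300.0
    total: 1200.0
  skin_tannin:
    release:
      type: polynomial
      coefficients:
      - -0.019916
      - 0.001554
      - -1.4e-05
    unavailable:
      type: polynomial
      coefficients:
      - 1080.7055
      - -25.1835
    reaction: ~
    total: 1350.0
  seed_tannin:
    release:
      type: polynomial
      coefficients:
      - 0.1903
      - -0.00703
      - 0.00089
    unavailable:
      type: polynomial
      coefficients: 0.0
    reaction: ~
    total: 417.1104
adsorption:
  synthetic: yes
  Gamma: 0.05
  phi: 0.2
  grape_load: 1000.0
  temperature_grid:
  - 20.0
  - 25.0
  - 30.0
  - 35.0
  ethanol_grid:
  - 0.0
  - 5.0
  - 10.0
  - 15.0
  species:
    anthocyanin:
      K:
      - - 0.004
        - 0.0032
        - 0.0024
        - 0.0016
      - - 0.0038
        - 0.00304
        - 0.00228
        - 0.00152
      - - 0.0036
        - 0.00288
        - 0.00216
        - 0.00144
      - - 0.0034
        - 0.00272
        - 0.00204
        - 0.00136
      q_m:
      - - 15.0
        - 13.5
        - 12.0
        - 10.5
      - - 14.625
        - 13.1625
        - 11.7
        - 10.2375
      - - 14.25
        - 12.825
        - 11.4
        - 9.975
      - - 13.875
        - 12.4875
        - 11.1
        - 9.7125
    skin_tannin:
      K:
      - - 0.008
        - 0.0064
        - 0.0048
        - 0.0032
      - - 0.0076
        - 0.00608
        - 0.00456
        - 0.00304
      - - 0.0072
        - 0.00576
        - 0.00432
        - 0.00288
      - - 0.0068
        - 0.00544
        - 0.00408
        - 0.00272
      q_m:
      - - 30.0
        - 27.0
        - 24.0
        - 21.0
      - - 29.25
        - 26.325
        - 23.4
        - 20.475
      - - 28.5
        - 25.65
        - 22.8
        - 19.95
      - - 27.75
        - 24.975
        - 22.2
        - 19.425
    seed_tannin:
      K:
      - - 0.008
        - 0.0064
        - 0.0048
        - 0.0032
      - - 0.0076
        - 0.00608
        - 0.00456
        - 0.00304
      - - 0.0072
        - 0.00576
        - 0.00432
        - 0.00288
      - - 0.0068
        - 0.00544
        - 0.00408
        - 0.00272
      q_m:
      - - 30.0
        - 27.0
        - 24.0
        - 21.0
      - - 29.25
        - 26.325
        - 23.4
        - 20.475
      - - 28.5
        - 25.65
        - 22.8
        - 19.95
      - - 27.75
        - 24.975
        - 22.2
        - 19.425
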