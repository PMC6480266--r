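# Shared fixtures and oracles for the test suite. Everything is generated in
# code; no data files.

# Ground-truth parameter table for the default configuration at the study
# temperatures, in the long shape returned by fit_study(). The `scale` column
# carries the denominator for scoring: |truth| for rate constants, C_G0 for
# the unavailable amounts (scored as unavailable fractions, since the truth
# can be exactly zero after clamping).
truth_table <- function(config = default_config(),
                        temperatures = c(20, 25, 30, 35)) {
  do.call(rbind, lapply(temperatures, function(tc) {
    kin <- params_at_conditions(config, tc)$kinetics
    g <- function(sp, col) kin[kin$species == sp, col]
    data.frame(
      parameter = c("k_G_anthocyanin", "k_G_skin_tannin", "k_G_seed_tannin",
                    "k_R_anthocyanin", "C_U_anthocyanin", "C_U_skin_tannin"),
      temperature_C = tc,
      truth = c(g("anthocyanin", "k_G"), g("skin_tannin", "k_G"),
                g("seed_tannin", "k_G"), g("anthocyanin", "k_R"),
                g("anthocyanin", "C_U"), g("skin_tannin", "C_U")),
      scale = c(abs(g("anthocyanin", "k_G")), abs(g("skin_tannin", "k_G")),
                abs(g("seed_tannin", "k_G")), abs(g("anthocyanin", "k_R")),
                g("anthocyanin", "C_G0"), g("skin_tannin", "C_G0")),
      stringsAsFactors = FALSE)
  }))
}

# Scored recovery errors of a fit_study() result against ground truth.
recovery_errors <- function(study_fit, config = default_config()) {
  m <- merge(study_fit$estimates, truth_table(config))
  m$scored_error <- abs(m$estimate - m$truth) / m$scale
  m
}

# Single-species competitive-Langmuir closed form: the positive root of
# K*C_F^2 + (1 + K*Q - K*M)*C_F - M = 0.
single_species_partition <- function(M, K, Q) {
  if (K == 0) return(M)
  b <- 1 + K * Q - K * M
  (-b + sqrt(b^2 + 4 * K * M)) / (2 * K)
}

# Random partition instances for property tests (mix of generic draws and
# degenerate corners with zero K / zero M entries).
random_partition_instance <- function(n) {
  M <- stats::runif(n, 0, 1000)
  K <- stats::runif(n, 0, 0.05)
  Q <- stats::runif(n, 0, 500)
  if (stats::runif(1) < 0.2) K[sample(n, 1)] <- 0
  if (stats::runif(1) < 0.2) M[sample(n, 1)] <- 0
  list(M = M, K = K, Q = Q)
}

# Configuration with adsorption switched off (all K = 0) and constant kinetic
# parameters, for closed-form simulator checks: only the anthocyanin reservoir
# is active unless `seed_only` is set, and the disappearance rate is zero.
no_adsorption_config <- function(k_G = 0.01, A0 = 400, seed_only = FALSE) {
  cfg <- default_config()
  for (sp in c("anthocyanin", "skin_tannin", "seed_tannin")) {
    cfg$adsorption$species[[sp]]$K <- matrix(0, 4, 4)
  }
  cfg$kinetics$anthocyanin$reaction <- list(type = "arrhenius", A = 0, Ea = 0)
  for (sp in c("anthocyanin", "skin_tannin", "seed_tannin")) {
    cfg$kinetics[[sp]]$release$coefficients <- 0
    cfg$kinetics[[sp]]$unavailable$coefficients <- 0
    cfg$kinetics[[sp]]$total <- 1
  }
  if (seed_only) {
    cfg$kinetics$seed_tannin$release$coefficients <- k_G
    cfg$kinetics$seed_tannin$total <- A0
  } else {
    cfg$kinetics$anthocyanin$release$coefficients <- k_G
    cfg$kinetics$anthocyanin$total <- A0
  }
  cfg
}
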