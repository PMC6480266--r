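#' Default model configuration
#'
#' Builds the complete default parameter configuration: temperature
#' regressions for the kinetic constants and unavailable amounts, the
#' Arrhenius law for anthocyanin disappearance, initial reservoirs, and
#' adsorption-parameter tables over temperature and ethanol.
#'
#' @details
#' Kinetic temperature regressions (argument of all polynomials is the
#' temperature in degrees Celsius; coefficients are stored intercept first):
#' \itemize{
#'   \item anthocyanin release constant (1/h):
#'     \code{-0.0000081*T^2 + 0.0011173*T - 0.0095045}
#'   \item skin-tannin release constant (1/h):
#'     \code{-0.000014*T^2 + 0.001554*T - 0.019916}
#'   \item seed-tannin release constant (mg/L/h, zero order):
#'     \code{0.00089*T^2 - 0.00703*T + 0.19030}
#'   \item unavailable anthocyanin (mg/L):
#'     \code{-0.53615*T^2 + 16.57825*T + 75.70350}
#'   \item unavailable skin tannin (mg/L): \code{-25.1835*T + 1080.7055}
#'   \item anthocyanin disappearance rate (mg/L/h): Arrhenius with
#'     pre-exponential \code{A = 1.38e18} mg/L/h and activation energy
#'     \code{Ea = 107300} J/mol.
#' }
#'
#' The Langmuir adsorption constants \code{K} (L/mg) and capacities
#' \code{q_m} (mg/g cell-wall material) shipped here are \emph{synthetic}
#' placeholder tables: plausible magnitudes with adsorption weakening as
#' temperature and ethanol increase. Users with measured isotherms should
#' replace them via [read_config()] overrides. The shared adsorbent-phase
#' factors are \code{Gamma} (g cell-wall material per g grape, default 0.05),
#' \code{phi} (exposed fraction, default 0.20) and \code{grape_load}
#' (g grape per L must, default 1000).
#'
#' Initial reservoirs \code{C_G0} (mg/L of must) default to 1200
#' (anthocyanin), 1350 (skin tannin) and, for the seed, 1.2 times the amount a
#' 336 h fermentation at 35 degrees C would release, so that zero-order seed
#' release is sustained over any in-range run.
#'
#' @return A nested list with components \code{kinetics} (per species:
#'   \code{release}, \code{unavailable}, \code{reaction}, \code{total}) and
#'   \code{adsorption} (\code{Gamma}, \code{phi}, \code{grape_load},
#'   \code{temperature_grid}, \code{ethanol_grid}, per-species \code{K} and
#'   \code{q_m} matrices indexed \code{[temperature, ethanol]}).
#' @export
#' @examples
#' cfg <- default_config()
#' eval_temperature_polynomial(cfg$kinetics$skin_tannin$release$coefficients, 20)
default_config <- function() {
  seed_release <- list(type = "polynomial",
                       coefficients = c(0.19030, -0.00703, 0.00089))
  k_seed_35 <- eval_temperature_polynomial(seed_release$coefficients, 35,
                                           warn = FALSE)
  t_grid <- c(20, 25, 30, 35)
  e_grid <- c(0, 5, 10, 15)
  # Synthetic Langmuir tables: separable bilinear decay in T and ethanol so
  # bilinear interpolation reproduces them exactly at any in-range point.
  ads_table <- function(base, t_slope, e_slope) {
    outer(1 - t_slope * (t_grid - 20), 1 - e_slope * e_grid) * base
  }
  list(
    kinetics = list(
      anthocyanin = list(
        release = list(type = "polynomial",
                       coefficients = c(-0.0095045, 0.0011173, -0.0000081)),
        unavailable = list(type = "polynomial",
                           coefficients = c(75.70350, 16.57825, -0.53615)),
        reaction = list(type = "arrhenius", A = 1.38e18, Ea = 107300),
        total = 1200
      ),
      skin_tannin = list(
        release = list(type = "polynomial",
                       coefficients = c(-0.019916, 0.001554, -0.000014)),
        unavailable = list(type = "polynomial",
                           coefficients = c(1080.7055, -25.1835)),
        reaction = NULL,
        total = 1350
      ),
      seed_tannin = list(
        release = seed_release,
        unavailable = list(type = "polynomial", coefficients = 0),
        reaction = NULL,
        total = 1.2 * k_seed_35 * 336
      )
    ),
    adsorption = list(
      synthetic = TRUE,
      Gamma = 0.05,
      phi = 0.20,
      grape_load = 1000,
      temperature_grid = t_grid,
      ethanol_grid = e_grid,
      species = list(
        anthocyanin = list(K = ads_table(0.004, 0.010, 0.040),
                           q_m = ads_table(15, 0.005, 0.020)),
        skin_tannin = list(K = ads_table(0.008, 0.010, 0.040),
                           q_m = ads_table(30, 0.005, 0.020)),
        seed_tannin = list(K = ads_table(0.008, 0.010, 0.040),
                           q_m = ads_table(30, 0.005, 0.020))
      )
    )
  )
}

#' Read a model configuration from YAML
#'
#' Reads a (possibly partial) configuration file and merges it over
#' [default_config()]: any field present in the file overrides the default,
#' everything else keeps its default value. Per-species adsorption tables are
#' coerced to matrices shaped \code{[temperature_grid, ethanol_grid]}.
#'
#' @param path Path to a YAML configuration file.
#' @return A configuration list as from [default_config()].
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    stop("configuration error: file not found: ", path, call. = FALSE)
  }
  user <- yaml::read_yaml(path)
  cfg <- utils::modifyList(default_config(), user)
  for (sp in names(cfg$adsorption$species)) {
    for (fld in c("K", "q_m")) {
      m <- cfg$adsorption$species[[sp]][[fld]]
      if (is.list(m)) m <- do.call(rbind, m)
      cfg$adsorption$species[[sp]][[fld]] <-
        matrix(as.numeric(m), nrow = length(cfg$adsorption$temperature_grid))
    }
  }
  validate_config(cfg)
  cfg
}

#' Write a model configuration to YAML
#'
#' @param config Configuration list (see [default_config()]).
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_config <- function(config, path) {
  validate_config(config)
  for (sp in names(config$adsorption$species)) {
    for (fld in c("K", "q_m")) {
      m <- config$adsorption$species[[sp]][[fld]]
      config$adsorption$species[[sp]][[fld]] <-
        lapply(seq_len(nrow(m)), function(i) as.numeric(m[i, ]))
    }
  }
  yaml::write_yaml(config, path, precision = 12L)
  invisible(path)
}

# Structural and physical checks on a configuration list. Errors name the
# missing or invalid entry so config files can be repaired.
validate_config <- function(config) {
  for (sp in PHX_SPECIES) {
    kin <- config$kinetics[[sp]]
    if (is.null(kin)) {
      stop("configuration error: missing kinetics entry for species '", sp,
           "'", call. = FALSE)
    }
    for (fld in c("release", "total")) {
      if (is.null(kin[[fld]])) {
        stop("configuration error: kinetics$", sp, " lacks '", fld, "'",
             call. = FALSE)
      }
    }
    if (!is.finite(kin$total) || kin$total <= 0) {
      stop("configuration error: kinetics$", sp, "$total must be positive",
           call. = FALSE)
    }
  }
  rx <- config$kinetics$anthocyanin$reaction
  if (is.null(rx) || is.null(rx$A) || is.null(rx$Ea)) {
    stop("configuration error: anthocyanin reaction (Arrhenius A, Ea) missing",
         call. = FALSE)
  }
  ads <- config$adsorption
  if (is.null(ads)) stop("configuration error: adsorption section missing",
                         call. = FALSE)
  if (!(ads$phi > 0 && ads$phi <= 1)) {
    stop("configuration error: adsorption phi must lie in (0, 1]",
         call. = FALSE)
  }
  if (!(ads$Gamma > 0) || !(ads$grape_load > 0)) {
    stop("configuration error: adsorption Gamma and grape_load must be > 0",
         call. = FALSE)
  }
  nt <- length(ads$temperature_grid)
  ne <- length(ads$ethanol_grid)
  for (sp in PHX_SPECIES) {
    tab <- ads$species[[sp]]
    if (is.null(tab)) {
      stop("configuration error: adsorption table missing for species '", sp,
           "'", call. = FALSE)
    }
    for (fld in c("K", "q_m")) {
      m <- tab[[fld]]
      if (!is.matrix(m) || !all(dim(m) == c(nt, ne))) {
        stop("configuration error: adsorption$species$", sp, "$", fld,
             " must be a ", nt, "x", ne, " matrix", call. = FALSE)
      }
      if (any(!is.finite(m)) || any(m < 0)) {
        stop("configuration error: adsorption$species$", sp, "$", fld,
             " must be finite and non-negative", call. = FALSE)
      }
    }
  }
  invisible(config)
}
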