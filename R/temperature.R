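#' Evaluate an empirical temperature polynomial
#'
#' Evaluates a polynomial regression in temperature (degrees Celsius) for a
#' kinetic constant or unavailable concentration. Raw values below zero are
#' clamped to zero — a negative rate constant or unavailable amount is
#' physically meaningless — and the clamping is flagged.
#'
#' @param coefficients Numeric vector of polynomial coefficients, intercept
#'   first (\code{c0 + c1*T + c2*T^2 + ...}).
#' @param temperature_C Temperature(s) in degrees Celsius.
#' @param warn Emit a warning when clamping occurs (default \code{TRUE}).
#' @return Numeric vector of non-negative values, with attributes
#'   \code{"raw"} (unclamped values) and \code{"clamped"} (logical vector).
#' @export
#' @examples
#' # skin-tannin release constant at 20 C
#' eval_temperature_polynomial(c(-0.019916, 0.001554, -0.000014), 20)
eval_temperature_polynomial <- function(coefficients, temperature_C,
                                        warn = TRUE) {
  if (!all(is.finite(coefficients))) {
    stop("validation error: polynomial coefficients must be finite",
         call. = FALSE)
  }
  if (!all(is.finite(temperature_C))) {
    stop("validation error: temperature must be finite", call. = FALSE)
  }
  raw <- vapply(temperature_C, function(T) {
    sum(coefficients * T^(seq_along(coefficients) - 1))
  }, numeric(1))
  clamped <- raw < 0
  if (warn && any(clamped)) {
    warning("temperature polynomial evaluated negative at T = ",
            paste(format(temperature_C[clamped]), collapse = ", "),
            " C; clamped to 0", call. = FALSE)
  }
  out <- pmax(raw, 0)
  attr(out, "raw") <- raw
  attr(out, "clamped") <- clamped
  out
}

#' Arrhenius rate law
#'
#' \code{k = A * exp(-Ea / (R * T))} with \code{T} in Kelvin and
#' \code{R = 8.314} J/mol/K. Used for the zero-order anthocyanin
#' disappearance rate.
#'
#' @param A Pre-exponential constant (same units as the returned rate,
#'   mg/L/h for a zero-order rate).
#' @param Ea Activation energy, J/mol.
#' @param temperature_C Temperature(s), degrees Celsius.
#' @return Rate(s) in the units of \code{A}.
#' @export
#' @examples
#' arrhenius_rate(1.38e18, 107300, 35)  # ~0.89 mg/L/h
arrhenius_rate <- function(A, Ea, temperature_C) {
  if (A < 0 || Ea < 0) {
    stop("validation error: A and Ea must be non-negative", call. = FALSE)
  }
  if (any(temperature_C <= -273.15)) {
    stop("validation error: temperature at or below absolute zero",
         call. = FALSE)
  }
  A * exp(-Ea / (PHX_R_GAS * (temperature_C + 273.15)))
}

#' Fermentation conditions
#'
#' Bundles the constant fermentation temperature with an ethanol-versus-time
#' profile. Temperatures outside the 20-35 C calibration range are accepted
#' with a warning and flagged as extrapolation.
#'
#' @param temperature_C Constant fermentation temperature, degrees Celsius.
#' @param ethanol Either a single percentage (held constant) or a function of
#'   time (h) returning percent v/v, e.g. from [ethanol_profile()]. Default:
#'   logistic ramp 0 to 13 \% v/v with midpoint 72 h and scale 24 h.
#' @return An object of class \code{phx_conditions} with elements
#'   \code{temperature_C}, \code{ethanol} (function of time) and
#'   \code{extrapolated}.
#' @export
fermentation_conditions <- function(temperature_C,
                                    ethanol = ethanol_profile("logistic")) {
  if (!is.finite(temperature_C)) {
    stop("validation error: temperature must be finite", call. = FALSE)
  }
  extrapolated <- temperature_C < 20 || temperature_C > 35
  if (extrapolated) {
    warning("temperature ", temperature_C,
            " C is outside the calibrated 20-35 C range; ",
            "parameters are extrapolated", call. = FALSE)
  }
  if (is.numeric(ethanol)) {
    ethanol <- ethanol_profile("constant", value = ethanol)
  }
  stopifnot(is.function(ethanol))
  structure(list(temperature_C = temperature_C, ethanol = ethanol,
                 extrapolated = extrapolated),
            class = "phx_conditions")
}

#' Look up adsorption parameters at given temperature and ethanol
#'
#' Bilinearly interpolates the per-species Langmuir constants \code{K} (L/mg)
#' and capacities \code{q_m} (mg/g) in temperature and ethanol, and converts
#' capacity to the concentration basis of the mass balance via
#' \code{Q = Gamma * phi * grape_load * q_m} (mg per L of must). Query points
#' outside the tabulated grid are clamped to the nearest edge with a warning.
#'
#' @param ads_config The \code{adsorption} section of a configuration list.
#' @param temperature_C Temperature, degrees Celsius.
#' @param ethanol Ethanol, percent v/v.
#' @return List with named vectors \code{K}, \code{q_m}, \code{Q} (species
#'   order anthocyanin, skin_tannin, seed_tannin) and scalars \code{Gamma},
#'   \code{phi}, \code{grape_load}.
#' @export
adsorption_at <- function(ads_config, temperature_C, ethanol) {
  tg <- ads_config$temperature_grid
  eg <- ads_config$ethanol_grid
  if (temperature_C < min(tg) || temperature_C > max(tg) ||
      ethanol < min(eg) || ethanol > max(eg)) {
    warning("adsorption lookup at (T = ", format(temperature_C),
            " C, ethanol = ", format(ethanol), " %v/v) lies outside the ",
            "tabulated grid; clamped to the nearest edge", call. = FALSE)
  }
  K <- q_m <- stats::setNames(numeric(length(PHX_SPECIES)), PHX_SPECIES)
  for (sp in PHX_SPECIES) {
    tab <- ads_config$species[[sp]]
    K[sp] <- bilinear_interp(tg, eg, tab$K, temperature_C, ethanol,
                             warn = FALSE)
    q_m[sp] <- bilinear_interp(tg, eg, tab$q_m, temperature_C, ethanol,
                               warn = FALSE)
  }
  Q <- ads_config$Gamma * ads_config$phi * ads_config$grape_load * q_m
  list(K = K, q_m = q_m, Q = Q, Gamma = ads_config$Gamma,
       phi = ads_config$phi, grape_load = ads_config$grape_load)
}

# Bilinear interpolation on a rectangular grid with edge clamping.
bilinear_interp <- function(xgrid, ygrid, Z, x, y, warn = TRUE) {
  if (warn && (x < min(xgrid) || x > max(xgrid) ||
               y < min(ygrid) || y > max(ygrid))) {
    warning("adsorption lookup at (T = ", format(x), " C, ethanol = ",
            format(y), " %v/v) lies outside the tabulated grid; ",
            "clamped to the nearest edge", call. = FALSE)
  }
  x <- min(max(x, min(xgrid)), max(xgrid))
  y <- min(max(y, min(ygrid)), max(ygrid))
  i <- max(findInterval(x, xgrid, rightmost.closed = TRUE), 1L)
  j <- max(findInterval(y, ygrid, rightmost.closed = TRUE), 1L)
  i <- min(i, length(xgrid) - 1L)
  j <- min(j, length(ygrid) - 1L)
  tx <- if (xgrid[i + 1] == xgrid[i]) 0 else (x - xgrid[i]) / (xgrid[i + 1] - xgrid[i])
  ty <- if (ygrid[j + 1] == ygrid[j]) 0 else (y - ygrid[j]) / (ygrid[j + 1] - ygrid[j])
  (1 - tx) * (1 - ty) * Z[i, j] + tx * (1 - ty) * Z[i + 1, j] +
    (1 - tx) * ty * Z[i, j + 1] + tx * ty * Z[i + 1, j + 1]
}

#' Assemble the full parameter bundle for one simulation
#'
#' Evaluates all kinetic temperature regressions at the given temperature and
#' looks up the adsorption parameters at the given ethanol level, returning
#' everything the simulator needs. Skin species release first order
#' (\code{alpha = 1}); the seed releases zero order (\code{alpha = 0});
#' disappearance is zero order (\code{beta = 0}) and applies to anthocyanin
#' only.
#'
#' @param config Configuration list (see [default_config()]).
#' @param temperature_C Temperature, degrees Celsius.
#' @param ethanol Ethanol (percent v/v) at which to snapshot the adsorption
#'   parameters; default 0.
#' @return List with \code{temperature_C}, a \code{kinetics} data.frame
#'   (columns \code{species}, \code{k_G}, \code{alpha}, \code{k_R},
#'   \code{beta}, \code{C_G0}, \code{C_U}), an \code{adsorption} snapshot
#'   from [adsorption_at()], and \code{adsorption_fun(ethanol)} for
#'   time-varying lookups.
#' @export
#' @examples
#' p <- params_at_conditions(default_config(), 20)
#' subset(p$kinetics, species == "anthocyanin")$k_G  # 0.0096015 1/h
params_at_conditions <- function(config, temperature_C, ethanol = 0) {
  validate_config(config)
  rows <- lapply(PHX_SPECIES, function(sp) {
    kin <- config$kinetics[[sp]]
    k_G <- eval_temperature_polynomial(kin$release$coefficients,
                                       temperature_C, warn = FALSE)
    C_U <- if (is.null(kin$unavailable)) 0 else
      eval_temperature_polynomial(kin$unavailable$coefficients,
                                  temperature_C, warn = FALSE)
    k_R <- 0
    if (!is.null(kin$reaction)) {
      k_R <- arrhenius_rate(kin$reaction$A, kin$reaction$Ea, temperature_C)
    }
    C_U <- min(as.numeric(C_U), kin$total)
    data.frame(species = sp,
               k_G = as.numeric(k_G),
               alpha = if (sp == "seed_tannin") 0 else 1,
               k_R = k_R,
               beta = 0,
               C_G0 = kin$total,
               C_U = C_U,
               stringsAsFactors = FALSE)
  })
  kinetics <- do.call(rbind, rows)
  ads_cfg <- config$adsorption
  list(temperature_C = temperature_C,
       kinetics = kinetics,
       adsorption = adsorption_at(ads_cfg, temperature_C, ethanol),
       adsorption_fun = function(e) adsorption_at(ads_cfg, temperature_C, e))
}

#' Fickian diffusive flux
#'
#' \code{J = D * deltaC / L}: steady diffusive flux across a path of length
#' \code{L} under concentration difference \code{deltaC}.
#'
#' @param D Diffusion coefficient (length^2/time).
#' @param L Path length (> 0).
#' @param deltaC Concentration difference along the path (mg/L).
#' @return Flux (mass/area/time), vectorized over the inputs.
#' @export
fickian_flux <- function(D, L, deltaC) {
  if (any(D <= 0)) stop("validation error: D must be > 0", call. = FALSE)
  if (any(L <= 0)) stop("validation error: path length must be > 0",
                        call. = FALSE)
  D * deltaC / L
}

#' Seed-ablation flux demonstration
#'
#' Illustrates why zero-order seed-tannin release is compatible with Fickian
#' diffusion: if the diffusion path length shrinks in proportion to the
#' decaying driving force — the seed endocarp ablating as the tannin gradient
#' relaxes — the flux \code{D*deltaC/L} stays exactly constant.
#'
#' @param times Time grid (h), same length as \code{deltaC}.
#' @param deltaC Positive concentration-difference series (mg/L).
#' @param D Diffusion coefficient (default 1).
#' @param L0 Initial path length (default 1).
#' @return data.frame with columns \code{time}, \code{deltaC}, \code{L},
#'   \code{flux}; the flux column is constant by construction.
#' @export
ablation_flux_demo <- function(times, deltaC, D = 1, L0 = 1) {
  stopifnot(length(times) == length(deltaC))
  if (any(deltaC <= 0)) {
    stop("validation error: deltaC must stay positive for the ablation demo",
         call. = FALSE)
  }
  L <- L0 * deltaC / deltaC[1]
  data.frame(time = times, deltaC = deltaC, L = L,
             flux = fickian_flux(D, L, deltaC))
}
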