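#' Ethanol-versus-time profile
#'
#' Fermentation ethanol profiles for the adsorption-parameter lookup. The
#' adsorption tables are calibrated over 0-15 percent v/v, so profiles are
#' constrained to that range.
#'
#' @param kind \code{"logistic"} (monotone ramp from ~0 to \code{asymptote})
#'   or \code{"constant"}.
#' @param asymptote Final ethanol level, percent v/v (logistic; default 13).
#' @param midpoint_h Time of half-maximal ethanol, h (default 72).
#' @param scale_h Logistic time scale, h (default 24).
#' @param value Constant level, percent v/v (constant profile; default 0).
#' @return A function of time (h) returning percent v/v, carrying its
#'   specification in attribute \code{"spec"} for serialization.
#' @export
#' @examples
#' f <- ethanol_profile("logistic")
#' f(72)  # 6.5
ethanol_profile <- function(kind = c("logistic", "constant"), asymptote = 13,
                            midpoint_h = 72, scale_h = 24, value = 0) {
  kind <- match.arg(kind)
  if (kind == "logistic") {
    if (asymptote < 0 || asymptote > 15) {
      stop("validation error: ethanol asymptote must lie in [0, 15] %v/v",
           call. = FALSE)
    }
    stopifnot(scale_h > 0)
    f <- function(t) asymptote / (1 + exp(-(t - midpoint_h) / scale_h))
    spec <- list(kind = "logistic", asymptote = asymptote,
                 midpoint_h = midpoint_h, scale_h = scale_h)
  } else {
    if (value < 0 || value > 15) {
      stop("validation error: constant ethanol must lie in [0, 15] %v/v",
           call. = FALSE)
    }
    f <- function(t) rep(value, length(t))
    spec <- list(kind = "constant", value = value)
  }
  attr(f, "spec") <- spec
  f
}

ethanol_from_spec <- function(spec) {
  if (spec$kind == "constant") {
    ethanol_profile("constant", value = spec$value)
  } else {
    ethanol_profile("logistic", asymptote = spec$asymptote,
                    midpoint_h = spec$midpoint_h, scale_h = spec$scale_h)
  }
}

#' Measurement-noise model
#'
#' Multiplicative lognormal noise, \code{C_obs = C * exp(sigma * Z)} with
#' \code{Z ~ N(0, 1)}: the natural choice for chromatographic quantification,
#' whose relative (not absolute) error is roughly constant across the two
#' orders of magnitude these concentrations span. Mean-preserving in log
#' space; for small \code{sigma} the coefficient of variation is ~\code{sigma}.
#'
#' @param kind \code{"multiplicative_lognormal"} or \code{"none"}.
#' @param sigma Relative noise scale (default 0.05).
#' @param seed Integer seed; identical seeds give identical datasets.
#' @return Object of class \code{phx_noise}.
#' @export
noise_model <- function(kind = c("multiplicative_lognormal", "none"),
                        sigma = 0.05, seed = NULL) {
  kind <- match.arg(kind)
  if (sigma < 0) stop("validation error: sigma must be >= 0", call. = FALSE)
  if (kind == "none") sigma <- 0
  structure(list(kind = kind, sigma = sigma, seed = seed),
            class = "phx_noise")
}

apply_noise <- function(values, noise) {
  if (noise$kind == "none" || noise$sigma == 0) {
    return(list(values = values, n_clamped = 0L))
  }
  if (!is.null(noise$seed)) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(noise$seed)
  }
  out <- values * exp(noise$sigma * stats::rnorm(length(values)))
  clamped <- out < 0
  list(values = pmax(out, 0), n_clamped = sum(clamped))
}

#' Generate a synthetic fermentation extraction dataset
#'
#' Simulates the extraction model at one temperature, extracts the
#' liquid-phase observables on a sampling grid, applies measurement noise,
#' and stamps the generating (ground-truth) parameters into the metadata so
#' parameter-recovery experiments can score themselves. Deterministic under a
#' fixed noise seed.
#'
#' @param config Configuration list (default [default_config()]).
#' @param temperature_C Fermentation temperature, degrees Celsius.
#' @param times Sampling grid, h (default every 12 h over 336 h, emulating a
#'   twice-daily sampled 14-day fermentation).
#' @param noise A [noise_model()] (default 5\% multiplicative lognormal,
#'   unseeded).
#' @param ethanol Ethanol profile function (default logistic ramp to 13\%).
#' @param trajectory Optional pre-computed \code{phx_trajectory} at matching
#'   conditions, to avoid re-integration across noise replicates.
#' @return Object of class \code{phx_dataset}: \code{records} (data.frame
#'   \code{time_h}, \code{species}, \code{concentration_mg_L}) and
#'   \code{metadata} (temperature, ethanol spec, noise spec, ground-truth
#'   kinetics table and Arrhenius pair, clamping count).
#' @export
generate_dataset <- function(config = default_config(), temperature_C = 25,
                             times = seq(0, 336, by = 12),
                             noise = noise_model(sigma = 0.05),
                             ethanol = ethanol_profile("logistic"),
                             trajectory = NULL) {
  if (is.null(trajectory)) {
    conditions <- fermentation_conditions(temperature_C, ethanol)
    trajectory <- simulate_fermentation(config, conditions, times)
  }
  obs <- observables(trajectory, tannin_mode = "per_source")
  noised <- apply_noise(obs$concentration_mg_L, noise)
  obs$concentration_mg_L <- noised$values
  truth <- params_at_conditions(config, temperature_C, ethanol(0))
  structure(list(
    records = obs,
    metadata = list(
      temperature_C = temperature_C,
      ethanol = attr(ethanol, "spec"),
      noise = unclass(noise),
      n_clamped = noised$n_clamped,
      ground_truth = list(
        kinetics = truth$kinetics,
        arrhenius = config$kinetics$anthocyanin$reaction)
    )
  ), class = "phx_dataset")
}

#' Default four-temperature synthetic study
#'
#' One dataset at each of 20, 25, 30 and 35 degrees Celsius — the
#' temperature span over which the default kinetic regressions were
#' calibrated — sampled every 12 h over 336 h with 5\% multiplicative noise
#' by default. Per-dataset noise seeds are derived from \code{seed} so the
#' whole study is reproducible.
#'
#' @param config Configuration list.
#' @param temperatures Study temperatures, degrees Celsius.
#' @param sigma Relative noise scale (0 for noiseless data).
#' @param seed Integer master seed.
#' @param times Sampling grid, h.
#' @return Named list of \code{phx_dataset} objects.
#' @export
#' @examples
#' study <- default_study(sigma = 0, seed = 1, times = seq(0, 96, 12))
#' names(study)
default_study <- function(config = default_config(),
                          temperatures = c(20, 25, 30, 35), sigma = 0.05,
                          seed = 101, times = seq(0, 336, by = 12)) {
  out <- lapply(seq_along(temperatures), function(i) {
    generate_dataset(config, temperatures[i], times = times,
                     noise = noise_model(sigma = sigma,
                                         seed = (seed + i) %% .Machine$integer.max))
  })
  stats::setNames(out, paste0("T", temperatures))
}

# --- dataset accessors -------------------------------------------------------

dataset_records <- function(dataset) {
  if (inherits(dataset, "phx_dataset")) return(dataset$records)
  if (is.data.frame(dataset)) {
    required <- c("time_h", "species", "concentration_mg_L")
    if (!all(required %in% names(dataset))) {
      stop("validation error: dataset needs columns ",
           paste(required, collapse = ", "), call. = FALSE)
    }
    return(dataset)
  }
  stop("validation error: not a dataset", call. = FALSE)
}

dataset_temperature <- function(dataset) {
  if (inherits(dataset, "phx_dataset")) return(dataset$metadata$temperature_C)
  tc <- attr(dataset, "temperature_C")
  if (is.null(tc)) {
    stop("validation error: dataset lacks a temperature_C attribute",
         call. = FALSE)
  }
  tc
}

dataset_ethanol <- function(dataset, default = ethanol_profile("logistic")) {
  if (inherits(dataset, "phx_dataset") && !is.null(dataset$metadata$ethanol)) {
    return(ethanol_from_spec(dataset$metadata$ethanol))
  }
  default
}

#' @export
print.phx_dataset <- function(x, ...) {
  cat("Synthetic fermentation dataset at", x$metadata$temperature_C, "C\n")
  cat(" ", length(unique(x$records$time_h)), "time points,",
      "noise:", x$metadata$noise$kind,
      "(sigma =", x$metadata$noise$sigma, ")\n")
  invisible(x)
}
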