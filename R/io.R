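#' Write a dataset as tidy CSV with a ground-truth sidecar
#'
#' Writes the records in the tidy long schema (\code{time_h}, \code{species},
#' \code{concentration_mg_L}) with full double precision, plus a sidecar JSON
#' (\code{<path-without-ext>.json}) holding the metadata: temperature,
#' ethanol profile, noise model, seed and ground-truth parameters.
#'
#' @param dataset A \code{phx_dataset}.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_dataset_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "phx_dataset"))
  recs <- dataset$records
  out <- data.frame(
    time_h = formatC(recs$time_h, digits = 17, format = "g"),
    species = recs$species,
    concentration_mg_L = formatC(recs$concentration_mg_L, digits = 17,
                                 format = "g"))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  side <- paste0(tools::file_path_sans_ext(path), ".json")
  jsonlite::write_json(dataset$metadata, side, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a dataset from tidy CSV
#'
#' Validates the schema (columns \code{time_h}, \code{species},
#' \code{concentration_mg_L}; numeric fields parseable) and reports malformed
#' rows by line number. If the sidecar JSON written by [write_dataset_csv()]
#' is present its metadata (including ground truth) is restored; otherwise
#' \code{temperature_C} must be supplied.
#'
#' @param path CSV path.
#' @param temperature_C Fermentation temperature (used when no sidecar JSON
#'   is found).
#' @return A \code{phx_dataset}.
#' @export
read_dataset_csv <- function(path, temperature_C = NULL) {
  if (!file.exists(path)) {
    stop("validation error: file not found: ", path, call. = FALSE)
  }
  raw <- utils::read.csv(path, colClasses = "character")
  required <- c("time_h", "species", "concentration_mg_L")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop("validation error: ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  tt <- suppressWarnings(as.numeric(raw$time_h))
  cc <- suppressWarnings(as.numeric(raw$concentration_mg_L))
  bad <- which(is.na(tt) | is.na(cc) | !nzchar(raw$species))
  if (length(bad)) {
    stop("validation error: malformed rows in ", path, " at line(s) ",
         paste(bad + 1L, collapse = ", "), " (1 header line)", call. = FALSE)
  }
  records <- data.frame(time_h = tt, species = raw$species,
                        concentration_mg_L = cc, stringsAsFactors = FALSE)
  records <- records[order(records$species, records$time_h), ]
  rownames(records) <- NULL
  side <- paste0(tools::file_path_sans_ext(path), ".json")
  metadata <- if (file.exists(side)) {
    md <- jsonlite::read_json(side, simplifyVector = TRUE)
    if (!is.null(md$ground_truth$kinetics)) {
      md$ground_truth$kinetics <- as.data.frame(md$ground_truth$kinetics)
    }
    md
  } else {
    if (is.null(temperature_C)) {
      stop("validation error: no sidecar metadata for ", path,
           "; supply temperature_C", call. = FALSE)
    }
    list(temperature_C = temperature_C)
  }
  structure(list(records = records, metadata = metadata),
            class = "phx_dataset")
}

write_run_log <- function(path, inputs) {
  log <- c(list(package = "phenolex",
                version = as.character(utils::packageVersion("phenolex")),
                r_version = as.character(getRversion()),
                timestamp = format(Sys.time(), tz = "UTC")),
           inputs)
  jsonlite::write_json(log, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Run a simulation and write its trajectory to CSV
#'
#' Thin runnable wrapper over [simulate_fermentation()]: loads the
#' configuration, simulates at the given temperature and ethanol profile,
#' writes the tidy trajectory CSV and a JSON run log (inputs and versions)
#' alongside it.
#'
#' @param out Output CSV path.
#' @param config Configuration list or path to a YAML configuration
#'   (\code{NULL} for the defaults).
#' @param temperature_C Fermentation temperature, degrees Celsius.
#' @param ethanol Constant ethanol (percent v/v), a profile function, or
#'   \code{NULL} for the default logistic ramp.
#' @param t_end Final time, h (default 336).
#' @param by Output spacing, h (default 2).
#' @return The trajectory, invisibly.
#' @export
run_simulation <- function(out, config = NULL, temperature_C = 25,
                           ethanol = NULL, t_end = 336, by = 2) {
  cfg <- resolve_config(config)
  eth <- if (is.null(ethanol)) ethanol_profile("logistic")
         else if (is.numeric(ethanol)) ethanol_profile("constant", value = ethanol)
         else ethanol
  conditions <- fermentation_conditions(temperature_C, eth)
  times <- if (t_end <= 0) 0 else seq(0, t_end, by = min(by, t_end))
  traj <- simulate_fermentation(cfg, conditions, times)
  write_trajectory_csv(traj, out)
  write_run_log(paste0(tools::file_path_sans_ext(out), ".log.json"),
                list(command = "simulate", temperature_C = temperature_C,
                     ethanol = attr(eth, "spec"), t_end = t_end, by = by,
                     extrapolated = conditions$extrapolated,
                     solver = traj$diagnostics))
  invisible(traj)
}

#' Generate a synthetic study and write it to disk
#'
#' Runs [default_study()] and writes one CSV (plus ground-truth sidecar
#' JSON) per temperature into \code{out_dir}, with a JSON run log.
#'
#' @param out_dir Output directory (created if needed).
#' @inheritParams default_study
#' @return Named character vector of CSV paths, invisibly.
#' @export
run_generation <- function(out_dir, config = NULL,
                           temperatures = c(20, 25, 30, 35), sigma = 0.05,
                           seed = 101, times = seq(0, 336, by = 12)) {
  cfg <- resolve_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  study <- default_study(cfg, temperatures, sigma = sigma, seed = seed,
                         times = times)
  paths <- vapply(names(study), function(nm) {
    p <- file.path(out_dir, paste0("dataset_", nm, ".csv"))
    write_dataset_csv(study[[nm]], p)
    p
  }, character(1))
  write_run_log(file.path(out_dir, "generation.log.json"),
                list(command = "generate", temperatures = temperatures,
                     sigma = sigma, seed = seed,
                     times = range(times), files = unname(paths)))
  invisible(paths)
}

#' Fit a study from a manifest and write the parameter table
#'
#' Reads the datasets listed in a study manifest, runs [fit_study()], and
#' writes a parameter-table CSV (per-temperature estimates plus the
#' cross-temperature model coefficients) and a diagnostics JSON that
#' includes, when \code{gof = TRUE}, the R-squared of the re-simulated fit
#' at each temperature.
#'
#' @param manifest Path to a YAML manifest, or an equivalent list, with
#'   fields \code{datasets} (list of \code{path} / optional
#'   \code{temperature_C} entries), optional \code{config} (YAML path) and
#'   optional \code{out_dir}.
#' @param out_dir Output directory (overrides the manifest's).
#' @param gof Also compute per-temperature goodness of fit by re-simulating
#'   with the fitted parameters (default \code{TRUE}).
#' @return The \code{phx_study_fit}, invisibly.
#' @export
run_fit <- function(manifest, out_dir = NULL, gof = TRUE) {
  mf <- if (is.character(manifest)) yaml::read_yaml(manifest) else manifest
  if (is.null(mf$datasets) || !length(mf$datasets)) {
    stop("configuration error: manifest lists no datasets", call. = FALSE)
  }
  cfg <- resolve_config(mf$config)
  out_dir <- out_dir %||% mf$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  datasets <- lapply(mf$datasets, function(d) {
    read_dataset_csv(d$path, temperature_C = d$temperature_C)
  })
  fit <- fit_study(datasets, config = cfg)

  coef_rows <- do.call(rbind, lapply(names(fit$temperature_models), function(p) {
    m <- fit$temperature_models[[p]]
    data.frame(parameter = p, temperature_C = NA_real_,
               estimate = NA_real_,
               model = m$parameter,
               coefficients = paste(names(m$estimate),
                                    signif(m$estimate, 8),
                                    sep = "=", collapse = "; "),
               r_squared = m$r_squared, stringsAsFactors = FALSE)
  }))
  est <- fit$estimates
  est$model <- "per_temperature"
  est$coefficients <- NA_character_
  est$r_squared <- NA_real_
  table_path <- file.path(out_dir, "parameter_table.csv")
  utils::write.csv(rbind(est, coef_rows), table_path, row.names = FALSE)

  diagnostics <- list(notes = fit$notes)
  if (gof) {
    diagnostics$goodness_of_fit <- lapply(datasets, function(ds) {
      tc <- dataset_temperature(ds)
      cfg_T <- config_at_estimates(cfg, fit$estimates, tc)
      cond <- fermentation_conditions(tc, dataset_ethanol(ds))
      tt <- sort(unique(dataset_records(ds)$time_h))
      traj <- simulate_fermentation(cfg_T, cond, tt)
      as.list(goodness_of_fit(traj, ds))
    })
    names(diagnostics$goodness_of_fit) <-
      paste0("T", vapply(datasets, dataset_temperature, numeric(1)))
  }
  stage1 <- lapply(fit$per_temperature, function(pt) {
    lapply(pt$stage1, function(f) {
      if (inherits(f, "phx_fit")) {
        list(estimate = as.list(f$estimate), r_squared = f$r_squared,
             window = f$window, note = f$note)
      } else {
        list(error = conditionMessage(f))
      }
    })
  })
  diagnostics$stage1 <- stage1
  jsonlite::write_json(diagnostics,
                       file.path(out_dir, "fit_diagnostics.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  write_run_log(file.path(out_dir, "fit.log.json"),
                list(command = "fit",
                     datasets = vapply(mf$datasets, `[[`, character(1), "path"),
                     parameter_table = table_path))
  invisible(fit)
}

#' Parameter-recovery experiment
#'
#' Repeats generate-then-fit over noise replicates of the default
#' four-temperature study and reports, per parameter and temperature, the
#' ground truth, mean estimate, bias, RMSE and relative RMSE. The noiseless
#' trajectories are simulated once and shared across replicates; each
#' replicate draws fresh measurement noise from a seed derived from
#' \code{seed}, so the whole report is deterministic.
#'
#' Rate constants are scored by relative error. The unavailable amounts are
#' pool sizes whose truth can be exactly zero at high temperature (the
#' clamped polynomial), so they are scored as errors in the unavailable
#' \emph{fraction}: \code{|estimate - truth| / C_G0}.
#'
#' @param n_replicates Number of noise replicates (>= 1).
#' @param sigma Relative noise scale (default 0.05).
#' @param seed Integer master seed.
#' @param config Configuration list.
#' @param temperatures Study temperatures.
#' @param times Sampling grid, h.
#' @param out Optional path for a JSON report.
#' @return data.frame report, one row per (parameter, temperature).
#' @export
run_recovery <- function(n_replicates = 20, sigma = 0.05, seed = 101,
                         config = default_config(),
                         temperatures = c(20, 25, 30, 35),
                         times = seq(0, 336, by = 12), out = NULL) {
  if (n_replicates < 1) {
    stop("validation error: n_replicates must be >= 1", call. = FALSE)
  }
  base_traj <- lapply(temperatures, function(tc) {
    simulate_fermentation(config, fermentation_conditions(tc), times)
  })
  truths <- do.call(rbind, lapply(temperatures, function(tc) {
    kin <- params_at_conditions(config, tc)$kinetics
    g <- function(sp, col) kin[kin$species == sp, col]
    data.frame(
      parameter = c("k_G_anthocyanin", "k_G_skin_tannin", "k_G_seed_tannin",
                    "k_R_anthocyanin", "C_U_anthocyanin", "C_U_skin_tannin"),
      temperature_C = tc,
      truth = c(g("anthocyanin", "k_G"), g("skin_tannin", "k_G"),
                g("seed_tannin", "k_G"), g("anthocyanin", "k_R"),
                g("anthocyanin", "C_U"), g("skin_tannin", "C_U")),
      scale = c(rep(NA_real_, 4),
                g("anthocyanin", "C_G0"),
                g("skin_tannin", "C_G0")),
      stringsAsFactors = FALSE)
  }))

  reps <- lapply(seq_len(n_replicates), function(r) {
    datasets <- lapply(seq_along(temperatures), function(i) {
      generate_dataset(config, temperatures[i], times = times,
                       noise = noise_model(sigma = sigma,
                                           seed = (seed * 1000 + r * 10 + i) %%
                                             .Machine$integer.max),
                       trajectory = base_traj[[i]])
    })
    fit_study(datasets, config = config)$estimates
  })

  est_all <- do.call(rbind, Map(function(e, r) {
    e$replicate <- r
    e
  }, reps, seq_along(reps)))

  report <- merge(truths, stats::aggregate(
    estimate ~ parameter + temperature_C, est_all,
    function(x) c(mean = mean(x), sd = stats::sd(x))),
    by = c("parameter", "temperature_C"))
  mean_est <- report$estimate[, "mean"]
  rmse <- vapply(seq_len(nrow(report)), function(i) {
    sel <- est_all$parameter == report$parameter[i] &
      est_all$temperature_C == report$temperature_C[i]
    sqrt(mean((est_all$estimate[sel] - report$truth[i])^2))
  }, numeric(1))
  denom <- ifelse(is.na(report$scale), abs(report$truth), report$scale)
  out_df <- data.frame(
    parameter = report$parameter,
    temperature_C = report$temperature_C,
    truth = report$truth,
    mean_estimate = mean_est,
    bias = mean_est - report$truth,
    rmse = rmse,
    relative_rmse = rmse / denom,
    n_replicates = n_replicates,
    sigma = sigma,
    stringsAsFactors = FALSE)
  out_df <- out_df[order(out_df$parameter, out_df$temperature_C), ]
  rownames(out_df) <- NULL
  if (!is.null(out)) {
    jsonlite::write_json(out_df, out, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    write_run_log(paste0(tools::file_path_sans_ext(out), ".log.json"),
                  list(command = "recover", n_replicates = n_replicates,
                       sigma = sigma, seed = seed,
                       temperatures = temperatures))
  }
  out_df
}

resolve_config <- function(config) {
  if (is.null(config)) return(default_config())
  if (is.character(config)) return(read_config(config))
  validate_config(config)
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a
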