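## Pipeline glue: configuration, seed fan-out and the four stages ------------
##
## Stages share a single global seed that fans out deterministically:
## stage k (1 = trace simulation, 2 = efficiency fit, 3 = Monte Carlo,
## 4 = ramp times) uses seed = (global_seed * 8 + k) mod 2^31, so stages are
## individually reproducible without sharing an RNG stream.

stage_seed <- function(global_seed, stage) {
  as.integer((as.numeric(global_seed) * 8 + stage) %% 2147483647)
}

#' Default pipeline configuration
#'
#' Returns the configuration list used by the pipeline stages, optionally
#' overridden by fields of a YAML or JSON file. Fields: `seed`,
#' `presets` (suspension names), `trace` (generator overrides passed to
#' [trace_gen_config()]), `mc` (`n_packets`, `profile`, plus overrides for
#' [tissue_model()]), `heating` (`concentrations_mg_per_g`,
#' `power_densities_W_per_cm2`, `depths_mm`), and `beam_area_cm2` for the
#' cuvette mass-in-beam bookkeeping.
#'
#' @param path optional YAML (`.yml`/`.yaml`) or JSON config file.
#' @param seed global seed overriding the file / default.
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(path = NULL, seed = NULL) {
  cfg <- list(
    seed = 1L,
    presets = c("AuNShell", "AuNR", "AuNStar"),
    trace = list(noise_sd_C = 0.05),
    beam_area_cm2 = 0.081,
    mc = list(n_packets = 1e6, profile = "flat"),
    heating = list(concentrations_mg_per_g = c(0.005, 0.01, 0.015, 0.02),
                   power_densities_W_per_cm2 = c(1, 3, 5),
                   depths_mm = c(0, 10, 20, 30)))
  if (!is.null(path)) {
    if (!file.exists(path)) stop_invalid("config file '%s' not found", path)
    user <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
      yaml::read_yaml(path)
    } else {
      jsonlite::read_json(path, simplifyVector = TRUE)
    }
    for (k in names(user)) {
      cfg[[k]] <- if (is.list(cfg[[k]]) && is.list(user[[k]])) {
        utils::modifyList(cfg[[k]], user[[k]])
      } else {
        user[[k]]
      }
    }
  }
  if (!is.null(seed)) cfg$seed <- seed
  check_scalar(cfg$seed, "seed")
  structure(cfg, class = c("pipeline_config", "list"))
}

provenance <- function(cfg, extra = list()) {
  c(list(package = "phototherm",
         version = as.character(utils::packageVersion("phototherm")),
         seed = cfg$seed,
         config_hash = sum(utf8ToInt(paste(
           deparse(unclass(cfg)), collapse = "")) * 1.0) %% 1e9),
    extra)
}

#' Pipeline stage 1: simulate benchmark thermal traces
#'
#' Writes one seeded synthetic heating/cooling trace per suspension preset
#' (each generated with its reference efficiency) plus a shared blank trace,
#' as CSV + JSON sidecars, along with a provenance file.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if missing).
#' @return Invisibly, the CSV paths written.
#' @export
run_simulate_traces <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed0 <- stage_seed(config$seed, 1L)
  paths <- character(0)
  for (i in seq_along(config$presets)) {
    susp <- preset_suspension(config$presets[i])
    args <- utils::modifyList(
      list(eta_true = susp$reference_eta,
           extinction = susp$extinction_808,
           seed = seed0 + i),
      config$trace)
    tr <- simulate_trace(do.call(trace_gen_config, args))
    p <- file.path(out_dir, paste0(susp$name, ".csv"))
    write_thermal_trace(tr, p)
    paths <- c(paths, p)
  }
  blank_args <- utils::modifyList(list(eta_true = 0, seed = seed0),
                                  config$trace)
  blank <- simulate_blank_trace(do.call(trace_gen_config, blank_args))
  bp <- file.path(out_dir, "blank.csv")
  write_thermal_trace(blank, bp)
  jsonlite::write_json(provenance(config, list(stage = "simulate_traces")),
                       file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(c(paths, bp))
}

#' Pipeline stage 2: fit efficiencies from traces
#'
#' Reads the trace CSVs written by [run_simulate_traces()], estimates the
#' time constant, eta and eta_m for each suspension, and writes an
#' efficiency-results CSV (one row per suspension) plus the benchmark
#' ranking.
#'
#' @param config a [pipeline_config()].
#' @param trace_dir directory containing the trace CSVs.
#' @param out_dir output directory.
#' @return Invisibly, the results data frame.
#' @export
run_fit_efficiency <- function(config, trace_dir, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  blank_path <- file.path(trace_dir, "blank.csv")
  if (!file.exists(blank_path)) {
    stop_invalid("missing blank trace '%s'; run run_simulate_traces first",
                 blank_path)
  }
  blank <- read_thermal_trace(blank_path)
  laser_power <- config$trace$laser_power_W %||% 1
  beam <- beam_geometry(area_cm2 = config$beam_area_cm2,
                        power_W = laser_power)
  rows <- lapply(config$presets, function(name) {
    p <- file.path(trace_dir, paste0(name, ".csv"))
    if (!file.exists(p)) {
      stop_invalid("missing trace '%s'; run run_simulate_traces first", p)
    }
    tr <- read_thermal_trace(p)
    susp <- preset_suspension(name)
    est <- estimate_eta(tr, blank, laser_power, susp$extinction_808)
    m_np <- mass_in_beam(susp$mass_concentration_mg_per_mL, beam,
                         susp$path_length_cm)
    est_m <- estimate_eta_m(tr, blank, laser_power, m_np,
                            tau_s = est$tau_s)
    data.frame(name = name, tau_s = est$tau_s, eta = est$eta,
               eta_m_per_ug = est_m$eta_m_per_ug,
               mass_in_beam_ug = m_np, r_squared = est$r_squared,
               equilibrated = est$equilibrated)
  })
  results <- do.call(rbind, rows)
  write.csv(results, file.path(out_dir, "efficiency_results.csv"),
            row.names = FALSE, quote = FALSE)
  rk <- benchmark_ranking(results)
  write.csv(rk$ranking, file.path(out_dir, "ranking.csv"),
            row.names = FALSE, quote = FALSE)
  jsonlite::write_json(provenance(config, list(stage = "fit_efficiency")),
                       file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(results)
}

#' Pipeline stage 3: Monte Carlo fluence map and depth profiles
#'
#' Runs the tissue Monte Carlo at the configured packet count, writes the
#' fluence map (CSV + JSON metadata) and depth-profile CSVs at the preset
#' lateral offsets (0, 4.8, 5.9, 11 mm), and logs the weight-conservation
#' residual.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @return Invisibly, the `fluence_map`.
#' @export
run_mc_fluence <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  mc <- config$mc
  if ((mc$n_packets %||% 0) < 1e4) {
    stop_invalid("mc$n_packets must be >= 1e4 for a usable map")
  }
  model_args <- mc[setdiff(names(mc), c("n_packets", "profile"))]
  model <- do.call(tissue_model, model_args)
  beam <- beam_model(profile = mc$profile %||% "flat")
  map <- run_mc(model, beam, n_packets = mc$n_packets,
                seed = stage_seed(config$seed, 3L))
  write_fluence_map(map, file.path(out_dir, "fluence_map.csv"))
  profs <- do.call(rbind, lapply(c(0, 4.8, 5.9, 11), function(off) {
    depth_profile(map, off)
  }))
  write.csv(profs, file.path(out_dir, "depth_profiles.csv"),
            row.names = FALSE, quote = FALSE)
  res <- conservation_residual(map)
  message(sprintf("weight conservation residual: %.3e", res))
  jsonlite::write_json(
    provenance(config, list(stage = "mc_fluence",
                            conservation_residual = res)),
    file.path(out_dir, "provenance.json"), auto_unbox = TRUE, digits = NA)
  invisible(map)
}

#' Pipeline stage 4: ramp-time tables
#'
#' Combines a fluence map (from [run_mc_fluence()]) with an eta_m estimate
#' (by default the AuNR value from stage 2's results CSV, or a value passed
#' directly) into pivoted ramp-time CSVs per concentration.
#'
#' @param config a [pipeline_config()].
#' @param mc_dir directory holding `fluence_map.csv` from stage 3.
#' @param out_dir output directory.
#' @param eta_m_per_ug mass conversion efficiency to use; when `NULL`, read
#'   from `efficiency_results.csv` in `efficiency_dir` (AuNR row).
#' @param efficiency_dir directory holding stage 2 results.
#' @return Invisibly, the [ramp_time_table()].
#' @export
run_ramp_times <- function(config, mc_dir, out_dir, eta_m_per_ug = NULL,
                           efficiency_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  map_path <- file.path(mc_dir, "fluence_map.csv")
  if (!file.exists(map_path)) {
    stop_invalid("missing fluence map '%s'; run run_mc_fluence first",
                 map_path)
  }
  map <- read_fluence_map(map_path)
  if (is.null(eta_m_per_ug)) {
    if (is.null(efficiency_dir)) {
      stop_invalid("supply eta_m_per_ug or efficiency_dir")
    }
    eff <- read.csv(file.path(efficiency_dir, "efficiency_results.csv"))
    eta_m_per_ug <- eff$eta_m_per_ug[eff$name == "AuNR"][1]
  }
  h <- config$heating
  tab <- ramp_time_table(
    map, eta_m_per_ug,
    concentrations_mg_per_g = h$concentrations_mg_per_g,
    power_densities_W_per_cm2 = h$power_densities_W_per_cm2,
    depths_mm = h$depths_mm)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  write_ramp_time_table(tab, out_dir)
  jsonlite::write_json(
    provenance(config, list(stage = "ramp_times", map_seed = map$seed,
                            eta_m_per_ug = eta_m_per_ug)),
    file.path(out_dir, "provenance.json"), auto_unbox = TRUE, digits = NA)
  invisible(tab)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
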