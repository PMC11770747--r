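## Synthetic thermal traces ---------------------------------------------------
##
## The generator produces heating/cooling traces that obey the lumped
## capacitance model exactly (up to optional Gaussian measurement noise):
##
##   laser on :  m C dT/dt = I eta (1 - 10^-eps) + Q_blank - m C (T - T_amb)/tau
##   laser off:  m C dT/dt = - m C (T - T_amb)/tau          (Newton cooling)
##
## so the heating phase approaches T_amb + dT_eq with
##   dT_eq = tau (I eta (1 - 10^-eps) + Q_blank) / (m C)
## and the cooling phase decays exponentially with time constant tau.

#' Configuration for the synthetic thermal-trace generator
#'
#' Bundles the physical parameters of a simulated cuvette calorimetry
#' experiment: a stirred nanoparticle suspension heated by a continuous-wave
#' laser and then left to cool. Defaults reflect the cuvette conditions used
#' for the estimator fixtures: 2 g of suspension, water's heat capacity,
#' 1 W laser, decadic extinction 0.1 at the laser wavelength, and a lumped
#' time constant of 600 s.
#'
#' @param eta_true true photothermal conversion efficiency, fraction in
#'   \[0, 1\].
#' @param extinction decadic optical depth of the suspension at the laser
#'   wavelength (dimensionless, >= 0).
#' @param laser_power_W laser power entering the cuvette (W).
#' @param sample_mass_g mass of the suspension (g).
#' @param heat_capacity_J_per_gK specific heat capacity (J g^-1 K^-1).
#' @param tau_s lumped heat-loss time constant (s), must be positive.
#' @param q_blank_W baseline heat-input rate of solvent plus cuvette (W).
#' @param t_ambient_C ambient temperature (degrees C).
#' @param heat_duration_s laser-on duration (s). The default, ten time
#'   constants, brings the trace to equilibrium as judged by the plateau
#'   slope criterion used by [estimate_eta()].
#' @param cool_duration_s laser-off duration (s).
#' @param sample_interval_s sampling interval (s).
#' @param noise_sd_C standard deviation of i.i.d. Gaussian measurement noise
#'   added to each sample (degrees C); 0 disables noise.
#' @param seed integer seed making noisy traces reproducible; ignored when
#'   `noise_sd_C` is 0.
#'
#' @return An object of class `trace_gen_config` (a validated list).
#' @seealso [simulate_trace()], [simulate_blank_trace()]
#' @export
#' @examples
#' cfg <- trace_gen_config(eta_true = 0.66, noise_sd_C = 0)
#' tr <- simulate_trace(cfg)
#' max(tr$temperatures_C) - cfg$t_ambient_C  # equilibrium temperature rise
trace_gen_config <- function(eta_true = 0.66,
                             extinction = 0.1,
                             laser_power_W = 1,
                             sample_mass_g = 2,
                             heat_capacity_J_per_gK = 4.182,
                             tau_s = 600,
                             q_blank_W = 0,
                             t_ambient_C = 25,
                             heat_duration_s = 6000,
                             cool_duration_s = 3600,
                             sample_interval_s = 1,
                             noise_sd_C = 0,
                             seed = NULL) {
  check_scalar(eta_true, "eta_true", 0, 1)
  check_scalar(extinction, "extinction", 0)
  check_scalar(laser_power_W, "laser_power_W", 0)
  check_scalar(sample_mass_g, "sample_mass_g", 1e-12)
  check_scalar(heat_capacity_J_per_gK, "heat_capacity_J_per_gK", 1e-12)
  check_scalar(tau_s, "tau_s", 1e-12)
  check_scalar(q_blank_W, "q_blank_W", 0)
  check_scalar(t_ambient_C, "t_ambient_C")
  check_scalar(heat_duration_s, "heat_duration_s", 0)
  check_scalar(cool_duration_s, "cool_duration_s", 0)
  check_scalar(sample_interval_s, "sample_interval_s", 1e-12)
  check_scalar(noise_sd_C, "noise_sd_C", 0)
  if (!is.null(seed)) check_scalar(seed, "seed")
  structure(
    list(eta_true = eta_true, extinction = extinction,
         laser_power_W = laser_power_W, sample_mass_g = sample_mass_g,
         heat_capacity_J_per_gK = heat_capacity_J_per_gK, tau_s = tau_s,
         q_blank_W = q_blank_W, t_ambient_C = t_ambient_C,
         heat_duration_s = heat_duration_s, cool_duration_s = cool_duration_s,
         sample_interval_s = sample_interval_s, noise_sd_C = noise_sd_C,
         seed = seed),
    class = "trace_gen_config")
}

#' Construct a thermal trace object
#'
#' A `thermal_trace` holds a timestamped temperature record with a laser-off
#' phase marker and the calorimetric constants (sample mass and heat
#' capacity) needed by the efficiency estimators.
#'
#' @param times_s strictly increasing sample times (s).
#' @param temperatures_C temperatures (degrees C), same length as `times_s`.
#' @param laser_off_time_s time at which the laser was switched off (s);
#'   must lie within the time range.
#' @param t_ambient_C ambient temperature (degrees C).
#' @param sample_mass_g sample mass (g).
#' @param heat_capacity_J_per_gK specific heat capacity (J g^-1 K^-1).
#'
#' @return An object of class `thermal_trace`.
#' @export
thermal_trace <- function(times_s, temperatures_C, laser_off_time_s,
                          t_ambient_C, sample_mass_g,
                          heat_capacity_J_per_gK) {
  if (!is.numeric(times_s) || !is.numeric(temperatures_C)) {
    stop_invalid("times and temperatures must be numeric")
  }
  if (length(times_s) != length(temperatures_C)) {
    stop_invalid("times (%d) and temperatures (%d) differ in length",
                 length(times_s), length(temperatures_C))
  }
  if (length(times_s) < 2L || any(diff(times_s) <= 0)) {
    stop_invalid("times must be strictly increasing with >= 2 samples")
  }
  check_scalar(laser_off_time_s, "laser_off_time_s",
               min(times_s), max(times_s))
  check_scalar(t_ambient_C, "t_ambient_C")
  check_scalar(sample_mass_g, "sample_mass_g", 1e-12)
  check_scalar(heat_capacity_J_per_gK, "heat_capacity_J_per_gK", 1e-12)
  structure(
    list(times_s = as.numeric(times_s),
         temperatures_C = as.numeric(temperatures_C),
         laser_off_time_s = laser_off_time_s,
         t_ambient_C = t_ambient_C,
         sample_mass_g = sample_mass_g,
         heat_capacity_J_per_gK = heat_capacity_J_per_gK),
    class = "thermal_trace")
}

#' @export
print.thermal_trace <- function(x, ...) {
  cat(sprintf(
    "<thermal_trace> %d samples over %.0f s (laser off at %.0f s)\n",
    length(x$times_s), max(x$times_s), x$laser_off_time_s))
  cat(sprintf("  T_amb %.2f C, peak %.2f C, m %.3g g, C %.4g J/(g K)\n",
              x$t_ambient_C, max(x$temperatures_C), x$sample_mass_g,
              x$heat_capacity_J_per_gK))
  invisible(x)
}

## closed-form solution of the lumped model at the sample times
lumped_solution <- function(cfg, eta) {
  gain_W <- cfg$laser_power_W * eta * (1 - 10^(-cfg$extinction)) +
    cfg$q_blank_W
  mC <- cfg$sample_mass_g * cfg$heat_capacity_J_per_gK
  dT_eq <- cfg$tau_s * gain_W / mC
  times <- seq(0, cfg$heat_duration_s + cfg$cool_duration_s,
               by = cfg$sample_interval_s)
  heating <- times <= cfg$heat_duration_s
  temp <- numeric(length(times))
  temp[heating] <- cfg$t_ambient_C +
    dT_eq * (1 - exp(-times[heating] / cfg$tau_s))
  t_off_temp <- cfg$t_ambient_C +
    dT_eq * (1 - exp(-cfg$heat_duration_s / cfg$tau_s))
  temp[!heating] <- cfg$t_ambient_C + (t_off_temp - cfg$t_ambient_C) *
    exp(-(times[!heating] - cfg$heat_duration_s) / cfg$tau_s)
  list(times = times, temp = temp)
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Simulate a heating/cooling thermal trace
#'
#' Generates a trace following the lumped-capacitance model exactly: during
#' the laser-on phase the temperature rises as
#' `T(t) = T_amb + dT_eq (1 - exp(-t/tau))` with equilibrium rise
#' `dT_eq = tau (I eta (1 - 10^-eps) + Q_blank) / (m C)`, and after laser-off
#' it decays by Newton cooling with the same time constant. Optional i.i.d.
#' Gaussian noise is added per sample.
#'
#' @param config a [trace_gen_config()].
#' @return A [thermal_trace()].
#' @export
#' @examples
#' tr <- simulate_trace(trace_gen_config(eta_true = 0.66))
simulate_trace <- function(config) {
  stopifnot(inherits(config, "trace_gen_config"))
  sol <- lumped_solution(config, config$eta_true)
  temp <- sol$temp
  if (config$noise_sd_C > 0) {
    temp <- with_seed(config$seed,
                      temp + rnorm(length(temp), sd = config$noise_sd_C))
  }
  thermal_trace(sol$times, temp, config$heat_duration_s,
                config$t_ambient_C, config$sample_mass_g,
                config$heat_capacity_J_per_gK)
}

#' Simulate a blank (water-only) thermal trace
#'
#' Same model as [simulate_trace()] but with no nanoparticles: the only heat
#' input is the solvent/cuvette baseline rate `q_blank_W`, giving an
#' equilibrium rise `tau Q_blank / (m C)`.
#'
#' @inheritParams simulate_trace
#' @return A [thermal_trace()].
#' @export
simulate_blank_trace <- function(config) {
  stopifnot(inherits(config, "trace_gen_config"))
  sol <- lumped_solution(config, eta = 0)
  temp <- sol$temp
  if (config$noise_sd_C > 0) {
    temp <- with_seed(config$seed,
                      temp + rnorm(length(temp), sd = config$noise_sd_C))
  }
  thermal_trace(sol$times, temp, config$heat_duration_s,
                config$t_ambient_C, config$sample_mass_g,
                config$heat_capacity_J_per_gK)
}

#' Reference nanoparticle suspensions
#'
#' Returns one of three benchmark gold nanoparticle suspensions -- silica-core
#' gold nanoshells (`"AuNShell"`), gold nanorods (`"AuNR"`) or gold nanostars
#' (`"AuNStar"`) -- each diluted to a decadic extinction of 0.1 at 808 nm in
#' a 1 cm cuvette. Mass extinction coefficients at 808 nm are 31.7 (shells),
#' 46.1 (rods) and 24.7 (stars) cm^2/mg; mass concentrations follow from the
#' Beer-Lambert mass form. Reference photothermal conversion efficiencies
#' (0.20, 0.66 and 0.34 respectively) are stored in the
#' `reference_eta` field. The nanoshell preset carries the core/shell radii
#' (r1 = 59.9 nm silica core, r2 = 76.4 nm outer gold surface) and the bulk
#' densities of silica and gold for the core-mass correction.
#'
#' @param name one of `"AuNShell"`, `"AuNR"`, `"AuNStar"`.
#' @return An [np_suspension()] with a `reference_eta` field.
#' @export
#' @examples
#' preset_suspension("AuNR")$mass_ext_coeff_cm2_per_mg  # 46.1
preset_suspension <- function(name) {
  presets <- list(
    AuNShell = list(mass_ext = 31.7, eta = 0.20,
                    r1 = 59.9, r2 = 76.4, rho_core = 2.65,
                    rho_shell = 19.32),
    AuNR = list(mass_ext = 46.1, eta = 0.66),
    AuNStar = list(mass_ext = 24.7, eta = 0.34))
  if (!is.character(name) || length(name) != 1L ||
      !name %in% names(presets)) {
    stop_invalid("unknown suspension preset '%s' (known: %s)",
                 paste(name, collapse = ","),
                 paste(names(presets), collapse = ", "))
  }
  p <- presets[[name]]
  extinction <- 0.1
  path_cm <- 1
  np_suspension(
    name = name,
    extinction_808 = extinction,
    mass_concentration_mg_per_mL =
      concentration_from_extinction(extinction, p$mass_ext, path_cm),
    mass_ext_coeff_cm2_per_mg = p$mass_ext,
    path_length_cm = path_cm,
    shell_r1_nm = p$r1, shell_r2_nm = p$r2,
    density_core_g_per_cm3 = p$rho_core,
    density_shell_g_per_cm3 = p$rho_shell,
    reference_eta = p$eta)
}

## Trace serialization: CSV of (time_s, temperature_C) plus a JSON sidecar
## holding the phase marker and calorimetric constants.

#' Write / read a thermal trace as CSV plus JSON sidecar
#'
#' The CSV has columns `time_s,temperature_C`; the sidecar
#' (`<path>.json`) records `laser_off_time_s`, `t_ambient_C`,
#' `sample_mass_g` and `heat_capacity_J_per_gK`.
#'
#' @param trace a [thermal_trace()].
#' @param path CSV file path.
#' @return `write_thermal_trace()` returns `path` invisibly;
#'   `read_thermal_trace()` returns a [thermal_trace()].
#' @export
write_thermal_trace <- function(trace, path) {
  stopifnot(inherits(trace, "thermal_trace"))
  df <- data.frame(time_s = trace$times_s,
                   temperature_C = trace$temperatures_C)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- trace[c("laser_off_time_s", "t_ambient_C", "sample_mass_g",
                  "heat_capacity_J_per_gK")]
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_thermal_trace
#' @export
read_thermal_trace <- function(path) {
  if (!file.exists(path)) stop_invalid("trace file '%s' not found", path)
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) {
    stop_invalid("trace sidecar '%s' not found", sidecar)
  }
  df <- tryCatch(read.csv(path), error = function(e) {
    stop_invalid("failed to parse '%s': %s", path, conditionMessage(e))
  })
  if (nrow(df) == 0L || !all(c("time_s", "temperature_C") %in% names(df))) {
    stop_invalid(
      "'%s': expected non-empty columns time_s,temperature_C (line 1)", path)
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  thermal_trace(df$time_s, df$temperature_C, meta$laser_off_time_s,
                meta$t_ambient_C, meta$sample_mass_g,
                meta$heat_capacity_J_per_gK)
}
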