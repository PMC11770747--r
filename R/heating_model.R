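## Idealized voxel heating model ---------------------------------------------
##
## Peak heating rate of a single nanoparticle-loaded tissue voxel, assuming
## no thermal exchange with the surroundings:
##   dT/dt = eta_m * P(z) * m_NPs / (m C)
## with P(z) the beam power reaching the voxel's depth, m_NPs the
## nanoparticle mass in the voxel (micrograms), m the voxel tissue mass
## (grams) and C the specific heat of water. Ramp times to the 43 C
## hyperthermia threshold are therefore minima: conduction, perfusion and
## attenuation by nanoparticles above the voxel would all lengthen them.

#' Voxel heating scenario
#'
#' @param np_concentration_mg_per_g nanoparticle concentration in the voxel
#'   (mg of nanoparticle per g of tissue); the benchmark range is
#'   0.005-0.020 mg/g.
#' @param surface_power_density_W_per_cm2 laser power density applied at the
#'   tissue surface (W/cm^2).
#' @param depth_mm voxel depth below the surface (mm).
#' @param eta_m_per_ug photothermal mass conversion efficiency of the
#'   nanoparticles (per microgram).
#' @param voxel_mass_ug tissue mass of the voxel (micrograms); 7.47 ug
#'   corresponds to a 0.0195 cm cube at density 1 g/cm^3.
#' @param heat_capacity_J_per_gK specific heat capacity of the voxel
#'   (water, 4.186 J g^-1 K^-1).
#' @param t_body_C,t_target_C body and target temperatures (degrees C);
#'   target must exceed body.
#' @return An object of class `heating_scenario`.
#' @export
heating_scenario <- function(np_concentration_mg_per_g = 0.01,
                             surface_power_density_W_per_cm2 = 1,
                             depth_mm = 0,
                             eta_m_per_ug,
                             voxel_mass_ug = 7.47,
                             heat_capacity_J_per_gK = 4.186,
                             t_body_C = 37,
                             t_target_C = 43) {
  check_scalar(np_concentration_mg_per_g, "np_concentration_mg_per_g", 0)
  check_scalar(surface_power_density_W_per_cm2,
               "surface_power_density_W_per_cm2", 0)
  check_scalar(depth_mm, "depth_mm", 0)
  check_scalar(eta_m_per_ug, "eta_m_per_ug", 0)
  check_scalar(voxel_mass_ug, "voxel_mass_ug", 1e-300)
  check_scalar(heat_capacity_J_per_gK, "heat_capacity_J_per_gK", 1e-300)
  check_scalar(t_body_C, "t_body_C")
  check_scalar(t_target_C, "t_target_C")
  if (t_target_C <= t_body_C) {
    stop_invalid("t_target_C (%g) must exceed t_body_C (%g)",
                 t_target_C, t_body_C)
  }
  structure(
    list(np_concentration_mg_per_g = np_concentration_mg_per_g,
         surface_power_density_W_per_cm2 = surface_power_density_W_per_cm2,
         depth_mm = depth_mm, eta_m_per_ug = eta_m_per_ug,
         voxel_mass_ug = voxel_mass_ug,
         heat_capacity_J_per_gK = heat_capacity_J_per_gK,
         t_body_C = t_body_C, t_target_C = t_target_C),
    class = "heating_scenario")
}

#' Peak voxel heating rate
#'
#' `dT/dt = eta_m P m_NPs / (m C)` in K/s, with
#' `m_NPs = concentration x voxel mass` (micrograms, tissue density
#' 1 g/cm^3) and `P` the beam power reaching the voxel's depth (see
#' [power_at_depth()]). No heat exchange with surrounding tissue is
#' modelled, so this is the peak (initial) rate.
#'
#' @param scenario a [heating_scenario()].
#' @param power_at_depth_W beam power arriving at the voxel's depth (W).
#' @return Heating rate (K/s).
#' @export
heating_rate <- function(scenario, power_at_depth_W) {
  stopifnot(inherits(scenario, "heating_scenario"))
  check_scalar(power_at_depth_W, "power_at_depth_W", 0)
  np_mass_ug <- scenario$np_concentration_mg_per_g *
    scenario$voxel_mass_ug * 1e-3  # (mg/g) x (ug) -> ug of NP
  voxel_mass_g <- scenario$voxel_mass_ug * 1e-6
  scenario$eta_m_per_ug * power_at_depth_W * np_mass_ug /
    (voxel_mass_g * scenario$heat_capacity_J_per_gK)
}

#' Ramp time from body temperature to the hyperthermia target
#'
#' `(t_target - t_body) / rate`; a zero rate yields `Inf` with an
#' `unreachable` attribute rather than an error.
#'
#' @param rate_K_per_s heating rate (K/s, >= 0).
#' @param t_body_C,t_target_C body and target temperatures (degrees C).
#' @return Ramp time (s).
#' @export
#' @examples
#' ramp_time(1)    # 6 s
#' ramp_time(0.5)  # 12 s
ramp_time <- function(rate_K_per_s, t_body_C = 37, t_target_C = 43) {
  if (!is.numeric(rate_K_per_s) || any(rate_K_per_s < 0)) {
    stop_invalid("rate must be non-negative")
  }
  out <- (t_target_C - t_body_C) / rate_K_per_s
  if (any(rate_K_per_s == 0)) {
    attr(out, "unreachable") <- which(rate_K_per_s == 0)
  }
  out
}

#' Grid of ramp times over depth, concentration and power density
#'
#' Evaluates the idealized voxel heating model over a full grid of
#' nanoparticle concentrations, surface power densities and depths, using
#' the on-axis relative photon density of a Monte Carlo fluence map to
#' attenuate the delivered power with depth.
#'
#' @param fluence a [run_mc()] result covering the requested depths.
#' @param eta_m_per_ug photothermal mass conversion efficiency (per
#'   microgram).
#' @param concentrations_mg_per_g nanoparticle concentrations (mg/g).
#' @param power_densities_W_per_cm2 surface power densities (W/cm^2).
#' @param depths_mm depths below the surface (mm).
#' @param ... further arguments passed to [heating_scenario()].
#' @return A data frame of class `ramp_time_table` with columns `depth_mm`,
#'   `concentration_mg_per_g`, `power_W_per_cm2`, `relative_density`,
#'   `heating_rate_K_per_s`, `ramp_time_s`; metadata (eta_m, map seed,
#'   model assumptions) in attributes.
#' @export
ramp_time_table <- function(fluence, eta_m_per_ug,
                            concentrations_mg_per_g =
                              c(0.005, 0.01, 0.015, 0.02),
                            power_densities_W_per_cm2 = c(1, 3, 5),
                            depths_mm = c(0, 10, 20, 30), ...) {
  stopifnot(inherits(fluence, "fluence_map"))
  check_scalar(eta_m_per_ug, "eta_m_per_ug", 0)
  max_depth <- max(fluence$axes_cm$z) * 10
  if (any(depths_mm < 0) || any(depths_mm > max_depth)) {
    stop_invalid("depths must lie within the fluence map (0-%g mm)",
                 max_depth)
  }
  grid <- expand.grid(depth_mm = depths_mm,
                      concentration_mg_per_g = concentrations_mg_per_g,
                      power_W_per_cm2 = power_densities_W_per_cm2,
                      KEEP.OUT.ATTRS = FALSE)
  rel <- on_axis_density(fluence, grid$depth_mm)
  rate <- mapply(function(conc, pd, d) {
    sc <- heating_scenario(np_concentration_mg_per_g = conc,
                           surface_power_density_W_per_cm2 = pd,
                           depth_mm = d, eta_m_per_ug = eta_m_per_ug, ...)
    heating_rate(sc, power_at_depth(fluence, pd, d))
  }, grid$concentration_mg_per_g, grid$power_W_per_cm2, grid$depth_mm)
  grid$relative_density <- rel
  grid$heating_rate_K_per_s <- rate
  sc0 <- heating_scenario(eta_m_per_ug = eta_m_per_ug, ...)
  grid$ramp_time_s <- ifelse(
    rate > 0, (sc0$t_target_C - sc0$t_body_C) / rate, Inf)
  structure(grid,
            class = c("ramp_time_table", "data.frame"),
            eta_m_per_ug = eta_m_per_ug,
            map_seed = fluence$seed,
            voxel_mass_ug = sc0$voxel_mass_ug,
            assumptions = paste(
              "Idealized minimum ramp times: no conduction, no perfusion,",
              "no laser attenuation by nanoparticles above the voxel."))
}

#' Write a ramp-time table as one pivoted CSV per concentration
#'
#' Each CSV is shaped with depth as rows and surface power density as
#' columns; a JSON metadata file records eta_m, the fluence-map seed and
#' the model assumptions.
#'
#' @param table a [ramp_time_table()].
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix.
#' @return Invisibly, the paths written.
#' @export
write_ramp_time_table <- function(table, dir, prefix = "ramp_times") {
  stopifnot(inherits(table, "ramp_time_table"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (conc in unique(table$concentration_mg_per_g)) {
    sub <- table[table$concentration_mg_per_g == conc, ]
    wide <- reshape_wide(sub)
    p <- file.path(dir, sprintf("%s_%gmg_per_g.csv", prefix, conc))
    write.csv(wide, p, row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
  }
  meta <- list(eta_m_per_ug = attr(table, "eta_m_per_ug"),
               map_seed = attr(table, "map_seed"),
               voxel_mass_ug = attr(table, "voxel_mass_ug"),
               assumptions = attr(table, "assumptions"))
  mp <- file.path(dir, paste0(prefix, "_metadata.json"))
  jsonlite::write_json(meta, mp, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, mp))
}

reshape_wide <- function(sub) {
  depths <- sort(unique(sub$depth_mm))
  powers <- sort(unique(sub$power_W_per_cm2))
  out <- data.frame(depth_mm = depths)
  for (p in powers) {
    col <- vapply(depths, function(d) {
      sub$ramp_time_s[sub$depth_mm == d & sub$power_W_per_cm2 == p][1]
    }, numeric(1))
    out[[sprintf("ramp_time_s_%gW_per_cm2", p)]] <- col
  }
  out
}
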