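## Suspension bookkeeping: Beer-Lambert mass form, shell mass correction,
## and mass-in-beam accounting.

#' Nanoparticle suspension metadata
#'
#' Holds the optical and mass bookkeeping for a nanoparticle suspension:
#' decadic extinction at the laser wavelength, mass concentration (total
#' nanoparticle mass, including any non-metal core), mass extinction
#' coefficient and cuvette path length, plus optional core/shell geometry
#' and densities for silica-core nanoshells.
#'
#' @param name label for the suspension.
#' @param extinction_808 decadic optical depth at 808 nm (>= 0).
#' @param mass_concentration_mg_per_mL total nanoparticle mass concentration
#'   (mg/mL).
#' @param mass_ext_coeff_cm2_per_mg mass extinction coefficient (cm^2/mg).
#' @param path_length_cm optical path length through the cuvette (cm).
#' @param shell_r1_nm,shell_r2_nm inner (core) and outer shell radii (nm),
#'   `NULL` unless the particle is a core-shell geometry; requires
#'   `0 < r1 < r2`.
#' @param density_core_g_per_cm3,density_shell_g_per_cm3 bulk densities of
#'   the core and shell materials (g/cm^3).
#' @param reference_eta optional literature photothermal conversion
#'   efficiency used as a reference value.
#' @return An object of class `np_suspension`.
#' @export
np_suspension <- function(name,
                          extinction_808,
                          mass_concentration_mg_per_mL,
                          mass_ext_coeff_cm2_per_mg = NA_real_,
                          path_length_cm = 1,
                          shell_r1_nm = NULL,
                          shell_r2_nm = NULL,
                          density_core_g_per_cm3 = NULL,
                          density_shell_g_per_cm3 = NULL,
                          reference_eta = NULL) {
  check_scalar(extinction_808, "extinction_808", 0)
  check_scalar(mass_concentration_mg_per_mL,
               "mass_concentration_mg_per_mL", 0)
  check_scalar(path_length_cm, "path_length_cm", 1e-12)
  if (!is.null(shell_r1_nm) || !is.null(shell_r2_nm)) {
    check_scalar(shell_r1_nm, "shell_r1_nm", 0)
    check_scalar(shell_r2_nm, "shell_r2_nm", 1e-12)
    if (shell_r1_nm >= shell_r2_nm) {
      stop_invalid("shell radii must satisfy 0 < r1 < r2 (got %g, %g)",
                   shell_r1_nm, shell_r2_nm)
    }
  }
  structure(
    list(name = name,
         extinction_808 = extinction_808,
         mass_concentration_mg_per_mL = mass_concentration_mg_per_mL,
         mass_ext_coeff_cm2_per_mg = mass_ext_coeff_cm2_per_mg,
         path_length_cm = path_length_cm,
         shell_r1_nm = shell_r1_nm, shell_r2_nm = shell_r2_nm,
         density_core_g_per_cm3 = density_core_g_per_cm3,
         density_shell_g_per_cm3 = density_shell_g_per_cm3,
         reference_eta = reference_eta),
    class = "np_suspension")
}

#' @export
print.np_suspension <- function(x, ...) {
  cat(sprintf("<np_suspension> %s: ext %.3g @ 808 nm, %.4g mg/mL, %s cm2/mg\n",
              x$name, x$extinction_808, x$mass_concentration_mg_per_mL,
              format(x$mass_ext_coeff_cm2_per_mg)))
  invisible(x)
}

#' Beam geometry for cuvette experiments
#'
#' @param area_cm2 beam cross-sectional area (cm^2). The cuvette experiments
#'   use 0.081 cm^2 (8.1 mm^2, FWHM-measured).
#' @param power_W laser power (W).
#' @return An object of class `beam_geometry`.
#' @export
beam_geometry <- function(area_cm2 = 0.081, power_W = 1) {
  check_scalar(area_cm2, "area_cm2", 1e-12)
  check_scalar(power_W, "power_W", 0)
  structure(list(area_cm2 = area_cm2, power_W = power_W),
            class = "beam_geometry")
}

#' Transmitted fraction of light through a suspension
#'
#' Converts a decadic extinction (optical depth) into the transmitted
#' fraction `10^-extinction`; an extinction of 0.1 transmits 79% of the
#' incident light.
#'
#' @param extinction decadic optical depth (>= 0); vectorized.
#' @return Transmitted fraction in (0, 1\].
#' @export
#' @examples
#' transmission_fraction(0.1)  # 0.794
transmission_fraction <- function(extinction) {
  if (!is.numeric(extinction) || any(!is.finite(extinction)) ||
      any(extinction < 0)) {
    stop_invalid("extinction must be finite and non-negative")
  }
  10^(-extinction)
}

#' Mass extinction coefficient (Beer-Lambert law in mass form)
#'
#' `eps_m = eps / (C L)` with `eps` the measured decadic extinction, `C` the
#' mass concentration (mg/mL) and `L` the path length (cm), giving cm^2/mg.
#' [concentration_from_extinction()] is the inverse operation.
#'
#' @param extinction decadic optical depth (>= 0).
#' @param concentration_mg_per_mL mass concentration (mg/mL, > 0).
#' @param path_cm optical path length (cm, > 0).
#' @return Mass extinction coefficient (cm^2/mg).
#' @export
#' @examples
#' mass_extinction_coefficient(0.1, 0.1 / 31.7, 1)  # 31.7 cm2/mg
mass_extinction_coefficient <- function(extinction, concentration_mg_per_mL,
                                        path_cm) {
  check_scalar(extinction, "extinction", 0)
  check_scalar(concentration_mg_per_mL, "concentration_mg_per_mL", 1e-300)
  check_scalar(path_cm, "path_cm", 1e-300)
  extinction / (concentration_mg_per_mL * path_cm)
}

#' @rdname mass_extinction_coefficient
#' @param mass_ext_coeff_cm2_per_mg mass extinction coefficient (cm^2/mg).
#' @export
concentration_from_extinction <- function(extinction,
                                          mass_ext_coeff_cm2_per_mg,
                                          path_cm) {
  check_scalar(extinction, "extinction", 0)
  check_scalar(mass_ext_coeff_cm2_per_mg, "mass_ext_coeff_cm2_per_mg",
               1e-300)
  check_scalar(path_cm, "path_cm", 1e-300)
  extinction / (mass_ext_coeff_cm2_per_mg * path_cm)
}

#' Silica core volume fraction of a core-shell particle
#'
#' Fraction of the particle volume occupied by the core: `(r1/r2)^3`. For
#' the benchmark nanoshells (r1 = 59.9 nm, r2 = 76.4 nm) this is 48%.
#'
#' @param r1_nm core radius (nm), `0 <= r1 <= r2`.
#' @param r2_nm outer radius (nm), > 0.
#' @return Volume fraction in \[0, 1\].
#' @export
silica_volume_fraction <- function(r1_nm, r2_nm) {
  check_scalar(r1_nm, "r1_nm", 0)
  check_scalar(r2_nm, "r2_nm", 1e-300)
  if (r1_nm > r2_nm) {
    stop_invalid("core radius r1 (%g) exceeds outer radius r2 (%g)",
                 r1_nm, r2_nm)
  }
  (r1_nm / r2_nm)^3
}

#' Core-mass correction for core-shell particles
#'
#' Ratio of core mass to shell-metal mass,
#' `f_v rho_core / ((1 - f_v) rho_shell)` with `f_v` the core volume
#' fraction. Metal mass measured by elemental analysis (e.g. ICP-MS gold
#' mass) is multiplied by `1 + correction` to obtain total particle mass;
#' for the benchmark nanoshells the correction is 12.7%.
#'
#' @inheritParams silica_volume_fraction
#' @param rho_core,rho_shell bulk densities of core and shell material
#'   (g/cm^3), e.g. 2.65 for silica and 19.32 for gold.
#' @param volume_fraction optional override of the core volume fraction
#'   (e.g. a rounded value); computed from the radii when `NULL`.
#' @return Added-mass fraction (core mass / shell-metal mass).
#' @export
#' @examples
#' core_mass_correction(59.9, 76.4, 2.65, 19.32, volume_fraction = 0.48)
core_mass_correction <- function(r1_nm, r2_nm, rho_core, rho_shell,
                                 volume_fraction = NULL) {
  check_scalar(rho_core, "rho_core", 1e-300)
  check_scalar(rho_shell, "rho_shell", 1e-300)
  f_v <- if (is.null(volume_fraction)) {
    silica_volume_fraction(r1_nm, r2_nm)
  } else {
    check_scalar(volume_fraction, "volume_fraction", 0, 1 - 1e-12)
  }
  if (f_v == 0) return(0)
  f_v * rho_core / ((1 - f_v) * rho_shell)
}

#' Nanoparticle mass in the laser path
#'
#' `m_NPs = C x beam area x path length`, converted to micrograms; beam
#' broadening by scattering is ignored, so this is the mass of suspension
#' volume geometrically illuminated by the beam.
#'
#' @param concentration_mg_per_mL mass concentration (mg/mL, >= 0).
#' @param beam a [beam_geometry()].
#' @param path_cm optical path length (cm, > 0).
#' @return Mass in the beam (micrograms).
#' @export
#' @examples
#' mass_in_beam(0.1 / 46.1, beam_geometry(area_cm2 = 0.081), 1)  # 0.176 ug
mass_in_beam <- function(concentration_mg_per_mL, beam, path_cm) {
  stopifnot(inherits(beam, "beam_geometry"))
  check_scalar(concentration_mg_per_mL, "concentration_mg_per_mL", 0)
  check_scalar(path_cm, "path_cm", 1e-300)
  # mg/mL == mg/cm^3; volume in cm^3; x1000 mg -> ug
  concentration_mg_per_mL * beam$area_cm2 * path_cm * 1000
}
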