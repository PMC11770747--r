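## Voxel Monte Carlo photon transport --------------------------------------

#' Homogeneous tissue slab model
#'
#' Optical model of a homogeneous tissue box illuminated through its front
#' face (z = 0). Defaults describe breast tissue at 808 nm: reduced
#' scattering 11.7 cm^-1 and absorption 0.035 cm^-1, in an
#' 8 x 8 x 5 cm volume. By default scattering is isotropic with
#' `mu_s = mu_s'` (the similarity reduction, adequate for fluence beyond a
#' transport mean free path); set `anisotropy_g > 0` to use
#' Henyey-Greenstein scattering with `mu_s = mu_s'/(1 - g)`.
#'
#' Two voxel sizes are carried: `voxel_size_cm` is the fine voxel used for
#' the heating model's mass bookkeeping (default 0.0195 cm, the side of a
#' cube of 7.47 micrograms of tissue at density 1 g/cm^3), while
#' `scoring_voxel_cm` (default 0.1 cm) is the coarser grid on which fluence
#' is tallied for variance control; values on the fine grid are obtained by
#' interpolation.
#'
#' @param dims_cm box dimensions (x, y, z) in cm.
#' @param voxel_size_cm fine voxel edge for heating-model coupling (cm).
#' @param scoring_voxel_cm edge of the fluence scoring voxels (cm).
#' @param mu_a_per_cm absorption coefficient (cm^-1).
#' @param mu_s_prime_per_cm reduced scattering coefficient (cm^-1).
#' @param anisotropy_g scattering anisotropy in \[-1, 1\]; 0 selects
#'   isotropic scattering at `mu_s'`.
#' @param refractive_index tissue refractive index relative to the
#'   surroundings; 1 (default) means index-matched boundaries, other values
#'   enable unpolarized Fresnel reflection at all faces.
#' @return An object of class `tissue_model`.
#' @export
tissue_model <- function(dims_cm = c(8, 8, 5),
                         voxel_size_cm = 0.0195,
                         scoring_voxel_cm = 0.1,
                         mu_a_per_cm = 0.035,
                         mu_s_prime_per_cm = 11.7,
                         anisotropy_g = 0,
                         refractive_index = 1) {
  if (length(dims_cm) != 3L || any(!is.finite(dims_cm)) ||
      any(dims_cm <= 0)) {
    stop_invalid("dims_cm must be three positive lengths")
  }
  check_scalar(voxel_size_cm, "voxel_size_cm", 1e-6)
  check_scalar(scoring_voxel_cm, "scoring_voxel_cm", 1e-6)
  check_scalar(mu_a_per_cm, "mu_a_per_cm", 0)
  check_scalar(mu_s_prime_per_cm, "mu_s_prime_per_cm", 0)
  check_scalar(anisotropy_g, "anisotropy_g", -1, 1)
  check_scalar(refractive_index, "refractive_index", 1e-6)
  if (mu_a_per_cm + mu_s_prime_per_cm <= 0) {
    stop_invalid("mu_a + mu_s' must be positive")
  }
  structure(
    list(dims_cm = as.numeric(dims_cm),
         voxel_size_cm = voxel_size_cm,
         scoring_voxel_cm = scoring_voxel_cm,
         mu_a_per_cm = mu_a_per_cm,
         mu_s_prime_per_cm = mu_s_prime_per_cm,
         anisotropy_g = anisotropy_g,
         refractive_index = refractive_index),
    class = "tissue_model")
}

#' Collimated laser beam model
#'
#' A beam normal to the front face of the tissue box, centred on the axis.
#' The default is a flat-top disc of 10 mm diameter; `profile = "gaussian"`
#' launches from a Gaussian with FWHM equal to `diameter_cm`, truncated at
#' twice the FWHM.
#'
#' @param diameter_cm beam diameter (cm).
#' @param profile `"flat"` or `"gaussian"`.
#' @param power_W beam power (W).
#' @return An object of class `beam_model`.
#' @export
beam_model <- function(diameter_cm = 1.0,
                       profile = c("flat", "gaussian"),
                       power_W = 1) {
  check_scalar(diameter_cm, "diameter_cm", 1e-6)
  check_scalar(power_W, "power_W", 0)
  profile <- match.arg(profile)
  structure(
    list(diameter_cm = diameter_cm, profile = profile, power_W = power_W,
         area_cm2 = pi * (diameter_cm / 2)^2),
    class = "beam_model")
}

#' Run the voxel Monte Carlo simulation
#'
#' Launches `n_packets` weighted photon packets across the beam profile and
#' propagates them through the tissue box: free paths are sampled as
#' `-ln(U)/mu_t`, fluence is tallied per scoring voxel by the track-length
#' estimator, absorption attenuates the packet weight (implicit capture),
#' scattering follows the model's phase function, and packets below weight
#' 1e-4 undergo Russian roulette (survival probability 0.1). The map is
#' normalized so that the mean fluence in the first voxel layer inside the
#' illuminated disc is 1 ("dose delivered to the tissue surface"); the
#' near-surface build-up can therefore exceed 1.
#'
#' Weight is conserved exactly: launched weight equals absorbed plus escaped
#' plus the net Russian-roulette balance, all recorded in the result.
#'
#' @param model a [tissue_model()].
#' @param beam a [beam_model()].
#' @param n_packets number of photon packets (>= 1e4).
#' @param seed integer seed; the run is bit-reproducible given the seed.
#' @return An object of class `fluence_map`: `values` (3D array of relative
#'   photon density, x by y by z), `axes_cm` (voxel-centre coordinates),
#'   `model`, `beam`, `n_packets`, `seed`, `surface_dose_raw`
#'   (normalization constant) and `tallies` (launched/absorbed/escaped/
#'   roulette_net weights).
#' @export
run_mc <- function(model, beam, n_packets = 1e6, seed = 1) {
  stopifnot(inherits(model, "tissue_model"), inherits(beam, "beam_model"))
  check_scalar(n_packets, "n_packets", 1e4)
  check_scalar(seed, "seed")
  n_packets <- as.integer(round(n_packets))
  grid <- round(model$dims_cm / model$scoring_voxel_cm)
  if (any(abs(grid * model$scoring_voxel_cm - model$dims_cm) > 1e-9)) {
    stop_invalid("scoring voxel size must divide the box dimensions")
  }
  g <- model$anisotropy_g
  mu_s <- if (g == 0) model$mu_s_prime_per_cm else
    model$mu_s_prime_per_cm / (1 - g)
  set.seed(seed)
  raw <- .mc_run_cpp(
    n_packets = n_packets,
    lx = model$dims_cm[1], ly = model$dims_cm[2], lz = model$dims_cm[3],
    nx = grid[1], ny = grid[2], nz = grid[3],
    mu_a = model$mu_a_per_cm, mu_s = mu_s, g = g,
    beam_radius = beam$diameter_cm / 2,
    gaussian_profile = as.integer(beam$profile == "gaussian"),
    beam_sigma = beam$diameter_cm / 2.3548200450309493,
    beam_trunc = beam$diameter_cm / 2,
    n_rel = model$refractive_index,
    w_min = 1e-4, p_survive = 0.1)

  h <- model$scoring_voxel_cm
  # track length (cm) per voxel -> fluence per voxel volume, per packet
  flu <- raw$fluence_track_cm / (h^3 * n_packets)
  ax <- (seq_len(grid[1]) - 0.5) * h - model$dims_cm[1] / 2
  ay <- (seq_len(grid[2]) - 0.5) * h - model$dims_cm[2] / 2
  az <- (seq_len(grid[3]) - 0.5) * h

  # surface dose unit: mean fluence in the first layer inside the beam disc
  rr <- outer(ax^2, ay^2, "+")
  disc <- rr <= (beam$diameter_cm / 2)^2
  surface_dose <- mean(flu[, , 1][disc])
  if (!is.finite(surface_dose) || surface_dose <= 0) {
    stop_invalid("no fluence recorded in the illuminated surface layer")
  }
  structure(
    list(values = flu / surface_dose,
         axes_cm = list(x = ax, y = ay, z = az),
         model = model, beam = beam,
         n_packets = n_packets, seed = seed,
         surface_dose_raw = surface_dose,
         tallies = list(launched = raw$launched, absorbed = raw$absorbed,
                        escaped = raw$escaped,
                        roulette_net = raw$roulette_net)),
    class = "fluence_map")
}

#' @export
print.fluence_map <- function(x, ...) {
  cat(sprintf(
    "<fluence_map> %s grid, %g packets (seed %g)\n",
    paste(dim(x$values), collapse = " x "), x$n_packets, x$seed))
  res <- conservation_residual(x)
  cat(sprintf("  weight conservation residual: %.2e\n", res))
  invisible(x)
}

#' Weight-conservation residual of a Monte Carlo run
#'
#' Relative difference between the launched packet weight and the sum of
#' absorbed, escaped and net-roulette weight. Should be at floating-point
#' level for any run.
#'
#' @param map a [run_mc()] result.
#' @return Relative residual (non-negative scalar).
#' @export
conservation_residual <- function(map) {
  stopifnot(inherits(map, "fluence_map"))
  t <- map$tallies
  abs(t$launched - (t$absorbed + t$escaped + t$roulette_net)) / t$launched
}

#' Extract a depth profile of relative photon density
#'
#' Averages the fluence map over a thin cylindrical shell at a given lateral
#' distance from the beam axis, for every depth layer. `lateral_offset_mm =
#' 0` averages a disc of radius `half_width_mm` around the axis. The
#' offsets 0, 4.8, 5.9 and 11 mm are the standard presets for profiles at
#' the beam centre, inside the beam edge, just outside it, and well outside.
#'
#' @param map a [run_mc()] result.
#' @param lateral_offset_mm lateral distance from the beam axis (mm).
#' @param half_width_mm half-width of the radial averaging band (mm).
#' @param normalize `"surface"` keeps the map's surface-dose normalization;
#'   `"peak"` rescales so the profile maximum is 1.
#' @return Data frame with columns `depth_mm`, `offset_mm`,
#'   `relative_density`.
#' @export
depth_profile <- function(map, lateral_offset_mm = 0, half_width_mm = 0.75,
                          normalize = c("surface", "peak")) {
  stopifnot(inherits(map, "fluence_map"))
  normalize <- match.arg(normalize)
  check_scalar(lateral_offset_mm, "lateral_offset_mm", 0)
  r0 <- lateral_offset_mm / 10  # cm
  max_r <- min(map$model$dims_cm[1], map$model$dims_cm[2]) / 2
  if (r0 > max_r) {
    stop_invalid("lateral offset %g mm is outside the grid (max %g mm)",
                 lateral_offset_mm, max_r * 10)
  }
  hw <- half_width_mm / 10
  r <- sqrt(outer(map$axes_cm$x^2, map$axes_cm$y^2, "+"))
  sel <- r >= max(0, r0 - hw) & r <= r0 + hw
  if (!any(sel)) stop_invalid("no voxels in the averaging band")
  dens <- apply(map$values, 3, function(layer) mean(layer[sel]))
  if (normalize == "peak") dens <- dens / max(dens)
  data.frame(depth_mm = map$axes_cm$z * 10,
             offset_mm = lateral_offset_mm,
             relative_density = dens)
}

## on-axis relative density at an arbitrary depth, interpolated between
## scoring layers (surface-dose normalization)
on_axis_density <- function(map, depth_mm) {
  prof <- depth_profile(map, 0)
  vapply(depth_mm, function(d) {
    if (d < 0 || d > max(prof$depth_mm) + 5) {
      stop_invalid("depth %g mm outside the simulated volume", d)
    }
    if (d > max(prof$depth_mm)) return(0)
    approx(prof$depth_mm, prof$relative_density, xout = d, rule = 2)$y
  }, numeric(1))
}

#' Beam power arriving at depth
#'
#' Scales a surface power density to the total beam power that reaches a
#' given depth on the optical axis:
#' `P(z) = surface_power_density x beam area x relative density(z)`, with
#' relative density taken from the map's on-axis profile (surface-dose
#' normalization, so `P(0)` equals the delivered power). Linear in the
#' surface power density.
#'
#' @param map a [run_mc()] result.
#' @param surface_power_density_W_per_cm2 power density applied at the
#'   tissue surface (W/cm^2).
#' @param depth_mm depth below the surface (mm); vectorized.
#' @return Power (W) at each depth.
#' @export
power_at_depth <- function(map, surface_power_density_W_per_cm2, depth_mm) {
  stopifnot(inherits(map, "fluence_map"))
  check_scalar(surface_power_density_W_per_cm2,
               "surface_power_density_W_per_cm2", 0)
  surface_power_density_W_per_cm2 * map$beam$area_cm2 *
    on_axis_density(map, depth_mm)
}

## Fluence map serialization: CSV of voxel values + JSON metadata ----------

#' Write / read a fluence map as CSV plus JSON metadata
#'
#' The CSV holds one row per voxel (`ix,iy,iz,relative_density`, 1-based
#' indices, zero-valued voxels omitted); the metadata JSON
#' (`<path>.json`) records grid dimensions, voxel size, optical
#' coefficients, beam, packet count, seed, normalization constant and the
#' conservation tallies.
#'
#' @param map a [run_mc()] result.
#' @param path CSV file path.
#' @return `write_fluence_map()` returns `path` invisibly;
#'   `read_fluence_map()` returns a `fluence_map`.
#' @export
write_fluence_map <- function(map, path) {
  stopifnot(inherits(map, "fluence_map"))
  nz <- which(map$values != 0, arr.ind = TRUE)
  df <- data.frame(ix = nz[, 1], iy = nz[, 2], iz = nz[, 3],
                   relative_density = map$values[nz])
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- list(
    dim = dim(map$values),
    dims_cm = map$model$dims_cm,
    scoring_voxel_cm = map$model$scoring_voxel_cm,
    voxel_size_cm = map$model$voxel_size_cm,
    mu_a_per_cm = map$model$mu_a_per_cm,
    mu_s_prime_per_cm = map$model$mu_s_prime_per_cm,
    anisotropy_g = map$model$anisotropy_g,
    refractive_index = map$model$refractive_index,
    beam = map$beam[c("diameter_cm", "profile", "power_W")],
    n_packets = map$n_packets, seed = map$seed,
    surface_dose_raw = map$surface_dose_raw,
    tallies = map$tallies,
    normalization = "mean fluence of first voxel layer inside beam disc = 1")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_fluence_map
#' @export
read_fluence_map <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(path) || !file.exists(sidecar)) {
    stop_invalid("fluence map '%s' (+ .json sidecar) not found", path)
  }
  df <- read.csv(path)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  vals <- array(0, dim = meta$dim)
  vals[cbind(df$ix, df$iy, df$iz)] <- df$relative_density
  model <- tissue_model(
    dims_cm = meta$dims_cm, voxel_size_cm = meta$voxel_size_cm,
    scoring_voxel_cm = meta$scoring_voxel_cm,
    mu_a_per_cm = meta$mu_a_per_cm,
    mu_s_prime_per_cm = meta$mu_s_prime_per_cm,
    anisotropy_g = meta$anisotropy_g,
    refractive_index = meta$refractive_index)
  beam <- beam_model(diameter_cm = meta$beam$diameter_cm,
                     profile = meta$beam$profile,
                     power_W = meta$beam$power_W)
  h <- meta$scoring_voxel_cm
  structure(
    list(values = vals,
         axes_cm = list(
           x = (seq_len(meta$dim[1]) - 0.5) * h - meta$dims_cm[1] / 2,
           y = (seq_len(meta$dim[2]) - 0.5) * h - meta$dims_cm[2] / 2,
           z = (seq_len(meta$dim[3]) - 0.5) * h),
         model = model, beam = beam,
         n_packets = meta$n_packets, seed = meta$seed,
         surface_dose_raw = meta$surface_dose_raw,
         tallies = as.list(meta$tallies)),
    class = "fluence_map")
}
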