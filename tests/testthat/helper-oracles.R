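# Shared fixtures and independent oracles for the estimator tests.

# AuNR-like fixture configuration (1 W, extinction 0.1, 2 g of water)
default_cfg <- function(...) {
  args <- utils::modifyList(
    list(eta_true = 0.66, extinction = 0.1, laser_power_W = 1,
         sample_mass_g = 2, heat_capacity_J_per_gK = 4.182,
         tau_s = 600, q_blank_W = 0, t_ambient_C = 25),
    list(...))
  do.call(trace_gen_config, args)
}

# independent oracle: integrate the lumped energy balance numerically
ode_trace_oracle <- function(cfg) {
  gain <- cfg$laser_power_W * cfg$eta_true * (1 - 10^(-cfg$extinction)) +
    cfg$q_blank_W
  mC <- cfg$sample_mass_g * cfg$heat_capacity_J_per_gK
  rhs <- function(t, y, p) {
    on <- as.numeric(t <= cfg$heat_duration_s)
    list(gain * on / mC - (y - cfg$t_ambient_C) / cfg$tau_s)
  }
  times <- seq(0, cfg$heat_duration_s + cfg$cool_duration_s,
               by = cfg$sample_interval_s)
  out <- deSolve::lsoda(c(T = cfg$t_ambient_C), times, rhs, NULL,
                        rtol = 1e-10, atol = 1e-10)
  list(times = out[, 1], temp = out[, 2])
}

# independent oracle: nonlinear exponential fit of the cooling segment
nls_tau_oracle <- function(trace) {
  idx <- trace$times_s >= trace$laser_off_time_s
  t <- trace$times_s[idx] - trace$laser_off_time_s
  y <- trace$temperatures_C[idx] - trace$t_ambient_C
  fit <- stats::nls(y ~ A * exp(-t / tau),
                    start = list(A = max(y), tau = 500),
                    control = stats::nls.control(warnOnly = TRUE))
  unname(coef(fit)["tau"])
}

# memoised Monte Carlo map at the breast-tissue benchmark configuration
benchmark_map_env <- new.env(parent = emptyenv())
get_benchmark_map <- function(n_packets = 1e6) {
  key <- paste0("map_", n_packets)
  if (is.null(benchmark_map_env[[key]])) {
    benchmark_map_env[[key]] <- run_mc(tissue_model(), beam_model(),
                                   n_packets = n_packets, seed = 808)
  }
  benchmark_map_env[[key]]
}

# small synthetic fluence map with a known exponential on-axis profile,
# for deterministic heating-model tests
synthetic_fluence_map <- function(mu = 2, nz = 40) {
  model <- tissue_model(dims_cm = c(2, 2, 4), scoring_voxel_cm = 0.1)
  beam <- beam_model()
  z <- (seq_len(nz) - 0.5) * 0.1
  vals <- array(rep(exp(-mu * z), each = 20 * 20), dim = c(20, 20, nz))
  structure(
    list(values = vals,
         axes_cm = list(x = (1:20 - 0.5) * 0.1 - 1,
                        y = (1:20 - 0.5) * 0.1 - 1, z = z),
         model = model, beam = beam, n_packets = 1e4, seed = 0,
         surface_dose_raw = 1,
         tallies = list(launched = 1e4, absorbed = 5e3, escaped = 5e3,
                        roulette_net = 0)),
    class = "fluence_map")
}
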