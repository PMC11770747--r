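# Synthetic thermal-trace generator: closed form vs numerical integration,
# model residuals, reproducibility, serialization.

test_that("heating plateau matches the closed form and an ODE integration", {
  cfg <- default_cfg(noise_sd_C = 0)
  tr <- simulate_trace(cfg)
  # closed form: dT_eq = tau * I * eta * (1 - 10^-eps) / (m C) = 9.7376 C
  expect_equal(max(tr$temperatures_C) - cfg$t_ambient_C, 9.7376,
               tolerance = 1e-4)
  ode <- ode_trace_oracle(cfg)
  expect_lt(max(abs(tr$temperatures_C - ode$temp)), 1e-5)
})

test_that("degenerate inputs give flat or relaxing traces", {
  flat <- simulate_trace(default_cfg(eta_true = 0, q_blank_W = 0))
  expect_true(all(abs(flat$temperatures_C - flat$t_ambient_C) < 1e-12))
  # after >= 10 tau of cooling the trace is back at ambient
  tr <- simulate_trace(default_cfg(cool_duration_s = 6000))
  expect_lt(abs(tr$temperatures_C[length(tr$temperatures_C)] -
                  tr$t_ambient_C), 1e-3)
})

test_that("blank traces are driven by the baseline rate alone", {
  cfg <- default_cfg(q_blank_W = 0.01)
  bl <- simulate_blank_trace(cfg)
  # tau * Q_blank / (m C) = 600 * 0.01 / 8.364 = 0.7174 C
  expect_equal(max(bl$temperatures_C) - cfg$t_ambient_C, 0.71736,
               tolerance = 1e-4)
  ode <- ode_trace_oracle(trace_gen_config(
    eta_true = 0, q_blank_W = 0.01, t_ambient_C = 25))
  bl2 <- simulate_blank_trace(default_cfg(q_blank_W = 0.02))
  expect_equal(max(bl2$temperatures_C) - 25,
               2 * (max(bl$temperatures_C) - 25), tolerance = 1e-9)
  flat <- simulate_blank_trace(default_cfg(q_blank_W = 0))
  expect_true(all(abs(flat$temperatures_C - 25) < 1e-12))
})

test_that("noise-free traces satisfy the generating ODE pointwise", {
  for (tau in c(300, 600)) {
    for (eta in c(0.2, 0.66)) {
      cfg <- default_cfg(eta_true = eta, tau_s = tau,
                         heat_duration_s = 1200, cool_duration_s = 1200)
      tr <- simulate_trace(cfg)
      gain <- cfg$laser_power_W * eta * (1 - 10^(-cfg$extinction)) /
        (cfg$sample_mass_g * cfg$heat_capacity_J_per_gK)
      t <- tr$times_s
      temp <- tr$temperatures_C
      n <- length(t)
      mid <- 2:(n - 1)
      dTdt <- (temp[mid + 1] - temp[mid - 1]) /
        (t[mid + 1] - t[mid - 1])
      on <- as.numeric(t[mid] < cfg$heat_duration_s)
      resid <- dTdt - (gain * on - (temp[mid] - cfg$t_ambient_C) / tau)
      # exclude the two samples straddling laser-off (derivative jump)
      ok <- abs(t[mid] - cfg$heat_duration_s) > 1.5
      expect_lt(max(abs(resid[ok])), 1e-6)
    }
  }
})

test_that("seeded noisy generation is bit-reproducible", {
  cfg1 <- default_cfg(noise_sd_C = 0.05, seed = 42)
  expect_identical(simulate_trace(cfg1)$temperatures_C,
                   simulate_trace(cfg1)$temperatures_C)
  cfg2 <- default_cfg(noise_sd_C = 0.05, seed = 43)
  expect_false(identical(simulate_trace(cfg1)$temperatures_C,
                         simulate_trace(cfg2)$temperatures_C))
})

test_that("sample minus blank plateau equals the nanoparticle term", {
  # 20 tau of heating so both traces are at equilibrium to ~1e-9
  cfg <- default_cfg(q_blank_W = 0.015, heat_duration_s = 12000)
  tr <- simulate_trace(cfg)
  bl <- simulate_blank_trace(cfg)
  np_term <- cfg$tau_s * cfg$laser_power_W * cfg$eta_true *
    (1 - 10^(-cfg$extinction)) /
    (cfg$sample_mass_g * cfg$heat_capacity_J_per_gK)
  expect_equal(max(tr$temperatures_C) - max(bl$temperatures_C), np_term,
               tolerance = 1e-6)
})

test_that("trace CSV + sidecar round-trips exactly", {
  tr <- simulate_trace(default_cfg(noise_sd_C = 0.03, seed = 7,
                                   heat_duration_s = 300,
                                   cool_duration_s = 300))
  path <- file.path(tempdir(), "trace_roundtrip.csv")
  write_thermal_trace(tr, path)
  back <- read_thermal_trace(path)
  expect_equal(back$temperatures_C, tr$temperatures_C, tolerance = 1e-12)
  expect_equal(back$laser_off_time_s, tr$laser_off_time_s)
  expect_equal(back$sample_mass_g, tr$sample_mass_g)
})

test_that("invalid generator configurations are rejected", {
  expect_error(trace_gen_config(eta_true = 1.2), "eta_true")
  expect_error(trace_gen_config(tau_s = 0), "tau_s")
  expect_error(trace_gen_config(noise_sd_C = -1), "noise_sd_C")
  expect_error(trace_gen_config(extinction = -0.1), "extinction")
  expect_error(preset_suspension("AuCube"), "unknown")
})
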