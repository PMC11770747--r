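# Efficiency estimators: time-constant fit, equilibrium energy balance,
# short-time mass estimator, cross-method consistency, ranking.

test_that("time constant is recovered exactly from a noiseless trace", {
  tr <- simulate_trace(default_cfg())
  fit <- fit_time_constant(tr)
  expect_equal(fit$tau_s, 600, tolerance = 1e-9)
  expect_gt(fit$r_squared, 1 - 1e-12)
  # theta at one time constant after laser-off is 1/e
  off <- tr$laser_off_time_s
  t_off <- tr$temperatures_C[tr$times_s == off]
  t_tau <- tr$temperatures_C[tr$times_s == off + 600]
  theta <- (t_tau - tr$t_ambient_C) / (t_off - tr$t_ambient_C)
  expect_equal(theta, exp(-1), tolerance = 1e-9)
})

test_that("noisy time constants agree with a nonlinear-fit oracle", {
  errs <- c()
  oracle_gap <- c()
  for (seed in 1:30) {
    tr <- simulate_trace(default_cfg(noise_sd_C = 0.05, seed = seed,
                                     heat_duration_s = 3000,
                                     cool_duration_s = 1200))
    tau_lin <- fit_time_constant(tr)$tau_s
    tau_nls <- nls_tau_oracle(tr)
    errs <- c(errs, abs(tau_lin - 600) / 600)
    oracle_gap <- c(oracle_gap, abs(tau_lin - tau_nls) / tau_nls)
  }
  expect_lt(median(errs), 0.02)
  expect_lt(median(oracle_gap), 0.02)
})

test_that("eta round-trips through noiseless synthetic traces", {
  for (eta in c(0.66, 0.20)) {
    cfg <- default_cfg(eta_true = eta)
    est <- estimate_eta(simulate_trace(cfg), simulate_blank_trace(cfg),
                        cfg$laser_power_W, cfg$extinction)
    expect_equal(est$eta, eta, tolerance = 1e-3)
    expect_true(est$equilibrated)
  }
  # with a non-zero blank baseline the subtraction still recovers eta
  cfg <- default_cfg(eta_true = 0.34, q_blank_W = 0.02)
  est <- estimate_eta(simulate_trace(cfg), simulate_blank_trace(cfg),
                      1, 0.1)
  expect_equal(est$eta, 0.34, tolerance = 2e-3)
  # sample identical to blank -> zero efficiency
  bl <- simulate_blank_trace(default_cfg(q_blank_W = 0.02))
  est0 <- estimate_eta(bl, bl, 1, 0.1)
  expect_equal(est0$eta, 0, tolerance = 1e-6)
})

test_that("eta recovery holds across the tau grid, noiseless and noisy", {
  for (eta in c(0.2, 0.34, 0.66)) {
    for (tau in c(300, 600, 1200)) {
      cfg <- default_cfg(eta_true = eta, tau_s = tau,
                         heat_duration_s = 10 * tau,
                         cool_duration_s = 6 * tau)
      est <- estimate_eta(simulate_trace(cfg), NULL, 1, 0.1)
      expect_equal(est$eta, eta, tolerance = 0.02 * eta)
    }
  }
  for (eta in c(0.2, 0.66)) {
    errs <- vapply(1:15, function(seed) {
      cfg <- default_cfg(eta_true = eta, noise_sd_C = 0.05, seed = seed)
      est <- estimate_eta(simulate_trace(cfg), NULL, 1, 0.1)
      abs(est$eta - eta) / eta
    }, numeric(1))
    expect_lt(median(errs), 0.05)
  }
})

test_that("eta estimates are invariant to ambient temperature offsets", {
  cfg_a <- default_cfg(t_ambient_C = 25)
  cfg_b <- default_cfg(t_ambient_C = 32)
  est_a <- estimate_eta(simulate_trace(cfg_a), NULL, 1, 0.1)
  est_b <- estimate_eta(simulate_trace(cfg_b), NULL, 1, 0.1)
  expect_equal(est_a$eta, est_b$eta, tolerance = 1e-12)
})

test_that("a non-equilibrated trace is flagged", {
  cfg <- default_cfg(heat_duration_s = 1200)  # 2 tau: 14% short of plateau
  expect_warning(
    est <- estimate_eta(simulate_trace(cfg), NULL, 1, 0.1),
    "not equilibrated")
  expect_false(est$equilibrated)
})

test_that("eta_m matches the closed form in the lossless limit", {
  # tau -> infinity: short-time slope is exact, no correction needed
  cfg <- default_cfg(tau_s = 1e9, heat_duration_s = 300,
                     cool_duration_s = 60)
  susp <- preset_suspension("AuNR")
  m_np <- mass_in_beam(susp$mass_concentration_mg_per_mL,
                       beam_geometry(), susp$path_length_cm)
  est <- estimate_eta_m(simulate_trace(cfg), NULL, 1, m_np,
                        correct_losses = FALSE)
  expect_equal(est$eta_m_per_ug, 0.66 * (1 - 10^(-0.1)) / m_np,
               tolerance = 1e-6)
  expect_equal(est$eta_m_per_ug, 0.7725, tolerance = 1e-3)
})

test_that("eta_m scales inversely with mass in beam and vanishes for blanks", {
  cfg <- default_cfg()
  tr <- simulate_trace(cfg)
  e1 <- estimate_eta_m(tr, NULL, 1, 0.176)
  e2 <- estimate_eta_m(tr, NULL, 1, 0.088)
  expect_equal(e2$eta_m_per_ug, 2 * e1$eta_m_per_ug, tolerance = 1e-12)
  bl <- simulate_blank_trace(cfg)
  expect_equal(estimate_eta_m(bl, bl, 1, 0.176,
                              correct_losses = FALSE)$eta_m_per_ug, 0,
               tolerance = 1e-12)
})

test_that("the two efficiency routes agree on the same traces", {
  # Eq. of state: eta = eta_m * m_NPs / (1 - 10^-eps); inversion identity
  expect_equal(eta_from_eta_m(0.771, 0.176, 0.1), 0.6598, tolerance = 1e-3)
  expect_identical(eta_from_eta_m(0, 0.176, 0.1), 0)
  # cross-method consistency at finite tau = 600 s
  for (eta in c(0.2, 0.66)) {
    cfg <- default_cfg(eta_true = eta)
    tr <- simulate_trace(cfg)
    bl <- simulate_blank_trace(cfg)
    susp <- preset_suspension("AuNR")
    m_np <- mass_in_beam(susp$mass_concentration_mg_per_mL,
                         beam_geometry(), 1)
    eta_eq <- estimate_eta(tr, bl, 1, 0.1)$eta
    em <- estimate_eta_m(tr, bl, 1, m_np)
    eta_slope <- eta_from_eta_m(em$eta_m_per_ug, m_np, 0.1)
    expect_equal(eta_slope, eta_eq, tolerance = 0.03 * eta_eq)
    # the uncorrected short-time estimator carries the known ~5% bias
    em0 <- estimate_eta_m(tr, bl, 1, m_np, correct_losses = FALSE)
    expect_lt(em0$eta_m_per_ug, em$eta_m_per_ug)
  }
})

test_that("benchmark ranking reproduces the pairwise reductions", {
  df <- data.frame(name = c("AuNR", "AuNStar"), eta = c(0.66, 0.34),
                   eta_m_per_ug = c(0.7725, 0.2132))
  rk <- benchmark_ranking(df)
  expect_equal(rk$ranking$name[1], "AuNR")
  expect_equal(rk$eta_reduction_pct["AuNStar", "AuNR"], 48.5,
               tolerance = 1e-2)
  expect_equal(rk$eta_m_reduction_pct["AuNStar", "AuNR"], 72.4,
               tolerance = 0.1)
  same <- data.frame(name = c("a", "b"), eta = c(0.5, 0.5),
                     eta_m_per_ug = c(1, 1))
  expect_true(all(benchmark_ranking(same)$eta_reduction_pct == 0))
})

test_that("estimator preconditions are enforced", {
  tr <- simulate_trace(default_cfg())
  expect_error(estimate_eta(tr, NULL, 1, 0), "positive")
  expect_error(estimate_eta_m(tr, NULL, 1, 0), "positive")
  expect_error(estimate_eta_m(tr, NULL, 1, 0.1, window_s = 1e6),
               "exceeds the heating phase")
  expect_error(eta_from_eta_m(0.7, 0.17, 0), "positive")
  short <- thermal_trace(0:20, rep(25, 21), 10, 25, 2, 4.182)
  expect_error(fit_time_constant(short), "above ambient")
})
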