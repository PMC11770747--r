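## Photothermal efficiency estimators ----------------------------------------
##
## Energy balance at equilibrium (laser on, stirred cuvette):
##   I eta (1 - 10^-eps) + Q_blank = m C (T_max - T_amb) / tau
## with tau the Newton-cooling time constant fitted from the laser-off
## segment. The mass-normalized efficiency eta_m (per microgram of
## nanoparticle in the beam path) follows from the short-time energy balance
## over the first heating window, where heat exchange with the surroundings
## is still negligible.

cooling_segment <- function(trace) {
  idx <- trace$times_s >= trace$laser_off_time_s
  list(t = trace$times_s[idx] - trace$laser_off_time_s,
       temp = trace$temperatures_C[idx])
}

heating_segment <- function(trace) {
  idx <- trace$times_s <= trace$laser_off_time_s
  list(t = trace$times_s[idx], temp = trace$temperatures_C[idx])
}

#' Fit the Newton-cooling time constant
#'
#' Linearizes the cooling law `T(t) = T_amb + (T_max - T_amb) exp(-t/tau)`
#' as `t = tau (-ln theta)` with `theta = (T - T_amb)/(T_max - T_amb)` and
#' estimates `tau` as the least-squares slope of time-since-laser-off
#' against `-ln theta` over the cooling segment. Points at or below ambient,
#' points within `floor_C` of ambient, and points below `theta_min` are
#' excluded: near ambient the logarithm amplifies measurement noise and,
#' worse, the positivity requirement selectively retains upward noise
#' excursions, which biases the fitted slope. Restricting the fit to the
#' upper part of the decay keeps that bias well below the fit's random
#' error while leaving the noiseless fit exact.
#'
#' @param trace a [thermal_trace()] containing a cooling phase.
#' @param floor_C exclusion band above ambient (degrees C); cooling samples
#'   closer to ambient than this are dropped from the fit.
#' @param theta_min smallest normalized excess temperature included in the
#'   fit (the default 0.2 uses the first ~1.6 time constants of cooling).
#' @return A list of class `tau_fit`: `tau_s`, `r_squared` of the linearized
#'   fit, `n_points` used, and `t_max_C` (temperature at laser-off).
#' @export
#' @examples
#' tr <- simulate_trace(trace_gen_config(tau_s = 600))
#' fit_time_constant(tr)$tau_s
fit_time_constant <- function(trace, floor_C = 0.02, theta_min = 0.2) {
  stopifnot(inherits(trace, "thermal_trace"))
  seg <- cooling_segment(trace)
  t_max <- seg$temp[1L]
  d_max <- t_max - trace$t_ambient_C
  if (!is.finite(d_max) || d_max <= 0) {
    stop_invalid("cooling segment does not start above ambient")
  }
  theta <- (seg$temp - trace$t_ambient_C) / d_max
  keep <- theta > theta_min & (seg$temp - trace$t_ambient_C) > floor_C
  keep[1L] <- TRUE  # theta = 1 anchor
  if (sum(keep) < 10L) {
    stop_invalid("need >= 10 usable cooling samples above ambient (got %d)",
                 sum(keep))
  }
  neg_log_theta <- -log(theta[keep])
  fit <- lm(seg$t[keep] ~ neg_log_theta)
  # R^2 computed directly: summary.lm() warns on noiseless fixtures
  r2 <- 1 - sum(fit$residuals^2) /
    sum((seg$t[keep] - mean(seg$t[keep]))^2)
  structure(
    list(tau_s = unname(coef(fit)[2L]),
         r_squared = r2,
         n_points = sum(keep),
         t_max_C = t_max),
    class = "tau_fit")
}

## plateau slope over the final `window_s` of the heating phase (C/s)
plateau_slope <- function(trace, window_s = 300) {
  seg <- heating_segment(trace)
  idx <- seg$t >= (max(seg$t) - window_s)
  if (sum(idx) < 3L) return(NA_real_)
  unname(coef(lm(seg$temp[idx] ~ seg$t[idx]))[2L])
}

## plateau (equilibrium) temperature: mean over the final window of heating,
## which is unbiased once equilibrated and averages measurement noise down
plateau_temperature <- function(trace, window_s = 300) {
  seg <- heating_segment(trace)
  idx <- seg$t >= (max(seg$t) - window_s)
  mean(seg$temp[idx])
}

#' Estimate photothermal conversion efficiency from equilibrium traces
#'
#' Applies the equilibrium energy balance: at the heating plateau the laser
#' power converted to heat equals the power lost to the surroundings, so
#' `eta = (m C (T_max - T_amb)/tau - Q_blank) / (I (1 - 10^-eps))`. `tau` is
#' fitted from the sample trace's cooling segment and the baseline rate
#' `Q_blank = m C (T_max,blank - T_amb)/tau_blank` from the blank
#' (water-only) trace. The plateau temperature is read as the mean over the
#' final 300 s of heating (unbiased at equilibrium, and it averages
#' measurement noise down). The trace must have reached equilibrium, judged
#' by the plateau slope over that window being below
#' `equilibrium_slope_C_per_s`; otherwise a warning is issued and the result
#' flagged.
#'
#' @param trace sample [thermal_trace()].
#' @param blank blank [thermal_trace()] (water-only cuvette); may be `NULL`
#'   for an ideal zero-baseline experiment.
#' @param laser_power_W laser power after the blank cuvette (W).
#' @param extinction decadic extinction of the suspension at the laser
#'   wavelength (> 0).
#' @param equilibrium_slope_C_per_s equilibrium criterion on the plateau
#'   slope (degrees C per second).
#' @return A list of class `eta_estimate`: `eta`, `tau_s`, `q_blank_W`,
#'   `t_max_C`, `r_squared` (of the tau fit), and `equilibrated` flag.
#' @export
estimate_eta <- function(trace, blank, laser_power_W, extinction,
                         equilibrium_slope_C_per_s = 1e-4) {
  stopifnot(inherits(trace, "thermal_trace"))
  check_scalar(laser_power_W, "laser_power_W", 1e-300)
  check_scalar(extinction, "extinction", 0)
  if (extinction == 0) {
    stop_invalid("extinction must be positive: no light is absorbed at 0")
  }
  mC <- trace$sample_mass_g * trace$heat_capacity_J_per_gK
  fit <- fit_time_constant(trace)
  t_max <- plateau_temperature(trace)
  equilibrated <- TRUE
  slope <- plateau_slope(trace)
  if (is.finite(slope) && abs(slope) > equilibrium_slope_C_per_s) {
    warning(sprintf(
      "trace not equilibrated: plateau slope %.3g C/s exceeds %.3g C/s",
      slope, equilibrium_slope_C_per_s), call. = FALSE)
    equilibrated <- FALSE
  }
  q_blank <- 0
  if (!is.null(blank)) {
    stopifnot(inherits(blank, "thermal_trace"))
    blank_rise <- plateau_temperature(blank) - blank$t_ambient_C
    if (blank_rise > 0.05) {  # fit only a resolvable blank rise
      bfit <- fit_time_constant(blank)
      q_blank <- blank$sample_mass_g * blank$heat_capacity_J_per_gK *
        blank_rise / bfit$tau_s
    }
  }
  eta <- (mC * (t_max - trace$t_ambient_C) / fit$tau_s - q_blank) /
    (laser_power_W * (1 - 10^(-extinction)))
  structure(
    list(eta = eta, tau_s = fit$tau_s, q_blank_W = q_blank,
         t_max_C = t_max, r_squared = fit$r_squared,
         equilibrated = equilibrated),
    class = "eta_estimate")
}

## least-squares slope of the first heating window, plus the sample times
## it was computed from (needed for the exact loss correction)
window_slope <- function(trace, window_s) {
  seg <- heating_segment(trace)
  if (max(seg$t) < window_s) {
    stop_invalid("window (%g s) exceeds the heating phase (%g s)",
                 window_s, max(seg$t))
  }
  idx <- seg$t <= window_s
  if (sum(idx) < 3L) {
    stop_invalid("need >= 3 samples inside the %g s window", window_s)
  }
  list(slope = unname(coef(lm(seg$temp[idx] ~ seg$t[idx]))[2L]),
       times = seg$t[idx])
}

## lumped-model bias of the window LS slope: slope of A(1 - exp(-t/tau))
## at the actual sample times, relative to the initial slope A/tau.
## Exact for the noiseless model, so dividing by it removes the finite-tau
## systematic entirely.
ls_slope_bias <- function(times, tau) {
  model <- 1 - exp(-times / tau)
  unname(coef(lm(model ~ times))[2L]) * tau
}

#' Estimate the photothermal mass conversion efficiency
#'
#' Short-time energy balance: over the first `window_s` of laser heating,
#' losses to the surroundings are small and
#' `eta_m = m C (dT - dT_blank) / (I dt m_NPs)` with `dT`, `dT_blank` the
#' temperature rises of sample and blank over the window and `m_NPs` the
#' nanoparticle mass in the beam path (micrograms). Rises are measured as
#' the least-squares slope over the window times the window length.
#'
#' Even a short window carries a finite-`tau` bias: under the lumped model
#' the measured rise is the true short-time rise scaled by a known factor
#' that depends only on `window_s / tau`. When a time constant is available
#' -- passed via `tau_s` or fitted from the trace's cooling segment -- the
#' exact correction is applied (set `correct_losses = FALSE` for the raw
#' short-time estimator). At `window_s = 60` and `tau = 600 s` the
#' correction is about 5%.
#'
#' @param trace sample [thermal_trace()].
#' @param blank blank [thermal_trace()], or `NULL` for zero baseline.
#' @param laser_power_W laser power (W).
#' @param mass_in_beam_ug nanoparticle mass in the beam path in micrograms
#'   (positive); see [mass_in_beam()].
#' @param window_s heating window (s); the trace must cover it.
#' @param tau_s optional lumped time constant (s) for the loss correction;
#'   fitted from the cooling segment when `NULL` and one is present.
#' @param correct_losses apply the finite-`tau` loss correction when a time
#'   constant is available.
#' @return A list of class `eta_m_estimate`: `eta_m_per_ug`,
#'   `mass_in_beam_ug`, `window_s`, `tau_s` used (or `NA`),
#'   `loss_correction` factor applied.
#' @export
estimate_eta_m <- function(trace, blank, laser_power_W, mass_in_beam_ug,
                           window_s = 60, tau_s = NULL,
                           correct_losses = TRUE) {
  stopifnot(inherits(trace, "thermal_trace"))
  check_scalar(laser_power_W, "laser_power_W", 1e-300)
  check_scalar(mass_in_beam_ug, "mass_in_beam_ug", 0)
  check_scalar(window_s, "window_s", 1e-300)
  if (mass_in_beam_ug == 0) {
    stop_invalid("mass_in_beam_ug must be positive")
  }
  mC <- trace$sample_mass_g * trace$heat_capacity_J_per_gK
  ws <- window_slope(trace, window_s)
  slope_blank <- if (is.null(blank)) 0 else window_slope(blank, window_s)$slope
  correction <- 1
  tau_used <- NA_real_
  if (correct_losses) {
    if (is.null(tau_s)) {
      tau_s <- tryCatch(fit_time_constant(trace)$tau_s,
                        error = function(e) NULL)
    }
    if (!is.null(tau_s) && is.finite(tau_s) && tau_s > 0) {
      correction <- 1 / ls_slope_bias(ws$times, tau_s)
      tau_used <- tau_s
    }
  }
  eta_m <- mC * (ws$slope - slope_blank) * correction /
    (laser_power_W * mass_in_beam_ug)
  structure(
    list(eta_m_per_ug = eta_m, mass_in_beam_ug = mass_in_beam_ug,
         window_s = window_s, tau_s = tau_used,
         loss_correction = correction),
    class = "eta_m_estimate")
}

#' Convert a mass conversion efficiency back to a conversion efficiency
#'
#' Inverts the defining relation `eta_m = eta (1 - 10^-eps) / m_NPs`:
#' `eta = eta_m m_NPs / (1 - 10^-eps)`. Used to cross-validate the
#' short-time mass estimator against the equilibrium estimator.
#'
#' @param eta_m_per_ug mass conversion efficiency (per microgram).
#' @param mass_in_beam_ug nanoparticle mass in the beam path (micrograms).
#' @param extinction decadic extinction (> 0).
#' @return Photothermal conversion efficiency (dimensionless).
#' @export
eta_from_eta_m <- function(eta_m_per_ug, mass_in_beam_ug, extinction) {
  check_scalar(eta_m_per_ug, "eta_m_per_ug")
  check_scalar(mass_in_beam_ug, "mass_in_beam_ug", 0)
  check_scalar(extinction, "extinction", 0)
  if (extinction == 0) {
    stop_invalid("extinction must be positive")
  }
  eta_m_per_ug * mass_in_beam_ug / (1 - 10^(-extinction))
}

#' Rank suspensions by mass conversion efficiency
#'
#' Sorts a benchmarking table by `eta_m` (best heater per microgram first)
#' and tabulates all pairwise relative reductions `(1 - x/y) * 100` for both
#' `eta` and `eta_m`.
#'
#' @param results data frame with columns `name`, `eta`, `eta_m_per_ug`
#'   (>= 2 rows).
#' @return A list of class `benchmark_ranking`: `ranking` (the sorted data
#'   frame) and square matrices `eta_reduction_pct`, `eta_m_reduction_pct`
#'   where entry `[i, j]` is the percent reduction of row `i` relative to
#'   row `j`.
#' @export
#' @examples
#' benchmark_ranking(data.frame(
#'   name = c("AuNR", "AuNStar"), eta = c(0.66, 0.34),
#'   eta_m_per_ug = c(0.77, 0.21)))
benchmark_ranking <- function(results) {
  stopifnot(is.data.frame(results),
            all(c("name", "eta", "eta_m_per_ug") %in% names(results)))
  if (nrow(results) < 2L) {
    stop_invalid("need >= 2 suspensions to rank (got %d)", nrow(results))
  }
  ranking <- results[order(-results$eta_m_per_ug), , drop = FALSE]
  rownames(ranking) <- NULL
  red <- function(v) {
    m <- 100 * (1 - outer(v, v, "/"))
    dimnames(m) <- list(ranking$name, ranking$name)
    m
  }
  structure(
    list(ranking = ranking,
         eta_reduction_pct = red(ranking$eta),
         eta_m_reduction_pct = red(ranking$eta_m_per_ug)),
    class = "benchmark_ranking")
}

#' @export
print.benchmark_ranking <- function(x, ...) {
  cat("<benchmark_ranking> sorted by eta_m (best first)\n")
  print(x$ranking)
  invisible(x)
}
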