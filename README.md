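# phototherm

Benchmarking plasmonic nanoparticle photoheaters and projecting their
performance to depth in tissue.

Photothermal therapy heats tumors with near-infrared light absorbed by
gold nanoparticles (nanorods, silica-core nanoshells, nanostars). Two
questions decide whether a given particle and illumination can work: how
much of the extinguished light a suspension converts to heat, and how much
light actually reaches a nanoparticle-loaded tissue voxel at depth.
phototherm answers both with three connected models:

1. **Calorimetric efficiency estimation.** From a heating/cooling thermal
   trace of a stirred cuvette, the package fits the Newton-cooling time
   constant τ from the laser-off segment
   (t = τ·(−ln θ), θ = (T − T_amb)/(T_max − T_amb)) and applies the
   equilibrium energy balance

   η = (m·C·ΔT_max/τ − Q_blank) / (I·(1 − 10^(−ε)))

   to estimate the photothermal conversion efficiency η. The
   mass-normalized efficiency η_m = η·(1 − 10^(−ε))/m_NPs (heat per
   microgram of nanoparticle in the beam path, units µg⁻¹) is estimated
   independently from the short-time heating slope, so the two routes
   cross-validate each other. η_m folds the mass extinction coefficient
   (Beer–Lambert in mass form, ε_m = ε/(C·L)) and η into a single
   figure of merit for ranking nanoheaters per microgram of delivered
   gold.

2. **Voxel Monte Carlo light transport.** Weighted photon packets
   propagate through a homogeneous breast-tissue slab (8×8×5 cm,
   µ_a = 0.035 cm⁻¹, µ_s′ = 11.7 cm⁻¹ at 808 nm) from a collimated 10 mm
   beam, with track-length fluence tallies, implicit capture, Russian
   roulette, and exact weight-conservation bookkeeping. The output is the
   relative photon density per voxel, normalized to the dose delivered at
   the tissue surface.

3. **Idealized voxel heating.** dT/dt = η_m·P(z)·m_NPs/(m·C) for a
   7.47 µg tissue voxel, with P(z) the beam power surviving to depth z,
   giving minimum ramp times from body temperature (37 °C) to the
   hyperthermia threshold (43 °C) over depth × nanoparticle concentration
   × surface power density.

A seeded synthetic-trace generator (`simulate_trace()`,
`simulate_blank_trace()`, `preset_suspension()`) produces data with
exactly the statistical structure the estimators assume, so the whole
pipeline is testable without measured data.

## Worked example

```r
library(phototherm)

# synthetic gold-nanorod experiment: eta 0.66, extinction 0.1, 1 W laser,
# 2 g of suspension, tau 600 s, 0.05 C thermocouple noise
cfg   <- trace_gen_config(eta_true = 0.66, extinction = 0.1, tau_s = 600,
                          noise_sd_C = 0.05, seed = 101)
trace <- simulate_trace(cfg)
blank <- simulate_blank_trace(cfg)

est  <- estimate_eta(trace, blank, laser_power_W = 1, extinction = 0.1)
rod  <- preset_suspension("AuNR")
m_np <- mass_in_beam(rod$mass_concentration_mg_per_mL, beam_geometry(), 1)
em   <- estimate_eta_m(trace, blank, 1, m_np)
sprintf("tau = %.1f s, eta = %.3f, eta_m = %.3f /ug", est$tau_s, est$eta,
        em$eta_m_per_ug)
#> [1] "tau = 599.6 s, eta = 0.660, eta_m = 0.773 /ug"
```

The estimators recover the generating values: τ within 0.1%, η to three
decimals, and η_m consistent with the closed form
0.66·(1 − 10^(−0.1))/0.176 µg = 0.772 µg⁻¹.

```r
# light penetration and ramp times at 0.01 mg of nanorods per g of tissue
map <- run_mc(tissue_model(), beam_model(), n_packets = 5e5, seed = 808)
tab <- ramp_time_table(map, em$eta_m_per_ug,
                       concentrations_mg_per_g = 0.01,
                       power_densities_W_per_cm2 = c(1, 3, 5),
                       depths_mm = c(0, 10, 20, 30))
tab[tab$power_W_per_cm2 == 1,
    c("depth_mm", "heating_rate_K_per_s", "ramp_time_s")]
#>   depth_mm heating_rate_K_per_s ramp_time_s
#> 1        0              1.72387       3.481
#> 2       10              0.18710      32.069
#> 3       20              0.02577     232.840
#> 4       30              0.00535    1120.967
```

At 1 W/cm² a surface voxel reaches 43 °C in seconds, while a voxel 30 mm
deep needs ~19 minutes — the ~300-fold stretch mirrors the attenuation of
the beam, since ramp-time ratios exactly invert the fluence ratios. These
are best-case minima: the model assumes no conduction, no perfusion, and
no shadowing by nanoparticles above the target voxel.

A thin command-line wrapper over the four pipeline stages
(`simulate-traces`, `fit-efficiency`, `mc-fluence`, `ramp-times`) is
installed at `inst/cli/phototherm.R`; each stage takes `--config`
(YAML/JSON), `--seed` and `--out`, and writes CSV outputs with JSON
provenance sidecars.

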