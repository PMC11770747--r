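---
title: "Models and methods in phototherm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in phototherm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

phototherm benchmarks plasmonic nanoparticle photoheaters and projects
their performance to depth in tissue. This vignette documents the three
models in the package — the lumped-capacitance calorimetry model behind the
efficiency estimators, the voxel Monte Carlo model of light transport, and
the idealized voxel heating model — together with the numerical choices,
default parameters, and the limits of what the synthetic-data tests can
show.

## The calorimetry model

A stirred nanoparticle suspension in a cuvette, heated by a continuous-wave
laser, is treated as a single thermal mass (lumped capacitance). With
sample mass $m$ (g), heat capacity $C$ (J g$^{-1}$ K$^{-1}$), laser power
$I$ (W), decadic extinction $\varepsilon$ at the laser wavelength and
photothermal conversion efficiency $\eta$ (the fraction of extinguished
light converted to heat), the energy balance while the laser is on is

$$ mC\,\frac{dT}{dt} \;=\; I\,\eta\,\bigl(1-10^{-\varepsilon}\bigr)
   \;+\; Q_\mathrm{blank} \;-\; \frac{mC}{\tau}\,(T - T_\mathrm{amb}), $$

where $\tau$ is the Newton-cooling time constant and $Q_\mathrm{blank}$ the
baseline heat-input rate of solvent and cuvette. We carry
$Q_\mathrm{blank}$ as a rate (W): that is the only dimensionally consistent
reading of the balance, and the blank trace determines it as
$mC\,\Delta T_\mathrm{blank,max}/\tau_\mathrm{blank}$. The temperature
rises exponentially to the equilibrium excess
$\Delta T_\mathrm{eq} = \tau\,(I\eta(1-10^{-\varepsilon}) +
Q_\mathrm{blank})/(mC)$, and after laser-off decays as
$T_\mathrm{amb} + (T_\mathrm{off}-T_\mathrm{amb})\,e^{-t'/\tau}$.

The synthetic generator (`simulate_trace()`, `simulate_blank_trace()`)
evaluates this solution exactly and optionally adds i.i.d. Gaussian
measurement noise per sample. Defaults are 2 g of aqueous suspension
($C = 4.182$), a 1 W laser, extinction 0.1 (79% transmission), and
$\tau = 600$ s — a typical cuvette-scale time constant; no published value
exists for this fixture, and every estimator must work for any positive
$\tau$. The heating window defaults to $10\tau$ (6000 s) so that the
generated trace satisfies the equilibrium criterion used by the estimator
(plateau slope below $10^{-4}$ °C/s); heating for only $3\tau$, as a
half-hour session would give at this $\tau$, leaves a 5% plateau shortfall
that would propagate directly into $\eta$. Sampling is 1 Hz. The noise
model is deliberately minimal (white Gaussian, default 0.05 °C in noisy
fixtures): it supports recovery tests but does not emulate thermocouple
drift, stirring ripple, or ambient excursions, so passing recovery tests
bounds estimator error only under well-behaved measurement noise.

### Estimating $\tau$ and $\eta$

`fit_time_constant()` linearizes Newton cooling: with
$\theta = (T - T_\mathrm{amb})/(T_\mathrm{max} - T_\mathrm{amb})$, time
since laser-off is $\tau\,(-\ln\theta)$, and $\tau$ is the least-squares
slope of $t$ on $-\ln\theta$. Two exclusion rules stabilise the fit under
noise. Points within 0.02 °C of ambient are dropped (the logarithm of
noise). Less obviously, points below $\theta_\mathrm{min} = 0.2$ are also
dropped: near ambient the positivity requirement $\theta > 0$ selectively
retains upward noise excursions, and simulation shows this biases $\tau$
upward by 5–25% at realistic noise levels for small-amplitude traces,
whereas restricting the fit to the upper decay leaves ~0.5% bias with
~0.4% random error — and leaves the noiseless fit exact. A nonlinear
exponential fit is kept in the test suite as an independent oracle, never
as the implementation.

`estimate_eta()` applies the equilibrium balance
$\eta = (mC\,\Delta T_\mathrm{max}/\tau - Q_\mathrm{blank}) /
(I\,(1-10^{-\varepsilon}))$. The plateau temperature is read as the mean
over the final 300 s of heating: the mean is unbiased once equilibrated
and averages noise down, whereas the maximum of several thousand noisy
samples is biased upward by the expected extreme deviate (≈ 0.2 °C at
0.05 °C noise — a 6% error for a 3 °C plateau). The same 300 s window
feeds the equilibrium slope check; 60 s would leave the slope estimate's
own standard error above the $10^{-4}$ °C/s threshold at fixture noise.

### The mass-normalized efficiency

$\eta$ ignores how efficiently a suspension extinguishes light per unit
mass. The mass conversion efficiency
$\eta_m = \eta\,(1-10^{-\varepsilon})/m_\mathrm{NPs}$ (per microgram of
nanoparticle in the beam path) folds in the mass extinction coefficient,
and can be estimated without knowing $\eta$ from the short-time balance:
over the first $\Delta t$ of heating, losses are small and
$\eta_m \approx mC\,(\Delta T - \Delta T_\mathrm{blank}) /
(I\,\Delta t\,m_\mathrm{NPs})$.

`estimate_eta_m()` measures the rise as the least-squares slope over the
window times the window length. Even a short window is not bias-free: under
the lumped model the measured slope is the initial slope times a factor
that depends only on the sample times and $\Delta t/\tau$ — about 0.95 at
$\Delta t = 60$ s and $\tau = 600$ s. Because that factor is an exact
property of the model, the package inverts it whenever a time constant is
available (passed explicitly, or fitted from the trace's own cooling
segment), computing the factor at the actual sample times so the corrected
noiseless estimator is exact. Without the correction the two efficiency
routes would disagree by ~5% by construction; with it they agree to the
fit error, which is what the cross-method consistency test checks. Set
`correct_losses = FALSE` for the raw short-time estimator.

Mass bookkeeping: `mass_in_beam()` is concentration × beam area × path
(0.081 cm² × 1 cm for the cuvette geometry), ignoring beam broadening by
scattering. For silica-core nanoshells, elemental (gold) mass is converted
to total particle mass with `core_mass_correction()`:
$f_v\rho_\mathrm{SiO_2}/((1-f_v)\rho_\mathrm{Au})$ with
$f_v = (r_1/r_2)^3$ — 12.7% added mass for the benchmark shell geometry
($r_1 = 59.9$, $r_2 = 76.4$ nm).

## The light-transport model

`run_mc()` simulates a collimated 808 nm beam entering a homogeneous
breast-tissue slab (8 × 8 × 5 cm; absorption 0.035 cm$^{-1}$, reduced
scattering 11.7 cm$^{-1}$). Weighted photon packets propagate with free
paths $-\ln U/\mu_t$; fluence is tallied per scoring voxel with the
track-length estimator; absorption attenuates weight by implicit capture;
packets below weight $10^{-4}$ face Russian roulette (survival 0.1,
weight ×10). Roulette creates and destroys weight, so exact bookkeeping
tracks its net balance: launched = absorbed + escaped + roulette-net to
floating-point precision on every run, and `conservation_residual()`
exposes the check.

Numerical and design choices:

* **Phase function.** Only the reduced scattering coefficient is specified
  for the tissue, so the default is isotropic scattering with
  $\mu_s = \mu_s'$ (the similarity reduction); Henyey–Greenstein with
  configurable $g$ and $\mu_s = \mu_s'/(1-g)$ is available. Beyond a few
  transport mean free paths the two agree within ~5% (verified by a
  property test); within the first millimetres they genuinely differ, and
  the position of the shallow fluence peak depends on $g$ — with isotropic
  scattering the peak sits within the first millimetre, while strongly
  forward-peaked scattering on a fine grid can place it a few millimetres
  deep. Readouts that normalize by the peak inherit this sensitivity,
  which should be remembered when comparing against published profiles
  whose phase function is unreported.
* **Scoring grid.** Fluence is tallied on 1 mm voxels for variance
  control; the 0.0195 cm voxel (7.47 µg of tissue at 1 g/cm³) enters only
  the heating model's mass bookkeeping, and on-axis values at arbitrary
  depth are obtained by interpolating the 1 mm profile.
* **Normalization.** Map values are expressed relative to the mean fluence
  in the first voxel layer inside the illuminated disc ("surface dose");
  the near-surface build-up can then exceed 1. `depth_profile()` can also
  renormalize to the profile peak. The two conventions differ by the
  build-up factor (~1.2 for the default configuration), which is the
  single largest source of ambiguity when comparing percentage-at-depth
  figures between codes.
* **Beam.** Default is a flat-top disc of 10 mm diameter. The Gaussian
  option uses FWHM = diameter truncated at the same 10 mm circle, so the
  launch area (and hence any power-density bookkeeping) matches the
  flat-top case; an untruncated Gaussian of that FWHM would put half its
  power outside the nominal spot.
* **Boundaries.** Refractive-index matched by default; a relative index
  (e.g. 1.37) enables unpolarized Fresnel specular reflection at the six
  faces, including total internal reflection.
* **RNG.** The kernel draws from R's RNG stream, so a run is
  bit-reproducible given `set.seed`-style seeding, at the cost of being
  single-threaded.

Validation in the test suite: Beer–Lambert attenuation within 2% in the
pure-absorber limit; escaped weight equal to launched weight in the
non-absorbing limit; left–right symmetry; standard error scaling as
$1/\sqrt{n}$; and a broad-beam on-axis decay within 15% of the
diffusion-theory effective attenuation
$\mu_\mathrm{eff} = \sqrt{3\mu_a(\mu_a+\mu_s')} = 1.11$ cm$^{-1}$. An
independent diffusion dipole calculation was also used during development
to confirm the on-axis profile shape; a narrow-beam on-axis profile decays
substantially faster than $\mu_\mathrm{eff}$ because of lateral spreading,
so percentage-at-depth readouts are sensitive to beam geometry as well as
to the optical coefficients.

## The voxel heating model

For a tissue voxel of mass $m$ = 7.47 µg (heat capacity of water, 4.186)
containing nanoparticle mass $m_\mathrm{NPs}$ (concentration in mg per g
of tissue × voxel mass, tissue density 1 g/cm³), the peak heating rate is

$$ \dot T \;=\; \frac{\eta_m \, P(z)\, m_\mathrm{NPs}}{m\,C}, $$

where $P(z)$ is the total beam power arriving at depth $z$: surface power
density × beam area × on-axis relative density (surface-dose
normalization, so $P(0)$ is the delivered power). The per-voxel-area
alternative reading of "power reaching the voxel" disagrees with the
observable ramp-time scale by orders of magnitude and is not used; the
interpretation is recorded in the output metadata. Ramp time to the 43 °C
hyperthermia threshold is $(43 - 37)/\dot T$. No conduction, perfusion, or
attenuation by nanoparticles above the target voxel is modelled — the
numbers are minima by construction, and every exported table carries that
caveat in its metadata. Two exact identities pin the model down: ramp time
× concentration × power density is constant at fixed depth, and ramp-time
ratios between depths invert the fluence ratios.

## Problem sizes and reproducibility

The test suite runs the Monte Carlo at $10^4$–$10^6$ packets depending on
what the assertion needs (conservation is exact at any count; depth
readouts at 30 mm need $\gtrsim 10^6$ for a few-percent standard error),
and the estimator recovery tests use 50 seeds at the default trace length.
The acceptance script uses $2\times10^6$ packets. The pipeline fans a
single global seed out to per-stage seeds as
`(seed * 8 + stage) mod (2^31 - 1)`, so stages are individually
reproducible and re-running any stage with the same configuration is
byte-identical.

## Known limitations

* The lumped model ignores spatial gradients in the cuvette; the generator
  therefore cannot expose estimator errors caused by imperfect stirring.
* The tissue model is homogeneous — no skin, adipose/glandular layering,
  or vasculature — and the optical coefficients are single-point values at
  808 nm.
* The heating model is a best case; with perfusion and conduction the true
  ramp times at depth are longer, and at high nanoparticle loadings
  attenuation by particles above the target voxel (not modelled) caps the
  achievable temperature.
* $\eta_m$ transfers between geometries only through the mass extinction
  coefficient; particles whose plasmon resonance is detuned from the laser
  wavelength will show correspondingly lower $\eta_m$.
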