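---
title: "Modelling micromotor motility under GUV confinement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling micromotor motility under GUV confinement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The system

Catalase-loaded coacervate droplets (~1.2 um diameter) decompose hydrogen
peroxide and self-propel by self-diffusiophoresis. Enclosed in giant
unilamellar vesicles (GUVs, 10-50 um), their motion is recorded by
bright-field video microscopy at 5 frames/s for 60 s, and the XY-projected
trajectories are analysed through the mean-square displacement (MSD):

* `MSD = K * dt^alpha` — the anomalous-diffusion power law. `alpha = 1` is
  Brownian (normal) diffusion, `alpha < 1` sub-diffusion, `alpha > 1`
  superdiffusion.
* `MSD = 4 * D_T * dt` — the linear law on short lags, yielding the
  translational diffusion coefficient of the 2D projection.

`guvmotility` implements a Brownian-dynamics generator that emulates the
statistical structure of such recordings, an imaging/tracking stand-in
(Gaussian-spot rendering, thresholded centroid detection, nearest-neighbour
linking), and the MSD analysis chain. Because the underlying videos of such
experiments are rarely archived, the generator doubles as the package's
reference data source: every quantitative claim in the test-suite is
recomputed from simulations at the package defaults.

## Dynamics model

Each motor carries a position `x` (3D, um, relative to the GUV centre) and a
unit propulsion axis `e`. One Euler-Maruyama step of length `dt` reads

```
x <- x + m(d) * v * e * dt + sqrt(2 * m(d) * D_T0 * dt) * xi    # xi ~ N(0, I3)
```

with specular reflection of the radial overshoot at the hard wall
`|x| = R_guv - radius_p`. The axis `e` performs rotational diffusion: a
random infinitesimal rotation `e <- normalize(e + eta x e)` with
`eta ~ N(0, 2 * D_rot * dt * I3)`, giving the exponential autocorrelation
`<e(0).e(t)> = exp(-2 * D_rot * t)`.

### Hydrodynamic wall drag

A particle near a no-slip boundary experiences viscous drag growing like
the inverse of the gap `d = R_guv - |x| - radius_p`. We represent this with
a single scalar mobility applied to drift and noise variance alike
(fluctuation-dissipation consistent):

```
m(d) = m_min + (1 - m_min) * d / (d + lambda_wall)
```

`lambda_wall` is the coupling length, `m_min` the mobility floor at
contact. The default `lambda_wall = 25 um` *exceeds* the compartment radii
(7-17 um): inside a closed vesicle the enclosed, incompressible fluid
couples the particle to the shell at all distances (any displacement forces
a global backflow), so the drag is felt throughout the lumen and is
governed by the compartment scale rather than by a thin boundary layer.
This matches treating the drag distance as approximately the GUV radius for
particles tracked near the centre. Two consequences the model reproduces:
confined effective diffusivity well below the bulk `D_T0`, and a monotone
increase of motility with GUV size.

An important structural fact, established during calibration and worth
recording: a spatially varying scalar mobility *rescales the MSD amplitude
but hardly moves the fitted exponent*. Mixtures of linear time-averaged
MSDs are linear, so no choice of `(lambda_wall, m_min)` alone produces
`alpha` well below 1 on a 0.2-10 s window at these diffusivities; the only
intrinsic lag-dependent deceleration is hard-wall saturation, which is weak
for 14-34 um GUVs. The apparent sub-diffusion of recorded confined
trajectories arises from the *measurement model* below acting on a
drag-reduced diffusivity.

### Measurement model: localization error

Recorded coordinates are the true positions plus iid Gaussian localization
error (`loc_noise`, default 0.09 um — roughly a tenth of the particle
diameter, typical of bright-field centroid tracking). A constant offset
`4 * loc_noise^2` adds to the MSD at every lag; on a log-log fit this
flattens the short-lag slope, and the effect scales inversely with the
effective diffusivity. In bulk (`D_T ~ 0.2 um^2/s`) the fitted exponent
stays near 1; under confinement, where wall drag lowers the effective
diffusivity severalfold, the same error produces the markedly sub-diffusive
apparent exponent. Fuel raises the effective diffusivity and thereby
*restores* the exponent towards 1 — the observed crossover. Set
`loc_noise = 0` to study the bare dynamics; the containment and
free-diffusion tests do exactly that.

### Propulsion: saturating fuel map and patch turnover

Speed follows Michaelis-Menten kinetics in the fuel concentration,
`v = v_max * c / (K_fuel + c)`, because catalase saturates with substrate.
The propulsion axis is not rigidly attached to the particle: catalytic
activity concentrates in enzyme patches that transiently assemble and
dissolve, so the axis decorrelates both by body rotation (`D_R = 1/tau_R`,
`tau_R = 2 s`) and by patch turnover (`tau_patch`, default 0.2 s). The
effective axis-relaxation rate is `2 * D_R + 1/tau_patch`. With the
sub-frame default, activity contributes a lag-independent diffusivity boost
`v^2 * tau_c / 3` (with `tau_c = 1/(2 D_R + 1/tau_patch)`) rather than a
ballistic signature at the recorded lags — active confined MSD curves stay
nearly linear while their slope doubles, as observed. Setting
`tau_patch = Inf` recovers the classic active Brownian particle, whose
long-lag enhancement `D_T0 + v^2/(6 D_R)` the test-suite verifies against
the closed form.

### Membrane permeation and the pore control

Fuel enters the lumen by permeation across the bilayer; a well-mixed flux
balance over the sphere gives exponential relaxation with time constant
`R_guv / (3 P)` (about 3 s for `P = 1.1e-6 m/s`, `R = 10 um`). With
alpha-hemolysin pores the permeability is taken 100-fold higher and the
lumen equilibrates within a fraction of a frame, which is why the pore
control behaves identically to the plain bilayer on the 60 s recordings —
fuel supply is not limiting in either case.

### Crowding

Neighbouring motors distort each other's product gradients and deplete fuel
locally. We model this as a mean-field speed attenuation
`f = 1/(1 + beta * rho)` with number density `rho = n / ((4/3) pi R^3)` and
coupling volume `beta = 250 um^3` by default, chosen so that the studied
range of 5-30 motors per 25-34 um GUV spans a ~10-35% speed reduction. At
zero fuel the factor multiplies zero speed, so concentration groups are
statistically indistinguishable without fuel — the experimental control.

## Parameters and defaults

| parameter | default | units | meaning |
|---|---|---|---|
| `D_T0` | 0.2 | um^2/s | passive diffusivity (middle of the 0.1-0.3 range) |
| `tau_R` | 2 | s | body-rotation relaxation, `1/D_R`; see below |
| `tau_patch` | 0.2 | s | catalytic-patch axis correlation time |
| `v_max` | 9.58 | um/s | saturating free-slip propulsion speed (calibrated) |
| `K_fuel` | 1.0 | % v/v | half-saturation fuel concentration (calibrated) |
| `radius_p` | 0.6 | um | particle radius |
| `lambda_wall` | 25 | um | wall-coupling length (calibrated) |
| `m_min` | 0.015 | — | mobility floor at contact (calibrated) |
| `permeability` | 1.1e-6 | m/s | bilayer H2O2 permeability |
| `frame_rate` / `duration` | 5 / 60 | 1/s, s | acquisition |
| `dt_integration` | 0.01 | s | Euler-Maruyama step |
| `loc_noise` | 0.09 | um | localization error of recorded coordinates |

On the `tau_R` convention: the Stokes-Einstein-Debye estimate
`D_R = k_B T / (8 pi mu r^3)` gives `1/D_R` of about 1.2 s for the mean
1.2 um diameter and 1.5-3 s across the upper half of the (broad, +/-0.4 um)
size distribution. We adopt `tau_R = 1/D_R` and the mid-band default of
2 s; `rotational_time()` exposes the estimate.

### Calibration, performed once and frozen

Four defaults are not first-principles quantities and were fixed by a
single calibration pass against the headline observations, then frozen
(they are *not* refit at run time):

1. `lambda_wall`, `m_min` and `loc_noise` jointly, so that passive
   ensembles fit `alpha ~ 1.0` in bulk and a clearly sub-diffusive
   `alpha` near 0.85 in 14-34 um GUVs;
2. `v_max` so that stepping fuel from 0 to 0.85% doubles the fitted
   `D_T` under confinement;
3. `K_fuel = 1.0 % v/v`, placing 3.4% fuel at ~77% saturation so the
   fitted exponent at the top fuel level sits at normal diffusion and the
   fuel sweep is gradual rather than step-like.

The calibrated `v_max` looks large for a micromotor; note it is the
*free-slip, fully fuelled* ceiling. Inside a GUV the realized propulsion is
attenuated by the wall mobility (lumen average ~0.2-0.3) and the speed only
manifests as an enhanced diffusivity because the axis decorrelates on the
0.2 s patch timescale — the instantaneous displacement per frame stays well
below a particle diameter.

## Analysis chain

* **TAMSD**: per-particle time average over all overlapping frame pairs —
  the standard estimator for short tracking videos; an `O(N^2)` brute-force
  implementation serves as the exactness oracle in the tests.
* **Ensemble**: unweighted per-lag mean over particles, SEM = sd/sqrt(n).
* **Power-law fit**: OLS of `log(msd)` on `log(lag)` over 0.2-10 s
  (config-exposed). Confinement dominates the curve only beyond ~6 s, so
  the window must extend past it; log-log OLS keeps residuals scale-free
  across decades.
* **Linear fit**: least squares through the origin over 0.2-3 s, where
  confinement is negligible; `D_T = slope/4`.
* **Regime labels**: `|alpha - 1| <= 0.05` is "normal", so a fitted 1.01
  classifies as normal diffusion.
* **Group tests**: two-tailed Welch t-tests by default (the safer variant
  when variances differ between condition groups); Student's pooled
  variant by flag. Tiers `*` < 0.05, `**` < 0.01, `***` < 0.001.
* **Concentration readout**: total fluorescence = sum over the 45-plane
  z-stack after per-pixel background subtraction clamped at zero; groups
  split at 100 and 175 a.u., with the boundary values assigned to
  "medium" (a literal reading of "between 100 and 175").
* **Size groups**: small 14-24 um, medium 25-34 um (operationally, above
  24 up to 34 so the partition has no gap), large above 34 um; below 14 um
  is outside the studied range and errors.

## Numerical choices and degenerate inputs

* Euler-Maruyama at `dt = 0.01 s`, subsampled to the 0.2 s frame interval;
  stable for the parameter ranges used (per-step displacement << gap
  scales).
* Boundary: specular reflection of the radial overshoot at
  `R_guv - radius_p`; no adhesion (membrane and particle are pegylated /
  near-neutral). Pathological overshoots (never reached at the default
  step sizes) clamp just inside the wall.
* `lambda_wall = 0` disables wall coupling exactly (avoids 0/0 at
  contact).
* Orientation renormalized after every rotation step (unit norm to 1e-9).
* Per-particle random streams derive from the condition's master seed by a
  fixed counter offset; identical configurations and seeds give
  byte-identical trajectory files.
* Linking: greedy nearest-neighbour per consecutive frame pair, links
  accepted in order of increasing displacement, ties by lowest track id,
  hard `max_disp` gate, no gap closing (tracked particles stay in focus).
  Global assignment is unnecessary at the studied densities; this is a
  documented limitation, not an optimization target.
* Zero-variance identical groups in `compare_groups()` return `p = 1`
  with a warning instead of erroring.
* `msd_at()` is an exact on-grid lookup; off-grid lags snap to the nearest
  grid point rather than interpolating.

## Problem sizes

Simulated ensembles follow the study design: 40 particles per condition
for bulk and fuel-sweep comparisons, 15 per stratified (size or crowding)
group, 60 s at 5 frames/s, with headline statistics averaged over three
seeds. These sizes match the reported experiments (ca. 40 tracked motors
in bulk, 10-20 per size group) and keep every analysis deterministic under
a master seed.

## What the generator does and does not emulate

It reproduces: the lag structure of time-averaged MSDs under confinement,
fuel-, size- and crowding-dependent motility orderings, measurement noise,
membrane permeation kinetics, and relative z-stack fluorescence as a
particle-count readout. It does **not** solve the microscopic
diffusiophoresis problem (propulsion is phenomenological), does not couple
particles hydrodynamically (crowding is mean-field), has no membrane
mechanics or adhesion, no optics beyond a Gaussian PSF, and an isotropic
scalar mobility rather than the anisotropic near-wall tensor. Passing
tests therefore validate the analysis chain and the stated statistical
structure — not the microphysics of any particular experimental system.

## Known limitations

* The wall-drag mobility controls MSD *amplitude*; the apparent
  sub-diffusive exponent requires the localization-error term. If real
  confined sub-diffusion at these scales has an additional physical source
  (e.g. transient membrane interactions), the model will underestimate
  absolute confined MSD levels; at the calibrated defaults the absolute
  MSD at 10 s under 0.85% fuel is about half the level reported for
  medium-concentration GUVs, while all relative comparisons (orderings,
  ratios, exponents) are preserved.
* `alpha` fitted on 0.2-10 s with 60 s videos has a seed-to-seed spread of
  ~0.01-0.015 at n = 40; headline values are therefore three-seed means.
* The mean-field crowding factor cannot represent spatial clustering or
  pair correlations.
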