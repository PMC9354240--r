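# guvmotility

Simulation and single-particle-tracking analysis of enzyme-powered
coacervate micromotors confined in giant unilamellar vesicles (GUVs).

Catalase-loaded coacervate droplets (~1.2 µm) decompose H₂O₂ fuel and
self-propel by self-diffusiophoresis. Enclosed in cell-sized lipid
compartments (GUVs, 10–50 µm), their recorded motion changes character:
confined passive motors look sub-diffusive, fuel restores normal
diffusion, and motility grows with compartment size and falls with
particle crowding. This package provides, for people studying active
matter in confinement:

* a **Brownian-dynamics generator** of such recordings — an active
  Brownian particle in a spherical compartment with a hydrodynamic
  wall-drag mobility `m(d) = m_min + (1 − m_min)·d/(d + λ_wall)`,
  Michaelis–Menten fuel-to-speed mapping `v = v_max·c/(K_fuel + c)`,
  catalytic-patch propulsion-axis turnover, membrane fuel permeation
  (`dc/dt = (3P/R)(c_out − c_in)`), mean-field crowding and a realistic
  localization-error measurement model;
* a **synthetic imaging & tracking** stand-in: Gaussian-spot frames and
  45-plane confocal-like z-stacks (multi-page TIFF), thresholded
  centroid detection, greedy nearest-neighbour linking;
* the **MSD analysis chain**: time-averaged MSD per trajectory, ensemble
  mean ± SEM, power-law fits `MSD = K·Δt^α` (log–log OLS, lags
  0.2–10 s), linear fits `MSD = 4·D_T·Δt` through the origin (first
  3 s), diffusion-regime classification and Welch t-tests between
  condition groups;
* an **experiment orchestrator** reproducing the four study designs
  (bulk vs confined, fuel sweep, size stratification, crowding groups)
  from one YAML configuration.

## Worked example

Forty motors per condition in GUVs of 14–34 µm diameter, recorded 60 s at
5 frames/s, without and with 0.85% v/v fuel:

```r
library(guvmotility)

cond0 <- experiment_condition("guv_fuel0",    fuel = 0,
                              guv_diameter = c(14, 34), n_particles = 40, seed = 11)
cond1 <- experiment_condition("guv_fuel0.85", fuel = 0.85,
                              guv_diameter = c(14, 34), n_particles = 40, seed = 11)

for (cc in list(cond0, cond1)) {
  trs <- simulate_condition(cc)                       # 40 trajectories
  ens <- ensemble_msd(lapply(trs, tamsd, max_lag = 10))
  pl  <- fit_power_law(ens)                           # MSD = K * dt^alpha
  lin <- fit_linear(ens)                              # MSD = 4 * D_T * dt
  cat(sprintf("%-13s alpha = %.3f (%s), K = %.3f, D_T = %.3f um^2/s\n",
              cc$label, pl$alpha, classify_regime(pl$alpha), pl$K, lin$D_T))
}
```

prints

```
guv_fuel0     alpha = 0.904 (subdiffusive), K = 0.230, D_T = 0.051 um^2/s
guv_fuel0.85  alpha = 0.988 (normal), K = 0.407, D_T = 0.102 um^2/s
```

Without fuel the confined ensemble is sub-diffusive (α ≈ 0.90): wall drag
lowers the effective diffusivity and the tracking error flattens the
short-lag MSD. Adding 0.85% fuel doubles the fitted `D_T`
(0.102/0.051 ≈ 2.0) and brings α back to normal diffusion — propulsion
compensates the confinement effect. The full 22-condition design
(bulk/confined, α-hemolysin permeability control, fuel sweep, three GUV
size groups, three crowding groups) runs with:

```r
cfg <- read_run_config(system.file("extdata", "paper_defaults.yaml",
                                   package = "guvmotility"))
out <- run_experiment(cfg, out_dir = "results")   # fits.csv, msd_curves.csv, ...
```

A thin CLI wraps the same functions
(`inst/cli/guvmotility simulate|track|analyze|run-experiment`).

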