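motor:
  D_T0: 0.2
  tau_R: 2.0
  v_max: 9.58
  K_fuel: 1.0
  radius_p: 0.6
  tau_patch: 0.2
acquisition:
  frame_rate: 5.0
  duration: 60.0
  dt_integration: 0.01
  loc_noise: 0.09
analysis:
  alpha_window:
  - 0.2
  - 10.0
  linear_window:
  - 0.2
  - 3.0
conditions:
- label: bulk_fuel0
  fuel: 0.0
  guv_diameter: bulk
  n_particles: 40
  crowding_beta: 0.0
  n_crowders: 40
  membrane: bilayer
  seed: 10007002
- label: bulk_fuel0.034
  fuel: 0.034
  guv_diameter: bulk
  n_particles: 40
  crowding_beta: 0.0
  n_crowders: 40
  membrane: bilayer
  seed: 20014002
- label: guv_fuel0.034_ahl
  fuel: 0.034
  guv_diameter:
  - 14.0
  - 34.0
  n_particles: 15
  crowding_beta: 0.0
  n_crowders: 15
  membrane: alpha_hemolysin
  seed: 30021002
- label: guv_fuel0
  fuel: 0.0
  guv_diameter:
  - 14.0
  - 34.0
  n_particles: 40
  crowding_beta: 0.0
  n_crowders: 40
  membrane: bilayer
  seed: 40028002
- label: guv_fuel0.034
  fuel: 0.034
  guv_diameter:
  - 14.0
  - 34.0
  n_particles: 40
  crowding_beta: 0.0
  n_crowders: 40
  membrane: bilayer
  seed: 50035002
- label: guv_fuel0.85
  fuel: 0.85
  guv_diameter:
  - 14.0
  - 34.0
  n_particles: 40
  crowding_beta: 0.0
  n_crowders: 40
  membrane: bilayer
  seed: 60042002
- label: guv_fuel3.4
  fuel: 3.4
  guv_diameter:
  - 14.0
  - 34.0
  n_particles: 40
  crowding_beta: 0.0
  n_crowders: 40
  membrane: bilayer
  seed: 70049002
- label: size_small_fuel0
  fuel: 0.0
  guv_diameter:
  - 14.0
  - 24.0
  n_particles: 15
  crowding_beta: 0.0
  n_crowders: 15
  membrane: bilayer
  seed: 80056002
- label: size_small_fuel0.85
  fuel: 0.85
  guv_diameter:
  - 14.0
  - 24.0
  n_particles: 15
  crowding_beta: 0.0
  n_crowders: 15
  membrane: bilayer
  seed: 90063002
- label: size_small_fuel3.4
  fuel: 3.4
  guv_diameter:
  - 14.0
  - 24.0
  n_particles: 15
  crowding_beta: 0.0
  n_crowders: 15
  membrane: bilayer
  seed: 100070002
- label: size_medium_fuel0
  fuel: 0.0
  guv_diameter:
  - 25.0
  - 34.0
  n_particles: 15
  crowding_beta: 0.0
  n_crowders: 15
  membrane: bilayer
  seed: 110077002
- label: size_medium_fuel0.85
  fuel: 0.85
  guv_diameter:
  - 25.0
  - 34.0
  n_particles: 15
  crowding_beta: 0.0
  n_crowders: 15
  membrane: bilayer
  seed: 120084002
- label: size_medium_fuel3.4
  fuel: 3.4
  guv_diameter:
  - 25.0
  - 34.0
  n_particles: 15
  crowding_beta: 0.0
  n_crowders: 15
  membrane: bilayer
  seed: 130091002
- label: size_large_fuel0
  fuel: 0.0
  guv_diameter:
  - 34.0
  - 50.0
  n_particles: 15
  crowding_beta: 0.0
  n_crowders: 15
  membrane: bilayer
  seed: 140098002
- label: size_large_fuel0.85
  fuel: 0.85
  guv_diameter:
  - 34.0
  - 50.0
  n_particles: 15
  crowding_beta: 0.0
  n_crowders: 15
  membrane: bilayer
  seed: 150105002
- label: size_large_fuel3.4
  fuel: 3.4
  guv_diameter:
  - 34.0
  - 50.0
  n_particles: 15
  crowding_beta: 0.0
  n_crowders: 15
  membrane: bilayer
  seed: 160112002
- label: crowd_low_fuel0.85
  fuel: 0.85
  guv_diameter:
  - 25.0
  - 34.0
  n_particles: 15
  crowding_beta: 250.0
  n_crowders: 5
  membrane: bilayer
  seed: 170119002
- label: crowd_medium_fuel0.85
  fuel: 0.85
  guv_diameter:
  - 25.0
  - 34.0
  n_particles: 15
  crowding_beta: 250.0
  n_crowders: 15
  membrane: bilayer
  seed: 180126002
- label: crowd_high_fuel0.85
  fuel: 0.85
  guv_diameter:
  - 25.0
  - 34.0
  n_particles: 15
  crowding_beta: 250.0
  n_crowders: 30
  membrane: bilayer
  seed: 190133002
- label: crowd_low_fuel0
  fuel: 0.0
  guv_diameter:
  - 25.0
  - 34.0
  n_particles: 15
  crowding_beta: 250.0
  n_crowders: 5
  membrane: bilayer
  seed: 200140002
- label: crowd_medium_fuel0
  fuel: 0.0
  guv_diameter:
  - 25.0
  - 34.0
  n_particles: 15
  crowding_beta: 250.0
  n_crowders: 15
  membrane: bilayer
  seed: 210147002
- label: crowd_high_fuel0
  fuel: 0.0
  guv_diameter:
  - 25.0
  - 34.0
  n_particles: 15
  crowding_beta: 250.0
  n_crowders: 30
  membrane: bilayer
  seed: 220154002
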