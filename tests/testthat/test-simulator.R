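test_that("fuel-to-speed map is saturating, monotone and anchored", {
  m <- motor_params(v_max = 0.5, K_fuel = 1.0)
  expect_equal(fuel_to_speed(0, m), 0)
  expect_equal(fuel_to_speed(1.0, m), 0.25)          # half-saturation
  expect_equal(fuel_to_speed(3.4, m), 0.5 * 3.4 / 4.4, tolerance = 1e-12)
  fuels <- seq(0, 10, by = 0.1)
  expect_true(all(diff(fuel_to_speed(fuels, m)) >= 0))
  expect_lt(fuel_to_speed(1e6, m), m$v_max)
  expect_error(fuel_to_speed(-0.1, m), "non-negative")
})

test_that("wall mobility interpolates between floor and bulk", {
  comp <- compartment_params(R_guv = 10, lambda_wall = 2, m_min = 0.05)
  rp <- 0.6
  # at gap d = lambda_wall the variable part is exactly half
  pos <- c(10 - rp - 2, 0, 0)
  expect_equal(wall_mobility(pos, comp, rp), 0.05 + 0.95 * 0.5,
               tolerance = 1e-12)
  # monotone increasing in the gap
  gaps <- seq(0.01, 9, length.out = 40)
  ms <- sapply(gaps, function(d) {
    wall_mobility(c(10 - rp - d, 0, 0), comp, rp)
  })
  expect_true(all(diff(ms) > 0))
  expect_true(all(ms >= 0.05 & ms <= 1))
  # bulk limit and disabled coupling
  huge <- compartment_params(R_guv = 1e5, lambda_wall = 2, m_min = 0.05)
  expect_equal(wall_mobility(c(0, 0, 0), huge, rp), 1, tolerance = 1e-3)
  off <- compartment_params(R_guv = 10, lambda_wall = 0, m_min = 0.05)
  expect_equal(wall_mobility(c(8, 0, 0), off, rp), 1)
  expect_error(wall_mobility(c(11, 0, 0), comp, rp), "outside")
})

test_that("membrane permeation follows the closed-form flux balance", {
  comp <- compartment_params(R_guv = 10, permeability = 1.1e-6)
  # equilibrium fixed point
  expect_equal(permeate_fuel(2, 2, comp, 5), 2)
  # time constant R/(3P) ~ 3.03 s: 1/e relaxation
  tau <- 10e-6 / (3 * 1.1e-6)
  expect_equal(tau, 3.0303, tolerance = 1e-4)
  expect_equal(permeate_fuel(0, 1, comp, tau), 1 - exp(-1), tolerance = 1e-9)
  # independent ODE integration as oracle
  ode <- deSolve::ode(y = c(c = 0), times = seq(0, 10, 0.1),
                      func = function(t, y, p) {
                        list(3 * 1.1e-6 * 1e6 / 10 * (1 - y))
                      }, parms = NULL)
  expect_equal(permeate_fuel(0, 1, comp, 10), unname(ode[101, "c"]),
               tolerance = 1e-5)
  # monotone approach, always between the two concentrations
  ts <- seq(0, 30, 0.5)
  cs <- permeate_fuel(0.2, 3.4, comp, ts)
  expect_true(all(diff(cs) > 0))
  expect_true(all(cs >= 0.2 & cs <= 3.4))
  # alpha-hemolysin pores: equilibrated within one frame interval
  ahl <- compartment_params(R_guv = 10,
                            permeability = alpha_hemolysin_permeability())
  expect_equal(permeate_fuel(0, 1, ahl, 0.2), 1, tolerance = 2e-3)
  expect_error(permeate_fuel(-1, 1, comp, 1), "non-negative")
})

test_that("a single step without forces or noise leaves the particle put", {
  st <- particle_state(c(1, 2, 3), c(0, 0, 1))
  m <- motor_params(D_T0 = 1e-12, D_R = 1e-12, v_max = 1, tau_patch = Inf)
  comp <- compartment_params(R_guv = 20, fuel_outside = 0)
  out <- step_particle(st, m, comp, dt = 0.01)
  expect_equal(out$position, st$position, tolerance = 1e-5)
  expect_equal(sqrt(sum(out$orientation^2)), 1, tolerance = 1e-9)
  expect_error(step_particle(particle_state(), m, comp, dt = -1), "positive")
})

test_that("free-space ensemble follows the 3D Brownian law 6*D*t", {
  m <- motor_params()
  comp <- compartment_params(R_guv = Inf)
  set.seed(42)
  n <- 120
  disp2 <- vapply(seq_len(n), function(i) {
    tr <- simulate_trajectory(m, comp,
      acquisition_params(duration = 5, seed = 5000 + i, loc_noise = 0))
    k <- length(tr$times)
    sum((c(tr$xy[k, ], tr$z[k]) - c(tr$xy[1, ], tr$z[1]))^2)
  }, numeric(1))
  expect_equal(mean(disp2), 6 * m$D_T0 * 5,
               tolerance = 3 * sqrt(2 / 3) / sqrt(n))
})

test_that("propulsion axis decorrelates at the body-rotation rate", {
  m <- motor_params(D_R = 0.5, v_max = 1, tau_patch = Inf)
  comp <- compartment_params(R_guv = Inf)
  set.seed(7)
  t_end <- 0.5
  n_steps <- 50
  corr <- replicate(300, {
    st <- particle_state(orientation = c(0, 0, 1))
    for (i in seq_len(n_steps)) st <- step_particle(st, m, comp, dt = 0.01)
    st$orientation[3]
  })
  expect_equal(mean(corr), exp(-2 * m$D_R * t_end), tolerance = 0.05)
})

test_that("confined trajectories never leave the compartment", {
  m <- motor_params(v_max = 7.4)
  for (i in 1:6) {
    R <- c(4, 7, 12)[(i - 1) %% 3 + 1]
    comp <- compartment_params(R_guv = R, fuel_outside = 3.4)
    tr <- simulate_trajectory(m, comp,
      acquisition_params(duration = 20, seed = 100 + i, loc_noise = 0))
    r3 <- sqrt(tr$xy[, 1]^2 + tr$xy[, 2]^2 + tr$z^2)
    expect_true(all(r3 <= R + 1e-9))
    expect_true(all(is.finite(tr$xy)))
  }
})

test_that("identical seeds give byte-identical trajectory files", {
  m <- motor_params()
  comp <- compartment_params(R_guv = 10, fuel_outside = 0.85)
  acq <- acquisition_params(seed = 99L)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_trajectory_csv(simulate_trajectory(m, comp, acq), f1)
  write_trajectory_csv(simulate_trajectory(m, comp, acq), f2)
  expect_identical(readLines(f1), readLines(f2))
  acq2 <- acquisition_params(seed = 100L)
  expect_false(isTRUE(all.equal(simulate_trajectory(m, comp, acq2)$xy,
                                simulate_trajectory(m, comp, acq)$xy)))
})

test_that("condition ensembles are reproducible and independent", {
  cond <- experiment_condition("c", fuel = 0.85, guv_diameter = c(14, 34),
                               n_particles = 5, seed = 17L)
  acq <- acquisition_params(duration = 10)
  a <- simulate_condition(cond, acq = acq)
  b <- simulate_condition(cond, acq = acq)
  expect_length(a, 5L)
  expect_identical(lapply(a, `[[`, "xy"), lapply(b, `[[`, "xy"))
  # distinct particles see distinct noise streams
  expect_false(isTRUE(all.equal(a[[1]]$xy, a[[2]]$xy)))
  # per-particle GUV diameters drawn from the requested range
  expect_true(all(sapply(a, `[[`, "guv_diameter") >= 14))
  expect_true(all(sapply(a, `[[`, "guv_diameter") <= 34))
})

test_that("crowding factor is a mean-field attenuation", {
  expect_equal(crowding_factor(10, 10, beta = 0), 1)
  ns <- c(1, 2, 4, 8, 16, 32)
  fs <- sapply(ns, crowding_factor, R_guv = 12, beta = 250)
  expect_true(all(diff(fs) < 0))
  expect_true(all(fs > 0 & fs <= 1))
  # beta * rho = 1 halves the speed by construction
  rho1 <- (4 / 3) * pi * 12^3 / 30   # beta making beta*rho = 1 at n = 30
  expect_equal(crowding_factor(30, 12, beta = rho1), 0.5, tolerance = 1e-12)
})

test_that("wall coupling damps the MSD amplitude monotonically", {
  # a scalar mobility rescales displacement amplitude; stronger coupling
  # (larger lambda_wall) must never increase the ensemble MSD
  m <- motor_params()
  amp <- sapply(c(0, 1, 3, 10), function(lam) {
    trs <- lapply(1:12, function(i) {
      comp <- compartment_params(R_guv = 9, lambda_wall = lam, m_min = 0.05)
      simulate_trajectory(m, comp,
        acquisition_params(duration = 30, seed = 300 + i, loc_noise = 0))
    })
    msd_at(ensemble_msd(lapply(trs, tamsd, max_lag = 5)), 1)$msd
  })
  expect_true(all(diff(amp) < 0))
})
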