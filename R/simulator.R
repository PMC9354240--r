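#' Particle state
#'
#' Position (um, relative to the compartment centre) and unit orientation
#' vector of one simulated particle. The orientation is the body axis along
#' which self-diffusiophoretic propulsion acts.
#'
#' @param position numeric 3-vector, um.
#' @param orientation numeric 3-vector; renormalized to unit length.
#' @return An object of class `particle_state`.
#' @export
particle_state <- function(position = c(0, 0, 0),
                           orientation = c(0, 0, 1)) {
  position <- as.numeric(position)
  orientation <- as.numeric(orientation)
  stopifnot(length(position) == 3L, length(orientation) == 3L)
  if (!all(is.finite(position)) || !all(is.finite(orientation))) {
    stop("particle_state: non-finite position or orientation")
  }
  nrm <- sqrt(sum(orientation^2))
  if (nrm == 0) stop("particle_state: orientation must be non-zero")
  structure(list(position = position, orientation = orientation / nrm),
            class = "particle_state")
}

#' Fuel-to-speed map
#'
#' Saturating (Michaelis-Menten) map from H2O2 fuel concentration to
#' propulsion speed, `v = v_max * c / (K_fuel + c)`. Catalase kinetics
#' saturate with substrate, so propulsion does too: no fuel gives no
#' propulsion, and speed approaches `v_max` at high fuel.
#'
#' @param fuel fuel concentration(s), % v/v; vectorized.
#' @param params a [motor_params()] object.
#' @return propulsion speed(s), um/s.
#' @export
#' @examples
#' m <- motor_params(v_max = 0.5, K_fuel = 1.0)
#' fuel_to_speed(0, m)            # 0
#' fuel_to_speed(1.0, m)          # v_max / 2
#' fuel_to_speed(3.4, m)          # 0.5 * 3.4 / 4.4
fuel_to_speed <- function(fuel, params) {
  stopifnot(inherits(params, "motor_params"))
  if (any(!is.finite(fuel)) || any(fuel < 0)) {
    stop("fuel_to_speed: fuel must be finite and non-negative")
  }
  params$v_max * fuel / (params$K_fuel + fuel)
}

#' Hydrodynamic wall mobility
#'
#' Scalar mobility factor `m(d) = m_min + (1 - m_min) * d / (d + lambda_wall)`
#' where `d = R_guv - |position| - radius_p` is the gap between the particle
#' surface and the membrane. Viscous drag near a no-slip boundary grows like
#' the inverse of the distance to the wall, so the mobility falls from 1 in
#' the bulk towards the floor `m_min` at contact. The same factor multiplies
#' the deterministic drift and the noise variance (fluctuation-dissipation
#' consistent).
#'
#' @param position numeric 3-vector, um, relative to compartment centre.
#' @param comp a [compartment_params()] object.
#' @param radius_p particle radius, um.
#' @return mobility factor in `[m_min, 1]`.
#' @export
wall_mobility <- function(position, comp, radius_p = 0.6) {
  stopifnot(inherits(comp, "compartment_params"))
  r <- sqrt(sum(position^2))
  if (!is.finite(comp$R_guv)) return(1)
  if (r > comp$R_guv) {
    stop("wall_mobility: position lies outside the compartment")
  }
  d <- max(comp$R_guv - r - radius_p, 0)
  if (comp$lambda_wall == 0) return(1)
  comp$m_min + (1 - comp$m_min) * d / (d + comp$lambda_wall)
}

#' Fuel permeation across the GUV membrane
#'
#' Well-mixed flux balance over a sphere: the lumen concentration relaxes
#' towards the outside concentration as
#' `dc_in/dt = (3 P / R_guv) * (c_out - c_in)`,
#' solved in closed form as an exponential with time constant
#' `R_guv / (3 P)`. For a plain bilayer (P = 1.1e-6 m/s) and a 10 um-radius
#' GUV this is about 3 s; with alpha-hemolysin pores the lumen equilibrates
#' within a fraction of a frame interval.
#'
#' @param c_in lumen fuel concentration, % v/v.
#' @param c_out outside fuel concentration, % v/v.
#' @param comp a [compartment_params()] object (uses `R_guv`, `permeability`).
#' @param t elapsed time, s.
#' @return new lumen concentration, % v/v.
#' @export
permeate_fuel <- function(c_in, c_out, comp, t) {
  stopifnot(inherits(comp, "compartment_params"))
  if (any(c_in < 0) || any(c_out < 0) || any(t < 0)) {
    stop("permeate_fuel: concentrations and time must be non-negative")
  }
  if (!is.finite(comp$R_guv)) return(rep_len(c_out, length(t)))
  rate <- 3 * comp$permeability * 1e6 / comp$R_guv  # 1/s (P m/s -> um/s)
  c_out + (c_in - c_out) * exp(-rate * t)
}

# One Euler-Maruyama substep on bare vectors. `noise6` holds six standard
# normals (3 translational, 3 rotational). Returns list(position, orientation).
.bd_substep <- function(pos, ori, motor, comp, dt, speed, noise6) {
  R_guv <- comp$R_guv
  if (is.finite(R_guv)) {
    r <- sqrt(sum(pos^2))
    d <- R_guv - r - motor$radius_p
    if (d < 0) d <- 0
    m <- if (comp$lambda_wall == 0) 1 else {
      comp$m_min + (1 - comp$m_min) * d / (d + comp$lambda_wall)
    }
  } else {
    m <- 1
  }
  pos <- pos + (m * speed * dt) * ori +
    sqrt(2 * m * motor$D_T0 * dt) * noise6[1:3]
  if (is.finite(R_guv)) {
    R_eff <- R_guv - motor$radius_p
    rn <- sqrt(sum(pos^2))
    if (rn > R_eff) {
      # specular reflection of the radial overshoot at the hard wall
      rp <- 2 * R_eff - rn
      if (rp < 0) rp <- 0.999 * R_eff
      pos <- pos * (rp / rn)
    }
  }
  D_rot <- motor$D_R +
    if (is.finite(motor$tau_patch)) 1 / (2 * motor$tau_patch) else 0
  eta <- sqrt(2 * D_rot * dt) * noise6[4:6]
  ori <- ori + c(eta[2] * ori[3] - eta[3] * ori[2],
                 eta[3] * ori[1] - eta[1] * ori[3],
                 eta[1] * ori[2] - eta[2] * ori[1])
  ori <- ori / sqrt(sum(ori^2))
  list(position = pos, orientation = ori)
}

#' Advance a particle by one Brownian-dynamics step
#'
#' Euler-Maruyama update of an active Brownian particle: drift
#' `m(d) * v * e * dt` along the body axis, translational noise with
#' variance `2 * m(d) * D_T0 * dt` per axis, rotational diffusion of the
#' body axis with coefficient `D_R`, and specular reflection at the hard
#' wall `|x| = R_guv - radius_p`. Draws noise from R's global random number
#' stream.
#'
#' @param state a [particle_state()].
#' @param motor a [motor_params()].
#' @param comp a [compartment_params()].
#' @param dt time step, s.
#' @param speed propulsion speed, um/s; defaults to the motor's speed at the
#'   compartment's outside fuel concentration.
#' @return the updated [particle_state()].
#' @export
step_particle <- function(state, motor, comp, dt,
                          speed = fuel_to_speed(comp$fuel_outside, motor)) {
  stopifnot(inherits(state, "particle_state"),
            inherits(motor, "motor_params"),
            inherits(comp, "compartment_params"))
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0) {
    stop("step_particle: dt must be a single positive number")
  }
  if (!all(is.finite(state$position)) || !all(is.finite(state$orientation))) {
    stop("step_particle: non-finite particle state")
  }
  s <- .bd_substep(state$position, state$orientation, motor, comp, dt,
                   speed, rnorm(6))
  particle_state(s$position, s$orientation)
}

#' Trajectory object
#'
#' Time-ordered positions of one tracked particle at a uniform frame
#' interval. The XY projection is the unit of all downstream MSD analysis;
#' simulated trajectories additionally carry the Z coordinate.
#'
#' @param times numeric vector of times, s, strictly increasing and uniform.
#' @param xy n x 2 matrix of coordinates, um.
#' @param particle_id identifier.
#' @param z optional numeric vector of z coordinates, um.
#' @param guv_id optional compartment identifier.
#' @param guv_diameter optional compartment diameter, um (`Inf` for bulk).
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(times, xy, particle_id = 1L, z = NULL,
                       guv_id = NA_integer_, guv_diameter = NA_real_) {
  xy <- as.matrix(xy)
  stopifnot(ncol(xy) == 2L, nrow(xy) == length(times), length(times) >= 2L)
  if (!all(is.finite(times)) || !all(is.finite(xy))) {
    stop("trajectory: non-finite times or coordinates")
  }
  dts <- diff(times)
  if (any(dts <= 0)) stop("trajectory: times must be strictly increasing")
  if (diff(range(dts)) > 1e-6 * mean(dts)) {
    stop("trajectory: frame interval must be uniform")
  }
  structure(list(particle_id = particle_id, times = as.numeric(times),
                 xy = unname(xy), z = z, guv_id = guv_id,
                 guv_diameter = guv_diameter),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> particle %s: %d frames, dt = %.3g s, duration %.3g s\n",
              as.character(x$particle_id), length(x$times),
              x$times[2] - x$times[1], diff(range(x$times))))
  invisible(x)
}

#' Simulate one particle trajectory
#'
#' Integrates the active-Brownian dynamics at `acq$dt_integration` and
#' records the XY(Z) position at every frame interval, emulating
#' acquisition at five frames per second for 60 s. The initial position is
#' drawn uniformly from the central sphere of radius `R_guv/4` (particles
#' tracked in experiments start near the GUV centre); in bulk the particle
#' starts at the origin. Fuel in the lumen relaxes towards
#' `comp$fuel_outside` by membrane permeation; by default the lumen starts
#' equilibrated (fuel added well before recording). Recorded coordinates
#' carry the acquisition's localization error (`acq$loc_noise`); the
#' underlying physical positions always satisfy the confinement bound.
#'
#' @param motor a [motor_params()].
#' @param comp a [compartment_params()].
#' @param acq an [acquisition_params()]; its `seed` fixes the random stream.
#' @param particle_id identifier stored in the result.
#' @param crowding scalar speed multiplier in (0, 1], see [crowding_factor()].
#' @param equilibrate_fuel if `FALSE`, the lumen starts fuel-free and fuel
#'   enters by permeation during the recording.
#' @param guv_id,guv_diameter metadata stored in the result.
#' @return A [trajectory()].
#' @export
simulate_trajectory <- function(motor, comp, acq, particle_id = 1L,
                                crowding = 1, equilibrate_fuel = TRUE,
                                guv_id = NA_integer_,
                                guv_diameter = NA_real_) {
  stopifnot(inherits(motor, "motor_params"),
            inherits(comp, "compartment_params"),
            inherits(acq, "acquisition_params"))
  stopifnot(crowding > 0, crowding <= 1)
  set.seed(acq$seed)
  frame_dt <- 1 / acq$frame_rate
  n_frames <- as.integer(round(acq$duration * acq$frame_rate)) + 1L
  n_sub <- as.integer(round(frame_dt / acq$dt_integration))
  dt <- acq$dt_integration
  n_steps <- (n_frames - 1L) * n_sub

  # initial state
  if (is.finite(comp$R_guv)) {
    u <- rnorm(3)
    u <- u / sqrt(sum(u^2))
    pos <- u * (comp$R_guv / 4) * runif(1)^(1 / 3)
  } else {
    pos <- c(0, 0, 0)
  }
  ori <- rnorm(3)
  ori <- ori / sqrt(sum(ori^2))

  # lumen fuel concentration at the start of each substep (closed form)
  c0 <- if (equilibrate_fuel) comp$fuel_outside else 0
  t_sub <- (seq_len(n_steps) - 1L) * dt
  c_in <- permeate_fuel(c0, comp$fuel_outside, comp, t_sub)
  speeds <- fuel_to_speed(c_in, motor) * crowding

  noise <- matrix(rnorm(n_steps * 6L), n_steps, 6L)
  rec <- matrix(NA_real_, n_frames, 3L)
  rec[1L, ] <- pos
  k <- 1L
  for (i in seq_len(n_steps)) {
    s <- .bd_substep(pos, ori, motor, comp, dt, speeds[i], noise[i, ])
    pos <- s$position
    ori <- s$orientation
    if (i %% n_sub == 0L) {
      k <- k + 1L
      rec[k, ] <- pos
    }
  }
  if (acq$loc_noise > 0) {
    # measurement model: iid localization error on every recorded coordinate
    rec <- rec + matrix(rnorm(length(rec), sd = acq$loc_noise), nrow(rec), 3L)
  }
  trajectory(times = (seq_len(n_frames) - 1L) * frame_dt,
             xy = rec[, 1:2, drop = FALSE], z = rec[, 3],
             particle_id = particle_id, guv_id = guv_id,
             guv_diameter = guv_diameter)
}

#' Mean-field crowding factor
#'
#' Speed attenuation by neighbouring active particles:
#' `f = 1 / (1 + beta * rho)` with number density
#' `rho = n / ((4/3) * pi * R_guv^3)`. Surrounding particles distort the
#' self-generated product gradient and locally deplete fuel, slowing
#' propulsion; `beta` (um^3) sets the strength of this mean-field coupling
#' and `beta = 0` disables it.
#'
#' @param n_particles number of particles in the compartment.
#' @param R_guv compartment radius, um.
#' @param beta coupling volume, um^3.
#' @return attenuation factor in (0, 1].
#' @export
crowding_factor <- function(n_particles, R_guv, beta) {
  stopifnot(n_particles >= 1, R_guv > 0, beta >= 0)
  rho <- n_particles / ((4 / 3) * pi * R_guv^3)
  1 / (1 + beta * rho)
}

# per-particle stream: fixed counter offset from the master seed
.derive_seed <- function(master, counter) {
  as.integer((as.numeric(master) + 10007 * as.numeric(counter)) %%
               (.Machine$integer.max - 1)) + 1L
}

#' Simulate an ensemble of particles under one experimental condition
#'
#' Generates `n_particles` independent trajectories under the condition's
#' fuel level, compartment geometry and membrane type. Each particle sits in
#' its own GUV; when `cond$guv_diameter` is a length-2 range, diameters are
#' drawn uniformly per particle. Per-particle random streams are derived
#' from the condition's master seed by a fixed counter offset, so runs are
#' reproducible. In crowding mode (`cond$crowding_beta > 0`) the propulsion
#' speed is attenuated by [crowding_factor()] using `cond$n_crowders`.
#'
#' @param cond an [experiment_condition()].
#' @param n_particles number of trajectories; defaults to `cond$n_particles`.
#' @param motor a [motor_params()] (defaults apply when omitted).
#' @param acq an [acquisition_params()]; its seed field is overridden per
#'   particle.
#' @param equilibrate_fuel passed to [simulate_trajectory()].
#' @return list of [trajectory()] objects.
#' @export
simulate_condition <- function(cond, n_particles = cond$n_particles,
                               motor = motor_params(),
                               acq = acquisition_params(),
                               equilibrate_fuel = TRUE) {
  stopifnot(inherits(cond, "experiment_condition"), n_particles >= 1)
  perm <- if (identical(cond$membrane, "alpha_hemolysin")) {
    alpha_hemolysin_permeability()
  } else {
    1.1e-6
  }
  bulk <- identical(cond$guv_diameter, "bulk")
  set.seed(.derive_seed(cond$seed, 0L))
  diam <- if (bulk) {
    rep(Inf, n_particles)
  } else if (length(cond$guv_diameter) == 2L) {
    runif(n_particles, cond$guv_diameter[1], cond$guv_diameter[2])
  } else {
    rep(cond$guv_diameter, n_particles)
  }
  lapply(seq_len(n_particles), function(i) {
    comp <- compartment_params(R_guv = if (bulk) Inf else diam[i] / 2,
                               permeability = perm,
                               fuel_outside = cond$fuel)
    crowd <- if (cond$crowding_beta > 0 && !bulk) {
      crowding_factor(cond$n_crowders, comp$R_guv, cond$crowding_beta)
    } else {
      1
    }
    acq_i <- acq
    acq_i$seed <- .derive_seed(cond$seed, i)
    simulate_trajectory(motor, comp, acq_i, particle_id = i,
                        crowding = crowd,
                        equilibrate_fuel = equilibrate_fuel,
                        guv_id = i, guv_diameter = diam[i])
  })
}
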