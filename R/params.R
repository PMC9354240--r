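#' Motor (particle) parameters
#'
#' Physical parameters of a single coacervate micromotor. Defaults describe a
#' 1.2 um diameter particle with passive diffusion in the middle of the
#' 0.1-0.3 um^2/s range and a rotational relaxation time of 2 s
#' (`tau_R = 1/D_R`). The propulsion speed responds to fuel (H2O2)
#' concentration through a saturating Michaelis-Menten map, see
#' [fuel_to_speed()]; `v_max` and `K_fuel` defaults are calibrated once so
#' that a 0 to 0.85% v/v fuel step doubles the fitted short-lag diffusion
#' coefficient and 3.4% v/v restores normal diffusion under confinement.
#'
#' @param D_T0 passive translational diffusion coefficient, um^2/s.
#' @param D_R rotational diffusion coefficient, 1/s. Exactly one of `D_R`
#'   and `tau_R` may be given; the other is derived via `tau_R = 1/D_R`.
#' @param tau_R rotational relaxation time, s.
#' @param v_max saturating propulsion speed, um/s.
#' @param K_fuel half-saturation fuel concentration, % v/v.
#' @param radius_p particle radius, um.
#' @param tau_patch correlation time of the catalytic-patch propulsion axis,
#'   s (`Inf` disables patch turnover). Propulsion arises from enzymes
#'   transiently clustering into surface patches, so the propulsion axis
#'   decorrelates by patch turnover (fast, sub-frame) on top of body
#'   rotation (`D_R`); the effective axis-relaxation rate is
#'   `2 * D_R + 1/tau_patch`. With the sub-frame default, activity acts as
#'   a lag-independent diffusivity boost `v^2 * tau_c / 3` with
#'   `tau_c = 1 / (2 * D_R + 1/tau_patch)` at the recorded lags.
#' @return An object of class `motor_params`.
#' @seealso [rotational_time()] for the Stokes-Einstein-Debye estimate of
#'   `tau_R` from particle size.
#' @export
#' @examples
#' m <- motor_params()
#' m$tau_R * m$D_R  # always 1
motor_params <- function(D_T0 = 0.2, D_R = NULL, tau_R = NULL,
                         v_max = 9.58, K_fuel = 1.0, radius_p = 0.6,
                         tau_patch = 0.2) {
  if (is.null(D_R) && is.null(tau_R)) tau_R <- 2
  if (is.null(D_R)) D_R <- 1 / tau_R
  if (is.null(tau_R)) tau_R <- 1 / D_R
  p <- list(D_T0 = D_T0, D_R = D_R, tau_R = tau_R,
            v_max = v_max, K_fuel = K_fuel, radius_p = radius_p)
  for (nm in names(p)) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !is.finite(p[[nm]]) ||
        p[[nm]] <= 0) {
      stop("motor_params: '", nm, "' must be a single positive finite number")
    }
  }
  if (!is.numeric(tau_patch) || length(tau_patch) != 1L || tau_patch <= 0) {
    stop("motor_params: 'tau_patch' must be a single positive number (Inf allowed)")
  }
  p$tau_patch <- tau_patch
  if (abs(p$tau_R * p$D_R - 1) > 1e-9) {
    stop("motor_params: tau_R and D_R are inconsistent (tau_R * D_R must be 1)")
  }
  structure(p, class = "motor_params")
}

#' Compartment (GUV) parameters
#'
#' Geometry, wall-coupling and membrane-permeability parameters of a
#' spherical GUV compartment. The hydrodynamic wall drag is a scalar
#' mobility `m(d)` that decays towards `m_min` as the particle-to-membrane
#' gap `d` closes (see [wall_mobility()]); it phenomenologically captures the
#' 1/L growth of viscous drag near a no-slip boundary. `lambda_wall` and
#' `m_min` defaults are calibrated once against the sub-diffusive exponent of
#' passive confined particles and then frozen. `R_guv = Inf` describes bulk
#' (unconfined) medium.
#'
#' @param R_guv compartment radius, um (`Inf` for bulk).
#' @param lambda_wall wall-coupling length of the mobility model, um.
#' @param m_min mobility floor at membrane contact, in (0, 1].
#' @param permeability membrane permeability to fuel, m/s. The default is
#'   the measured H2O2 permeability of a plain lipid bilayer; use
#'   [alpha_hemolysin_permeability()] for pore-bearing membranes.
#' @param fuel_outside fuel concentration outside the GUV, % v/v.
#' @return An object of class `compartment_params`.
#' @export
#' @examples
#' compartment_params(R_guv = 10, fuel_outside = 0.85)
compartment_params <- function(R_guv = 12, lambda_wall = 25, m_min = 0.015,
                               permeability = 1.1e-6, fuel_outside = 0) {
  stopifnot(is.numeric(R_guv), length(R_guv) == 1L, R_guv > 0)
  stopifnot(is.numeric(lambda_wall), length(lambda_wall) == 1L,
            is.finite(lambda_wall), lambda_wall >= 0)
  stopifnot(is.numeric(m_min), length(m_min) == 1L, m_min > 0, m_min <= 1)
  stopifnot(is.numeric(permeability), length(permeability) == 1L,
            permeability >= 0)
  stopifnot(is.numeric(fuel_outside), length(fuel_outside) == 1L,
            fuel_outside >= 0)
  structure(list(R_guv = R_guv, lambda_wall = lambda_wall, m_min = m_min,
                 permeability = permeability, fuel_outside = fuel_outside),
            class = "compartment_params")
}

#' Effective permeability of an alpha-hemolysin-porated membrane
#'
#' Pore-forming alpha-hemolysin renders the GUV membrane highly permeable to
#' small solutes; it is used as a control to rule out substrate-limitation
#' artefacts. Modelled as a large multiple of the plain-bilayer H2O2
#' permeability, so the lumen equilibrates with the outside within a fraction
#' of one frame interval.
#'
#' @param fold multiple of the plain-bilayer permeability (default 100).
#' @param bilayer plain-bilayer permeability, m/s.
#' @return permeability, m/s.
#' @export
alpha_hemolysin_permeability <- function(fold = 100, bilayer = 1.1e-6) {
  stopifnot(fold >= 1)
  fold * bilayer
}

#' Acquisition parameters
#'
#' Video-acquisition settings emulating bright-field tracking at five frames
#' per second for 60 s, together with the Brownian-dynamics integration step.
#' The frame interval must be an integer multiple of `dt_integration`.
#'
#' @param frame_rate frames per second, 1/s.
#' @param duration recording length, s.
#' @param dt_integration Euler-Maruyama integration step, s.
#' @param seed integer seed for the trajectory's random stream.
#' @param loc_noise localization error of the tracking, um (standard
#'   deviation of the iid Gaussian error added to every recorded
#'   coordinate). Centroid tracking of a ~1.2 um particle in bright-field
#'   video localizes to roughly a tenth of the particle diameter; set to 0
#'   for noise-free recording of the true positions.
#' @return An object of class `acquisition_params`.
#' @export
acquisition_params <- function(frame_rate = 5, duration = 60,
                               dt_integration = 0.01, seed = 1L,
                               loc_noise = 0.09) {
  stopifnot(frame_rate > 0, duration > 0, dt_integration > 0, loc_noise >= 0)
  frame_dt <- 1 / frame_rate
  if (dt_integration > frame_dt + 1e-12) {
    stop("acquisition_params: dt_integration must not exceed the frame interval")
  }
  n_sub <- frame_dt / dt_integration
  if (abs(n_sub - round(n_sub)) > 1e-9) {
    stop("acquisition_params: frame interval must be an integer multiple of dt_integration")
  }
  structure(list(frame_rate = frame_rate, duration = duration,
                 dt_integration = dt_integration, seed = as.integer(seed),
                 loc_noise = loc_noise),
            class = "acquisition_params")
}

#' Rotational relaxation time from particle size
#'
#' Stokes-Einstein-Debye estimate: the rotational diffusion coefficient of a
#' sphere of radius `r` is `D_R = k_B T / (8 pi mu r^3)` and the relaxation
#' time is taken as `tau_R = 1/D_R`. For a 1.2 um particle in water at room
#' temperature this gives roughly 1.2 s; particles in the upper part of the
#' 1.2 +/- 0.4 um size distribution fall in the 1.5-3 s band.
#'
#' @param radius_p particle radius, um.
#' @param viscosity dynamic viscosity of the medium, Pa s.
#' @param temperature absolute temperature, K.
#' @return rotational relaxation time `tau_R`, s.
#' @export
#' @examples
#' rotational_time(0.6)          # ~1.3 s for the mean 1.2 um diameter
#' rotational_time(0.8) / rotational_time(0.4)  # cubic in radius: 8
rotational_time <- function(radius_p, viscosity = 8.9e-4, temperature = 298.15) {
  stopifnot(radius_p > 0, viscosity > 0, temperature > 0)
  kB <- 1.380649e-23  # J/K
  r_m <- radius_p * 1e-6
  D_R <- kB * temperature / (8 * pi * viscosity * r_m^3)  # 1/s
  1 / D_R
}
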