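# Independent oracles used across the suite. These deliberately use naive
# O(N^2) loops / textbook formulas, not the package's own code paths.

# brute-force time-averaged MSD: explicit double loop over all frame pairs
brute_force_tamsd <- function(xy, dt, k_max) {
  n <- nrow(xy)
  vapply(seq_len(k_max), function(k) {
    acc <- 0
    for (i in 1:(n - k)) {
      acc <- acc + sum((xy[i + k, ] - xy[i, ])^2)
    }
    acc / (n - k)
  }, numeric(1))
}

# textbook Welch two-sample t-test
welch_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- var(a); vb <- var(b)
  se2 <- va / na + vb / nb
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(t = t, p = 2 * pt(-abs(t), df))
}

# random uniform-step trajectory for estimator equivalence checks
random_trajectory <- function(n_frames = 50, dt = 0.2, sd = 0.3) {
  xy <- apply(matrix(rnorm(n_frames * 2, sd = sd), ncol = 2), 2, cumsum)
  trajectory(times = (seq_len(n_frames) - 1) * dt, xy = xy)
}

# ensemble alpha/D_T fit used by the acceptance-style simulations
fit_condition_ensemble <- function(trajs, alpha_window = c(0.2, 10),
                                   linear_window = c(0.2, 3)) {
  ens <- ensemble_msd(lapply(trajs, tamsd, max_lag = max(alpha_window)))
  list(ens = ens,
       alpha = fit_power_law(ens, alpha_window)$alpha,
       D_T = fit_linear(ens, linear_window)$D_T)
}

# simulate one confined/bulk ensemble under study-default parameters
simulate_study_ensemble <- function(fuel, seed, n = 40, diam = c(14, 34),
                                    bulk = FALSE, motor = motor_params(),
                                    crowding = 1, loc_noise = NULL) {
  set.seed(seed)
  diams <- runif(n, diam[1], diam[2])
  lapply(seq_len(n), function(i) {
    comp <- compartment_params(R_guv = if (bulk) Inf else diams[i] / 2,
                               fuel_outside = fuel)
    acq <- if (is.null(loc_noise)) {
      acquisition_params(seed = seed * 1000 + i)
    } else {
      acquisition_params(seed = seed * 1000 + i, loc_noise = loc_noise)
    }
    simulate_trajectory(motor, comp, acq, particle_id = i,
                        crowding = crowding, guv_diameter = diams[i])
  })
}
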