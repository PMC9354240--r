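#' Experimental condition
#'
#' One cell of the in-silico experimental design: a fuel level, a
#' compartment geometry (bulk or a GUV diameter / diameter range), an
#' ensemble size, optional mean-field crowding, a membrane type and a
#' master seed.
#'
#' @param label condition label.
#' @param fuel H2O2 concentration, % v/v (study levels: 0, 0.034, 0.85, 3.4).
#' @param guv_diameter `"bulk"`, a single diameter (um), or a `c(min, max)`
#'   range sampled uniformly per particle.
#' @param n_particles trajectories to simulate.
#' @param crowding_beta mean-field crowding coupling, um^3 (0 disables).
#' @param n_crowders particle count used for the crowding density
#'   (defaults to `n_particles`).
#' @param membrane `"bilayer"` or `"alpha_hemolysin"`.
#' @param seed master seed of the condition.
#' @return An object of class `experiment_condition`.
#' @export
experiment_condition <- function(label = "cond", fuel = 0,
                                 guv_diameter = "bulk", n_particles = 15,
                                 crowding_beta = 0,
                                 n_crowders = n_particles,
                                 membrane = c("bilayer", "alpha_hemolysin"),
                                 seed = 1L) {
  membrane <- match.arg(membrane)
  stopifnot(fuel >= 0, n_particles >= 1, crowding_beta >= 0, n_crowders >= 1)
  if (!identical(guv_diameter, "bulk")) {
    guv_diameter <- as.numeric(guv_diameter)
    stopifnot(length(guv_diameter) %in% 1:2, all(guv_diameter > 1.2))
    if (length(guv_diameter) == 2L) {
      stopifnot(guv_diameter[1] <= guv_diameter[2])
    }
  }
  structure(list(label = label, fuel = fuel, guv_diameter = guv_diameter,
                 n_particles = as.integer(n_particles),
                 crowding_beta = crowding_beta,
                 n_crowders = as.integer(n_crowders),
                 membrane = membrane, seed = as.integer(seed)),
            class = "experiment_condition")
}

#' Assign a GUV to a size group
#'
#' Small: 14-24 um, medium: 25-34 um (operationally, above 24 and up to
#' 34 um so the partition has no gap), large: above 34 um. Diameters below
#' 14 um fall outside the studied range and raise an error.
#'
#' @param diameter GUV diameter, um (vectorized).
#' @return character vector: `"small"`, `"medium"` or `"large"`.
#' @export
#' @examples
#' assign_size_group(c(20, 30, 40))
assign_size_group <- function(diameter) {
  stopifnot(all(diameter > 0))
  if (any(diameter < 14)) {
    stop("assign_size_group: diameters below 14 um are outside the studied range")
  }
  ifelse(diameter <= 24, "small", ifelse(diameter <= 34, "medium", "large"))
}

#' Sample a GUV diameter within a size group
#'
#' Uniform within the group bounds (small 14-24 um, medium 25-34 um,
#' large 34-50 um; GUVs span 10-50 um overall, so the large group is
#' capped at 50 um). The within-group distribution is a modelling choice:
#' the droplet-transfer method yields a broad, unreported size spread.
#'
#' @param group `"small"`, `"medium"` or `"large"`.
#' @param n number of draws.
#' @return diameters, um.
#' @export
sample_guv_diameter <- function(group = c("small", "medium", "large"), n = 1) {
  group <- match.arg(group)
  b <- switch(group, small = c(14, 24), medium = c(25, 34), large = c(34, 50))
  runif(n, b[1], b[2])
}

#' Confinement-to-particle size ratio
#'
#' Ratio of the GUV diameter to the particle diameter; motility is known to
#' be severely restricted at ratios of a few, and the small and large GUV
#' groups here sit at roughly 11-30.
#'
#' @param guv_diameter GUV diameter, um.
#' @param particle_diameter particle diameter, um (default 1.2).
#' @return unitless ratio.
#' @export
confinement_ratio <- function(guv_diameter, particle_diameter = 1.2) {
  stopifnot(all(guv_diameter > 0), particle_diameter > 0)
  guv_diameter / particle_diameter
}

#' Default multi-condition experiment configuration
#'
#' Conditions covering the four in-silico studies: bulk versus confined
#' motility (with an alpha-hemolysin permeability control), a confined fuel
#' sweep over 0-3.4% v/v, size-stratified ensembles (small/medium/large
#' GUVs) and crowding groups at 0.85% fuel (plus their zero-fuel controls).
#' Ensemble sizes follow the study design: 40 particles in bulk, 15 per
#' stratified group.
#'
#' @param seed master seed; per-condition seeds are derived by fixed offsets.
#' @param n_bulk,n_group ensemble sizes.
#' @return list of [experiment_condition()] objects.
#' @export
default_experiment_config <- function(seed = 1L, n_bulk = 40, n_group = 15) {
  fuels <- c(0, 0.034, 0.85, 3.4)
  conds <- list()
  add <- function(...) conds[[length(conds) + 1L]] <<- experiment_condition(...)
  i <- 0L
  nseed <- function() {
    i <<- i + 1L
    .derive_seed(seed, 1000L * i)
  }
  # bulk vs confined (+ permeability control)
  add("bulk_fuel0", fuel = 0, guv_diameter = "bulk", n_particles = n_bulk,
      seed = nseed())
  add("bulk_fuel0.034", fuel = 0.034, guv_diameter = "bulk",
      n_particles = n_bulk, seed = nseed())
  add("guv_fuel0.034_ahl", fuel = 0.034, guv_diameter = c(14, 34),
      n_particles = n_group, membrane = "alpha_hemolysin", seed = nseed())
  # confined fuel sweep
  for (f in fuels) {
    add(sprintf("guv_fuel%g", f), fuel = f, guv_diameter = c(14, 34),
        n_particles = n_bulk, seed = nseed())
  }
  # size stratification
  for (g in c("small", "medium", "large")) {
    b <- switch(g, small = c(14, 24), medium = c(25, 34), large = c(34, 50))
    for (f in c(0, 0.85, 3.4)) {
      add(sprintf("size_%s_fuel%g", g, f), fuel = f, guv_diameter = b,
          n_particles = n_group, seed = nseed())
    }
  }
  # crowding groups at fixed size, 0.85% fuel, plus zero-fuel controls
  for (f in c(0.85, 0)) {
    for (g in c("low", "medium", "high")) {
      nc <- switch(g, low = 5L, medium = 15L, high = 30L)
      add(sprintf("crowd_%s_fuel%g", g, f), fuel = f,
          guv_diameter = c(25, 34), n_particles = n_group,
          crowding_beta = 250, n_crowders = nc, seed = nseed())
    }
  }
  conds
}

#' Run a multi-condition in-silico experiment
#'
#' For every condition: simulate the ensemble, compute per-particle
#' time-averaged MSDs, ensemble-average them, fit the anomalous power law
#' and the short-lag linear law (on the ensemble curve and per particle),
#' classify the diffusion regime and read the MSD at 10 s. Group
#' dispersion is reported as SD for the per-particle alpha / D_T fits and
#' as SEM for the ensemble MSD curves. Pairwise Welch t-tests compare
#' per-particle D_T between all condition pairs. A failing condition is
#' logged and skipped; the others proceed.
#'
#' @param conditions list of [experiment_condition()]s (default
#'   [default_experiment_config()]), or a config list from
#'   [read_run_config()].
#' @param motor a [motor_params()].
#' @param acq an [acquisition_params()].
#' @param alpha_window,linear_window fit windows, s.
#' @param msd_readout_lag lag for the MSD point readout, s.
#' @param out_dir if given, writes `conditions.csv`, `msd_curves.csv`,
#'   `fits.csv`, `particle_fits.csv`, `comparisons.csv` and `run.log` there.
#' @return list of data.frames: `conditions`, `msd_curves`, `fits`,
#'   `particle_fits`, `comparisons`, plus `curves` (named list of ensemble
#'   `msd_curve`s) and `errors`.
#' @export
run_experiment <- function(conditions = default_experiment_config(),
                           motor = motor_params(),
                           acq = acquisition_params(),
                           alpha_window = c(0.2, 10),
                           linear_window = c(0.2, 3),
                           msd_readout_lag = 10,
                           out_dir = NULL) {
  if (!is.null(conditions$conditions)) {  # read_run_config() bundle
    cfg <- conditions
    conditions <- cfg$conditions
    motor <- cfg$motor
    acq <- cfg$acq
    alpha_window <- cfg$analysis$alpha_window
    linear_window <- cfg$analysis$linear_window
  }
  stopifnot(length(conditions) >= 0)
  cond_df <- do.call(rbind, lapply(conditions, function(cc) {
    data.frame(label = cc$label, fuel = cc$fuel,
               guv_diameter = paste(cc$guv_diameter, collapse = "-"),
               n_particles = cc$n_particles,
               crowding_beta = cc$crowding_beta, n_crowders = cc$n_crowders,
               membrane = cc$membrane, seed = cc$seed)
  }))
  fits <- list()
  pfits <- list()
  curves_long <- list()
  curves <- list()
  errors <- character(0)
  for (cc in conditions) {
    res <- tryCatch({
      trajs <- simulate_condition(cc, motor = motor, acq = acq)
      pc <- lapply(trajs, tamsd, max_lag = max(alpha_window))
      ens <- ensemble_msd(pc)
      pl <- fit_power_law(ens, alpha_window)
      lin <- fit_linear(ens, linear_window)
      pp <- do.call(rbind, lapply(seq_along(pc), function(i) {
        ppl <- fit_power_law(pc[[i]], alpha_window)
        pli <- fit_linear(pc[[i]], linear_window)
        data.frame(label = cc$label, particle_id = i,
                   guv_diameter = trajs[[i]]$guv_diameter,
                   K = ppl$K, alpha = ppl$alpha, D_T = pli$D_T)
      }))
      rd <- msd_at(ens, msd_readout_lag)
      list(ens = ens, pl = pl, lin = lin, pp = pp, rd = rd)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors <- c(errors, sprintf("%s: %s", cc$label, conditionMessage(res)))
      next
    }
    curves[[cc$label]] <- res$ens
    curves_long[[cc$label]] <- data.frame(condition_id = cc$label,
                                          lag_s = res$ens$lag,
                                          msd_um2 = res$ens$msd,
                                          sem_um2 = res$ens$sem,
                                          n = res$ens$n_obs)
    fits[[cc$label]] <- data.frame(
      condition_id = cc$label, fuel = cc$fuel,
      K = res$pl$K, alpha = res$pl$alpha, r2_alpha = res$pl$r_squared,
      D_T = res$lin$D_T, r2_linear = res$lin$r_squared,
      regime = classify_regime(res$pl$alpha),
      alpha_mean = mean(res$pp$alpha), alpha_sd = stats::sd(res$pp$alpha),
      D_T_mean = mean(res$pp$D_T), D_T_sd = stats::sd(res$pp$D_T),
      msd_at_readout = res$rd$msd, msd_readout_lag = res$rd$lag,
      alpha_window_lo = alpha_window[1], alpha_window_hi = alpha_window[2],
      linear_window_lo = linear_window[1], linear_window_hi = linear_window[2])
    pfits[[cc$label]] <- res$pp
  }
  fits <- if (length(fits)) do.call(rbind, fits) else NULL
  pfits <- if (length(pfits)) do.call(rbind, pfits) else NULL
  curves_long <- if (length(curves_long)) do.call(rbind, curves_long) else NULL
  comparisons <- NULL
  labs <- names(curves)
  if (length(labs) >= 2L) {
    comparisons <- do.call(rbind, apply(utils::combn(labs, 2), 2, function(pr) {
      a <- pfits$D_T[pfits$label == pr[1]]
      b <- pfits$D_T[pfits$label == pr[2]]
      cmp <- compare_groups(a, b)
      data.frame(condition_a = pr[1], condition_b = pr[2], metric = "D_T",
                 t_statistic = cmp$t_statistic, p_value = cmp$p_value,
                 significance = cmp$significance)
    }))
  }
  out <- list(conditions = cond_df, msd_curves = curves_long, fits = fits,
              particle_fits = pfits, comparisons = comparisons,
              curves = curves, errors = errors)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(df, nm) if (!is.null(df)) {
      write.csv(df, file.path(out_dir, nm), row.names = FALSE, quote = FALSE)
    }
    wr(cond_df, "conditions.csv")
    wr(curves_long, "msd_curves.csv")
    wr(fits, "fits.csv")
    wr(pfits, "particle_fits.csv")
    wr(comparisons, "comparisons.csv")
    writeLines(c(sprintf("guvmotility %s",
                         as.character(utils::packageVersion("guvmotility"))),
                 sprintf("run at %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
                 sprintf("conditions: %d", nrow(cond_df)),
                 sprintf("config digest: %s",
                         paste(cond_df$label, cond_df$seed, collapse = ";")),
                 if (length(errors)) paste("ERROR", errors) else "no errors"),
               file.path(out_dir, "run.log"))
  }
  out
}

#' Simulate the z-stack concentration readout for a set of GUVs
#'
#' Emulates the confocal concentration assay: each GUV holds a
#' Poisson-distributed number of fluorescent particles placed uniformly in
#' its volume, a 45-plane z-stack is rendered, total fluorescence is summed
#' over the planes and the GUV is assigned to the low/medium/high group.
#' With the default per-particle brightness of 10 a.u., the 100 and
#' 175 a.u. cuts correspond to roughly 10 and 17-18 particles per GUV.
#'
#' @param n_guvs number of GUVs to render.
#' @param mean_particles Poisson mean particle count per GUV.
#' @param guv_radius GUV radius, um.
#' @param intensity_per_particle integrated brightness per particle, a.u.
#' @param noise_sd background noise, a.u.
#' @param seed random seed.
#' @param n_planes planes per z-stack.
#' @return data.frame with `guv_id, n_particles, total_fluorescence, group`.
#' @export
simulate_concentration_readout <- function(n_guvs = 40, mean_particles = 13,
                                           guv_radius = 10,
                                           intensity_per_particle = 10,
                                           noise_sd = 0, seed = 1L,
                                           n_planes = 45) {
  stopifnot(n_guvs >= 1, mean_particles > 0, guv_radius > 0)
  set.seed(seed)
  fov <- c(4 * guv_radius, 4 * guv_radius)
  z_range <- 4 * guv_radius
  out <- lapply(seq_len(n_guvs), function(g) {
    n <- stats::rpois(1, mean_particles)
    pos <- NULL
    if (n > 0) {
      u <- matrix(rnorm(3 * n), n, 3)
      u <- u / sqrt(rowSums(u^2))
      r <- guv_radius * runif(n)^(1 / 3)
      pos <- u * r + matrix(rep(c(fov / 2, z_range / 2), each = n), n, 3)
    }
    stk <- render_zstack(pos, n_planes = n_planes, pixel_size = 1,
                         fov = fov, z_range = z_range, noise_sd = noise_sd,
                         intensity = intensity_per_particle)
    data.frame(guv_id = g, n_particles = n,
               total_fluorescence = total_fluorescence(stk))
  })
  out <- do.call(rbind, out)
  out$group <- classify_concentration(out$total_fluorescence)
  out
}
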