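test_that("GUV size groups partition the studied diameter range", {
  expect_equal(assign_size_group(20), "small")
  expect_equal(assign_size_group(30), "medium")
  expect_equal(assign_size_group(40), "large")
  expect_equal(assign_size_group(c(14, 24, 24.5, 34, 34.5)),
               c("small", "small", "medium", "medium", "large"))
  expect_error(assign_size_group(10), "outside the studied range")
})

test_that("sampled diameters respect group bounds and seeds", {
  set.seed(3)
  s <- sample_guv_diameter("small", 200)
  expect_true(all(s >= 14 & s <= 24))
  l <- sample_guv_diameter("large", 200)
  expect_true(all(l > 34 & l <= 50))
  set.seed(9); a <- sample_guv_diameter("medium", 5)
  set.seed(9); b <- sample_guv_diameter("medium", 5)
  expect_identical(a, b)
})

test_that("confinement ratio is the diameter ratio", {
  expect_equal(confinement_ratio(14), 14 / 1.2, tolerance = 1e-12)
  expect_equal(confinement_ratio(36), 30)
  expect_equal(confinement_ratio(1.2), 1)
  # small and large study groups span roughly 11 to 30
  expect_equal(round(confinement_ratio(14)), 12)
  expect_true(confinement_ratio(50) > 30)
})

test_that("experiment conditions validate their design cell", {
  expect_error(experiment_condition(fuel = -1))
  expect_error(experiment_condition(guv_diameter = 1.0), "")
  expect_error(experiment_condition(membrane = "porous"))
  cc <- experiment_condition("x", fuel = 0.85, guv_diameter = c(14, 34),
                             membrane = "alpha_hemolysin", seed = 5)
  expect_s3_class(cc, "experiment_condition")
  expect_equal(cc$n_crowders, cc$n_particles)
})

test_that("the default design covers all four studies", {
  conds <- default_experiment_config(seed = 2)
  labs <- sapply(conds, `[[`, "label")
  expect_true(any(grepl("^bulk", labs)))
  expect_true(any(grepl("ahl", labs)))
  expect_true(sum(grepl("^guv_fuel[0-9.]+$", labs)) == 4L)
  expect_true(sum(grepl("^size_", labs)) == 9L)
  expect_true(sum(grepl("^crowd_", labs)) == 6L)
  expect_equal(anyDuplicated(sapply(conds, `[[`, "seed")), 0L)
})

test_that("run_experiment produces coherent, reproducible summaries", {
  conds <- list(
    experiment_condition("bulk0", fuel = 0, guv_diameter = "bulk",
                         n_particles = 4, seed = 21),
    experiment_condition("guv0", fuel = 0, guv_diameter = c(14, 34),
                         n_particles = 4, seed = 22))
  acq <- acquisition_params(duration = 20)
  out <- run_experiment(conds, acq = acq, alpha_window = c(0.2, 5),
                        linear_window = c(0.2, 3), msd_readout_lag = 5,
                        out_dir = file.path(tempdir(), "gmrun"))
  expect_equal(nrow(out$fits), 2L)
  expect_equal(sort(out$fits$condition_id), c("bulk0", "guv0"))
  expect_true(all(out$fits$K > 0))
  expect_true(all(out$fits$regime %in%
                    c("subdiffusive", "normal", "superdiffusive")))
  expect_equal(nrow(out$particle_fits), 8L)
  expect_equal(nrow(out$comparisons), 1L)
  expect_length(out$errors, 0L)
  expect_true(all(file.exists(file.path(tempdir(), "gmrun",
    c("conditions.csv", "msd_curves.csv", "fits.csv",
      "particle_fits.csv", "comparisons.csv", "run.log")))))
  out2 <- run_experiment(conds, acq = acq, alpha_window = c(0.2, 5),
                         linear_window = c(0.2, 3), msd_readout_lag = 5)
  expect_equal(out$fits$alpha, out2$fits$alpha)
  expect_equal(out$fits$D_T, out2$fits$D_T)
  # empty condition list is a successful no-op
  empty <- run_experiment(list(), acq = acq)
  expect_null(empty$fits)
  expect_length(empty$errors, 0L)
})

test_that("z-stack readout ties particle counts to concentration groups", {
  df <- simulate_concentration_readout(n_guvs = 8, mean_particles = 13,
                                       guv_radius = 8, seed = 4)
  expect_equal(nrow(df), 8L)
  expect_equal(df$group, classify_concentration(df$total_fluorescence))
  # fluorescence is (near-)proportional to the encapsulated particle count
  expect_equal(df$total_fluorescence, 10 * df$n_particles, tolerance = 0.05)
  df2 <- simulate_concentration_readout(n_guvs = 8, mean_particles = 13,
                                        guv_radius = 8, seed = 4)
  expect_identical(df, df2)
})

test_that("YAML run configurations round trip through the reader", {
  cfg <- list(
    motor = list(D_T0 = 0.15, v_max = 2, K_fuel = 0.5),
    acquisition = list(duration = 30, seed = 7),
    analysis = list(alpha_window = c(0.2, 8)),
    conditions = list(
      list(label = "a", fuel = 0.85, guv_diameter = c(14, 34),
           n_particles = 3, seed = 1),
      list(label = "b", fuel = 0, guv_diameter = "bulk",
           n_particles = 3, seed = 2)))
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, path)
  got <- read_run_config(path)
  expect_equal(got$motor$D_T0, 0.15)
  expect_equal(got$motor$tau_R, 2)  # defaults fill unspecified fields
  expect_equal(got$acq$duration, 30)
  expect_equal(got$analysis$alpha_window, c(0.2, 8))
  expect_equal(got$analysis$linear_window, c(0.2, 3))
  expect_length(got$conditions, 2L)
  expect_equal(got$conditions[[1]]$fuel, 0.85)
  expect_identical(got$conditions[[2]]$guv_diameter, "bulk")
})

test_that("trajectory tables round trip through CSV", {
  cond <- experiment_condition("rt", fuel = 0, guv_diameter = 20,
                               n_particles = 3, seed = 77)
  trs <- simulate_condition(cond, acq = acquisition_params(duration = 5))
  path <- tempfile(fileext = ".csv")
  write_trajectory_csv(trs, path, condition_id = "rt")
  df <- read.csv(path)
  expect_named(df, c("condition_id", "guv_id", "particle_id", "frame",
                     "time_s", "x_um", "y_um", "z_um"))
  back <- read_trajectory_csv(path)
  expect_length(back, 3L)
  orig <- trs[order(sapply(trs, `[[`, "particle_id"))]
  back <- back[order(sapply(back, `[[`, "particle_id"))]
  for (i in 1:3) {
    expect_equal(back[[i]]$xy, orig[[i]]$xy, tolerance = 1e-9)
    expect_equal(back[[i]]$times, orig[[i]]$times)
  }
})
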