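#' Convert trajectories to a flat table
#'
#' Long-format table with one row per recorded frame, the interchange format
#' shared by the simulator, the tracker and the analysis side. Columns:
#' `condition_id, guv_id, particle_id, frame, time_s, x_um, y_um` and, for
#' simulated trajectories, `z_um`.
#'
#' @param trajs list of [trajectory()] objects (or a single one).
#' @param condition_id condition label recycled over rows.
#' @return a `data.frame`.
#' @export
trajectories_to_df <- function(trajs, condition_id = "cond1") {
  if (inherits(trajs, "trajectory")) trajs <- list(trajs)
  stopifnot(length(trajs) >= 1L)
  do.call(rbind, lapply(trajs, function(tr) {
    n <- length(tr$times)
    df <- data.frame(condition_id = condition_id,
                     guv_id = tr$guv_id,
                     particle_id = tr$particle_id,
                     frame = seq_len(n) - 1L,
                     time_s = tr$times,
                     x_um = tr$xy[, 1],
                     y_um = tr$xy[, 2])
    if (!is.null(tr$z)) df$z_um <- tr$z
    df
  }))
}

#' Write trajectories to CSV
#'
#' @param trajs list of [trajectory()] objects or a flat table from
#'   [trajectories_to_df()].
#' @param path output file.
#' @param condition_id condition label when `trajs` is a list.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(trajs, path, condition_id = "cond1") {
  df <- if (is.data.frame(trajs)) trajs else {
    trajectories_to_df(trajs, condition_id)
  }
  write.csv(df, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read trajectories from CSV
#'
#' Inverse of [write_trajectory_csv()]: splits the flat table back into
#' [trajectory()] objects (one per `condition_id` x `guv_id` x
#' `particle_id`).
#'
#' @param path CSV file with the standard trajectory columns.
#' @return list of [trajectory()] objects.
#' @export
read_trajectory_csv <- function(path) {
  df <- read.csv(path, fileEncoding = "UTF-8")
  need <- c("particle_id", "frame", "time_s", "x_um", "y_um")
  if (!all(need %in% names(df))) {
    stop("read_trajectory_csv: missing required columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  if (is.null(df$condition_id)) df$condition_id <- "cond1"
  if (is.null(df$guv_id)) df$guv_id <- NA_integer_
  key <- interaction(df$condition_id, df$guv_id, df$particle_id, drop = TRUE)
  lapply(split(df, key), function(d) {
    d <- d[order(d$frame), ]
    trajectory(times = d$time_s, xy = cbind(d$x_um, d$y_um),
               particle_id = d$particle_id[1],
               z = if (!is.null(d$z_um)) d$z_um else NULL,
               guv_id = d$guv_id[1])
  })
}

#' Read a run configuration from YAML
#'
#' A run configuration has optional `motor`, `acquisition` and `analysis`
#' blocks (overriding the package defaults field by field) and a
#' `conditions` list, each entry holding the fields of
#' [experiment_condition()].
#'
#' @param path YAML file.
#' @return list with elements `motor` ([motor_params()]), `acq`
#'   ([acquisition_params()]), `analysis` (list of fit windows) and
#'   `conditions` (list of [experiment_condition()]).
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  motor <- do.call(motor_params, raw$motor %||% list())
  acq <- do.call(acquisition_params, raw$acquisition %||% list())
  analysis <- modifyList(list(alpha_window = c(0.2, 10),
                              linear_window = c(0.2, 3)),
                         raw$analysis %||% list())
  conds <- lapply(raw$conditions %||% list(), function(cc) {
    do.call(experiment_condition, cc)
  })
  list(motor = motor, acq = acq, analysis = analysis, conditions = conds)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
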