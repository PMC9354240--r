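#' Time-averaged mean-square displacement of one trajectory
#'
#' For each lag `k * dt` up to `max_lag`, averages the squared XY
#' displacement over all overlapping pairs of frames,
#' `mean(|r(t + k dt) - r(t)|^2)`. This time-averaged estimator uses every
#' pair of frames, the standard practice for 60 s single-particle-tracking
#' videos where per-particle statistics are scarce.
#'
#' @param traj a [trajectory()].
#' @param max_lag largest lag, s; defaults to half the trajectory duration.
#' @return An `msd_curve`: data.frame with columns `lag, msd, sem, n_obs`.
#'   `sem` here is the spread over the overlapping pairs within this single
#'   trajectory; curve-to-curve SEM comes from [ensemble_msd()].
#' @export
#' @examples
#' tr <- trajectory(times = 0:4, xy = cbind(c(0, 1, 1, 2, 2), c(0, 0, 1, 1, 2)))
#' tamsd(tr)  # msd(1 s) = 1, msd(2 s) = 2
tamsd <- function(traj, max_lag = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  n <- nrow(traj$xy)
  if (n < 2L) stop("tamsd: trajectory must have at least 2 frames")
  dt <- traj$times[2] - traj$times[1]
  duration <- traj$times[n] - traj$times[1]
  if (is.null(max_lag)) max_lag <- duration / 2
  if (max_lag >= duration + 1e-9) {
    stop("tamsd: max_lag must be smaller than the trajectory duration")
  }
  k_max <- min(as.integer(floor(max_lag / dt + 1e-9)), n - 1L)
  x <- traj$xy[, 1]
  y <- traj$xy[, 2]
  out <- vapply(seq_len(k_max), function(k) {
    dx <- x[(1L + k):n] - x[1L:(n - k)]
    dy <- y[(1L + k):n] - y[1L:(n - k)]
    sq <- dx * dx + dy * dy
    c(mean(sq), stats::sd(sq) / sqrt(length(sq)), length(sq))
  }, numeric(3))
  structure(data.frame(lag = seq_len(k_max) * dt,
                       msd = out[1, ], sem = out[2, ],
                       n_obs = as.integer(out[3, ])),
            class = c("msd_curve", "data.frame"))
}

#' Ensemble average of MSD curves
#'
#' Per-lag unweighted mean over particles with SEM = sd / sqrt(n_particles),
#' the "mean +/- SEM" representation used for MSD plots. Curves are
#' intersected on their common lag grid.
#'
#' @param curves list of `msd_curve` objects (from [tamsd()]).
#' @return an `msd_curve` with `n_obs` = number of particles per lag.
#' @export
ensemble_msd <- function(curves) {
  if (inherits(curves, "msd_curve")) curves <- list(curves)
  if (length(curves) == 0L) stop("ensemble_msd: empty input")
  stopifnot(all(vapply(curves, inherits, logical(1), "msd_curve")))
  lags <- Reduce(function(a, b) a[a %in% b],
                 lapply(curves, function(cu) round(cu$lag, 9)))
  if (length(lags) == 0L) stop("ensemble_msd: curves share no lags")
  mat <- vapply(curves, function(cu) {
    cu$msd[match(lags, round(cu$lag, 9))]
  }, numeric(length(lags)))
  mat <- matrix(mat, nrow = length(lags))
  n <- ncol(mat)
  structure(data.frame(lag = lags,
                       msd = rowMeans(mat),
                       sem = if (n > 1) apply(mat, 1, stats::sd) / sqrt(n)
                             else rep(NA_real_, length(lags)),
                       n_obs = n),
            class = c("msd_curve", "data.frame"))
}

.window_idx <- function(curve, window) {
  stopifnot(length(window) == 2L, window[1] < window[2])
  which(curve$lag >= window[1] - 1e-9 & curve$lag <= window[2] + 1e-9)
}

#' Fit the anomalous-diffusion power law
#'
#' Fits `MSD = K * dt^alpha` by ordinary least squares of `log(msd)` on
#' `log(lag)` over the given lag window: `alpha` is the slope and `K` the
#' exponentiated intercept. `alpha = 1` indicates Brownian (normal)
#' diffusion, `alpha < 1` sub-diffusion (constrained motion) and
#' `alpha > 1` superdiffusion.
#'
#' @param curve an `msd_curve`.
#' @param window lag window `c(min, max)`, s; default 0.2-10 s (confinement
#'   dominates the curve only beyond ~6 s, so the window must reach past it
#'   to sense sub-diffusion).
#' @return list with `K` (um^2/s^alpha), `alpha`, `r_squared`, `window`.
#' @export
#' @examples
#' cu <- structure(data.frame(lag = seq(0.2, 10, 0.2)), class = c("msd_curve", "data.frame"))
#' cu$msd <- 1.0 * cu$lag^0.5
#' fit_power_law(cu)$alpha  # 0.5
fit_power_law <- function(curve, window = c(0.2, 10)) {
  stopifnot(inherits(curve, "msd_curve"))
  idx <- .window_idx(curve, window)
  if (length(idx) < 4L) stop("fit_power_law: need at least 4 lags in window")
  if (any(curve$msd[idx] <= 0)) {
    stop("fit_power_law: msd must be positive throughout the window")
  }
  lx <- log(curve$lag[idx])
  ly <- log(curve$msd[idx])
  fit <- stats::lm(ly ~ lx)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((ly - mean(ly))^2)
  list(K = unname(exp(coef(fit)[1])),
       alpha = unname(coef(fit)[2]),
       r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1,
       window = window)
}

#' Fit the linear (Brownian) MSD law
#'
#' Fits `MSD = 4 * D_T * dt` by least squares through the origin over the
#' short-lag window (default the first 3 s), where confinement has a
#' negligible effect on the curve and alpha = 1 is a safe assumption.
#'
#' @param curve an `msd_curve`.
#' @param window lag window `c(min, max)`, s.
#' @return list with `D_T` (um^2/s), `r_squared`, `window`.
#' @export
fit_linear <- function(curve, window = c(0.2, 3)) {
  stopifnot(inherits(curve, "msd_curve"))
  idx <- .window_idx(curve, window)
  if (length(idx) < 3L) stop("fit_linear: need at least 3 lags in window")
  x <- curve$lag[idx]
  y <- curve$msd[idx]
  slope <- sum(x * y) / sum(x * x)
  ss_res <- sum((y - slope * x)^2)
  ss_tot <- sum((y - mean(y))^2)
  list(D_T = slope / 4,
       r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1,
       window = window)
}

#' Classify the diffusion regime from the anomalous exponent
#'
#' `|alpha - 1| <= tol` is normal (Brownian) diffusion, `alpha < 1 - tol`
#' sub-diffusive, `alpha > 1 + tol` superdiffusive. The default tolerance
#' 0.05 treats fitted exponents such as 1.01 as normal diffusion.
#'
#' @param alpha fitted anomalous exponent.
#' @param tol half-width of the "normal" band.
#' @return one of `"subdiffusive"`, `"normal"`, `"superdiffusive"`.
#' @export
classify_regime <- function(alpha, tol = 0.05) {
  stopifnot(is.finite(alpha), tol >= 0)
  if (abs(alpha - 1) <= tol) "normal"
  else if (alpha < 1 - tol) "subdiffusive"
  else "superdiffusive"
}

#' MSD value at a given lag
#'
#' Exact on-grid lookup (no interpolation); an off-grid lag snaps to the
#' nearest grid point. Used e.g. to read the MSD at 10 s when comparing
#' particle-concentration groups.
#'
#' @param curve an `msd_curve`.
#' @param lag lag time, s.
#' @return list with `lag` (the grid lag used), `msd`, `sem`.
#' @export
msd_at <- function(curve, lag) {
  stopifnot(inherits(curve, "msd_curve"), is.finite(lag), lag > 0)
  if (lag > max(curve$lag) + 1e-9) {
    stop("msd_at: lag exceeds the largest available lag")
  }
  i <- which.min(abs(curve$lag - lag))
  list(lag = curve$lag[i], msd = curve$msd[i], sem = curve$sem[i])
}

#' Two-sample comparison of motility metrics
#'
#' Two-tailed two-sample t-test between condition groups (fitted alpha,
#' D_T, or MSD readouts). Welch's unequal-variance variant is the default;
#' the pooled-variance Student variant is available by flag. Identical
#' zero-variance groups are reported as `p = 1` with a warning rather than
#' an error. Significance tiers: `*` p < 0.05, `**` p < 0.01,
#' `***` p < 0.001.
#'
#' @param values_a,values_b numeric vectors, each of length >= 2.
#' @param welch use Welch's variant (default) or pooled-variance Student.
#' @return list with `t_statistic`, `p_value`, `significance` (one of
#'   `"ns"`, `"*"`, `"**"`, `"***"`).
#' @export
compare_groups <- function(values_a, values_b, welch = TRUE) {
  stopifnot(length(values_a) >= 2L, length(values_b) >= 2L)
  if (stats::sd(values_a) == 0 && stats::sd(values_b) == 0 &&
      values_a[1] == values_b[1]) {
    warning("compare_groups: identical zero-variance groups; p = 1")
    res <- list(t_statistic = 0, p_value = 1)
  } else {
    tt <- stats::t.test(values_a, values_b, var.equal = !welch)
    res <- list(t_statistic = unname(tt$statistic), p_value = tt$p.value)
  }
  res$significance <- if (res$p_value < 0.001) "***"
  else if (res$p_value < 0.01) "**"
  else if (res$p_value < 0.05) "*"
  else "ns"
  res
}

#' Write an MSD curve to CSV
#'
#' Columns `lag_s, msd_um2, sem_um2, n`.
#'
#' @param curve an `msd_curve`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_msd_csv <- function(curve, path) {
  stopifnot(inherits(curve, "msd_curve"))
  df <- data.frame(lag_s = curve$lag, msd_um2 = curve$msd,
                   sem_um2 = curve$sem, n = curve$n_obs)
  write.csv(df, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
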