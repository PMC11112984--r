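# Trajectory and reconstruction-quality analytics: time-averaged MSD,
# localization precision, depth-error statistics, drift velocity.

# coerce either a trajectory_set, a tidy track table, or a single-track
# data.frame into a list of per-track data.frames (frame, time_s, coords)
as_track_list <- function(traj) {
  if (inherits(traj, "trajectory_set")) traj <- traj$tracks
  stopifnot(is.data.frame(traj))
  if (!"track_id" %in% names(traj)) traj$track_id <- 1L
  if (!"time_s" %in% names(traj)) traj$time_s <- traj$frame
  lapply(split(traj, traj$track_id), function(tr)
    tr[order(tr$frame), , drop = FALSE])
}

#' Time-averaged mean squared displacement
#'
#' Overlapping time-average estimator: at lag `L` frames, all ordered
#' observation pairs `(f, f + L)` contribute `|r(f+L) - r(f)|^2` over the
#' selected dimensions. Pairs spanning missing frames (including bridged
#' gaps) are excluded, so gap links never contribute displacement pairs.
#' Set `overlapping = FALSE` for the non-overlapping variant (independent
#' windows `f = 0, L, 2L, ...`).
#'
#' @param traj A single-track `data.frame` with `frame, time_s, x_um, y_um,
#'   z_um` (or a `trajectory_set` with exactly one track).
#' @param dims Subset of `c("x", "y", "z")`. Default all three.
#' @param max_lag_fraction Longest lag as a fraction of the track duration.
#'   Default 0.5.
#' @param overlapping Use all ordered pairs (default) or disjoint windows.
#' @return `data.frame` (class `msd_curve`) with `lag_s, msd_um2, n_pairs`,
#'   starting at lag 0 (msd 0 by definition).
#' @export
compute_msd <- function(traj, dims = c("x", "y", "z"),
                        max_lag_fraction = 0.5, overlapping = TRUE) {
  tl <- as_track_list(traj)
  if (length(tl) != 1L)
    stop("compute_msd expects a single trajectory; got ", length(tl))
  tr <- tl[[1L]]
  if (nrow(tr) < 2L) stop("trajectory must have at least 2 observations")
  dims <- match.arg(dims, c("x", "y", "z"), several.ok = TRUE)
  cols <- paste0(dims, "_um")
  dt <- if (nrow(tr) >= 2L) min(diff(tr$time_s) / diff(tr$frame)) else 1
  frames <- tr$frame
  span <- max(frames) - min(frames)
  max_lag <- max(1L, floor(span * max_lag_fraction))
  pos <- as.matrix(tr[, cols, drop = FALSE])
  fmin <- min(frames)
  offs <- frames - fmin                     # 0-based frame offsets
  pres <- rep(FALSE, span + 1L)
  pres[offs + 1L] <- TRUE
  row_at <- rep(NA_integer_, span + 1L)
  row_at[offs + 1L] <- seq_len(nrow(tr))
  cum <- c(0L, cumsum(pres))
  lags <- seq_len(max_lag)
  res <- lapply(lags, function(L) {
    o0 <- if (overlapping) offs else offs[offs %% L == 0]
    o0 <- o0[o0 + L <= span]
    o0 <- o0[pres[o0 + L + 1L]]
    # a pair (f, f+L) is valid only if every intermediate frame is present
    o0 <- o0[cum[o0 + L + 2L] - cum[o0 + 1L] == L + 1L]
    if (!length(o0)) return(c(NA_real_, 0))
    i0 <- row_at[o0 + 1L]
    i1 <- row_at[o0 + L + 1L]
    d2 <- rowSums((pos[i1, , drop = FALSE] - pos[i0, , drop = FALSE])^2)
    c(mean(d2), length(d2))
  })
  res <- do.call(rbind, res)
  out <- data.frame(lag_s = c(0, lags * dt),
                    msd_um2 = c(0, res[, 1L]),
                    n_pairs = c(nrow(tr), res[, 2L]))
  out <- out[!is.na(out$msd_um2), , drop = FALSE]
  class(out) <- c("msd_curve", "data.frame")
  out
}

#' Fit a diffusion coefficient from an MSD curve
#'
#' Least-squares slope of `msd(tau)` through the origin over the first
#' `n_lags` non-zero lags; for d-dimensional Brownian motion
#' `msd(tau) = 2 d D tau`, so `D = slope / (2 d)`.
#'
#' @param msd An `msd_curve` from [compute_msd()].
#' @param n_lags Number of initial non-zero lags to fit. Default 10.
#' @param dims Dimensionality d the curve was computed over. Default 3.
#' @return List with `slope_um2_per_s` and `D_um2_per_s`.
#' @export
fit_msd_diffusion <- function(msd, n_lags = 10L, dims = 3L) {
  m <- msd[msd$lag_s > 0, , drop = FALSE]
  m <- m[seq_len(min(n_lags, nrow(m))), , drop = FALSE]
  slope <- sum(m$lag_s * m$msd_um2) / sum(m$lag_s^2)
  list(slope_um2_per_s = slope, D_um2_per_s = slope / (2 * dims))
}

#' Localization precision of a nominally stationary particle
#'
#' Per-axis sample standard deviation of the reconstructed coordinates
#' across frames. Requires at least 10 observations.
#'
#' @param traj Single-track table with `x_um, y_um, z_um`.
#' @return List (class `precision_report`) with `sd_x_um, sd_y_um, sd_z_um,
#'   n_frames`.
#' @export
localization_precision <- function(traj) {
  tl <- as_track_list(traj)
  if (length(tl) != 1L)
    stop("localization_precision expects a single trajectory")
  tr <- tl[[1L]]
  if (nrow(tr) < 10L)
    stop("need at least 10 frames to estimate precision; got ", nrow(tr))
  structure(list(sd_x_um = stats::sd(tr$x_um),
                 sd_y_um = stats::sd(tr$y_um),
                 sd_z_um = stats::sd(tr$z_um),
                 n_frames = nrow(tr)),
            class = "precision_report")
}

#' @export
print.precision_report <- function(x, ...) {
  cat(sprintf("<precision_report> sd x/y/z = %.3f / %.3f / %.3f um (n = %d)\n",
              x$sd_x_um, x$sd_y_um, x$sd_z_um, x$n_frames))
  invisible(x)
}

#' Depth-error statistics against ground truth
#'
#' Pairs estimated and true depths by particle `id` and reports absolute
#' depth errors, their mean, and a `fraction_below(threshold)` accessor
#' (the empirical CDF of the error).
#'
#' @param estimates `data.frame` with columns `id, z_um`.
#' @param ground_truth `data.frame` with columns `id, z_um`.
#' @return List (class `depth_error_report`) with `errors_um`, `mean_um`,
#'   `n`, and function `fraction_below(threshold_um)` returning the
#'   fraction of errors strictly below the threshold.
#' @export
depth_error_report <- function(estimates, ground_truth) {
  stopifnot(all(c("id", "z_um") %in% names(estimates)),
            all(c("id", "z_um") %in% names(ground_truth)))
  if (anyDuplicated(estimates$id) || anyDuplicated(ground_truth$id))
    stop("duplicate ids in estimates or ground truth")
  if (!all(estimates$id %in% ground_truth$id))
    stop("estimates contain ids missing from the ground truth")
  gt <- ground_truth[match(estimates$id, ground_truth$id), ]
  errors <- abs(estimates$z_um - gt$z_um)
  structure(list(errors_um = errors,
                 mean_um = mean(errors),
                 n = length(errors),
                 fraction_below = function(threshold_um)
                   mean(errors < threshold_um)),
            class = "depth_error_report")
}

#' @export
print.depth_error_report <- function(x, ...) {
  cat(sprintf(
    "<depth_error_report> n = %d, mean |dz| = %.3f um, <2 um: %.1f%%, <5 um: %.1f%%\n",
    x$n, x$mean_um, 100 * x$fraction_below(2), 100 * x$fraction_below(5)))
  invisible(x)
}

#' Pair reconstructed particles with ground-truth scene beads
#'
#' Assigns each reconstructed particle the id of the nearest ground-truth
#' particle in the lateral (x, y) plane by optimal one-to-one assignment,
#' so depth estimates can be scored against the simulator truth without
#' using the depth being tested. Errors if the pairing is ambiguous
#' (fewer truth particles than estimates).
#'
#' @param particles `data.frame` with `x_um, y_um, z_um` (e.g. from
#'   [reconstruct_3d()]).
#' @param truth A `particle_scene` or truth table with `id, x_um, y_um`.
#' @return `particles` with an added `id` column.
#' @export
pair_with_truth <- function(particles, truth) {
  if (nrow(particles) > nrow(truth))
    stop("more estimates than ground-truth particles")
  d <- sqrt(outer(particles$x_um, truth$x_um, `-`)^2 +
              outer(particles$y_um, truth$y_um, `-`)^2)
  assign <- solve_assignment(d)
  particles$id <- truth$id[assign]
  particles
}

#' Mean drift velocity of an ensemble of trajectories
#'
#' For each trajectory, the least-squares slope of the chosen coordinate
#' against time; the estimate is the mean slope across trajectories
#' (each trajectory weighted equally).
#'
#' @param traj A `trajectory_set` or tidy track table.
#' @param axis One of `"x"`, `"y"`, `"z"`.
#' @return Mean velocity along the axis, um/s.
#' @export
drift_velocity <- function(traj, axis = c("z", "x", "y")) {
  axis <- match.arg(axis)
  col <- paste0(axis, "_um")
  tl <- as_track_list(traj)
  slopes <- vapply(tl, function(tr) {
    if (nrow(tr) < 2L) return(NA_real_)
    t <- tr$time_s - mean(tr$time_s)
    sum(t * (tr[[col]] - mean(tr[[col]]))) / sum(t^2)
  }, numeric(1))
  mean(slopes, na.rm = TRUE)
}
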