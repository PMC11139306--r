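#' Resample a trajectory onto the common analysis grid
#'
#' Linear interpolation of the (t, x) path onto a fixed grid of
#' `rate * duration_ms / 1000` samples (200 at the defaults), starting at 0.
#' Samples requested beyond the last observation hold the final observed
#' value (the response has been registered); samples before the first
#' observation hold the first value.
#'
#' @param t_ms strictly increasing timestamps, ms.
#' @param x scale coordinate per sample.
#' @param rate target rate in Hz.
#' @param duration_ms grid duration in ms.
#' @return list(t_ms, x) on the fixed grid.
#' @export
resample_trajectory <- function(t_ms, x, rate = 100, duration_ms = 2000) {
  if (length(t_ms) < 2L) stop("trajectory needs at least 2 samples")
  if (any(diff(t_ms) <= 0)) stop("timestamps must be strictly increasing")
  step <- 1000 / rate
  grid <- seq(0, duration_ms - step, by = step)
  out <- approx(t_ms, x, xout = grid, method = "linear", rule = 2)
  list(t_ms = grid, x = out$y)
}

#' Normalize a raw trajectory coordinate to the [-1, 1] scale
#'
#' Affine map sending the two ends of the response scale to -1 and +1, then a
#' sign flip for blocks presented with the scale reversed so that +1 always
#' denotes the high pole (unswapped coordinates).
#'
#' @param x_raw raw coordinates (e.g., pixels).
#' @param scale_lo,scale_hi raw coordinates of the scale ends as displayed.
#' @param scale_orientation "low_to_high" or "high_to_low".
#' @return normalized coordinates on [-1, 1].
#' @export
normalize_trajectory <- function(x_raw, scale_lo, scale_hi,
                                 scale_orientation = c("low_to_high",
                                                       "high_to_low")) {
  scale_orientation <- match.arg(scale_orientation)
  width <- scale_hi - scale_lo
  if (width == 0) stop("zero-width scale")
  x <- 2 * (x_raw - scale_lo) / width - 1
  if (scale_orientation == "high_to_low") x <- -x
  x
}

#' Assemble resampled trajectories of one participant into a matrix
#'
#' @param trajs a `trajectory_set` (long data.frame trial_id, t_ms, x).
#' @param trial_ids which trials to include, in order.
#' @param rate,duration_ms grid parameters, see [resample_trajectory()].
#' @return list(x = trials x time matrix, t_ms = grid).
#' @export
trajectory_matrix <- function(trajs, trial_ids, rate = 100,
                              duration_ms = 2000) {
  step <- 1000 / rate
  grid <- seq(0, duration_ms - step, by = step)
  idx <- split(seq_len(nrow(trajs)), trajs$trial_id)
  xmat <- matrix(NA_real_, length(trial_ids), length(grid))
  for (k in seq_along(trial_ids)) {
    rows <- idx[[trial_ids[k]]]
    if (is.null(rows)) stop(sprintf("trajectory '%s' not found", trial_ids[k]))
    r <- resample_trajectory(trajs$t_ms[rows], trajs$x[rows],
                             rate = rate, duration_ms = duration_ms)
    xmat[k, ] <- r$x
  }
  list(x = xmat, t_ms = grid)
}

#' Per-timepoint regression of trajectory position on antonym pole
#'
#' At each timepoint, ordinary least squares of the scale coordinate on the
#' pole predictor coded low = -1 / high = +1, with intercept. With this
#' coding the slope at time t is half the difference between the high-pole
#' and low-pole mean positions: positive beta means movement toward the
#' adjective's own pole, negative beta toward the antonym.
#'
#' @param xmat trials x time matrix of resampled trajectories.
#' @param pole character/factor of "low"/"high" per trial.
#' @param t_ms the time grid.
#' @return a `beta_series`: list(times_ms, beta).
#' @export
timepoint_regression <- function(xmat, pole, t_ms) {
  pole <- as.character(pole)
  if (length(unique(pole)) < 2L)
    stop("both antonym poles must be present")
  code <- ifelse(pole == "high", 1, -1)
  cc <- code - mean(code)
  beta <- as.numeric(crossprod(cc, xmat)) / sum(cc^2)
  structure(list(times_ms = t_ms, beta = beta), class = "beta_series")
}

#' Group-level cluster inference on per-participant beta series
#'
#' Stacks the per-participant beta series into a participants x time matrix
#' and delegates to [one_sample_cluster_test()] over the requested window
#' (by default from adjective onset up to 1.4 s after it, i.e., 600-2000 ms
#' on the trial clock).
#'
#' @param betas list of `beta_series`, one per participant, on a common grid.
#' @param window c(start, end) ms on the trajectory clock.
#' @param n_perm number of sign-flip permutations.
#' @param tail "two_sided" (default; positive and negative clusters reported
#'   separately), "greater" or "less".
#' @param seed optional seed for the permutations.
#' @return a `cluster_test` object.
#' @export
group_beta_inference <- function(betas, window = c(600, 2000),
                                 n_perm = 10000, tail = "two_sided",
                                 seed = NULL) {
  if (length(betas) < 2L) stop("need >= 2 participants")
  times <- betas[[1]]$times_ms
  mat <- do.call(rbind, lapply(betas, function(b) {
    stopifnot(identical(b$times_ms, times))
    b$beta
  }))
  one_sample_cluster_test(mat, times, window = window, n_perm = n_perm,
                          tail = tail, seed = seed)
}
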