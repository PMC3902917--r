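# Mean-square-displacement estimation and apparent diffusion coefficients.

#' Compute the mean square displacement of a trajectory
#'
#' MSD as a function of lag time on the long axis, short axis, or in 2D. In
#' `time_avg` mode the MSD at lag `k * dt` is the mean squared displacement
#' over *all* ordered pairs `(i, i + k)` within the track; in `ensemble`
#' mode only the displacement from the first point is used (one pair per
#' lag), the convention used when curves are subsequently averaged across
#' many synchronised tracks. Lags are multiples of the native frame interval
#' only; no interpolation.
#'
#' @param traj a [trajectory()].
#' @param axis `"long"`, `"short"`, or `"2d"` (sum of both axes).
#' @param max_lag largest lag in seconds; defaults to half the track span
#'   (larger lags have too few pairs to be useful).
#' @param mode `"time_avg"` (default) or `"ensemble"`.
#' @return An `msd_curve`: data frame with columns `lag_s`, `msd_um2`,
#'   `n_pairs`, and attributes `axis` and `mode`. `n_pairs` is
#'   non-increasing in lag.
#' @examples
#' tr <- trajectory(t_s = 0:3, x_um = c(0, 1, 2, 3), y_um = numeric(4))
#' compute_msd(tr, axis = "long") # ballistic: 1, 4 um^2 at lags 1, 2 s
#' @export
compute_msd <- function(traj, axis = c("long", "short", "2d"), max_lag = NULL,
                        mode = c("time_avg", "ensemble")) {
  axis <- match.arg(axis)
  mode <- match.arg(mode)
  if (!is.data.frame(traj) || nrow(traj) < 2L)
    stop("'traj' must be a trajectory with at least 2 points", call. = FALSE)
  dt <- traj_dt(traj)
  n <- nrow(traj)
  span <- traj$t_s[n] - traj$t_s[1]
  if (is.null(max_lag)) max_lag <- span / 2
  kmax <- min(n - 1L, floor(max_lag / dt + 1e-9))
  if (kmax < 1L) stop("max_lag below one frame interval", call. = FALSE)
  x <- traj$x_um; y <- traj$y_um
  lag_s <- msd <- numeric(kmax)
  n_pairs <- integer(kmax)
  for (k in seq_len(kmax)) {
    if (mode == "time_avg") {
      dx <- x[(k + 1L):n] - x[1L:(n - k)]
      dy <- y[(k + 1L):n] - y[1L:(n - k)]
    } else {
      dx <- x[k + 1L] - x[1L]
      dy <- y[k + 1L] - y[1L]
    }
    sq <- switch(axis, long = dx^2, short = dy^2, `2d` = dx^2 + dy^2)
    lag_s[k] <- k * dt
    msd[k] <- mean(sq)
    n_pairs[k] <- length(sq)
  }
  out <- data.frame(lag_s = lag_s, msd_um2 = msd, n_pairs = n_pairs)
  attr(out, "axis") <- axis
  attr(out, "mode") <- mode
  class(out) <- c("msd_curve", "data.frame")
  out
}

#' Average MSD curves across tracks
#'
#' Per-lag average of several `msd_curve`s on a common lag grid, weighted by
#' the number of displacement pairs behind each point (the small-N
#' single-particle convention). Lags present in only some curves are kept;
#' their weights reflect the contributing tracks only.
#'
#' @param curves list of `msd_curve` objects on compatible lag grids.
#' @return A single `msd_curve` whose `n_pairs` column holds summed weights.
#' @export
average_msd <- function(curves) {
  if (!length(curves)) stop("no curves to average", call. = FALSE)
  all_lags <- sort(unique(unlist(lapply(curves, function(cu) cu$lag_s))))
  msd <- w <- numeric(length(all_lags))
  for (cu in curves) {
    idx <- match(round(cu$lag_s, 9), round(all_lags, 9))
    msd[idx] <- msd[idx] + cu$msd_um2 * cu$n_pairs
    w[idx] <- w[idx] + cu$n_pairs
  }
  out <- data.frame(lag_s = all_lags, msd_um2 = msd / w,
                    n_pairs = as.integer(w))
  attr(out, "axis") <- attr(curves[[1]], "axis")
  attr(out, "mode") <- "averaged"
  class(out) <- c("msd_curve", "data.frame")
  out
}

#' @export
plot.msd_curve <- function(x, ...) {
  plot(x$lag_s, x$msd_um2, xlab = "lag (s)",
       ylab = expression(MSD ~ (mu * m^2)), pch = 16, ...)
  invisible(x)
}

#' Apparent diffusion coefficient from an MSD value
#'
#' `D_app = MSD / (tau * q_i)`, with `q_i` the dimensionality factor: 2 for
#' a single axis, 4 for two dimensions. Applied at the printed positional
#' change of 0.20 um per 5 s (MSD 0.04 um^2, `q_i = 4`) this gives
#' 2.0e-3 um^2/s.
#'
#' @param msd_um2 mean square displacement (um^2) at lag `tau`.
#' @param tau lag time (s), `> 0`.
#' @param q_i dimensionality factor, 2 (per axis) or 4 (2D).
#' @return A `diffusion_estimate`: list with `d_app` (um^2/s), `tau`, `q_i`.
#' @examples
#' compute_dapp(0.20^2, tau = 5, q_i = 4)$d_app # 2e-3 um^2/s
#' @export
compute_dapp <- function(msd_um2, tau, q_i = 4) {
  check_num(msd_um2, "msd_um2", lower = 0)
  check_num(tau, "tau", lower = 0, strict_lower = TRUE)
  if (!q_i %in% c(2, 4)) stop("q_i must be 2 (per axis) or 4 (2D)", call. = FALSE)
  structure(list(d_app = msd_um2 / (tau * q_i), tau = tau, q_i = q_i),
            class = "diffusion_estimate")
}

#' @export
print.diffusion_estimate <- function(x, ...) {
  cat(sprintf("D_app = %.3g um^2/s (tau = %g s, q_i = %d)\n",
              x$d_app, x$tau, x$q_i))
  invisible(x)
}

#' Per-interval step-size statistics of a trajectory
#'
#' Euclidean displacement over each consecutive window of `interval`
#' seconds, divided by the interval, summarised as a mean and SD in um/s
#' (the "average step size" convention of plasmid-mobility reports).
#'
#' @param traj a [trajectory()].
#' @param interval window length in seconds; must be a multiple of the frame
#'   interval.
#' @return List with `mean_um_s`, `sd_um_s`, `n`.
#' @examples
#' tr <- trajectory(t_s = seq(0, 20, 5), x_um = seq(0, 0.4, 0.1),
#'                  y_um = numeric(5))
#' step_size_stats(tr, interval = 5) # ballistic 0.02 um/s, SD 0
#' @export
step_size_stats <- function(traj, interval = NULL) {
  dt <- traj_dt(traj)
  if (is.null(interval)) interval <- dt
  k <- interval / dt
  if (abs(k - round(k)) > 1e-6)
    stop("'interval' must be a multiple of the frame interval", call. = FALSE)
  k <- as.integer(round(k))
  n <- nrow(traj)
  if (n <= k) stop("trajectory shorter than one interval", call. = FALSE)
  idx <- seq(1L, n, by = k)
  dx <- diff(traj$x_um[idx]); dy <- diff(traj$y_um[idx])
  speed <- sqrt(dx^2 + dy^2) / interval
  list(mean_um_s = mean(speed),
       sd_um_s = if (length(speed) > 1L) stats::sd(speed) else 0,
       n = length(speed))
}
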