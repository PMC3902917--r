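#' Single-particle trajectory container
#'
#' A `trajectory` is a data frame with one row per frame and columns
#' `track_id`, `frame`, `t_s` (time, seconds), `x_um` (long-axis position,
#' micrometres, pole at 0), `y_um` (short-axis position, centreline at 0) and
#' `cell_id`. Times must be strictly increasing and, within a track, sampled
#' uniformly (1% tolerance), which is what the lag-based MSD estimator
#' assumes.
#'
#' @param t_s numeric vector of times in seconds, strictly increasing.
#' @param x_um,y_um numeric vectors of long-/short-axis positions (um).
#' @param track_id,cell_id identifiers recycled along the track.
#' @param frame optional integer frame numbers; defaults to `seq_along(t_s)`.
#' @return A data frame of class `c("trajectory", "data.frame")`.
#' @examples
#' tr <- trajectory(t_s = 0:4, x_um = c(0, .1, .2, .1, 0), y_um = numeric(5))
#' tr
#' @export
trajectory <- function(t_s, x_um, y_um = rep(0, length(t_s)),
                       track_id = "track1", cell_id = "cell1", frame = NULL) {
  t_s <- as.numeric(t_s)
  n <- length(t_s)
  if (n < 2L) stop("a trajectory needs at least 2 points", call. = FALSE)
  if (any(diff(t_s) <= 0)) stop("times must be strictly increasing", call. = FALSE)
  dt <- diff(t_s)
  if (max(dt) - min(dt) > 0.01 * mean(dt))
    stop("sampling must be uniform within a track (1% tolerance)", call. = FALSE)
  if (length(x_um) != n || length(y_um) != n)
    stop("x_um and y_um must match the length of t_s", call. = FALSE)
  out <- data.frame(
    track_id = rep_len(as.character(track_id), n),
    frame = if (is.null(frame)) seq_len(n) else as.integer(frame),
    t_s = t_s, x_um = as.numeric(x_um), y_um = as.numeric(y_um),
    cell_id = rep_len(as.character(cell_id), n),
    stringsAsFactors = FALSE
  )
  class(out) <- c("trajectory", "data.frame")
  out
}

#' @export
print.trajectory <- function(x, ...) {
  dt <- mean(diff(x$t_s))
  cat(sprintf("Trajectory '%s' (cell '%s'): %d frames, dt = %g s, span = %g s\n",
              x$track_id[1], x$cell_id[1], nrow(x), dt, diff(range(x$t_s))))
  cat(sprintf("  x range [%.3f, %.3f] um, y range [%.3f, %.3f] um\n",
              min(x$x_um), max(x$x_um), min(x$y_um), max(x$y_um)))
  invisible(x)
}

#' @export
plot.trajectory <- function(x, ...) {
  plot(x$x_um, x$y_um, type = "l", asp = 1,
       xlab = expression(x ~ (mu * m)), ylab = expression(y ~ (mu * m)), ...)
  points(x$x_um[1], x$y_um[1], pch = 16)
  invisible(x)
}

# Frame interval of a trajectory (s).
traj_dt <- function(traj) mean(diff(traj$t_s))

#' Cell geometry
#'
#' Describes one cell: its length and width (um) and the nucleoid as a set of
#' disjoint intervals in relative long-axis coordinates (0 = pole,
#' 1 = opposite pole). Positions outside the nucleoid intervals are
#' nucleoid-free (poles, inter-nucleoid gaps).
#'
#' @param length,width cell dimensions in micrometres.
#' @param nucleoid_intervals two-column matrix (or list of pairs) of relative
#'   `(start, end)` intervals, disjoint, inside `[0, 1]`.
#' @param cell_id identifier.
#' @return An object of class `cell_geometry`.
#' @examples
#' cell_geometry(3, 1, rbind(c(0.2, 0.8)))
#' @export
cell_geometry <- function(length, width, nucleoid_intervals = NULL,
                          cell_id = "cell1") {
  check_num(length, "length", lower = 0, strict_lower = TRUE)
  check_num(width, "width", lower = 0, strict_lower = TRUE)
  iv <- check_nucleoid_intervals(nucleoid_intervals)
  structure(list(cell_id = as.character(cell_id), length = length,
                 width = width, nucleoid_intervals = iv),
            class = "cell_geometry")
}

#' @export
print.cell_geometry <- function(x, ...) {
  cat(sprintf("Cell '%s': %g x %g um, %d nucleoid interval(s)\n",
              x$cell_id, x$length, x$width, nrow(x$nucleoid_intervals)))
  if (nrow(x$nucleoid_intervals))
    cat(paste(sprintf("  [%.2f, %.2f]", x$nucleoid_intervals[, 1],
                      x$nucleoid_intervals[, 2]), collapse = " "), "\n")
  invisible(x)
}

# One long-axis displacement under entry-gated hop diffusion.
#
# Cell walls at lo/hi always reflect. Nucleoid intervals (absolute
# coordinates, k x 2 matrix) are entered only with probability p_hop per
# attempted crossing; an accepted crossing carries the whole remaining step
# (folded at the walls); a rejected one reflects specularly at the entry
# boundary. Steps leaving a nucleoid interval are free: exclusion is
# entropic, so the barrier acts on the way in, which gives a stationary
# density inside the nucleoid reduced by a factor ~p_hop.
hop_step <- function(x0, dx, lo, hi, intervals, p_hop, depth = 0L) {
  if (depth > 60L) return(min(max(x0, lo), hi))
  x1 <- x0 + dx
  if (dx == 0) return(x0)
  # entry boundaries in the direction of travel: interval starts when moving
  # up, interval ends when moving down; plus the walls
  if (dx > 0) {
    ent <- intervals[, 1]
    cand <- c(ent[ent > x0 & ent < x1], if (x1 > hi) hi)
    b <- if (length(cand)) min(cand) else NA_real_
  } else {
    ent <- intervals[, 2]
    cand <- c(ent[ent < x0 & ent > x1], if (x1 < lo) lo)
    b <- if (length(cand)) max(cand) else NA_real_
  }
  if (is.na(b)) return(x1)
  if (b > lo && b < hi) { # nucleoid entry attempt
    if (stats::runif(1) < p_hop)
      return(reflect_into(x1, lo, hi)) # accepted whole; walls still reflect
    return(hop_step(b, -(x1 - b), lo, hi, intervals, p_hop, depth + 1L))
  }
  # wall: always reflect and resolve the folded remainder (it may now attempt
  # a nucleoid entry)
  hop_step(b, -(x1 - b), lo, hi, intervals, p_hop, depth + 1L)
}
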