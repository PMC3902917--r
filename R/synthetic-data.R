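# Seeded generators for every input class the analysis consumes, with known
# ground truth so that estimator tests can be written as recovery tests.

#' Simulate a confined Brownian trajectory in a reflecting box
#'
#' Discrete Brownian motion per axis with Gaussian increments of variance
#' `2 * D * dt`, confined by specular reflection to a box of size
#' `box_long` (long axis, `[0, box_long]`) by `box_short` (short axis,
#' centred on 0). Reflection is applied by folding the free cumulative path,
#' which is exact for a reflecting interval and preserves the uniform
#' stationary distribution. Independent Gaussian localization noise of SD
#' `loc_noise_sd` is added to the *observed* positions only; it does not
#' propagate into the dynamics (camera error, as in FROS spot imaging).
#'
#' @param D diffusion coefficient (um^2/s), `>= 0`.
#' @param box_long,box_short confinement lengths (um), `> 0`. Use a very
#'   large `box_long` for effectively free diffusion.
#' @param dt sampling interval (s), `> 0`.
#' @param n_steps number of recorded positions, `>= 2`.
#' @param loc_noise_sd localization error SD (um), `>= 0`.
#' @param seed integer seed; identical arguments and seed give identical
#'   output. `NULL` leaves the RNG state alone.
#' @param start optional length-2 start position `c(x, y)`; default uniform
#'   in the box.
#' @param track_id,cell_id identifiers passed to [trajectory()].
#' @return A [trajectory()] whose positions include localization noise. The
#'   noise-free path is attached as attributes `x_true`, `y_true`.
#' @examples
#' tr <- gen_confined_trajectory(D = 2.5e-3, box_long = 0.43, box_short = 0.4,
#'                               dt = 10, n_steps = 100, seed = 1)
#' range(attr(tr, "x_true"))
#' @export
gen_confined_trajectory <- function(D, box_long, box_short, dt, n_steps,
                                    loc_noise_sd = 0, seed = NULL,
                                    start = NULL, track_id = "track1",
                                    cell_id = "cell1") {
  check_num(D, "D", lower = 0)
  check_num(box_long, "box_long", lower = 0, strict_lower = TRUE)
  check_num(box_short, "box_short", lower = 0, strict_lower = TRUE)
  check_num(dt, "dt", lower = 0, strict_lower = TRUE)
  n_steps <- check_count(n_steps, "n_steps", lower = 2L)
  check_num(loc_noise_sd, "loc_noise_sd", lower = 0)
  set_seed_if(seed)
  sd_step <- sqrt(2 * D * dt)
  if (is.null(start)) {
    start <- c(stats::runif(1, 0, box_long),
               stats::runif(1, -box_short / 2, box_short / 2))
  }
  x_free <- start[1] + c(0, cumsum(stats::rnorm(n_steps - 1L, 0, sd_step)))
  y_free <- start[2] + c(0, cumsum(stats::rnorm(n_steps - 1L, 0, sd_step)))
  x_true <- reflect_into(x_free, 0, box_long)
  y_true <- reflect_into(y_free, -box_short / 2, box_short / 2)
  x_obs <- x_true + stats::rnorm(n_steps, 0, loc_noise_sd)
  y_obs <- y_true + stats::rnorm(n_steps, 0, loc_noise_sd)
  out <- trajectory(t_s = (seq_len(n_steps) - 1L) * dt, x_um = x_obs,
                    y_um = y_obs, track_id = track_id, cell_id = cell_id)
  attr(out, "x_true") <- x_true
  attr(out, "y_true") <- y_true
  out
}

#' Simulate hop diffusion past nucleoid barriers
#'
#' Brownian motion inside a cell (long axis `[0, length]`, short axis
#' `[-width/2, width/2]`, walls reflecting) in which the nucleoid intervals
#' of `cell` act as partially permeable obstacles on the long axis: a step
#' whose segment would *enter* a nucleoid interval is accepted whole with
#' probability `p_hop` and otherwise reflected specularly at the entry
#' boundary; steps leaving an interval are free. The one-sided gate models
#' entropic nucleoid exclusion: at stationarity the density inside the
#' nucleoid is depressed by a factor of order `p_hop`, while `p_hop = 1`
#' recovers plain confined diffusion (uniform occupancy).
#'
#' @param cell a [cell_geometry()].
#' @param D diffusion coefficient (um^2/s).
#' @param p_hop per-attempt probability of crossing into the nucleoid, in
#'   `[0, 1]`.
#' @param dt sampling interval (s).
#' @param n_steps number of recorded positions.
#' @param seed integer seed (see [gen_confined_trajectory()]).
#' @param loc_noise_sd localization error SD (um) added to observed positions.
#' @param start optional `c(x, y)` start; default uniform over the
#'   nucleoid-free long-axis region.
#' @param track_id identifier.
#' @return A [trajectory()] (noise-free path in attributes as for
#'   [gen_confined_trajectory()]).
#' @examples
#' cell <- cell_geometry(3, 1, rbind(c(0.2, 0.8)))
#' tr <- gen_hop_trajectory(cell, D = 2.5e-3, p_hop = 0.05, dt = 1,
#'                          n_steps = 200, seed = 1)
#' @export
gen_hop_trajectory <- function(cell, D, p_hop, dt, n_steps, seed = NULL,
                               loc_noise_sd = 0, start = NULL,
                               track_id = "track1") {
  if (!inherits(cell, "cell_geometry")) stop("'cell' must be a cell_geometry")
  check_num(D, "D", lower = 0)
  check_num(p_hop, "p_hop", lower = 0, upper = 1)
  check_num(dt, "dt", lower = 0, strict_lower = TRUE)
  n_steps <- check_count(n_steps, "n_steps", lower = 2L)
  set_seed_if(seed)
  L <- cell$length
  iv <- cell$nucleoid_intervals * L # absolute coordinates
  if (is.null(start)) {
    start <- c(sample_free_position(L, iv),
               stats::runif(1, -cell$width / 2, cell$width / 2))
  }
  sd_step <- sqrt(2 * D * dt)
  x <- numeric(n_steps); y <- numeric(n_steps)
  x[1] <- start[1]; y[1] <- start[2]
  for (i in seq_len(n_steps - 1L)) {
    x[i + 1L] <- hop_step(x[i], stats::rnorm(1, 0, sd_step), 0, L, iv, p_hop)
    y[i + 1L] <- reflect_into(y[i] + stats::rnorm(1, 0, sd_step),
                              -cell$width / 2, cell$width / 2)
  }
  x_obs <- x + stats::rnorm(n_steps, 0, loc_noise_sd)
  y_obs <- y + stats::rnorm(n_steps, 0, loc_noise_sd)
  out <- trajectory(t_s = (seq_len(n_steps) - 1L) * dt, x_um = x_obs,
                    y_um = y_obs, track_id = track_id, cell_id = cell$cell_id)
  attr(out, "x_true") <- x
  attr(out, "y_true") <- y
  out
}

# Uniform draw from the nucleoid-free part of [0, L]; iv in absolute um.
sample_free_position <- function(L, iv) {
  if (nrow(iv) == 0L) return(stats::runif(1, 0, L))
  gaps <- rbind(c(0, iv[1, 1]),
                if (nrow(iv) > 1L) cbind(iv[-nrow(iv), 2], iv[-1L, 1]),
                c(iv[nrow(iv), 2], L))
  gaps <- gaps[gaps[, 2] > gaps[, 1], , drop = FALSE]
  if (nrow(gaps) == 0L) stop("no nucleoid-free space to place a particle in")
  w <- gaps[, 2] - gaps[, 1]
  g <- gaps[sample.int(nrow(gaps), 1L, prob = w), ]
  stats::runif(1, g[1], g[2])
}

#' Generate a synthetic qPCR plate with known plasmid:oriC ratio
#'
#' Emulates relative quantification of plasmid against the chromosomal
#' *oriC* region. Four well classes are produced: `chr` and `pl` (sample
#' wells for the chromosome and plasmid targets) and `cal_chr`/`cal_pl`
#' (calibrator wells, equal template so their true ratio is 1). Threshold
#' cycles follow `Ct = Ct_ref - log_eff(copies)` so that the
#' efficiency-corrected delta-delta-Ct ratio computed by [qpcr_ratio()]
#' equals `true_ratio` exactly in the absence of noise. Gaussian noise of SD
#' `ct_noise_sd` cycles is added to every well independently.
#'
#' @param true_ratio ground-truth plasmid:oriC copy ratio, `> 0`.
#' @param eff_chr,eff_pl per-cycle amplification efficiencies (fold per
#'   cycle, in `(1, 2]`).
#' @param ct_noise_sd Ct noise SD (cycles).
#' @param n_replicates wells per target class.
#' @param seed integer seed.
#' @param ct_cal,ct_chr base threshold cycles for the calibrator wells and
#'   the sample chromosome wells (arbitrary instrument offsets).
#' @return A `qpcr_plate`: data frame with columns `well`, `target`, `ct`,
#'   and attributes `eff_chr`, `eff_pl`.
#' @examples
#' gen_qpcr_plate(true_ratio = 8, ct_noise_sd = 0, n_replicates = 1, seed = 1)
#' @export
gen_qpcr_plate <- function(true_ratio, eff_chr = 2, eff_pl = 2,
                           ct_noise_sd = 0, n_replicates = 3, seed = NULL,
                           ct_cal = 20, ct_chr = 22) {
  check_num(true_ratio, "true_ratio", lower = 0, strict_lower = TRUE)
  check_num(eff_chr, "eff_chr", lower = 1, upper = 2, strict_lower = TRUE)
  check_num(eff_pl, "eff_pl", lower = 1, upper = 2, strict_lower = TRUE)
  check_num(ct_noise_sd, "ct_noise_sd", lower = 0)
  n_replicates <- check_count(n_replicates, "n_replicates")
  set_seed_if(seed)
  # invert ratio = eff_pl^(ct_cal - ct_pl) / eff_chr^(ct_cal - ct_chr)
  ct_pl <- ct_cal -
    (log(true_ratio) + (ct_cal - ct_chr) * log(eff_chr)) / log(eff_pl)
  targets <- c("chr", "pl", "cal_chr", "cal_pl")
  base <- c(chr = ct_chr, pl = ct_pl, cal_chr = ct_cal, cal_pl = ct_cal)
  tg <- rep(targets, each = n_replicates)
  ct <- base[tg] + stats::rnorm(length(tg), 0, ct_noise_sd)
  out <- data.frame(
    well = sprintf("W%02d", seq_along(tg)), target = tg,
    ct = as.numeric(ct), stringsAsFactors = FALSE, row.names = NULL
  )
  attr(out, "eff_chr") <- eff_chr
  attr(out, "eff_pl") <- eff_pl
  attr(out, "true_ratio") <- true_ratio
  class(out) <- c("qpcr_plate", "data.frame")
  out
}

#' Generate per-cell EdU spot counts
#'
#' Under replication events that occur independently for each plasmid with a
#' constant per-cell accumulation rate, the number of labelled spots after a
#' labelling window is Poisson with mean `rate_per_min * window_min`.
#'
#' @param rate_per_min per-cell spot accumulation rate (1/min), `>= 0`.
#' @param window_min labelling duration (min), `>= 0`.
#' @param n_cells number of cells, `>= 1`.
#' @param seed integer seed.
#' @return Data frame with columns `cell_id`, `n_spots`.
#' @examples
#' counts <- gen_edu_counts(1 / 17.6, window_min = 17.6, n_cells = 500, seed = 1)
#' mean(counts$n_spots) # ~1: the one-spot calibration point
#' @export
gen_edu_counts <- function(rate_per_min, window_min, n_cells, seed = NULL) {
  check_num(rate_per_min, "rate_per_min", lower = 0)
  check_num(window_min, "window_min", lower = 0)
  n_cells <- check_count(n_cells, "n_cells")
  set_seed_if(seed)
  data.frame(cell_id = sprintf("cell%04d", seq_len(n_cells)),
             n_spots = stats::rpois(n_cells, rate_per_min * window_min),
             stringsAsFactors = FALSE)
}

#' Render a synthetic fluorescence spot image
#'
#' Sums isotropic Gaussian spots onto a constant background and adds
#' Gaussian read noise; a fixture for [localize_spots()]. Pixel coordinates
#' are `(x, y)` with `x` along columns and `y` along rows, 1-based at pixel
#' centres.
#'
#' @param positions n-by-2 matrix of spot centres `(x, y)` in pixels, all
#'   inside the image; may have zero rows.
#' @param amplitude peak intensity per spot (recycled).
#' @param psf_sd Gaussian PSF standard deviation (pixels).
#' @param noise_sd background noise SD.
#' @param shape image size `c(rows, cols)`.
#' @param seed integer seed.
#' @param background constant background level.
#' @return Numeric matrix of dimension `shape`.
#' @examples
#' img <- gen_spot_image(cbind(16, 16), amplitude = 50, psf_sd = 1.5,
#'                       noise_sd = 1, shape = c(32, 32), seed = 1)
#' @export
gen_spot_image <- function(positions, amplitude = 100, psf_sd = 1.5,
                           noise_sd = 1, shape = c(64, 64), seed = NULL,
                           background = 10) {
  positions <- matrix(as.numeric(positions), ncol = 2)
  shape <- as.integer(shape)
  if (nrow(positions) > 0 &&
      (any(positions[, 1] < 1) || any(positions[, 1] > shape[2]) ||
       any(positions[, 2] < 1) || any(positions[, 2] > shape[1])))
    stop("spot positions must lie inside the image", call. = FALSE)
  check_num(psf_sd, "psf_sd", lower = 0, strict_lower = TRUE)
  check_num(noise_sd, "noise_sd", lower = 0)
  set_seed_if(seed)
  img <- matrix(background, shape[1], shape[2])
  if (nrow(positions) > 0) {
    amplitude <- rep_len(amplitude, nrow(positions))
    cc <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
    rr <- matrix(seq_len(shape[1]), shape[1], shape[2])
    for (i in seq_len(nrow(positions))) {
      img <- img + amplitude[i] *
        exp(-((cc - positions[i, 1])^2 + (rr - positions[i, 2])^2) /
              (2 * psf_sd^2))
    }
  }
  img + matrix(stats::rnorm(prod(shape), 0, noise_sd), shape[1], shape[2])
}
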