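# Stochastic whole-cell model: plasmids hop-diffuse in a growing cell with a
# central nucleoid, initiate replication with a constant (or RNA I-inhibited)
# per-plasmid probability, and are partitioned to daughters by position at
# division.

#' Simulator configuration
#'
#' Builds and validates the parameter set of the whole-cell simulator. The
#' defaults describe a slow-growing cell carrying a high-copy 11.3-kb
#' ColE1-type plasmid: 100-min generation time, 2 x 1 um newborn geometry,
#' plasmid diffusion coefficient 2.5e-3 um^2/s, a central nucleoid covering
#' 60% of the length that splits (opening a midcell gap) at cell-cycle
#' stage 0.75, 12 plasmid copies at birth, ~600 bp/s fork speed, and ~283 s
#' sliding-clamp retention after synthesis (so DnaN-like spots outlive
#' SSB-like ones by ~5 min).
#'
#' Replication modes: `"constant_rate"` gives every non-replicating plasmid
#' a fixed initiation probability per unit time (calibrated to
#' `ln(2)/tau_gen` so copies double per generation in expectation — a
#' critical branching process, faithful to constant-probability initiation
#' but without copy-number homeostasis); `"rnaI_feedback"` divides the base
#' rate by `1 + n/K`, a well-mixed RNA I pool (~`rnaI_pool` molecules per
#' cell) inhibiting priming in proportion to total copy number `n`, with
#' half-inhibition at `K = rnaI_K` copies. The feedback base rate is
#' calibrated so the deterministic trajectory still doubles over one
#' generation from `n_birth` copies.
#'
#' @param tau_gen generation time (min).
#' @param birth_length,width newborn cell length and width (um).
#' @param D plasmid diffusion coefficient (um^2/s).
#' @param p_hop probability of crossing into the nucleoid per attempt.
#' @param nucleoid_fraction fraction of cell length covered by nucleoid,
#'   `< 1`.
#' @param nucleoid_split_x cell-cycle stage at which the nucleoid splits.
#' @param nucleoid_gap relative width of the midcell gap after splitting.
#' @param n_birth plasmid copies at birth.
#' @param rep_mode `"constant_rate"` or `"rnaI_feedback"`.
#' @param rep_rate per-plasmid initiation rate (1/min); `NULL` calibrates it
#'   to double copy number per generation (see Details).
#' @param rnaI_K copy number at half-inhibition (feedback mode). The
#'   default, 2 copies, puts the system deep in the saturated regime where
#'   the total initiation rate is nearly independent of copy number —
#'   the hallmark of RNA I control — which is what gives the tight
#'   copy-number homeostasis and multi-generation stability of ColE1
#'   plasmids.
#' @param rnaI_pool nominal RNA I molecules per cell (documentation of the
#'   feedback scale; does not enter the dynamics beyond `rnaI_K`).
#' @param plasmid_bp plasmid size (bp).
#' @param fork_speed replication fork speed (bp/s).
#' @param dnan_retention_s clamp retention after synthesis (s).
#' @param dt simulation time step (s).
#' @param seed integer seed.
#' @return A validated `sim_config` list with `rep_rate` filled in.
#' @examples
#' cfg <- sim_config(tau_gen = 10, n_birth = 8, seed = 1)
#' cfg$rep_rate
#' @export
sim_config <- function(tau_gen = 100, birth_length = 2, width = 1,
                       D = 2.5e-3, p_hop = 0.1, nucleoid_fraction = 0.6,
                       nucleoid_split_x = 0.75, nucleoid_gap = 0.1,
                       n_birth = 12,
                       rep_mode = c("rnaI_feedback", "constant_rate"),
                       rep_rate = NULL, rnaI_K = NULL, rnaI_pool = 400,
                       plasmid_bp = 11300, fork_speed = 600,
                       dnan_retention_s = 283, dt = 1, seed = 1) {
  rep_mode <- match.arg(rep_mode)
  check_num(tau_gen, "tau_gen", lower = 0, strict_lower = TRUE)
  check_num(birth_length, "birth_length", lower = 0, strict_lower = TRUE)
  check_num(width, "width", lower = 0, strict_lower = TRUE)
  check_num(D, "D", lower = 0)
  check_num(p_hop, "p_hop", lower = 0, upper = 1)
  check_num(nucleoid_fraction, "nucleoid_fraction", lower = 0, upper = 1,
            strict_upper = TRUE)
  check_num(nucleoid_split_x, "nucleoid_split_x", lower = 0, upper = 1)
  check_num(nucleoid_gap, "nucleoid_gap", lower = 0,
            upper = nucleoid_fraction)
  n_birth <- check_count(n_birth, "n_birth")
  check_num(plasmid_bp, "plasmid_bp", lower = 0)
  check_num(fork_speed, "fork_speed", lower = 0, strict_lower = TRUE)
  check_num(dnan_retention_s, "dnan_retention_s", lower = 0)
  check_num(dt, "dt", lower = 0, strict_lower = TRUE)
  rnaI_K <- rnaI_K %||% 2
  check_num(rnaI_K, "rnaI_K", lower = 0, strict_lower = TRUE)
  if (is.null(rep_rate)) {
    rep_rate <- if (rep_mode == "constant_rate") log(2) / tau_gen
                else (log(2) + n_birth / rnaI_K) / tau_gen
  }
  check_num(rep_rate, "rep_rate", lower = 0)
  # per-step initiation probability sanity (rate is per min, dt per s)
  p_step <- rep_rate / 60 * dt
  if (p_step > 0.5) stop("dt too large: per-step initiation probability > 0.5",
                         call. = FALSE)
  if (p_step > 0.1) warning("per-step initiation probability > 0.1; decrease dt")
  structure(list(tau_gen = tau_gen, birth_length = birth_length,
                 width = width, D = D, p_hop = p_hop,
                 nucleoid_fraction = nucleoid_fraction,
                 nucleoid_split_x = nucleoid_split_x,
                 nucleoid_gap = nucleoid_gap, n_birth = n_birth,
                 rep_mode = rep_mode, rep_rate = rep_rate, rnaI_K = rnaI_K,
                 rnaI_pool = rnaI_pool, plasmid_bp = plasmid_bp,
                 fork_speed = fork_speed,
                 dnan_retention_s = dnan_retention_s, dt = dt,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Whole-cell simulator configuration\n")
  cat(sprintf("  tau_gen = %g min, newborn %g x %g um, D = %g um^2/s, p_hop = %g\n",
              x$tau_gen, x$birth_length, x$width, x$D, x$p_hop))
  cat(sprintf("  nucleoid: %.0f%% of length, splits at stage %g (gap %g)\n",
              100 * x$nucleoid_fraction, x$nucleoid_split_x, x$nucleoid_gap))
  cat(sprintf("  replication: %s, rate %.4g /min/plasmid, %d copies at birth\n",
              x$rep_mode, x$rep_rate, x$n_birth))
  invisible(x)
}

# Nucleoid intervals (relative coordinates) at cell-cycle stage x_stage.
nucleoid_at_stage <- function(config, x_stage) {
  f <- config$nucleoid_fraction
  if (f <= 0) return(matrix(numeric(0), ncol = 2))
  if (x_stage < config$nucleoid_split_x || config$nucleoid_gap <= 0)
    return(rbind(c(0.5 - f / 2, 0.5 + f / 2)))
  g <- config$nucleoid_gap
  rbind(c(0.5 - f / 2, 0.5 - g / 2), c(0.5 + g / 2, 0.5 + f / 2))
}

# Effective per-plasmid initiation rate (1/min) at total copy number n
# (vectorised over n).
initiation_rate <- function(config, n) {
  if (config$rep_mode == "constant_rate") rep_len(config$rep_rate, length(n))
  else config$rep_rate / (1 + n / config$rnaI_K)
}

#' Construct a simulator state
#'
#' A `sim_state` holds one cell at one instant: time, length, plasmid
#' positions and any replications in progress. [sim_run()] builds states
#' internally; this constructor exists so that [sim_divide()] can be
#' exercised on hand-made configurations.
#'
#' @param cell_length current cell length (um).
#' @param x,y plasmid positions (um; long axis from pole 0, short axis from
#'   centreline).
#' @param t time (s).
#' @param t_done per-plasmid replication completion times (s), `NA` when a
#'   plasmid is not replicating.
#' @param generation generation counter.
#' @return A `sim_state` list.
#' @export
sim_state <- function(cell_length, x, y = rep(0, length(x)), t = 0,
                      t_done = rep(NA_real_, length(x)), generation = 0L) {
  check_num(cell_length, "cell_length", lower = 0, strict_lower = TRUE)
  if (any(x < 0 | x > cell_length))
    stop("plasmid positions must lie inside the cell", call. = FALSE)
  structure(list(t = t, cell_length = cell_length, x = as.numeric(x),
                 y = as.numeric(y), t_done = as.numeric(t_done),
                 generation = as.integer(generation)),
            class = "sim_state")
}

#' Divide a cell and partition plasmids by position
#'
#' Places the septum at relative position 0.5 and assigns each plasmid to
#' the daughter whose half it occupies; a plasmid exactly at the septum is
#' assigned by a fair coin. Copy number is conserved: the daughters' counts
#' always sum to the mother's. Each daughter is born at half the mother's
#' length with the nucleoid reset to a single central block (the daughter
#' state carries positions re-expressed in its own frame, pole at 0).
#'
#' @param state a [sim_state()] at the moment of division.
#' @return List with `daughter1` (left), `daughter2` (right) — both
#'   `sim_state`s — and `n_left`, `n_right`.
#' @examples
#' st <- sim_state(4, x = c(0.3, 0.5, 3.8))
#' sim_divide(st)$n_left # 2
#' @export
sim_divide <- function(state) {
  septum <- state$cell_length / 2
  side <- ifelse(state$x < septum, 1L,
                 ifelse(state$x > septum, 2L,
                        ifelse(stats::runif(length(state$x)) < 0.5, 1L, 2L)))
  left <- side == 1L
  d1 <- sim_state(cell_length = septum, x = state$x[left],
                  y = state$y[left], t = state$t,
                  t_done = state$t_done[left],
                  generation = state$generation + 1L)
  d2 <- sim_state(cell_length = septum, x = state$x[!left] - septum,
                  y = state$y[!left], t = state$t,
                  t_done = state$t_done[!left],
                  generation = state$generation + 1L)
  list(daughter1 = d1, daughter2 = d2,
       n_left = sum(left), n_right = sum(!left))
}

#' Advance the simulator by one time step
#'
#' One step of duration `config$dt`: the cell elongates exponentially
#' (doubling over `tau_gen`) and plasmid positions rescale with it; each
#' plasmid takes a hop-diffusion step against the current nucleoid
#' configuration; each non-replicating plasmid initiates replication with
#' probability `rate * dt` (constant mode) or `rate / (1 + n/K) * dt`
#' (feedback mode); completed replications add a copy at the parent's
#' position with a 0.01-um jitter. Used internally by [sim_run()]; exported
#' for stepping hand-built states.
#'
#' @param state a [sim_state()].
#' @param config a [sim_config()].
#' @param t_birth absolute time at which this cell was born (s), to compute
#'   the cell-cycle stage; defaults to 0.
#' @return List `state` (advanced), `initiations` (data frame of new events:
#'   `t_s`, `rel_pos`), `completions` (integer count).
#' @export
sim_step <- function(state, config, t_birth = 0) {
  dt <- config$dt
  tau_s <- config$tau_gen * 60
  x_stage <- min(1, (state$t - t_birth) / tau_s)
  growth <- 2^(dt / tau_s)
  L <- state$cell_length * growth
  x <- state$x * growth
  y <- state$y
  n <- length(x)
  iv <- nucleoid_at_stage(config, x_stage) * L
  sd_step <- sqrt(2 * config$D * dt)
  if (n > 0 && config$D > 0) {
    dxs <- stats::rnorm(n, 0, sd_step)
    dys <- stats::rnorm(n, 0, sd_step)
    for (i in seq_len(n)) {
      x[i] <- hop_step(x[i], dxs[i], 0, L, iv, config$p_hop)
      y[i] <- reflect_into(y[i] + dys[i], -config$width / 2, config$width / 2)
    }
  }
  t_new <- state$t + dt
  t_done <- state$t_done
  inits <- data.frame(t_s = numeric(0), rel_pos = numeric(0))
  if (n > 0) {
    eligible <- is.na(t_done)
    p_init <- initiation_rate(config, n) / 60 * dt
    started <- eligible & stats::runif(n) < p_init
    if (any(started)) {
      t_done[started] <- t_new + config$plasmid_bp / config$fork_speed
      inits <- data.frame(t_s = rep(t_new, sum(started)),
                          rel_pos = x[started] / L)
    }
  }
  done <- which(!is.na(t_done) & t_done <= t_new)
  if (length(done)) {
    newx <- reflect_into(x[done] + stats::rnorm(length(done), 0, 0.01), 0, L)
    newy <- reflect_into(y[done] + stats::rnorm(length(done), 0, 0.01),
                         -config$width / 2, config$width / 2)
    x <- c(x, newx); y <- c(y, newy)
    t_done[done] <- NA_real_
    t_done <- c(t_done, rep(NA_real_, length(done)))
  }
  st <- structure(list(t = t_new, cell_length = L, x = x, y = y,
                       t_done = t_done, generation = state$generation),
                  class = "sim_state")
  list(state = st, initiations = inits, completions = length(done))
}

#' Run the whole-cell simulator over generations
#'
#' Follows a single cell lineage for `n_generations` generations (at each
#' division one daughter is chosen by a fair coin), logging per-generation
#' birth/division copy numbers and partition outcomes, every initiation
#' event with its time and relative position, SSB-like (synthesis-time) and
#' DnaN-like (synthesis + retention) marker spot intervals, periodic
#' position snapshots for density profiles, and the full trajectory of one
#' tracked plasmid per generation for closed-loop MSD analysis. Fully
#' deterministic under `config$seed`.
#'
#' @param config a [sim_config()].
#' @param n_generations generations to simulate.
#' @param sample_every snapshot/trajectory sampling interval (s).
#' @return A `plasmid_sim` with components `generations` (data frame: `gen`,
#'   `n_birth`, `n_division`, `n_left`, `n_right`, `lost`), `initiations`
#'   (`gen`, `t_s`, `rel_pos`), `markers` (`gen`, `marker`, `t_start_s`,
#'   `t_end_s`, `rel_pos`), `snapshots` (`t_s`, `rel_pos`), `tracked` (list
#'   of [trajectory()] objects, one per generation) and `config`.
#' @examples
#' cfg <- sim_config(tau_gen = 2, n_birth = 6, dt = 0.5, seed = 1)
#' res <- sim_run(cfg, n_generations = 2)
#' summary(res)
#' @export
sim_run <- function(config, n_generations = 1, sample_every = 10) {
  if (!inherits(config, "sim_config")) stop("'config' must be a sim_config")
  n_generations <- check_count(n_generations, "n_generations")
  set.seed(config$seed)
  tau_s <- config$tau_gen * 60
  n_steps <- max(1L, as.integer(round(tau_s / config$dt)))
  sample_stride <- max(1L, as.integer(round(sample_every / config$dt)))

  # newborn: plasmids uniform over the nucleoid-free region
  iv0 <- nucleoid_at_stage(config, 0) * config$birth_length
  x0 <- vapply(seq_len(config$n_birth), function(i)
    sample_free_position(config$birth_length, iv0), 0)
  y0 <- stats::runif(config$n_birth, -config$width / 2, config$width / 2)
  state <- sim_state(config$birth_length, x0, y0)

  gen_rows <- vector("list", n_generations)
  init_rows <- list(); marker_rows <- list(); snap_rows <- list()
  tracked <- vector("list", n_generations)

  for (gen in seq_len(n_generations)) {
    t_birth <- state$t
    nb <- length(state$x)
    tr_t <- tr_x <- tr_y <- numeric(0)
    for (s in seq_len(n_steps)) {
      res <- sim_step(state, config, t_birth = t_birth)
      # marker bookkeeping from fresh initiations
      if (nrow(res$initiations)) {
        synth <- config$plasmid_bp / config$fork_speed
        ini <- res$initiations
        init_rows[[length(init_rows) + 1L]] <-
          cbind(gen = gen, ini)
        marker_rows[[length(marker_rows) + 1L]] <- rbind(
          data.frame(gen = gen, marker = "SSB", t_start_s = ini$t_s,
                     t_end_s = ini$t_s + synth, rel_pos = ini$rel_pos),
          data.frame(gen = gen, marker = "DnaN", t_start_s = ini$t_s,
                     t_end_s = ini$t_s + synth + config$dnan_retention_s,
                     rel_pos = ini$rel_pos))
      }
      state <- res$state
      if (s %% sample_stride == 0L && length(state$x)) {
        snap_rows[[length(snap_rows) + 1L]] <-
          data.frame(t_s = state$t, rel_pos = state$x / state$cell_length)
        tr_t <- c(tr_t, state$t)
        tr_x <- c(tr_x, state$x[1]); tr_y <- c(tr_y, state$y[1])
      }
    }
    if (length(tr_t) >= 2L) {
      tracked[[gen]] <- trajectory(t_s = tr_t, x_um = tr_x, y_um = tr_y,
                                   track_id = sprintf("gen%03d", gen),
                                   cell_id = sprintf("gen%03d", gen))
    }
    div <- sim_divide(state)
    gen_rows[[gen]] <- data.frame(
      gen = gen, n_birth = nb, n_division = length(state$x),
      n_left = div$n_left, n_right = div$n_right,
      lost = div$n_left == 0L || div$n_right == 0L)
    state <- if (stats::runif(1) < 0.5) div$daughter1 else div$daughter2
  }

  structure(list(
    generations = do.call(rbind, gen_rows),
    initiations = if (length(init_rows)) do.call(rbind, init_rows)
                  else data.frame(gen = integer(0), t_s = numeric(0),
                                  rel_pos = numeric(0)),
    markers = if (length(marker_rows)) do.call(rbind, marker_rows)
              else data.frame(gen = integer(0), marker = character(0),
                              t_start_s = numeric(0), t_end_s = numeric(0),
                              rel_pos = numeric(0)),
    snapshots = if (length(snap_rows)) do.call(rbind, snap_rows)
                else data.frame(t_s = numeric(0), rel_pos = numeric(0)),
    tracked = tracked[!vapply(tracked, is.null, TRUE)],
    config = config), class = "plasmid_sim")
}

#' @export
print.plasmid_sim <- function(x, ...) {
  g <- x$generations
  cat(sprintf("Whole-cell simulation: %d generation(s), %s replication\n",
              nrow(g), x$config$rep_mode))
  cat(sprintf("  copies at birth %.1f (mean), at division %.1f; %d loss event(s)\n",
              mean(g$n_birth), mean(g$n_division), sum(g$lost)))
  cat(sprintf("  %d initiation events, %d position snapshots\n",
              nrow(x$initiations), nrow(x$snapshots)))
  invisible(x)
}

#' @export
summary.plasmid_sim <- function(object, cutoff = 0.2, ...) {
  g <- object$generations
  out <- list(
    n_generations = nrow(g),
    mean_birth_copies = mean(g$n_birth),
    mean_division_copies = mean(g$n_division),
    losses = sum(g$lost),
    polar_fraction_positions =
      if (nrow(object$snapshots)) polar_fraction(object$snapshots$rel_pos,
                                                 cutoff) else NA_real_,
    polar_fraction_initiations =
      if (nrow(object$initiations)) polar_fraction(object$initiations$rel_pos,
                                                   cutoff) else NA_real_,
    mean_interinitiation_min = {
      k <- nrow(object$initiations)
      if (k > 1) (nrow(g) * object$config$tau_gen) / k else NA_real_
    })
  class(out) <- "summary.plasmid_sim"
  out
}

#' @export
print.summary.plasmid_sim <- function(x, ...) {
  cat(sprintf("Generations: %d; copies %.1f at birth, %.1f at division; %d losses\n",
              x$n_generations, x$mean_birth_copies, x$mean_division_copies,
              x$losses))
  cat(sprintf("Polar fraction: positions %.2f, initiations %.2f\n",
              x$polar_fraction_positions, x$polar_fraction_initiations))
  cat(sprintf("Mean inter-initiation interval: %.2f min\n",
              x$mean_interinitiation_min))
  invisible(x)
}

#' @export
plot.plasmid_sim <- function(x, n_bins = 20, ...) {
  hist(x$snapshots$rel_pos, breaks = seq(0, 1, length.out = n_bins + 1),
       freq = FALSE, xlab = "relative long-axis position",
       main = "Plasmid position density", ...)
  invisible(x)
}

#' Fast multi-lineage copy-number simulation
#'
#' The copy-number projection of the whole-cell model, for stability
#' statistics over many generations and lineages at negligible cost: the
#' spatial degrees of freedom are dropped and partition is
#' `Binomial(n, 1/2)` (the positional rule at a symmetric steady state),
#' while replication follows the same constant-probability or RNA
#' I-feedback initiation law, discretised in `n_sub` sub-steps per
#' generation. Synthesis time is neglected (it is ~2 orders of magnitude
#' shorter than the generation time). One daughter per division is
#' followed, chosen by a fair coin; a loss event is recorded whenever
#' either daughter receives zero copies.
#'
#' @param config a [sim_config()].
#' @param n_generations generations per lineage.
#' @param n_lineages number of independent lineages.
#' @param n_sub initiation sub-steps per generation.
#' @param seed integer seed (defaults to `config$seed`).
#' @return List with `birth_copies` (lineages x generations matrix),
#'   `division_copies` (same shape), `losses` (total loss events),
#'   `extinct` (lineages at zero copies by the end).
#' @examples
#' cfg <- sim_config(n_birth = 12, seed = 1)
#' out <- sim_lineages(cfg, n_generations = 70, n_lineages = 100)
#' out$losses
#' @export
sim_lineages <- function(config, n_generations, n_lineages, n_sub = 25,
                         seed = NULL) {
  if (!inherits(config, "sim_config")) stop("'config' must be a sim_config")
  n_generations <- check_count(n_generations, "n_generations")
  n_lineages <- check_count(n_lineages, "n_lineages")
  n_sub <- check_count(n_sub, "n_sub")
  set.seed(if (is.null(seed)) config$seed else as.integer(seed))
  dt_min <- config$tau_gen / n_sub
  n <- rep(config$n_birth, n_lineages)
  birth <- division <- matrix(0L, n_lineages, n_generations)
  losses <- 0L
  for (gen in seq_len(n_generations)) {
    birth[, gen] <- n
    for (s in seq_len(n_sub)) {
      # expm1 so that expected growth compounds to exp(rate * tau) exactly
      p <- pmin(expm1(initiation_rate(config, n) * dt_min), 1)
      n <- n + stats::rbinom(n_lineages, n, p)
    }
    division[, gen] <- n
    left <- stats::rbinom(n_lineages, n, 0.5)
    losses <- losses + sum((left == 0L | left == n) & n > 0L)
    keep_left <- stats::runif(n_lineages) < 0.5
    n <- ifelse(keep_left, left, n - left)
  }
  list(birth_copies = birth, division_copies = division,
       losses = losses, extinct = sum(n == 0L))
}

#' Binomial plasmid-loss probability at division
#'
#' With `n` copies at division partitioned as `Binomial(n, 1/2)`, the
#' probability that a daughter receives no plasmid is `2 * (1/2)^n` —
#' about 1.2e-7 at 24 copies, consistent with stable inheritance over 70
#' generations.
#'
#' @param n_division copies at division.
#' @return Loss probability per division.
#' @examples
#' plasmid_loss_probability(24)
#' @export
plasmid_loss_probability <- function(n_division) {
  check_num(n_division, "n_division", lower = 1)
  2 * 0.5^n_division
}

#' Gyration diameter of a supercoiled plasmid by power-law interpolation
#'
#' Fits `d = A * bp^nu` through calibration points of (size in bp, gyration
#' diameter in nm) measured for supercoiled plasmids, and evaluates it at
#' `plasmid_bp`. The bundled default table is synthetic: a nu = 0.5
#' (ideal-coil scaling) law anchored so that 11.3 kb maps to 265 nm; it is
#' a stand-in for literature calibration data, not a measurement.
#'
#' @param plasmid_bp plasmid size (bp).
#' @param calibration data frame with columns `bp` and `diameter_nm`, at
#'   least two rows, all positive. Default [gyration_calibration()].
#' @return Diameter in nm, with attributes `A` and `nu`.
#' @examples
#' gyration_diameter(11300) # 265
#' @export
gyration_diameter <- function(plasmid_bp, calibration = gyration_calibration()) {
  check_num(plasmid_bp, "plasmid_bp", lower = 0, strict_lower = TRUE)
  if (!is.data.frame(calibration) || nrow(calibration) < 2L)
    stop("need at least 2 calibration points", call. = FALSE)
  if (any(calibration$bp <= 0) || any(calibration$diameter_nm <= 0))
    stop("calibration points must be positive", call. = FALSE)
  fit <- stats::lm(log(diameter_nm) ~ log(bp), data = calibration)
  A <- exp(stats::coef(fit)[[1]]); nu <- stats::coef(fit)[[2]]
  structure(A * plasmid_bp^nu, A = A, nu = nu)
}

#' Synthetic gyration-diameter calibration table
#'
#' Power-law (`nu = 0.5`) synthetic calibration anchored at 11.3 kb =
#' 265 nm; see [gyration_diameter()].
#'
#' @return Data frame with columns `bp`, `diameter_nm`.
#' @export
gyration_calibration <- function() {
  bp <- c(2686, 4361, 7164, 11300)
  data.frame(bp = bp, diameter_nm = 265 * sqrt(bp / 11300))
}
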