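# CSV dialects shared by all modules, and configuration loading.
#
# Units are encoded in column names (x_um, t_s, time_min) so files are
# self-describing; schemas are validated strictly on read.

traj_cols <- c("track_id", "frame", "t_s", "x_um", "y_um", "cell_id")

require_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(sprintf("%s is missing column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  invisible(df)
}

#' Read trajectories from CSV
#'
#' Reads the package's trajectory dialect (`track_id`, `frame`, `t_s`,
#' `x_um`, `y_um`, `cell_id`), groups rows by `track_id` and sorts each
#' track by frame, so row order in the file does not matter. Duplicated or
#' non-increasing frames within a track are an error (with the track
#' named), as is any missing column.
#'
#' @param path CSV file path.
#' @return Named list of [trajectory()] objects.
#' @seealso [write_trajectories()]
#' @export
read_trajectories <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_cols(df, traj_cols, sprintf("'%s'", path))
  out <- lapply(split(df, df$track_id), function(tr) {
    tr <- tr[order(tr$frame), , drop = FALSE]
    if (anyDuplicated(tr$frame) || any(diff(tr$t_s) <= 0))
      stop(sprintf("track '%s': frames/times must be strictly increasing",
                   tr$track_id[1]), call. = FALSE)
    trajectory(t_s = tr$t_s, x_um = tr$x_um, y_um = tr$y_um,
               track_id = tr$track_id[1], cell_id = tr$cell_id[1],
               frame = tr$frame)
  })
  out[unique(df$track_id)]
}

#' Write trajectories to CSV
#'
#' Inverse of [read_trajectories()]: concatenates one or more trajectories
#' into the shared CSV dialect.
#'
#' @param trajs a [trajectory()] or list of them.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(trajs, path) {
  if (inherits(trajs, "trajectory")) trajs <- list(trajs)
  df <- do.call(rbind, lapply(trajs, function(tr) as.data.frame(tr)[traj_cols]))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read / write qPCR plates
#'
#' CSV dialect: `well`, `target` (one of `chr`, `pl`, `cal_chr`, `cal_pl`),
#' `ct`. Amplification efficiencies are not stored in the file; supply them
#' to [qpcr_ratio()] or rely on its perfect-doubling default.
#'
#' @param path CSV file path.
#' @param plate a `qpcr_plate` or compatible data frame.
#' @return `read_qpcr`: a `qpcr_plate` data frame. `write_qpcr`: `path`,
#'   invisibly.
#' @export
read_qpcr <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_cols(df, c("well", "target", "ct"), sprintf("'%s'", path))
  bad <- setdiff(unique(df$target), c("chr", "pl", "cal_chr", "cal_pl"))
  if (length(bad))
    stop("unknown qPCR target(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  class(df) <- c("qpcr_plate", "data.frame")
  df
}

#' @rdname read_qpcr
#' @export
write_qpcr <- function(plate, path) {
  utils::write.csv(as.data.frame(plate)[c("well", "target", "ct")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Read / write per-cell spot counts
#'
#' CSV dialect: `cell_id`, `n_spots` (and optionally `time_min` for
#' calibration tables).
#'
#' @param path CSV file path.
#' @param counts data frame with at least `cell_id`, `n_spots`.
#' @return `read_counts`: the data frame. `write_counts`: `path`, invisibly.
#' @export
read_counts <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_cols(df, c("cell_id", "n_spots"), sprintf("'%s'", path))
  df
}

#' @rdname read_counts
#' @export
write_counts <- function(counts, path) {
  utils::write.csv(counts, path, row.names = FALSE)
  invisible(path)
}

#' Read / write replisome spot events
#'
#' CSV dialect: `cell_id`, `marker` (`SSB`, `DnaN` or `DnaQ`), `t_start_s`,
#' `t_end_s`, `rel_pos`. Lifetimes must be non-negative
#' (`t_end_s >= t_start_s`).
#'
#' @param path CSV file path.
#' @param events compatible data frame.
#' @return `read_events`: the data frame. `write_events`: `path`, invisibly.
#' @export
read_events <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_cols(df, c("cell_id", "marker", "t_start_s", "t_end_s", "rel_pos"),
               sprintf("'%s'", path))
  if (any(df$t_end_s < df$t_start_s))
    stop("event lifetimes must be non-negative", call. = FALSE)
  df
}

#' @rdname read_events
#' @export
write_events <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE)
  invisible(path)
}

#' Read / write line profiles
#'
#' CSV dialect: `cell_id`, `channel` (`plasmid` or `nucleoid`), `rel_pos`,
#' `intensity`. `read_profiles` returns a list of per-cell-and-channel
#' data frames suitable for [average_profiles()].
#'
#' @param path CSV file path.
#' @param profiles list of profile data frames (each with `cell_id` and
#'   `channel` columns) or one combined data frame.
#' @return `read_profiles`: named list of profile data frames.
#'   `write_profiles`: `path`, invisibly.
#' @export
read_profiles <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_cols(df, c("cell_id", "channel", "rel_pos", "intensity"),
               sprintf("'%s'", path))
  split(df, interaction(df$cell_id, df$channel, drop = TRUE))
}

#' @rdname read_profiles
#' @export
write_profiles <- function(profiles, path) {
  if (is.data.frame(profiles)) profiles <- list(profiles)
  df <- do.call(rbind, lapply(profiles, function(p)
    p[c("cell_id", "channel", "rel_pos", "intensity")]))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Load a validated configuration file
#'
#' Reads a JSON (`.json`) or YAML (`.yml`/`.yaml`) file and validates it
#' against a schema of defaults: unknown keys are rejected by name, values
#' must match the type of the default, and absent keys are filled in. An
#' empty file yields all defaults. The default schema is the simulator
#' configuration; pass any named list of defaults to validate other stages.
#'
#' @param path config file path.
#' @param schema named list of defaults defining the allowed keys and their
#'   types; default: the [sim_config()] argument defaults.
#' @return Named list with every schema key present.
#' @seealso [load_sim_config()]
#' @export
load_config <- function(path, schema = sim_config_defaults()) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "json") {
    txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
    if (!nzchar(trimws(txt))) list()
    else jsonlite::fromJSON(txt, simplifyVector = TRUE)
  } else if (ext %in% c("yml", "yaml")) {
    yaml::read_yaml(path) %||% list()
  } else stop("config must be .json, .yml or .yaml", call. = FALSE)
  if (!is.list(raw)) stop("config must be a mapping of key: value",
                          call. = FALSE)
  unknown <- setdiff(names(raw), names(schema))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  out <- schema
  for (key in names(raw)) {
    val <- raw[[key]]
    dflt <- schema[[key]]
    if (!is.null(dflt) && is.numeric(dflt) && !is.numeric(val))
      stop(sprintf("config key '%s': expected a number, got %s", key,
                   class(val)[1]), call. = FALSE)
    if (!is.null(dflt) && is.character(dflt) && !is.character(val))
      stop(sprintf("config key '%s': expected a string, got %s", key,
                   class(val)[1]), call. = FALSE)
    out[[key]] <- val
  }
  out
}

# Defaults of sim_config() as a plain named list (the config schema).
sim_config_defaults <- function() {
  f <- formals(sim_config)
  f$rep_mode <- "rnaI_feedback"
  f$rep_rate <- NULL
  f$rnaI_K <- NULL
  lapply(f, function(v) if (is.language(v)) eval(v) else v)
}

#' Load a simulator configuration from file
#'
#' [load_config()] followed by [sim_config()] validation.
#'
#' @param path JSON or YAML file with `sim_config` keys.
#' @return A `sim_config`.
#' @export
load_sim_config <- function(path) {
  do.call(sim_config, load_config(path, sim_config_defaults()))
}

#' Write per-track confinement fits to CSV
#'
#' Serialises a list of [fit_confinement()] results as the fit-table
#' dialect: `track_id`, `axis`, `L_um`, `D_um2_s`, `plateau_reached`,
#' `rss`.
#'
#' @param fits named list of `confinement_fit` objects (names become
#'   `track_id`).
#' @param path output CSV path.
#' @return The table, invisibly (also written to `path` if not `NULL`).
#' @export
write_fit_table <- function(fits, path = NULL) {
  ids <- names(fits) %||% sprintf("track%03d", seq_along(fits))
  df <- do.call(rbind, Map(function(f, id) {
    data.frame(track_id = id, axis = f$axis, L_um = f$L, D_um2_s = f$D,
               plateau_reached = f$plateau_reached, rss = f$rss)
  }, fits, ids))
  rownames(df) <- NULL
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
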