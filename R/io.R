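trajectory_columns <- function() {
  c("t_ms", "rx", "ry", "rz", "wx", "wy", "wz", "drx", "dry", "drz",
    muscle_cols("u_"), muscle_cols("T_"))
}

#' Write a trajectory to CSV
#'
#' Fixed column order `t_ms, rx..rz, wx..wz, drx..drz, u_LR..u_IO,
#' T_LR..T_IO` with a `#`-prefixed unit header comment. Values are written
#' at 12 significant digits, giving a lossless round trip at 1e-9 relative
#' precision.
#'
#' @param traj an `eye_trajectory`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(all(trajectory_columns() %in% names(traj)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0(
    "# units: t_ms ms; rx..rz rad/2; wx..wz rad/s; drx..drz rad/2 per s; ",
    "u_* mm (re. straight-ahead holding command); T_* N"), con)
  df <- traj[, trajectory_columns()]
  df[] <- lapply(df, function(z) signif(z, 12))
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trajectory written by [write_trajectory()]
#'
#' @param path CSV file.
#' @return an `eye_trajectory` data frame.
#' @export
read_trajectory <- function(path) {
  first <- readLines(path, n = 1)
  if (!startsWith(first, "# units:"))
    stop("not a trajectory file: missing unit header comment", call. = FALSE)
  df <- read.csv(path, comment.char = "#")
  missing <- setdiff(trajectory_columns(), names(df))
  if (length(missing))
    stop("trajectory file lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  df <- df[, trajectory_columns()]
  class(df) <- c("eye_trajectory", "data.frame")
  attr(df, "dt") <- 1e-3
  df
}

#' Serialize / restore a run configuration
#'
#' A run configuration (plant geometry, physical parameters, cost weights
#' and a master seed) serializes losslessly to JSON, so any run can be
#' re-executed exactly from its stored configuration.
#'
#' @param plant an [eye_plant()].
#' @param weights a [cost_weights()].
#' @param seed master seed.
#' @param path output file.
#' @return `write_run_config()` returns `path` invisibly;
#'   `read_run_config()` returns `list(plant=, weights=, seed=)` rebuilt
#'   from the file.
#' @export
write_run_config <- function(plant, weights = cost_weights(), seed = 1,
                             path) {
  g <- plant$geometry; pp <- plant$params
  cfg <- list(
    geometry = list(radius = g$radius,
                    insertion = unname(apply(g$insertion, 1, c, simplify = FALSE)),
                    attach = unname(apply(g$attach, 1, c, simplify = FALSE)),
                    pulley = g$pulley, gain = g$gain),
    params = unclass(pp)[c("inertia", "damping", "stiffness", "pretension",
                           "dt", "tension_floor")],
    weights = unclass(weights),
    seed = seed)
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_mat <- function(x) if (is.list(x)) do.call(rbind, x) else as.matrix(x)
  geo <- eye_geometry(radius = cfg$geometry$radius,
                      insertion = as_mat(cfg$geometry$insertion),
                      attach = as_mat(cfg$geometry$attach),
                      pulley = cfg$geometry$pulley,
                      gain = cfg$geometry$gain)
  pp <- do.call(plant_params, as.list(cfg$params))
  w <- do.call(cost_weights, as.list(cfg$weights))
  list(plant = eye_plant(geo, pp), weights = w, seed = cfg$seed)
}

#' Derive per-stage seeds from a master seed
#'
#' Deterministic splitter: stage `k` (1-based) receives
#' `(master + k * 10007) mod (2^31 - 1)`, keeping every derived seed a
#' valid 32-bit integer. Used so that one master seed reproduces an entire
#' multi-stage run while the stages stay statistically decoupled.
#'
#' @param master master seed (integer).
#' @param k stage index or vector of indices.
#' @return integer seed(s).
#' @export
split_seed <- function(master, k) {
  as.integer((as.numeric(master) + as.numeric(k) * 10007) %% (2^31 - 1))
}

#' Write / read a saccade data set as CSVs plus a JSON manifest
#'
#' The data set is stored as a directory: one trajectory CSV per saccade
#' ([write_trajectory()] schema) and a `manifest.json` holding, per record,
#' the goal, start, end, duration, amplitude, costs and endpoint error,
#' together with the paradigm configuration snapshot.
#'
#' @param dataset a `saccade_dataset`.
#' @param dir output directory (created if needed).
#' @return `write_dataset()` returns `dir` invisibly; `read_dataset()`
#'   returns a list with the manifest and trajectories (a full
#'   `saccade_dataset` is reconstructed except for the control knots, which
#'   are recovered from the stored `u_*` columns).
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("saccade_%03d.csv", seq_along(dataset$records))
  man <- list(paradigm = dataset$paradigm,
              config = unclass(dataset$config),
              n = dataset$n,
              records = lapply(seq_along(dataset$records), function(j) {
                rec <- dataset$records[[j]]
                list(file = files[j], goal = rec$goal, start = rec$start,
                     end = rec$end, D = rec$D, amplitude = rec$amplitude,
                     cost = as.list(rec$cost),
                     endpoint_error_deg = rec$endpoint_error_deg,
                     seed = rec$seed)
              }))
  jsonlite::write_json(man, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  for (j in seq_along(dataset$records))
    write_trajectory(dataset$records[[j]]$trajectory, file.path(dir, files[j]))
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  if (is.null(manifest$records) || length(manifest$records) == 0)
    stop("empty dataset: manifest lists no records", call. = FALSE)
  recs <- lapply(seq_len(nrow(manifest$records)), function(j) {
    row <- manifest$records[j, ]
    traj <- read_trajectory(file.path(dir, row$file))
    u <- t(as.matrix(traj[seq_len(row$D), muscle_cols("u_")]))
    rownames(u) <- c("LR", "MR", "SR", "IR", "SO", "IO")
    structure(list(goal = unlist(row$goal), start = unlist(row$start),
                   end = unlist(row$end), D = row$D,
                   amplitude = row$amplitude,
                   controls = u, trajectory = traj,
                   cost = unlist(row$cost),
                   endpoint_error_deg = row$endpoint_error_deg,
                   seed = row$seed), class = "saccade_record")
  })
  structure(list(records = recs, paradigm = manifest$paradigm,
                 config = manifest$config, n = length(recs)),
            class = "saccade_dataset")
}
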