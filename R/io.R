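#' Write a trial log
#'
#' Serializes a trial set as a CSV log (one row per trial: `trial_id`,
#' `alpha`, `target_side`, `choice`, `rt_ms`, `correct`, `timeout`,
#' `stimulus_seed`, `noise_seed`, `noise_ref`) plus a compressed array
#' container holding the per-trial bar-noise matrices keyed by `noise_ref`.
#'
#' @param trials a `trial_set`.
#' @param dir output directory (created if missing).
#' @param name base name for the artifact pair.
#' @return invisibly, the paths written (`log`, `noise`).
#' @export
write_trial_log <- function(trials, dir, name = "trials") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  df <- as.data.frame.trial_set(trials)
  df$noise_ref <- sprintf("trial_%06d", df$trial_id)
  log_path <- file.path(dir, paste0(name, ".csv"))
  noise_path <- file.path(dir, paste0(name, "_noise.rds"))
  utils::write.csv(df, log_path, row.names = FALSE)
  noise <- lapply(seq_along(trials), function(i)
    list(noise_left = trials[[i]]$noise_left,
         noise_right = trials[[i]]$noise_right,
         frame_ms = trials[[i]]$frame_ms))
  names(noise) <- df$noise_ref
  saveRDS(noise, noise_path, compress = "gzip")
  invisible(c(log = log_path, noise = noise_path))
}

#' Read a trial log
#'
#' Reconstructs a `trial_set` from the CSV + noise-container pair written by
#' [write_trial_log()] (or any log matching that schema, which is how
#' externally recorded data enter the analysis).
#'
#' @param log_path path to the trial CSV.
#' @param noise_path path to the noise container; defaults to the sibling
#'   `<name>_noise.rds`.
#' @return a `trial_set`.
#' @export
read_trial_log <- function(log_path,
                           noise_path = sub("\\.csv$", "_noise.rds", log_path)) {
  df <- utils::read.csv(log_path, stringsAsFactors = FALSE)
  required <- c("trial_id", "alpha", "target_side", "choice", "rt_ms",
                "correct", "timeout", "noise_ref")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("trial log lacks columns: ", paste(missing, collapse = ", "))
  noise <- if (file.exists(noise_path)) readRDS(noise_path) else NULL
  trials <- lapply(seq_len(nrow(df)), function(i) {
    nz <- if (!is.null(noise)) noise[[df$noise_ref[i]]] else NULL
    structure(list(
      noise_left = nz$noise_left, noise_right = nz$noise_right,
      alpha = df$alpha[i], target_side = df$target_side[i],
      choice = df$choice[i],
      rt = if (df$timeout[i]) NA_real_ else df$rt_ms[i],
      correct = df$correct[i], timeout = df$timeout[i],
      crossing_frame = NA_integer_,
      frame_ms = if (!is.null(nz)) nz$frame_ms else 1000 / 30,
      stimulus_seed = df$stimulus_seed[i], noise_seed = df$noise_seed[i]
    ), class = "trial_record")
  })
  as_trial_set(trials)
}

#' Write a kernel (or its curves) as CSV
#'
#' Space-by-lag matrix with a `bar` index column and one column per lag,
#' headed by the lag in ms before the response.
#'
#' @param ci a `classification_image`.
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_kernel_csv <- function(ci, path) {
  stopifnot(inherits(ci, "classification_image"))
  df <- as.data.frame(ci$kernel)
  names(df) <- sprintf("lag_%.1f_ms", ci$lag_ms)
  df <- cbind(bar = ci$space_axis, df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a kernel CSV
#'
#' @param path CSV written by [write_kernel_csv()].
#' @return a `classification_image` (kernel, lag and space axes only).
#' @export
read_kernel_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  lag_cols <- grep("^lag_", names(df))
  kernel <- as.matrix(df[, lag_cols])
  dimnames(kernel) <- NULL
  lag_ms <- as.numeric(sub("^lag_([0-9.]+)_ms$", "\\1", names(df)[lag_cols]))
  structure(list(kernel = kernel, mu1 = NULL, mu0 = NULL,
                 n_trials_per_lag = NULL, lag_ms = lag_ms,
                 space_axis = df$bar, statistic = "mean",
                 n_trials_used = NA_integer_,
                 motor_delay = NA_real_,
                 frame_ms = if (length(lag_ms) > 1) diff(lag_ms[1:2]) else NA_real_),
            class = "classification_image")
}

#' Write / read configuration files
#'
#' Stimulus configurations and observer parameters round-trip through plain
#' YAML key/value files, with the shipped defaults for any omitted key.
#'
#' @param x a `stimulus_config` or `model_params`.
#' @param path file path.
#' @return `write_config`: invisibly `path`; `read_stimulus_config` /
#'   `read_model_params`: the reconstructed object.
#' @export
write_config <- function(x, path) {
  keep <- setdiff(names(x), c("n_frames", "n_samples", "frame_ms"))
  yaml::write_yaml(lapply(unclass(x)[keep], function(v)
    if (is.integer(v)) as.integer(v) else v), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_stimulus_config <- function(path) {
  vals <- yaml::read_yaml(path)
  bad <- setdiff(names(vals), names(formals(stimulus_config)))
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(stimulus_config, vals)
}

#' @rdname write_config
#' @export
read_model_params <- function(path) {
  vals <- yaml::read_yaml(path)
  bad <- setdiff(names(vals), names(formals(model_params)))
  if (length(bad)) stop("unknown parameter keys: ", paste(bad, collapse = ", "))
  do.call(model_params, vals)
}

#' Write a run manifest
#'
#' JSON record tying a pipeline stage's outputs to the command, the full
#' configuration snapshot, the master seed and the package version, so any
#' artifact can be regenerated from its manifest alone.
#'
#' @param path output JSON path.
#' @param command stage name.
#' @param seed master seed.
#' @param config configuration object(s) to snapshot.
#' @param inputs,outputs character vectors of paths.
#' @return invisibly, `path`.
#' @export
write_manifest <- function(path, command, seed, config = NULL,
                           inputs = character(), outputs = character()) {
  manifest <- list(
    command = command,
    seed = seed,
    package = "rlci",
    version = as.character(utils::packageVersion("rlci")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = if (!is.null(config)) unclass(config),
    inputs = inputs, outputs = outputs
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
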