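#' Read a trial table from CSV
#'
#' Validates the schema (comma-separated, UTF-8, header row, "." decimal).
#' Required columns: participant_id, modifier1, modifier2, pole, rt_ms,
#' feedback. Missing derived columns (negated, n_modifiers, modifier_combo,
#' is_not_not) are computed from the modifiers; unknown columns are
#' preserved.
#'
#' @param path CSV path.
#' @param negation_rule "any_not" or "odd_not", used if `negated` is absent.
#' @return a `trial_table` data.frame.
#' @export
read_trial_table <- function(path, negation_rule = "any_not") {
  df <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("participant_id", "modifier1", "modifier2", "pole",
                "rt_ms", "feedback")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(sprintf("trial table is missing required column(s): %s",
                 paste(missing, collapse = ", ")))
  if (!all(df$pole %in% c("low", "high")))
    stop("column 'pole' must contain only 'low'/'high'")
  if (is.null(df$negated))
    df$negated <- is_negated(df$modifier1, df$modifier2, negation_rule)
  df$negated <- as.logical(df$negated)
  if (is.null(df$n_modifiers))
    df$n_modifiers <- (df$modifier1 != "none") + (df$modifier2 != "none")
  if (is.null(df$modifier_combo))
    df$modifier_combo <- combo_label(df$modifier1, df$modifier2)
  if (is.null(df$is_not_not))
    df$is_not_not <- df$modifier1 == "not" & df$modifier2 == "not"
  class(df) <- c("trial_table", "data.frame")
  df
}

#' Write a trial table to CSV
#'
#' @param trials the table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trial_table <- function(trials, path) {
  write.csv(as.data.frame(trials), path, row.names = FALSE)
  invisible(path)
}

#' Read / write trajectories (long CSV: trial_id, t_ms, x)
#'
#' @param path CSV path.
#' @return a `trajectory_set` data.frame.
#' @export
read_trajectories <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("trial_id", "t_ms", "x"), names(df))
  if (length(missing))
    stop(sprintf("trajectory file is missing required column(s): %s",
                 paste(missing, collapse = ", ")))
  class(df) <- c("trajectory_set", "data.frame")
  df
}

#' @rdname read_trajectories
#' @param trajs the trajectory set to write.
#' @export
write_trajectories <- function(trajs, path) {
  write.csv(as.data.frame(trajs), path, row.names = FALSE)
  invisible(path)
}

#' Read / write an epoch container
#'
#' The on-disk container is a single RDS file holding the named members
#' data (trials x sensors x time), times_ms, sfreq and labels; members are
#' validated on read and the array round-trips at machine precision.
#'
#' @param ep an `epoch_set`.
#' @param path file path.
#' @return `path` invisibly (write); an `epoch_set` (read).
#' @export
write_epochs <- function(ep, path) {
  stopifnot(inherits(ep, "epoch_set"))
  saveRDS(unclass(ep), path)
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  obj <- readRDS(path)
  missing <- setdiff(c("data", "times_ms", "sfreq", "labels"), names(obj))
  if (length(missing))
    stop(sprintf("epoch container is missing member(s): %s",
                 paste(missing, collapse = ", ")))
  new_epoch_set(obj$data, obj$times_ms, obj$sfreq, obj$labels)
}

#' Write an analysis result as JSON
#'
#' @param obj a list / data.frame of results.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(obj, path) {
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}

#' Read / write a run configuration (YAML)
#'
#' The configuration round-trips losslessly: read(write(read(x))) is
#' identical to read(x). Missing keys take the package defaults of
#' [default_run_config()].
#'
#' @param path YAML path.
#' @return named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  out <- modifyList(default_run_config(), cfg)
  class(out) <- c("run_config", "list")
  out
}

#' @rdname read_run_config
#' @param config a run configuration list.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Default pipeline configuration
#'
#' Every simulation field plus the stage parameters (folds, windows,
#' permutations, bands, alpha, seeds, exclusion switches).
#'
#' @return named list of class `run_config`.
#' @export
default_run_config <- function() {
  structure(list(
    seed = 1L,
    simulate = list(n_participants = 10, n_trials_per_cell = 20,
                    n_sensors = 30, sfreq = 100,
                    epoch_window = c(-300, 1000),
                    pattern_window = c(130, 550),
                    snr = 1, mechanism = "mitigation",
                    feedback_error_rate = 0.15,
                    negation_rule = "any_not"),
    behavior = list(rt_sd_mult = 2),
    trajectory = list(window = c(600, 2000), n_perm = 10000,
                      exclude_not_not = TRUE),
    decoding = list(k_folds = 10, C = 1, var_explained = 0.99,
                    window = c(0, 500), n_perm = 10000, alpha = 0.05,
                    include_negative_feedback = FALSE),
    tfr = list(enabled = FALSE, band = c(12, 20),
               baseline = c(-300, -100), n_perm = 10000,
               windows = list(c(0, 500), c(500, 1000)))
  ), class = c("run_config", "list"))
}
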