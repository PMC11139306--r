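#' Run the full analysis pipeline
#'
#' Executes simulate -> behavioral statistics -> trajectory regression ->
#' decoding + mechanism adjudication (-> optional beta-band contrast) from a
#' configuration, writing every stage's outputs plus a manifest recording the
#' parameters and seeds, so a run can be reproduced exactly from its
#' manifest.
#'
#' @param config a `run_config` list (see [default_run_config()]) or the path
#'   to a YAML file.
#' @param out_dir output directory (created if needed).
#' @return the output directory, invisibly. Side effects: trial table and
#'   trajectory CSVs, epoch container, JSON results per stage, manifest.json.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  config <- modifyList(default_run_config(), config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_stage <- function(stage, ...) {
    message(sprintf("[%s] %s", stage, sprintf(...)))
  }

  sim_args <- config$simulate
  sim_args$seed <- config$seed
  cfg <- do.call(simulation_config, sim_args)

  log_stage("simulate", "mechanism=%s participants=%d trials/cell=%d",
            cfg$mechanism, cfg$n_participants, cfg$n_trials_per_cell)
  trials <- simulate_trial_table(cfg)
  trajs <- simulate_trajectories(trials, cfg)
  epochs <- simulate_meg_epochs(trials, cfg)
  write_trial_table(trials, file.path(out_dir, "trials.csv"))
  write_trajectories(trajs, file.path(out_dir, "trajectories.csv"))
  write_epochs(epochs, file.path(out_dir, "epochs.rds"))

  log_stage("behavior", "filtering %d trials", nrow(trials))
  filtered <- filter_trials(trials, config$behavior$rt_sd_mult)
  rt <- rt_stats(filtered)
  ep_stats <- endpoint_stats(filtered)
  write_results(list(
    removed = as.list(attr(filtered, "removed")),
    rt_anova = as.data.frame(rt),
    endpoint_mean_anova = as.data.frame(ep_stats$anova_mean),
    endpoint_sd_anova = as.data.frame(ep_stats$anova_sd),
    posthoc_holm = as.list(ep_stats$posthoc)
  ), file.path(out_dir, "behavior.json"))

  log_stage("trajectory", "per-timepoint regression, window %g..%g ms",
            config$trajectory$window[1], config$trajectory$window[2])
  keep <- filtered$negated
  if (config$trajectory$exclude_not_not) keep <- keep & !filtered$is_not_not
  betas <- lapply(unique(filtered$participant_id), function(p) {
    rows <- which(filtered$participant_id == p & keep)
    tm <- trajectory_matrix(trajs, filtered$trajectory_id[rows])
    timepoint_regression(tm$x, filtered$pole[rows], tm$t_ms)
  })
  traj_test <- group_beta_inference(betas, window = config$trajectory$window,
                                    n_perm = config$trajectory$n_perm,
                                    seed = config$seed)
  write_results(cluster_test_summary(traj_test),
                file.path(out_dir, "trajectory.json"))

  log_stage("decode", "k=%d C=%g window %g..%g ms",
            config$decoding$k_folds, config$decoding$C,
            config$decoding$window[1], config$decoding$window[2])
  prep <- preprocess_epochs(epochs, baseline = c(cfg$epoch_window[1], 0),
                            reject = Inf, target_sfreq = NULL)
  study <- decoding_study(prep, k = config$decoding$k_folds,
                          C = config$decoding$C,
                          var_explained = config$decoding$var_explained,
                          include_negative_feedback =
                            config$decoding$include_negative_feedback,
                          seed = config$seed)
  verdict <- adjudicate(study, window = config$decoding$window,
                        alpha = config$decoding$alpha,
                        n_perm = config$decoding$n_perm,
                        seed = config$seed)
  write_results(list(label = verdict$label,
                     evidence = lapply(verdict$evidence, isTRUE),
                     window = verdict$window, alpha = verdict$alpha),
                file.path(out_dir, "verdict.json"))

  tfr_summary <- NULL
  if (isTRUE(config$tfr$enabled)) {
    log_stage("tfr", "band %g-%g Hz", config$tfr$band[1], config$tfr$band[2])
    bc <- band_contrast_study(prep, band = config$tfr$band,
                              baseline = config$tfr$baseline)
    tests <- condition_contrast(bc$neg, bc$aff, bc$times_ms,
                                windows = config$tfr$windows,
                                n_perm = config$tfr$n_perm,
                                seed = config$seed)
    tfr_summary <- lapply(tests, cluster_test_summary)
    write_results(tfr_summary, file.path(out_dir, "tfr.json"))
  }

  manifest <- list(
    package = "negshift",
    version = as.character(utils::packageVersion("negshift")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    config = unclass(config),
    outputs = list.files(out_dir)
  )
  write_results(manifest, file.path(out_dir, "manifest.json"))
  log_stage("done", "verdict=%s outputs in %s", verdict$label, out_dir)
  invisible(out_dir)
}

# Serializable summary of a cluster test.
cluster_test_summary <- function(x) {
  cl <- x$clusters
  list(
    window = x$window,
    tail = x$tail,
    n_permutations = x$n_permutations,
    threshold = x$threshold,
    clusters = if (nrow(cl)) data.frame(
      start_ms = x$times_ms[cl$start], end_ms = x$times_ms[cl$end],
      sign = cl$sign, stat = cl$stat, p = cl$p) else list()
  )
}
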