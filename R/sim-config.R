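#' Simulation configuration
#'
#' Builds and validates the configuration object consumed by the three
#' synthetic-data generators. Defaults describe a desk-scale version of the
#' factorial phrase design: each participant sees all 9 modifier combinations
#' ("### ###", "### really", "really ###", "### not", "not ###", "really not",
#' "not really", "really really", "not not") crossed with the two antonym
#' poles, `n_trials_per_cell` times each.
#'
#' The `mechanism` and `lambda` fields control how the negated-condition class
#' pattern in the simulated epochs relates to the affirmative one:
#' `no_effect` (lambda = 1), `mitigation` (0 < lambda < 1), `inversion`
#' (lambda = -1), or `change` (an orthogonal sensor pattern; lambda ignored).
#'
#' Trajectory dynamics are two-stage for negated trials: an initial pull
#' toward the adjective's own pole (`traj_stage1`), then a later pull toward
#' the mitigated endpoint on the opposite side (`traj_stage2`). Onsets are in
#' ms from adjective onset; gains are first-order pursuit rates in 1/s.
#'
#' @param n_participants number of simulated participants.
#' @param n_trials_per_cell trials per modifier-combination x pole cell.
#' @param n_sensors number of abstract sensors in the epoch array.
#' @param sfreq sampling rate of the simulated epochs, Hz.
#' @param epoch_window c(start, end) of the epoch in ms from adjective onset.
#' @param pattern_window c(start, end) in ms during which the class pattern is
#'   active; must lie inside `epoch_window`.
#' @param snr ratio of peak pattern amplitude to sensor noise SD.
#' @param mechanism one of "no_effect", "mitigation", "inversion", "change".
#' @param lambda scale factor applied to the negated-condition pattern.
#'   Defaults to the canonical value for the chosen mechanism
#'   (1, 0.5, -1 respectively); ignored for "change".
#' @param noise_lowpass_hz optional cutoff for low-pass smoothing of the
#'   sensor noise (moving-average kernel); NULL leaves the noise white.
#' @param traj_stage1,traj_stage2 named numeric c(onset_ms, gain).
#' @param traj_noise_sd trajectory noise SD per sqrt(second).
#' @param endpoint_means named numeric: mean final rating on [-1, 1] for
#'   aff_low, aff_high, neg_low, neg_high (unswapped coordinates, +1 = high
#'   pole).
#' @param endpoint_sd_aff,endpoint_sd_neg endpoint dispersions; the default
#'   has the negated endpoints more variable.
#' @param rt_meanlog,rt_sdlog lognormal RT parameters (ms scale).
#' @param rt_offset_negated,rt_offset_low additive RT offsets (ms) for
#'   negated and low-pole trials.
#' @param feedback_error_rate probability a trial is flagged with negative
#'   feedback.
#' @param beta_burst optional named numeric c(freq_hz, start_ms, end_ms, amp):
#'   an oscillatory burst added to negated trials only, emulating a
#'   beta-power increase under negation. NULL disables it.
#' @param negation_rule "any_not" (default; "not not" counts as negated, the
#'   grouping used for the neural contrasts) or "odd_not".
#' @param seed master integer seed; per-participant streams are derived from
#'   it by fixed offsets so participant subsets are reproducible.
#'
#' @return an object of class `sim_config` (a validated named list).
#' @export
simulation_config <- function(n_participants = 10,
                              n_trials_per_cell = 20,
                              n_sensors = 30,
                              sfreq = 100,
                              epoch_window = c(-300, 1000),
                              pattern_window = c(130, 550),
                              snr = 1,
                              mechanism = c("mitigation", "no_effect",
                                            "inversion", "change"),
                              lambda = NULL,
                              noise_lowpass_hz = NULL,
                              traj_stage1 = c(onset_ms = 350, gain = 2.5),
                              traj_stage2 = c(onset_ms = 700, gain = 4),
                              traj_noise_sd = 0.05,
                              endpoint_means = c(aff_low = -0.8, aff_high = 0.8,
                                                 neg_low = 0.35, neg_high = -0.35),
                              endpoint_sd_aff = 0.15,
                              endpoint_sd_neg = 0.30,
                              rt_meanlog = log(1400),
                              rt_sdlog = 0.25,
                              rt_offset_negated = 150,
                              rt_offset_low = 80,
                              feedback_error_rate = 0.15,
                              beta_burst = NULL,
                              negation_rule = c("any_not", "odd_not"),
                              seed = 1L) {
  mechanism <- match.arg(mechanism)
  negation_rule <- match.arg(negation_rule)
  if (is.null(lambda)) {
    lambda <- switch(mechanism,
                     no_effect = 1, mitigation = 0.5,
                     inversion = -1, change = NA_real_)
  }
  cfg <- list(
    n_participants = as.integer(n_participants),
    n_trials_per_cell = as.integer(n_trials_per_cell),
    n_sensors = as.integer(n_sensors),
    sfreq = sfreq,
    epoch_window = as.numeric(epoch_window),
    pattern_window = as.numeric(pattern_window),
    snr = snr,
    mechanism = mechanism,
    lambda = lambda,
    noise_lowpass_hz = noise_lowpass_hz,
    traj_stage1 = traj_stage1,
    traj_stage2 = traj_stage2,
    traj_noise_sd = traj_noise_sd,
    endpoint_means = endpoint_means,
    endpoint_sd_aff = endpoint_sd_aff,
    endpoint_sd_neg = endpoint_sd_neg,
    rt_meanlog = rt_meanlog,
    rt_sdlog = rt_sdlog,
    rt_offset_negated = rt_offset_negated,
    rt_offset_low = rt_offset_low,
    feedback_error_rate = feedback_error_rate,
    beta_burst = beta_burst,
    negation_rule = negation_rule,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  err <- function(field, msg) {
    stop(sprintf("invalid simulation config field '%s': %s", field, msg),
         call. = FALSE)
  }
  for (f in c("n_participants", "n_trials_per_cell", "n_sensors")) {
    if (length(cfg[[f]]) != 1L || is.na(cfg[[f]]) || cfg[[f]] < 1L)
      err(f, "must be a positive count")
  }
  if (!cfg$mechanism %in% c("no_effect", "mitigation", "inversion", "change"))
    err("mechanism", "unknown mechanism")
  if (cfg$mechanism == "no_effect" && !isTRUE(all.equal(cfg$lambda, 1)))
    err("lambda", "mechanism 'no_effect' implies lambda = 1")
  if (cfg$mechanism == "mitigation" &&
      (is.na(cfg$lambda) || cfg$lambda <= 0 || cfg$lambda >= 1))
    err("lambda", "mechanism 'mitigation' implies 0 < lambda < 1")
  if (cfg$mechanism == "inversion" && !isTRUE(all.equal(cfg$lambda, -1)))
    err("lambda", "mechanism 'inversion' implies lambda = -1")
  if (cfg$mechanism == "change" && cfg$n_sensors < 2L)
    err("n_sensors", "mechanism 'change' needs >= 2 sensors for an orthogonal pattern")
  if (cfg$snr <= 0) err("snr", "must be > 0")
  if (cfg$feedback_error_rate < 0 || cfg$feedback_error_rate >= 1)
    err("feedback_error_rate", "must be in [0, 1)")
  if (length(cfg$epoch_window) != 2L || diff(cfg$epoch_window) <= 0)
    err("epoch_window", "must be an increasing (start, end) pair")
  if (cfg$pattern_window[1] < cfg$epoch_window[1] ||
      cfg$pattern_window[2] > cfg$epoch_window[2] ||
      diff(cfg$pattern_window) <= 0)
    err("pattern_window", "must be an increasing pair inside epoch_window")
  if (cfg$traj_stage2[["onset_ms"]] <= cfg$traj_stage1[["onset_ms"]])
    err("traj_stage2", "stage-2 onset must come after stage-1 onset")
  needed <- c("aff_low", "aff_high", "neg_low", "neg_high")
  if (!all(needed %in% names(cfg$endpoint_means)))
    err("endpoint_means", paste("must name", paste(needed, collapse = ", ")))
  if (any(abs(cfg$endpoint_means) > 1))
    err("endpoint_means", "must lie on [-1, 1]")
  if (cfg$endpoint_sd_aff < 0 || cfg$endpoint_sd_neg < 0)
    err("endpoint_sd_aff", "dispersions must be nonnegative")
  if (!is.null(cfg$beta_burst)) {
    needed <- c("freq_hz", "start_ms", "end_ms", "amp")
    if (!all(needed %in% names(cfg$beta_burst)))
      err("beta_burst", paste("must name", paste(needed, collapse = ", ")))
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration\n")
  cat(sprintf("  participants: %d, trials/cell: %d, sensors: %d\n",
              x$n_participants, x$n_trials_per_cell, x$n_sensors))
  cat(sprintf("  mechanism: %s (lambda = %s), snr = %g\n",
              x$mechanism, format(x$lambda), x$snr))
  cat(sprintf("  epochs: %g..%g ms @ %g Hz, pattern %g..%g ms\n",
              x$epoch_window[1], x$epoch_window[2], x$sfreq,
              x$pattern_window[1], x$pattern_window[2]))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

# Fixed per-participant, per-generator seed streams so that adding or
# subsetting participants never perturbs the draws of the others.
participant_seed <- function(cfg, participant, stream) {
  offset <- switch(stream, trials = 0L, traj = 500000L, epochs = 900000L,
                   stop("unknown stream"))
  as.integer((cfg$seed + offset + 1009L * participant) %% .Machine$integer.max)
}

# The 9 modifier combinations of the factorial design.
modifier_combinations <- function() {
  data.frame(
    modifier1 = c("none", "none", "really", "none", "not",
                  "really", "not", "really", "not"),
    modifier2 = c("none", "really", "none", "not", "none",
                  "not", "really", "really", "not"),
    stringsAsFactors = FALSE
  )
}

combo_label <- function(m1, m2) {
  lab <- function(m) ifelse(m == "none", "###", m)
  paste(lab(m1), lab(m2))
}

is_negated <- function(m1, m2, rule = "any_not") {
  n_not <- (m1 == "not") + (m2 == "not")
  if (rule == "odd_not") n_not %% 2L == 1L else n_not >= 1L
}
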