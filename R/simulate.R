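#' Simulate a behavioral trial table
#'
#' Generates one row per trial for a factorial phrase design: every
#' participant sees all 9 modifier combinations crossed with the two antonym
#' poles, `n_trials_per_cell` times each. Reaction times are lognormal with
#' configurable additive offsets making negated and low-pole trials slower;
#' feedback is flagged negative with probability `feedback_error_rate`;
#' final-rating endpoints are drawn per (pole x negation) condition with the
#' negated conditions pulled toward the scale center and (by default) more
#' dispersed. Output is byte-identical for identical (config, seed).
#'
#' @param config a [simulation_config()] object.
#' @return a data.frame of class `trial_table` with columns participant_id,
#'   block, scale_dimension, scale_orientation, modifier1, modifier2,
#'   modifier_combo, pole, negated, is_not_not, n_modifiers, rt_ms, feedback,
#'   endpoint, trajectory_id. Endpoints are in unswapped scale coordinates
#'   (+1 always the high pole).
#' @export
simulate_trial_table <- function(config) {
  validate_sim_config(config)
  combos <- modifier_combinations()
  dims <- c("quality", "beauty", "mood", "temperature", "speed", "size")
  per_part <- vector("list", config$n_participants)
  for (p in seq_len(config$n_participants)) {
    set.seed(participant_seed(config, p, "trials"))
    cell <- expand.grid(rep = seq_len(config$n_trials_per_cell),
                        pole = c("low", "high"),
                        combo = seq_len(nrow(combos)),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    n <- nrow(cell)
    m1 <- combos$modifier1[cell$combo]
    m2 <- combos$modifier2[cell$combo]
    negated <- is_negated(m1, m2, config$negation_rule)
    rt <- rlnorm(n, config$rt_meanlog, config$rt_sdlog) +
      config$rt_offset_negated * negated +
      config$rt_offset_low * (cell$pole == "low")
    feedback <- 1L - rbinom(n, 1L, config$feedback_error_rate)
    cond <- paste0(ifelse(negated, "neg", "aff"), "_", cell$pole)
    ep_mean <- config$endpoint_means[cond]
    ep_sd <- ifelse(negated, config$endpoint_sd_neg, config$endpoint_sd_aff)
    endpoint <- pmin(1, pmax(-1, rnorm(n, ep_mean, ep_sd)))
    orientation <- rep(c("low_to_high", "high_to_low"), length.out = n)
    dim_ <- dims[1L + (cell$combo + cell$rep) %% length(dims)]
    df <- data.frame(
      participant_id = sprintf("P%02d", p),
      block = paste0(dim_, "_", orientation),
      scale_dimension = dim_,
      scale_orientation = orientation,
      modifier1 = m1,
      modifier2 = m2,
      modifier_combo = combo_label(m1, m2),
      pole = cell$pole,
      negated = negated,
      is_not_not = m1 == "not" & m2 == "not",
      n_modifiers = (m1 != "none") + (m2 != "none"),
      rt_ms = rt,
      feedback = feedback,
      endpoint = endpoint,
      stringsAsFactors = FALSE
    )
    df$trajectory_id <- sprintf("P%02d_T%04d", p, seq_len(n))
    per_part[[p]] <- df
  }
  out <- do.call(rbind, per_part)
  rownames(out) <- NULL
  class(out) <- c("trial_table", "data.frame")
  out
}

# Word onsets in the behavioral task: 250 ms per word + 50 ms inter-word
# interval, so modifier1/modifier2/adjective onset at 0/300/600 ms.
BEHAV_ADJ_ONSET_MS <- 600

#' Simulate mouse trajectories for a trial table
#'
#' Each trajectory is a first-order pursuit path on the normalized scale
#' coordinate x in [-1, 1], sampled on a raw grid (default ~60 Hz) from 0 to
#' `duration_ms`. Affirmative trials drift monotonically toward the trial's
#' endpoint from stage-1 onset. Negated trials first pursue the adjective's
#' own pole (stage 1) and, from stage-2 onset, reverse toward the mitigated
#' endpoint on the opposite side, reproducing the two-stage shape in which
#' negated responses first deviate toward the adjective and only later toward
#' the antonym. Stage onsets are configured relative to adjective onset
#' (600 ms into the trial given the 250 + 50 ms word timing).
#'
#' @param trials a `trial_table` from [simulate_trial_table()].
#' @param config the same [simulation_config()].
#' @param raw_dt_ms spacing of the raw samples in ms (default 16, ~60 Hz).
#' @param duration_ms trial duration in ms.
#' @return a data.frame of class `trajectory_set` with columns trial_id,
#'   t_ms, x (long format, one block per trial).
#' @export
simulate_trajectories <- function(trials, config, raw_dt_ms = 16,
                                  duration_ms = 2000) {
  validate_sim_config(config)
  t_raw <- seq(0, duration_ms, by = raw_dt_ms)
  nt <- length(t_raw)
  dt_s <- raw_dt_ms / 1000
  on1 <- BEHAV_ADJ_ONSET_MS + config$traj_stage1[["onset_ms"]]
  on2 <- BEHAV_ADJ_ONSET_MS + config$traj_stage2[["onset_ms"]]
  g1 <- config$traj_stage1[["gain"]]
  g2 <- config$traj_stage2[["gain"]]
  parts <- unique(trials$participant_id)
  out <- vector("list", length(parts))
  for (ip in seq_along(parts)) {
    set.seed(participant_seed(config, ip, "traj"))
    rows <- which(trials$participant_id == parts[ip])
    blocks <- vector("list", length(rows))
    for (k in seq_along(rows)) {
      i <- rows[k]
      pole_sign <- if (trials$pole[i] == "high") 1 else -1
      endpoint <- trials$endpoint[i]
      x <- numeric(nt)
      noise <- if (config$traj_noise_sd > 0)
        rnorm(nt, 0, config$traj_noise_sd * sqrt(dt_s)) else numeric(nt)
      for (j in 2:nt) {
        tj <- t_raw[j]
        if (trials$negated[i]) {
          if (tj < on1) {
            target <- 0; gain <- 0
          } else if (tj < on2) {
            target <- pole_sign; gain <- g1
          } else {
            target <- endpoint; gain <- g2
          }
        } else {
          if (tj < on1) {
            target <- 0; gain <- 0
          } else {
            target <- endpoint; gain <- g1
          }
        }
        x[j] <- x[j - 1] + dt_s * gain * (target - x[j - 1]) + noise[j]
        x[j] <- min(1, max(-1, x[j]))
      }
      x[nt] <- endpoint  # response registered at the sampled endpoint
      blocks[[k]] <- data.frame(trial_id = trials$trajectory_id[i],
                                t_ms = t_raw, x = x,
                                stringsAsFactors = FALSE)
    }
    out[[ip]] <- do.call(rbind, blocks)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("trajectory_set", "data.frame")
  res
}

#' Simulate epoched sensor-array data
#'
#' Builds a trials x sensors x time array in which the antonym pole is
#' encoded by a fixed random unit sensor pattern p modulated by a smooth
#' half-cosine time course A(t) inside `pattern_window`:
#' \deqn{data[i, s, t] = sign(pole_i) A(t) p_s m_i + noise}
#' with m = 1 for affirmative trials and m = lambda for negated trials
#' (mechanisms no_effect / mitigation / inversion). Under mechanism "change",
#' negated trials instead use a second unit pattern q orthogonal to p. Noise
#' is i.i.d. Gaussian per sensor and sample with SD 1 (so `snr` is the peak
#' pattern amplitude), optionally low-pass smoothed. If `beta_burst` is
#' configured, an oscillatory burst at the given frequency is added to all
#' sensors of negated trials, emulating a band-limited power increase.
#'
#' @param trials a `trial_table`.
#' @param config the matching [simulation_config()].
#' @return an `epoch_set`: list(data, times_ms, sfreq, labels) where labels
#'   is the trial table subset aligned with the first array dimension.
#' @export
simulate_meg_epochs <- function(trials, config) {
  validate_sim_config(config)
  times <- seq(config$epoch_window[1], config$epoch_window[2],
               by = 1000 / config$sfreq)
  nt <- length(times)
  ns <- config$n_sensors
  # fixed patterns shared across participants, drawn from the master seed
  set.seed(config$seed)
  p_pat <- rnorm(ns)
  p_pat <- p_pat / sqrt(sum(p_pat^2))
  q_raw <- rnorm(ns)
  q_raw <- q_raw - sum(q_raw * p_pat) * p_pat
  q_pat <- q_raw / sqrt(sum(q_raw^2))
  # half-cosine ramp up/down inside the pattern window, peak = snr
  a_t <- numeric(nt)
  inside <- times >= config$pattern_window[1] & times <= config$pattern_window[2]
  u <- (times[inside] - config$pattern_window[1]) / diff(config$pattern_window)
  a_t[inside] <- config$snr * 0.5 * (1 - cos(2 * pi * u))
  burst <- NULL
  if (!is.null(config$beta_burst)) {
    bb <- config$beta_burst
    env <- numeric(nt)
    bi <- times >= bb[["start_ms"]] & times <= bb[["end_ms"]]
    ub <- (times[bi] - bb[["start_ms"]]) / (bb[["end_ms"]] - bb[["start_ms"]])
    env[bi] <- 0.5 * (1 - cos(2 * pi * ub))
    burst <- bb[["amp"]] * env * sin(2 * pi * bb[["freq_hz"]] * times / 1000)
  }
  parts <- unique(trials$participant_id)
  n_trials <- nrow(trials)
  data <- array(0, dim = c(n_trials, ns, nt))
  for (ip in seq_along(parts)) {
    set.seed(participant_seed(config, ip, "epochs"))
    rows <- which(trials$participant_id == parts[ip])
    noise <- array(rnorm(length(rows) * ns * nt), c(length(rows), ns, nt))
    if (!is.null(config$noise_lowpass_hz)) {
      k <- max(1L, round(config$sfreq / (2 * config$noise_lowpass_hz)))
      if (k > 1L) {
        kern <- rep(1 / k, k)
        for (i in seq_len(length(rows))) {
          for (s in seq_len(ns)) {
            noise[i, s, ] <- stats::filter(noise[i, s, ], kern, sides = 2)
          }
        }
        noise[is.na(noise)] <- 0
      }
    }
    for (k in seq_along(rows)) {
      i <- rows[k]
      cls <- if (trials$pole[i] == "high") 1 else -1
      if (trials$negated[i] && config$mechanism == "change") {
        pat <- q_pat; m <- 1
      } else {
        pat <- p_pat
        m <- if (trials$negated[i]) config$lambda else 1
      }
      sig <- outer(pat, cls * a_t * m)
      if (!is.null(burst) && trials$negated[i]) {
        sig <- sig + matrix(burst, ns, nt, byrow = TRUE)
      }
      data[i, , ] <- noise[k, , ] + sig
    }
  }
  new_epoch_set(data, times, config$sfreq, trials)
}

#' Construct an epoch set
#'
#' Low-level constructor for the trials x sensors x time container used by
#' the decoding and time-frequency stages.
#'
#' @param data numeric array, trials x sensors x time.
#' @param times_ms numeric time axis, ms (relative to adjective onset by
#'   package convention).
#' @param sfreq sampling rate, Hz.
#' @param labels data.frame of per-trial labels, nrow matching dim(data)[1].
#' @return an object of class `epoch_set`.
#' @export
new_epoch_set <- function(data, times_ms, sfreq, labels) {
  stopifnot(length(dim(data)) == 3L,
            dim(data)[3] == length(times_ms),
            dim(data)[1] == nrow(labels))
  if (anyNA(data)) stop("epoch data must not contain missing values")
  structure(list(data = data, times_ms = as.numeric(times_ms),
                 sfreq = sfreq, labels = as.data.frame(labels)),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Epoch set: %d trials x %d sensors x %d samples (%g..%g ms @ %g Hz)\n",
              d[1], d[2], d[3], min(x$times_ms), max(x$times_ms), x$sfreq))
  if (!is.null(x$labels$negated))
    cat(sprintf("  negated: %d, affirmative: %d\n",
                sum(x$labels$negated), sum(!x$labels$negated)))
  invisible(x)
}

#' Subset an epoch set by trials
#'
#' @param ep an `epoch_set`.
#' @param i logical or integer trial index.
#' @return the subsetted `epoch_set`.
#' @export
epochs_subset <- function(ep, i) {
  new_epoch_set(ep$data[i, , , drop = FALSE], ep$times_ms, ep$sfreq,
                ep$labels[i, , drop = FALSE])
}
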