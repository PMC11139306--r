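# Small configurations used across test files.

tiny_config <- function(...) {
  simulation_config(n_participants = 2, n_trials_per_cell = 2,
                    n_sensors = 8, epoch_window = c(-100, 600),
                    seed = 1L, ...)
}

# Deterministic high-SNR config for construction checks: the sensor noise SD
# is fixed at 1, so large snr plays the role of "noise -> 0".
clean_config <- function(mechanism = "no_effect", snr = 50,
                         n_trials_per_cell = 8, ...) {
  simulation_config(n_participants = 1, n_trials_per_cell = n_trials_per_cell,
                    n_sensors = 12, epoch_window = c(-100, 600),
                    snr = snr, mechanism = mechanism, seed = 2L, ...)
}

# Class-mean sensor pattern at the pattern-window peak:
# mean(high trials) - mean(low trials) per sensor.
class_pattern <- function(ep, trials_idx, t_ms) {
  ti <- which.min(abs(ep$times_ms - t_ms))
  lab <- ep$labels[trials_idx, ]
  x <- ep$data[trials_idx, , ti, drop = FALSE]
  colMeans(x[lab$pole == "high", , 1, drop = FALSE]) -
    colMeans(x[lab$pole == "low", , 1, drop = FALSE])
}
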