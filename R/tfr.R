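#' Default time-frequency analysis grid
#'
#' 19 frequencies logarithmically spaced (geometric progression) between
#' 3.9 and 37.2 Hz inclusive.
#'
#' @param n number of frequencies.
#' @param fmin,fmax range in Hz.
#' @return numeric vector of frequencies.
#' @export
tfr_frequencies <- function(n = 19, fmin = 3.9, fmax = 37.2) {
  exp(seq(log(fmin), log(fmax), length.out = n))
}

#' Beta-band definitions
#'
#' Low beta spans 12-20 Hz, high beta 21-30 Hz.
#' @return named list of c(lo, hi) bands in Hz.
#' @export
beta_bands <- function() {
  list(low_beta = c(12, 20), high_beta = c(21, 30))
}

# Complex Morlet wavelet: a complex exponential under a Gaussian envelope
# with SD sigma_t = n_cycles / (2 pi f), truncated at +/- 5 SD and
# normalized to unit energy.
morlet_wavelet <- function(freq, sfreq, n_cycles = 3, sd_cut = 5) {
  sigma_t <- n_cycles / (2 * pi * freq)
  half <- floor(sd_cut * sigma_t * sfreq)
  t <- seq(-half, half) / sfreq
  w <- exp(2i * pi * freq * t) * exp(-t^2 / (2 * sigma_t^2))
  w / sqrt(sum(Mod(w)^2))
}

#' Morlet wavelet power of epoched data
#'
#' Per-trial squared magnitude of the complex Morlet wavelet transform
#' (`n_cycles` cycles per frequency), optionally averaged over trials within
#' groups. Samples closer to an epoch edge than half the wavelet length are
#' marked invalid (NA) rather than silently zero-padded; analyses on wide
#' epochs that are later cropped avoid these edges at the frequencies of
#' interest.
#'
#' @param ep an `epoch_set`.
#' @param freqs frequencies in Hz (default [tfr_frequencies()]).
#' @param n_cycles wavelet cycles per frequency.
#' @param average_by optional per-trial grouping factor; when given, power is
#'   averaged over trials within each group and the first array dimension
#'   indexes groups, keeping memory bounded.
#' @return an object of class `tfr`: list(power, freqs_hz, times_ms, sfreq,
#'   groups). `power` is trials (or groups) x sensors x freqs x times.
#' @export
morlet_power <- function(ep, freqs = tfr_frequencies(), n_cycles = 3,
                         average_by = NULL) {
  d <- dim(ep$data)
  n_trials <- d[1]; n_sensors <- d[2]; n_times <- d[3]
  wavelets <- lapply(freqs, morlet_wavelet, sfreq = ep$sfreq,
                     n_cycles = n_cycles)
  lens <- vapply(wavelets, length, 0L)
  too_long <- lens > n_times
  if (any(too_long))
    stop(sprintf("wavelet at %.2f Hz (%d samples) is longer than the epoch (%d samples)",
                 freqs[which(too_long)[1]], lens[which(too_long)[1]], n_times))
  nfft <- n_times + max(lens) - 1L
  # one forward FFT per trial-sensor series, reused across frequencies
  x <- matrix(aperm(ep$data, c(3, 1, 2)), n_times, n_trials * n_sensors)
  xf <- mvfft(rbind(x, matrix(0, nfft - n_times, ncol(x))))
  if (is.null(average_by)) {
    groups <- seq_len(n_trials)
    gidx <- as.list(groups)
  } else {
    average_by <- as.character(average_by)
    groups <- unique(average_by)
    gidx <- lapply(groups, function(g) which(average_by == g))
  }
  out <- array(NA_real_, c(length(groups), n_sensors, length(freqs), n_times))
  for (k in seq_along(freqs)) {
    w <- wavelets[[k]]
    lw <- lens[k]
    half <- (lw - 1L) %/% 2L
    wf <- fft(c(w, rep(0, nfft - lw)))
    conv <- mvfft(xf * wf, inverse = TRUE) / nfft
    seg <- conv[(half + 1):(half + n_times), , drop = FALSE]
    pow <- Mod(seg)^2
    valid <- rep(TRUE, n_times)
    if (half > 0) {
      valid[seq_len(half)] <- FALSE
      valid[(n_times - half + 1):n_times] <- FALSE
    }
    pow[!valid, ] <- NA_real_
    pa <- array(pow, c(n_times, n_trials, n_sensors))
    for (g in seq_along(gidx)) {
      sel <- pa[, gidx[[g]], , drop = FALSE]
      m <- apply(sel, c(1, 3), mean)
      out[g, , k, ] <- t(m)
    }
  }
  structure(list(power = out, freqs_hz = freqs, times_ms = ep$times_ms,
                 sfreq = ep$sfreq, n_cycles = n_cycles,
                 groups = if (is.null(average_by)) NULL else groups),
            class = "tfr")
}

#' @export
print.tfr <- function(x, ...) {
  d <- dim(x$power)
  cat(sprintf("TFR: %d %s x %d sensors x %d freqs (%.1f..%.1f Hz) x %d samples\n",
              d[1], if (is.null(x$groups)) "trials" else "groups",
              d[2], min(x$freqs_hz), max(x$freqs_hz), d[4]))
  invisible(x)
}

#' Percent-change baseline correction
#'
#' Transforms power to percent change relative to the mean over the baseline
#' window: (x - b) / b, computed per trial/group, sensor and frequency.
#' Baseline means use the valid (non-edge) samples inside the window; a
#' frequency whose wavelet invalidates the entire window is an error, as is
#' a zero baseline mean.
#'
#' @param tfr a `tfr` object with raw power.
#' @param window c(start, end) ms of the baseline.
#' @return the `tfr` with percent-change power.
#' @export
baseline_percent <- function(tfr, window = c(-300, -100)) {
  bi <- tfr$times_ms >= window[1] & tfr$times_ms <= window[2]
  if (!any(bi)) stop("baseline window lies outside the epoch")
  p <- tfr$power
  d <- dim(p)
  for (k in seq_len(d[3])) {
    b <- apply(p[, , k, bi, drop = FALSE], c(1, 2), mean, na.rm = TRUE)
    if (anyNA(b))
      stop(sprintf("no valid baseline samples at %.2f Hz", tfr$freqs_hz[k]))
    if (any(b == 0))
      stop("zero baseline mean (degenerate input)")
    p[, , k, ] <- sweep(p[, , k, , drop = FALSE], c(1, 2), b, "-") /
      array(b, c(d[1], d[2], 1, d[4]))
  }
  tfr$power <- p
  tfr$baseline_window <- window
  tfr$mode <- "percent"
  tfr
}

#' Band-averaged power time course
#'
#' Unweighted mean over the frequency bins whose center lies in the closed
#' band, and over the selected sensors.
#'
#' @param tfr a `tfr` object.
#' @param band c(lo, hi) in Hz (see [beta_bands()]).
#' @param sensors optional sensor index subset; default all.
#' @return matrix trials/groups x time (rownames = group names if averaged).
#' @export
band_timecourse <- function(tfr, band, sensors = NULL) {
  sel <- which(tfr$freqs_hz >= band[1] & tfr$freqs_hz <= band[2])
  if (!length(sel)) stop("band overlaps no frequency bin")
  if (is.null(sensors)) sensors <- seq_len(dim(tfr$power)[2])
  sub <- tfr$power[, sensors, sel, , drop = FALSE]
  out <- apply(sub, c(1, 4), mean)
  if (!is.null(tfr$groups)) rownames(out) <- tfr$groups
  out
}

#' Negated - affirmative band power contrast with cluster inference
#'
#' Takes per-participant band power time courses for the negated and
#' affirmative conditions, forms the within-participant difference and tests
#' it against 0 with a one-tailed (greater) sign-flip cluster permutation
#' test in each requested window.
#'
#' @param tc_neg,tc_aff participants x time matrices on a common grid.
#' @param times_ms the time axis.
#' @param windows list of c(start, end) windows in ms.
#' @param n_perm,alpha,seed passed to [one_sample_cluster_test()].
#' @return list of `cluster_test`, one per window.
#' @export
condition_contrast <- function(tc_neg, tc_aff, times_ms,
                               windows = list(c(0, 500), c(500, 1000)),
                               n_perm = 10000, alpha = 0.05, seed = NULL) {
  stopifnot(all(dim(tc_neg) == dim(tc_aff)))
  diffs <- tc_neg - tc_aff
  valid <- !apply(is.na(diffs), 2, any)
  lapply(windows, function(w) {
    keep <- valid & times_ms >= w[1] & times_ms <= w[2]
    if (!any(keep)) stop("window has no valid samples")
    one_sample_cluster_test(diffs[, keep, drop = FALSE], times_ms[keep],
                            n_perm = n_perm, tail = "greater",
                            alpha = alpha, seed = seed)
  })
}

#' Per-participant beta-band contrast series
#'
#' For each participant: Morlet power averaged within the negated and
#' affirmative conditions, percent baseline correction, band averaging over
#' sensors, returning the two participants x time matrices used by
#' [condition_contrast()]. No-modifier trials are excluded (they serve only
#' as a time-frequency baseline condition in the design).
#'
#' @param ep an `epoch_set` with participant_id, negated and modifier labels.
#' @param band c(lo, hi) Hz.
#' @param baseline baseline window, ms.
#' @param freqs,n_cycles wavelet parameters.
#' @return list(neg, aff, times_ms).
#' @export
band_contrast_study <- function(ep, band, baseline = c(-300, -100),
                                freqs = tfr_frequencies(), n_cycles = 3) {
  lab <- ep$labels
  keep <- lab$n_modifiers > 0L
  parts <- unique(lab$participant_id)
  tc_neg <- NULL
  tc_aff <- NULL
  for (p in parts) {
    idx <- which(keep & lab$participant_id == p)
    sub <- epochs_subset(ep, idx)
    tfr <- morlet_power(sub, freqs = freqs, n_cycles = n_cycles,
                        average_by = ifelse(sub$labels$negated,
                                            "negated", "affirmative"))
    tfr <- baseline_percent(tfr, baseline)
    tc <- band_timecourse(tfr, band)
    tc_neg <- rbind(tc_neg, tc["negated", ])
    tc_aff <- rbind(tc_aff, tc["affirmative", ])
  }
  list(neg = tc_neg, aff = tc_aff, times_ms = ep$times_ms)
}
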