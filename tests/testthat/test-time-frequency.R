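make_epochs <- function(signal_fun, n_trials = 4, n_sensors = 2,
                        sfreq = 200, t_lim = c(-1000, 2000), noise_sd = 0) {
  times <- seq(t_lim[1], t_lim[2], by = 1000 / sfreq)
  nt <- length(times)
  data <- array(rnorm(n_trials * n_sensors * nt, sd = noise_sd),
                c(n_trials, n_sensors, nt))
  sig <- signal_fun(times / 1000)
  for (i in seq_len(n_trials)) for (s in seq_len(n_sensors))
    data[i, s, ] <- data[i, s, ] + sig
  new_epoch_set(data, times, sfreq, data.frame(id = seq_len(n_trials)))
}

test_that("frequency grid is geometric with 19 bins over 3.9-37.2 Hz", {
  f <- tfr_frequencies()
  expect_length(f, 19)
  expect_equal(f[1], 3.9)
  expect_equal(f[19], 37.2)
  ratios <- f[-1] / f[-19]
  expect_lt(diff(range(ratios)), 1e-12)  # constant ratio = log spacing
})

test_that("Morlet power localizes a pure tone and scales quadratically", {
  # tone placed on a bin center, so the unit-energy normalization (which
  # boosts lower-frequency bins by sqrt(sigma_t)) cannot shift the peak
  f_tone <- tfr_frequencies()[12]
  ep <- make_epochs(function(t) sin(2 * pi * f_tone * t))
  tfr <- morlet_power(ep)
  mid <- which.min(abs(tfr$times_ms - 500))
  spec <- tfr$power[1, 1, , mid]
  peak_bin <- which.max(spec)
  # FFT-based oracle: periodogram of the raw series, peak mapped onto the
  # wavelet grid
  x <- ep$data[1, 1, ]
  pg <- Mod(fft(x * (1 - cos(2 * pi * seq_along(x) / length(x))) / 2))^2
  fr <- (seq_along(x) - 1) * ep$sfreq / length(x)
  half <- seq_len(length(x) %/% 2)
  f_peak <- fr[half][which.max(pg[half])]
  oracle_bin <- which.min(abs(tfr$freqs_hz - f_peak))
  expect_equal(peak_bin, oracle_bin)
  # an off-bin 15 Hz tone still localizes within one bin spacing
  ep15 <- make_epochs(function(t) sin(2 * pi * 15 * t), n_trials = 1)
  tfr15 <- morlet_power(ep15)
  pk15 <- which.max(tfr15$power[1, 1, , mid])
  expect_lte(abs(pk15 - which.min(abs(tfr15$freqs_hz - 15))), 1)
  # doubling the amplitude quadruples raw power
  ep2 <- make_epochs(function(t) 2 * sin(2 * pi * f_tone * t))
  tfr2 <- morlet_power(ep2)
  valid <- !is.na(tfr$power[1, 1, peak_bin, ])
  expect_equal(tfr2$power[1, 1, peak_bin, valid],
               4 * tfr$power[1, 1, peak_bin, valid], tolerance = 1e-8)
  # zero input gives zero power everywhere valid, and power is nonnegative
  ep0 <- make_epochs(function(t) 0 * t)
  tfr0 <- morlet_power(ep0)
  expect_equal(max(abs(tfr0$power), na.rm = TRUE), 0)
  expect_true(all(tfr$power >= 0, na.rm = TRUE))
})

test_that("wavelets longer than the epoch raise an error naming the frequency", {
  ep <- make_epochs(function(t) 0 * t, t_lim = c(0, 400))
  expect_error(morlet_power(ep, freqs = c(3.9, 20)), "3.90 Hz")
})

test_that("percent baseline correction matches its pointwise definition", {
  set.seed(51)
  ep <- make_epochs(function(t) sin(2 * pi * 10 * t), noise_sd = 0.2)
  tfr <- morlet_power(ep, freqs = c(8, 10, 12.5))
  cor <- baseline_percent(tfr, window = c(-300, -100))
  # literal (x - b) / b recomputation
  bi <- tfr$times_ms >= -300 & tfr$times_ms <= -100
  for (k in 1:3) {
    b <- mean(tfr$power[2, 1, k, bi], na.rm = TRUE)
    expect_equal(cor$power[2, 1, k, ],
                 (tfr$power[2, 1, k, ] - b) / b, tolerance = 1e-12)
  }
  # power constant in time corrects to 0; doubling the baseline gives +1
  flat <- tfr
  flat$power[] <- 3
  flat0 <- baseline_percent(flat, c(-300, -100))
  expect_equal(max(abs(flat0$power)), 0)
  stepped <- tfr
  stepped$power[] <- 3
  stepped$power[, , , stepped$times_ms > 500] <- 6
  step1 <- baseline_percent(stepped, c(-300, -100))
  expect_equal(unique(as.numeric(step1$power[, , , step1$times_ms > 500])), 1)
  # invariant to rescaling the raw signal by a positive constant
  tfr_scaled <- tfr
  tfr_scaled$power <- tfr$power * 7.3
  expect_equal(baseline_percent(tfr_scaled, c(-300, -100))$power,
               cor$power, tolerance = 1e-10)
  # degenerate zero baseline errors
  zero <- tfr
  zero$power[] <- 0
  expect_error(baseline_percent(zero, c(-300, -100)), "zero baseline")
})

test_that("band averaging selects exactly the bins inside the closed band", {
  ep <- make_epochs(function(t) sin(2 * pi * 15 * t), n_trials = 2)
  tfr <- morlet_power(ep)
  f <- tfr$freqs_hz
  # low beta on the 19-bin grid: exactly the bins with 12 <= f <= 20
  expected_bins <- which(f >= 12 & f <= 20)
  expect_equal(f[expected_bins],
               f[f >= beta_bands()$low_beta[1] & f <= beta_bands()$low_beta[2]])
  tc <- band_timecourse(tfr, beta_bands()$low_beta)
  manual <- apply(tfr$power[, , expected_bins, , drop = FALSE], c(1, 4), mean)
  expect_equal(tc, manual, tolerance = 1e-12)
  # a band covering a single bin returns that bin's series
  tc1 <- band_timecourse(tfr, c(f[7] - 0.01, f[7] + 0.01))
  expect_equal(tc1, apply(tfr$power[, , 7, , drop = FALSE], c(1, 4), mean),
               tolerance = 1e-12)
  # a band covering everything returns the global mean
  tc_all <- band_timecourse(tfr, range(f))
  expect_equal(tc_all, apply(tfr$power, c(1, 4), mean), tolerance = 1e-12)
  expect_error(band_timecourse(tfr, c(60, 80)), "no frequency bin")
})

test_that("beta burst in negated trials yields a band-specific contrast", {
  base <- list(n_participants = 6, n_trials_per_cell = 2, n_sensors = 6,
               epoch_window = c(-800, 1200), snr = 1, seed = 52)
  run_contrast <- function(burst_freq, band) {
    cfg <- do.call(simulation_config, c(base, list(
      beta_burst = c(freq_hz = burst_freq, start_ms = 300, end_ms = 700,
                     amp = 1.5))))
    tr <- simulate_trial_table(cfg)
    ep <- simulate_meg_epochs(tr, cfg)
    bc <- band_contrast_study(ep, band = band)
    condition_contrast(bc$neg, bc$aff, bc$times_ms,
                       windows = list(c(0, 800)), n_perm = 500, seed = 1)[[1]]
  }
  # identical conditions (no burst): no cluster expected
  cfg0 <- do.call(simulation_config, c(base))
  tr0 <- simulate_trial_table(cfg0)
  ep0 <- simulate_meg_epochs(tr0, cfg0)
  bc0 <- band_contrast_study(ep0, band = beta_bands()$low_beta)
  ct0 <- condition_contrast(bc0$neg, bc0$aff, bc0$times_ms,
                            windows = list(c(0, 800)), n_perm = 500,
                            seed = 1)[[1]]
  expect_equal(nrow(significant_clusters(ct0, 0.01)), 0)
  # a 15 Hz burst creates a low-beta cluster overlapping the injection
  ct_low <- run_contrast(15, beta_bands()$low_beta)
  sig <- significant_clusters(ct_low, 0.05, sign = 1L)
  expect_gt(nrow(sig), 0)
  expect_true(any(sig$start_ms <= 700 & sig$end_ms >= 300))
  # band specificity is ordinal between adjacent bands (3-cycle wavelets
  # leak across neighboring bins): the injected band carries more mass
  ct_high <- run_contrast(15, beta_bands()$high_beta)
  mass <- function(ct) {
    s <- significant_clusters(ct, 0.05, sign = 1L)
    if (nrow(s)) max(s$stat) else 0
  }
  expect_gt(mass(ct_low), mass(ct_high))
  # and absolute across a wide spectral gap: a 5 Hz theta burst leaves the
  # high-beta contrast silent
  ct_theta <- run_contrast(5, beta_bands()$high_beta)
  expect_equal(nrow(significant_clusters(ct_theta, 0.01)), 0)
})
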