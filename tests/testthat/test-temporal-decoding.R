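test_that("epoch preprocessing removes offsets, rejects spikes and decimates", {
  set.seed(31)
  n <- 6; s <- 4; nt <- 100
  times <- seq(-300, 690, 10)
  offsets <- matrix(rnorm(n * s, 0, 10), n, s)
  data <- array(rnorm(n * s * nt, sd = 0.1), c(n, s, nt)) +
    array(offsets, c(n, s, nt))
  ep <- new_epoch_set(data, times, 100, data.frame(id = 1:n))
  pre <- preprocess_epochs(ep, baseline = c(-300, 0), reject = Inf,
                           target_sfreq = NULL)
  # per-trial per-sensor baseline means are exactly zero afterwards
  bl <- apply(pre$data[, , times <= 0, drop = FALSE], c(1, 2), mean)
  expect_equal(max(abs(bl)), 0, tolerance = 1e-12)
  # one spiking trial is dropped and counted
  data2 <- data
  data2[3, 2, 50] <- 5000
  ep2 <- new_epoch_set(data2, times, 100, data.frame(id = 1:n))
  pre2 <- preprocess_epochs(ep2, baseline = NULL, reject = 3000,
                            target_sfreq = NULL)
  expect_equal(dim(pre2$data)[1], n - 1)
  expect_equal(attr(pre2, "n_rejected"), 1)
  expect_false(3 %in% pre2$labels$id)
  # 1000 Hz input decimates to a grid with exactly 10 ms spacing
  nt3 <- 1000
  ep3 <- new_epoch_set(array(rnorm(2 * 2 * nt3), c(2, 2, nt3)),
                       seq(-300, by = 1, length.out = nt3), 1000,
                       data.frame(id = 1:2))
  pre3 <- preprocess_epochs(ep3, baseline = NULL, reject = Inf,
                            target_sfreq = 100)
  expect_equal(unique(diff(pre3$times_ms)), 10)
  expect_equal(pre3$sfreq, 100)
  # errors
  expect_error(preprocess_epochs(ep, baseline = c(-900, -800)), "baseline")
  expect_error(preprocess_epochs(ep3, baseline = NULL, target_sfreq = 300),
               "integer multiple")
})

test_that("AUC matches brute-force pair counting and its invariances", {
  expect_equal(compute_auc(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0)), 1)
  expect_equal(compute_auc(rep(0.4, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  # brute-force enumeration over all pairs, ties counted 0.5
  pair_auc <- function(s, y) {
    pos <- s[y == 1]; neg <- s[y == 0]
    tot <- 0
    for (a in pos) for (b in neg)
      tot <- tot + (a > b) + 0.5 * (a == b)
    tot / (length(pos) * length(neg))
  }
  s6 <- c(0.2, 0.5, 0.5, 0.7, 0.1, 0.9)
  y6 <- c(0, 0, 1, 1, 0, 1)
  expect_equal(compute_auc(s6, y6), pair_auc(s6, y6))
  set.seed(32)
  for (i in 1:10) {
    s <- round(runif(12), 1)  # rounding forces ties
    y <- rbinom(12, 1, 0.5)
    if (length(unique(y)) < 2) next
    expect_equal(compute_auc(s, y), pair_auc(s, y))
    # invariance under strictly increasing transforms
    expect_equal(compute_auc(qlogis(pmin(pmax(s, 0.01), 0.99)), y),
                 compute_auc(pmin(pmax(s, 0.01), 0.99), y))
  }
  expect_error(compute_auc(1:3, c(1, 1, 1)), "both classes")
})

test_that("ridge logistic matches the glmnet oracle", {
  skip_if_not_installed("glmnet")
  set.seed(33)
  n <- 80; p <- 6
  X <- matrix(rnorm(n * p), n, p)
  y <- rbinom(n, 1, plogis(X[, 1] - 0.5 * X[, 2]))
  for (C in c(0.5, 1, 2)) {
    ours <- negshift:::cpp_ridge_logistic(X, y, rep(1, n), C = C)
    # glmnet parameterizes the same objective with lambda = 1 / (n C)
    g <- glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                        lambda = 1 / (n * C), standardize = FALSE,
                        thresh = 1e-12)
    expect_equal(as.numeric(ours), as.numeric(coef(g)), tolerance = 1e-6)
  }
})

test_that("decoder finds the pattern window and only the pattern window", {
  cfg <- clean_config("no_effect", snr = 50)
  tr <- simulate_trial_table(cfg)
  ep <- simulate_meg_epochs(tr, cfg)
  sub <- epochs_subset(ep, tr$n_modifiers > 0 & !tr$negated)
  pole <- factor(sub$labels$pole, levels = c("low", "high"))
  r <- fit_temporal_decoder(sub, pole, k_folds = 5, seed = 1)
  inside <- r$times_ms >= 180 & r$times_ms <= 500
  outside <- r$times_ms < 80 | r$times_ms > 590
  expect_true(all(r$auc[inside] > 0.95))
  expect_lt(mean(abs(r$auc[outside] - 0.5)), 0.1)
  # probability estimates point to the correct classes inside the window
  expect_gt(mean(r$prob_by_class[, inside]), 0.8)
  # duplicating every trial leaves the AUC essentially unchanged
  dup <- epochs_subset(sub, rep(seq_len(dim(sub$data)[1]), 2))
  pole2 <- factor(dup$labels$pole, levels = c("low", "high"))
  r2 <- fit_temporal_decoder(dup, pole2, k_folds = 5, seed = 1)
  expect_lt(mean(abs(r2$auc[inside] - r$auc[inside])), 0.05)
  expect_error(fit_temporal_decoder(sub, factor(rep("high", length(pole)),
                                                levels = c("low", "high"))),
               "both classes")
})

test_that("label shuffling yields chance AUC and no train-test leakage", {
  cfg <- simulation_config(n_participants = 1, n_trials_per_cell = 6,
                           n_sensors = 12, epoch_window = c(-100, 600),
                           seed = 3)
  tr <- simulate_trial_table(cfg)
  ep <- simulate_meg_epochs(tr, cfg)
  sub <- epochs_subset(ep, tr$n_modifiers > 0)
  pole <- as.character(sub$labels$pole)
  set.seed(34)
  aucs <- replicate(20, {
    ysh <- factor(sample(pole), levels = c("low", "high"))
    fit_temporal_decoder(sub, ysh, k_folds = 5)$auc
  })
  m <- rowMeans(aucs)
  se <- apply(aucs, 1, sd) / sqrt(ncol(aucs))
  # mean AUC within a null band around 0.5 at every timepoint
  expect_true(all(abs(m - 0.5) < pmax(3.3 * se, 0.02)))
  # leakage probe: an informative feature planted only in the held-out
  # trials of one fold must not lift that fold's AUC above chance
  set.seed(35)
  n <- 40; ns <- 10; nt <- 15
  y <- rep(c(0L, 1L), 20)
  dat <- array(rnorm(n * ns * nt), c(n, ns, nt))
  folds <- rep(1:5, each = 8)
  planted <- folds == 1 & y == 1L
  dat[planted, 1, ] <- dat[planted, 1, ] + 5
  epl <- new_epoch_set(dat, seq(0, by = 10, length.out = nt), 100,
                       data.frame(id = seq_len(n)))
  r <- fit_temporal_decoder(epl, y, folds = folds)
  in_fold <- folds == 1
  auc_fold1 <- apply(r$scores[in_fold, , drop = FALSE], 2, compute_auc,
                     labels = y[in_fold])
  expect_lt(mean(auc_fold1), 0.65)
  expect_lt(abs(mean(r$auc) - 0.5), 0.1)
})

test_that("cross-condition generalization reflects the true mechanism", {
  run_gen <- function(mechanism) {
    cfg <- clean_config(mechanism, snr = 3, n_trials_per_cell = 20)
    tr <- simulate_trial_table(cfg)
    ep <- simulate_meg_epochs(tr, cfg)
    sub <- epochs_subset(ep, tr$n_modifiers > 0)
    sl <- sub$labels
    pole <- factor(sl$pole, levels = c("low", "high"))
    cross_condition_generalize(epochs_subset(sub, !sl$negated),
                               epochs_subset(sub, sl$negated),
                               pole[!sl$negated], pole[sl$negated],
                               n_baseline_perm = 20, seed = 1)
  }
  inside <- function(r) r$times_ms >= 180 & r$times_ms <= 500
  # no effect: transfer is as good as within-condition decoding
  r_no <- run_gen("no_effect")
  expect_gt(mean(r_no$auc[inside(r_no)]), 0.9)
  # inversion: transfer lands below chance with swapped probabilities
  r_inv <- run_gen("inversion")
  expect_lt(mean(r_inv$auc[inside(r_inv)]), 0.1)
  expect_lt(mean(r_inv$prob_by_class[, inside(r_inv)]),
            mean(r_inv$chance_baseline[, inside(r_inv)]))
  # change: the orthogonal pattern does not transfer at all
  r_ch <- run_gen("change")
  expect_lt(mean(abs(r_ch$auc[inside(r_ch)] - 0.5)), 0.1)
  # the chance baseline stays near 0.5 with balanced-weight training
  expect_lt(max(abs(r_no$chance_baseline - 0.5)), 0.15)
})

test_that("pooled training with split testing separates the conditions", {
  cfg <- clean_config("mitigation", lambda = 0.5, snr = 1.5)
  tr <- simulate_trial_table(cfg)
  ep <- simulate_meg_epochs(tr, cfg)
  sub <- epochs_subset(ep, tr$n_modifiers > 0)
  pair <- pooled_train_split_test(sub, k = 10, seed = 1)
  inside <- sub$times_ms >= 180 & sub$times_ms <= 500
  expect_gt(mean(pair$aff$auc[inside]), mean(pair$neg$auc[inside]))
  expect_gt(mean(pair$neg$auc[inside]), 0.5)
  # grid mismatch and missing-cell errors
  short <- epochs_subset(sub, sub$labels$pole == "high")
  expect_error(pooled_train_split_test(short), "cells")
  sl <- sub$labels
  pole <- factor(sl$pole, levels = c("low", "high"))
  ep_other <- new_epoch_set(sub$data[, , 1:10], sub$times_ms[1:10],
                            sub$sfreq, sl)
  expect_error(
    cross_condition_generalize(sub, ep_other, pole, pole),
    "grid")
})
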