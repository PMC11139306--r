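# Brute-force re-implementation of the filtering rule, row by row.
brute_filter <- function(trials, k = 2) {
  keep <- logical(nrow(trials))
  for (i in seq_len(nrow(trials))) {
    if (trials$feedback[i] != 1L) next
    same <- trials$participant_id == trials$participant_id[i] &
      trials$feedback == 1L
    med <- median(trials$rt_ms[same])
    s <- sd(trials$rt_ms[same])
    if (is.na(s)) s <- 0
    keep[i] <- trials$rt_ms[i] >= med - k * s & trials$rt_ms[i] <= med + k * s
  }
  trials[keep, , drop = FALSE]
}

test_that("trial filtering matches a brute-force oracle", {
  set.seed(41)
  tr <- data.frame(
    participant_id = rep(sprintf("P%02d", 1:8), each = 25),
    rt_ms = rlnorm(200, log(1200), 0.6),
    feedback = rbinom(200, 1, 0.85)
  )
  f1 <- filter_trials(tr)
  oracle <- brute_filter(tr)
  expect_equal(as.data.frame(f1), as.data.frame(oracle),
               ignore_attr = TRUE)
  expect_gt(sum(attr(f1, "removed")), 0)
  # a second pass never reinstates trials and removes none by feedback
  # (the band itself shrinks as the survivor SD shrinks, so the single-pass
  # rule is applied exactly once in the pipeline)
  f2 <- filter_trials(as.data.frame(f1))
  expect_true(all(f2$rt_ms %in% f1$rt_ms))
  expect_equal(unname(attr(f2, "removed")["feedback"]), 0)
})

test_that("filtering handles degenerate and single-removal cases", {
  # constant RTs, all positive feedback: zero-SD band keeps everything
  tr <- data.frame(participant_id = "P01", rt_ms = rep(800, 10),
                   feedback = rep(1L, 10))
  expect_equal(nrow(filter_trials(tr)), 10)
  # one negative-feedback trial among 10 in-range trials: exactly it goes
  tr$feedback[4] <- 0L
  f <- filter_trials(tr)
  expect_equal(nrow(f), 9)
  expect_equal(unname(attr(f, "removed")["feedback"]), 1)
  # a participant left with < 2 trials is flagged with a warning
  tr2 <- rbind(tr, data.frame(participant_id = "P02", rt_ms = 500,
                              feedback = 1L))
  expect_warning(f2 <- filter_trials(tr2), "P02")
  expect_true("P02" %in% attr(f2, "flagged_participants"))
})

# Independent sum-of-squares decomposition for the 2x2 within design.
ss_oracle <- function(cells) {
  v <- cells$value
  g <- mean(v)
  pm <- tapply(v, cells$participant, mean)
  am <- tapply(v, cells$A, mean)
  bm <- tapply(v, cells$B, mean)
  cm <- tapply(v, list(cells$participant, cells$A), mean)
  cb <- tapply(v, list(cells$participant, cells$B), mean)
  n <- length(pm)
  ss_a <- 2 * n * sum((am - g)^2)
  ss_b <- 2 * n * sum((bm - g)^2)
  # participant x A interaction (error term for A), 2 obs per (p, a) cell
  ss_err_a <- 2 * sum((cm - outer(pm, rep(1, 2)) -
                         outer(rep(1, n), am) + g)^2)
  ss_err_b <- 2 * sum((cb - outer(pm, rep(1, 2)) -
                         outer(rep(1, n), bm) + g)^2)
  abm <- tapply(v, list(cells$A, cells$B), mean)
  ss_ab <- n * sum((abm - outer(am, rep(1, 2)) -
                      outer(rep(1, 2), bm) + g)^2)
  cell_full <- tapply(v, list(cells$participant, cells$A, cells$B), mean)
  resid <- cell_full
  for (i in 1:n) for (j in 1:2) for (k in 1:2) {
    resid[i, j, k] <- cell_full[i, j, k] - cm[i, j] - cb[i, k] - abm[j, k] +
      pm[i] + am[j] + bm[k] - g
  }
  ss_err_ab <- sum(resid^2)
  list(F_a = ss_a / (ss_err_a / (n - 1)),
       F_b = ss_b / (ss_err_b / (n - 1)),
       F_ab = ss_ab / (ss_err_ab / (n - 1)))
}

test_that("rm_anova_2x2 matches the sum-of-squares and paired-t oracles", {
  set.seed(42)
  cells <- expand.grid(participant = sprintf("P%d", 1:4),
                       A = c("low", "high"),
                       B = c("affirmative", "negated"),
                       stringsAsFactors = FALSE)
  cells$value <- rnorm(nrow(cells), 1000, 100) +
    50 * (cells$A == "high") + 120 * (cells$B == "negated")
  res <- rm_anova_2x2(cells, factor_names = c("antonym", "negation"))
  oracle <- ss_oracle(cells)
  expect_equal(res$F, c(oracle$F_a, oracle$F_b, oracle$F_ab),
               tolerance = 1e-10)
  expect_equal(res$df1, rep(1, 3))
  expect_equal(res$df2, rep(3, 3))
  # each main-effect F equals the squared paired t of its contrast
  wide <- tapply(cells$value, list(cells$participant, cells$A, cells$B), mean)
  contrast_a <- (wide[, 2, 1] + wide[, 2, 2]) / 2 -
    (wide[, 1, 1] + wide[, 1, 2]) / 2
  t_a <- t.test(contrast_a)$statistic
  expect_equal(res$F[1], unname(t_a^2), tolerance = 1e-10)
  contrast_ab <- (wide[, 2, 2] - wide[, 1, 2]) - (wide[, 2, 1] - wide[, 1, 1])
  t_ab <- t.test(contrast_ab)$statistic
  expect_equal(res$F[3], unname(t_ab^2), tolerance = 1e-10)
  # partial eta squared identity for df1 = 1
  expect_equal(res$eta_p2, res$F / (res$F + res$df2), tolerance = 1e-10)
  # exact p from the F distribution
  expect_equal(res$p, pf(res$F, 1, 3, lower.tail = FALSE))
})

test_that("rm_anova_2x2 is invariant to per-participant constants and handles degenerate input", {
  set.seed(43)
  cells <- expand.grid(participant = sprintf("P%d", 1:6),
                       A = c("a1", "a2"), B = c("b1", "b2"),
                       stringsAsFactors = FALSE)
  cells$value <- rnorm(nrow(cells))
  res1 <- rm_anova_2x2(cells)
  shifted <- cells
  shifted$value <- shifted$value +
    as.numeric(factor(shifted$participant)) * 1000
  res2 <- rm_anova_2x2(shifted)
  expect_equal(res1$F, res2$F, tolerance = 1e-8)
  # all cells identical for every participant: F = 0 everywhere
  cells$value <- 7
  res0 <- rm_anova_2x2(cells)
  expect_equal(res0$F, rep(0, 3))
  # missing cell errors with the participant named
  expect_error(rm_anova_2x2(cells[-1, ]), "P1")
})

test_that("Holm adjustment matches the step-down formula and its properties", {
  expect_equal(unname(holm_posthoc(0.03)), 0.03)
  # hand computation: 0.01*3, max(0.03, 0.02*2), max(0.04, 0.04*1)
  expect_equal(unname(holm_posthoc(c(0.01, 0.02, 0.04))),
               c(0.03, 0.04, 0.04))
  expect_error(holm_posthoc(c(0.2, 1.3)), "\\[0, 1\\]")
  set.seed(44)
  for (i in 1:20) {
    p <- runif(sample(2:8, 1))
    adj <- holm_posthoc(p)
    expect_true(all(adj >= p))
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
    expect_true(all(adj <= 1))
  }
})

test_that("endpoint statistics recover the generator's ground truth", {
  cfg <- simulation_config(n_participants = 30, n_trials_per_cell = 6,
                           seed = 6)
  tr <- simulate_trial_table(cfg)
  f <- filter_trials(tr)
  es <- endpoint_stats(f)
  a_mean <- as.data.frame(es$anova_mean)
  a_sd <- as.data.frame(es$anova_sd)
  # mitigation endpoints (negated means pulled toward the center and across
  # the midline): strong antonym x negation interaction
  expect_lt(a_mean$p[a_mean$effect == "antonym x negation"], 1e-6)
  # endpoint_sd_neg > endpoint_sd_aff: variability main effect of negation
  expect_lt(a_sd$p[a_sd$effect == "negation"], 1e-6)
  # post hocs exist for all 6 cell pairs and stay in [0, 1]
  expect_length(es$posthoc, 6)
  expect_true(all(es$posthoc >= 0 & es$posthoc <= 1))
  # constant endpoints per cell: variability analysis gives F = 0
  tr2 <- tr
  tr2$endpoint <- ifelse(tr2$negated, 0.1, 0.9) * ifelse(tr2$pole == "low", -1, 1)
  es2 <- endpoint_stats(tr2)
  expect_equal(as.data.frame(es2$anova_sd)$F, rep(0, 3))
})

test_that("complexity analysis runs through the same within-subject machinery", {
  cfg <- simulation_config(n_participants = 12, n_trials_per_cell = 6, seed = 8)
  tr <- simulate_trial_table(cfg)
  res <- complexity_stats(filter_trials(tr))
  expect_equal(as.character(res$effect),
               c("complexity", "negation", "complexity x negation"))
  expect_true(all(is.finite(res$F)))
  # the generator has no complexity effect on RTs: F should be unremarkable
  expect_gt(res$p[res$effect == "complexity"], 0.001)
})
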