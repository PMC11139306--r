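#' Preprocess epochs for decoding
#'
#' Applies the standard epoch hygiene: per-trial per-sensor baseline
#' subtraction (mean over `baseline` ms), rejection of trials whose absolute
#' amplitude anywhere exceeds `reject`, and decimation of the time axis to
#' `target_sfreq` (the sampling rate must be an integer multiple of it).
#'
#' @param ep an `epoch_set`.
#' @param baseline c(start, end) ms of the baseline window; NULL skips it.
#' @param reject absolute amplitude threshold; Inf disables rejection.
#' @param target_sfreq output rate, Hz; NULL keeps the native grid.
#' @return the preprocessed `epoch_set`; attribute `n_rejected` counts the
#'   dropped trials.
#' @export
preprocess_epochs <- function(ep, baseline = c(-300, 0), reject = 3000,
                              target_sfreq = 100) {
  data <- ep$data
  times <- ep$times_ms
  if (!is.null(baseline)) {
    bi <- times >= baseline[1] & times <= baseline[2]
    if (!any(bi)) stop("baseline window lies outside the epoch")
    d <- dim(data)
    bl <- rowMeans(matrix(data[, , bi, drop = FALSE], d[1] * d[2], sum(bi)))
    data <- data - as.vector(bl)  # recycles over the time dimension
  }
  keep <- rep(TRUE, dim(data)[1])
  if (is.finite(reject)) {
    mx <- apply(abs(data), 1, max)
    keep <- mx <= reject
  }
  n_rejected <- sum(!keep)
  data <- data[keep, , , drop = FALSE]
  labels <- ep$labels[keep, , drop = FALSE]
  sfreq <- ep$sfreq
  if (!is.null(target_sfreq) && target_sfreq != sfreq) {
    dec <- sfreq / target_sfreq
    if (abs(dec - round(dec)) > 1e-9 || dec < 1)
      stop("sampling rate must be an integer multiple of target_sfreq")
    idx <- seq(1, length(times), by = round(dec))
    data <- data[, , idx, drop = FALSE]
    times <- times[idx]
    sfreq <- target_sfreq
  }
  out <- new_epoch_set(data, times, sfreq, labels)
  attr(out, "n_rejected") <- n_rejected
  out
}

#' Empirical ROC AUC by pair counting
#'
#' Mann-Whitney AUC: the probability that a positive-class score exceeds a
#' negative-class score, with ties counted 0.5. Computed from midranks.
#'
#' @param scores numeric classifier scores.
#' @param labels binary labels (logical, 0/1, or a 2-level factor whose
#'   second level is the positive class).
#' @return AUC in [0, 1].
#' @export
compute_auc <- function(scores, labels) {
  y <- as_binary(labels)
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores)  # midranks handle ties as 0.5
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

as_binary <- function(labels) {
  if (is.factor(labels)) {
    if (nlevels(labels) != 2L) stop("labels must have exactly 2 levels")
    as.integer(labels == levels(labels)[2])
  } else if (is.logical(labels)) {
    as.integer(labels)
  } else if (is.numeric(labels) && all(labels %in% c(0, 1))) {
    as.integer(labels)
  } else {
    u <- sort(unique(labels))
    if (length(u) != 2L) stop("labels must take exactly 2 values")
    as.integer(labels == u[2])
  }
}

#' Stratified fold assignment
#'
#' Assigns each trial to one of `k` folds so that every stratum is spread as
#' evenly as possible across folds.
#'
#' @param strata per-trial stratum id (e.g., the class label, or the
#'   interaction of pole and negation).
#' @param k number of folds.
#' @return integer vector of fold ids in 1..k.
#' @export
make_stratified_folds <- function(strata, k) {
  strata <- as.character(strata)
  folds <- integer(length(strata))
  for (s in unique(strata)) {
    idx <- which(strata == s)
    idx <- idx[sample.int(length(idx))]
    folds[idx] <- rep(seq_len(k), length.out = length(idx))
  }
  folds
}

# Standardizer + PCA fit on training trials only: sensors are the features,
# trials x timepoints are the samples. Retains the smallest number of
# components explaining more than `var_explained` of the variance.
# Sufficient statistics are accumulated per time slice to avoid transposing
# the full array.
fit_projection <- function(data, var_explained = 0.99) {
  d <- dim(data)
  sum_x <- numeric(d[2])
  sum_xx <- matrix(0, d[2], d[2])
  for (t in seq_len(d[3])) {
    xt <- data[, , t]
    sum_x <- sum_x + colSums(xt)
    sum_xx <- sum_xx + crossprod(xt)
  }
  n_samp <- d[1] * d[3]
  mu <- sum_x / n_samp
  cv <- (sum_xx - n_samp * tcrossprod(mu)) / (n_samp - 1)
  sdv <- sqrt(diag(cv))
  sdv[sdv == 0] <- 1
  cv <- cv / tcrossprod(sdv)
  eg <- eigen(cv, symmetric = TRUE)
  vals <- pmax(eg$values, 0)
  cum <- cumsum(vals) / sum(vals)
  m <- which(cum > var_explained)[1]
  rot <- eg$vectors[, seq_len(m), drop = FALSE]
  list(mean = mu, sd = sdv, rot = rot,
       # scaling folded into the projection: x %*% w - shift
       w = rot / sdv, shift = as.numeric((mu / sdv) %*% rot),
       n_components = m, variance_explained = cum[m])
}

# Apply scaler + projection; returns a trials x components x time cube.
project_epochs <- function(data, proj) {
  d <- dim(data)
  m <- ncol(proj$w)
  out <- array(0, c(d[1], m, d[3]))
  shift <- matrix(proj$shift, d[1], m, byrow = TRUE)
  for (t in seq_len(d[3])) {
    out[, , t] <- data[, , t] %*% proj$w - shift
  }
  out
}

balanced_weights <- function(y) {
  n <- length(y)
  n1 <- sum(y == 1L)
  ifelse(y == 1L, n / (2 * n1), n / (2 * (n - n1)))
}

decoding_result <- function(times_ms, auc, prob_by_class, n_components,
                            variance_explained, folds = NULL,
                            chance_baseline = NULL) {
  structure(list(times_ms = times_ms, auc = auc,
                 prob_by_class = prob_by_class,
                 n_components = n_components,
                 variance_explained = variance_explained,
                 folds = folds, chance_baseline = chance_baseline),
            class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("Per-timepoint decoding: %d timepoints (%g..%g ms)\n",
              length(x$times_ms), min(x$times_ms), max(x$times_ms)))
  cat(sprintf("  peak AUC %.3f at %g ms; components: %s (>%s var)\n",
              max(x$auc), x$times_ms[which.max(x$auc)],
              paste(unique(x$n_components), collapse = "/"),
              format(min(x$variance_explained))))
  invisible(x)
}

#' Within-condition cross-validated temporal decoding
#'
#' Per-timepoint multivariate classification with stratified k-fold
#' cross-validation. For each fold, a standardizer (zero mean, unit variance
#' per sensor) and a PCA projection retaining the smallest number of
#' components explaining more than `var_explained` of the variance are fitted
#' on the training split only; an l2-regularized logistic regression with
#' class-balanced weights is then fitted at each timepoint, and the held-out
#' trials are scored. Held-out scores are pooled across folds (each trial is
#' predicted exactly once) before computing the per-timepoint ROC AUC and
#' per-class mean probability estimates.
#'
#' @param ep a preprocessed `epoch_set`.
#' @param labels binary per-trial labels (2-level factor; second level is the
#'   positive class).
#' @param k_folds number of stratified folds (5 or 10 in typical use).
#' @param C inverse regularization strength of the logistic model.
#' @param var_explained PCA variance threshold (fraction).
#' @param folds optional explicit fold assignment (overrides k_folds).
#' @param seed optional seed for the fold shuffle.
#' @return a `decoding_result`; element `scores` holds the held-out
#'   positive-class probability of every trial at every timepoint.
#' @export
fit_temporal_decoder <- function(ep, labels, k_folds = 10, C = 1,
                                 var_explained = 0.99, folds = NULL,
                                 seed = NULL) {
  y <- as_binary(labels)
  if (length(unique(y)) < 2L) stop("both classes must be present")
  if (min(table(y)) < k_folds && is.null(folds))
    stop("fewer trials than folds in one class")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(folds)) folds <- make_stratified_folds(y, k_folds)
  n <- dim(ep$data)[1]
  n_t <- dim(ep$data)[3]
  scores <- matrix(NA_real_, n, n_t)
  ncomp <- integer(0)
  vexp <- numeric(0)
  for (f in sort(unique(folds))) {
    tr <- folds != f
    te <- !tr
    proj <- fit_projection(ep$data[tr, , , drop = FALSE], var_explained)
    w <- balanced_weights(y[tr])
    scores[te, ] <- cpp_decode_raw(ep$data[tr, , , drop = FALSE], proj$w,
                                   proj$shift, y[tr], w,
                                   ep$data[te, , , drop = FALSE], C)
    ncomp <- c(ncomp, proj$n_components)
    vexp <- c(vexp, proj$variance_explained)
  }
  auc <- apply(scores, 2, compute_auc, labels = y)
  prob <- rbind(low = colMeans(1 - scores[y == 0L, , drop = FALSE]),
                high = colMeans(scores[y == 1L, , drop = FALSE]))
  out <- decoding_result(ep$times_ms, auc, prob, ncomp, vexp, folds)
  out$scores <- scores
  out
}

#' Cross-condition generalization (train affirmative, test negated)
#'
#' Fits the standardizer + PCA + l2 logistic pipeline once per timepoint on
#' all training epochs and scores all test epochs, quantifying how well the
#' class structure learned in one condition transfers to the other. The
#' chance baseline of the probability estimates (which departs from 0.5 when
#' the training classes are imbalanced) is estimated by refitting under
#' `n_baseline_perm` random permutations of the training labels and averaging
#' the predicted test probabilities.
#'
#' @param train_ep,test_ep `epoch_set`s on identical sensor/time grids.
#' @param train_labels,test_labels binary labels for the two sets.
#' @param C,var_explained as in [fit_temporal_decoder()].
#' @param n_baseline_perm label permutations for the chance baseline
#'   (0 skips it).
#' @param seed seed for the baseline permutations.
#' @return a `decoding_result` whose AUC and probability estimates describe
#'   the test condition; `chance_baseline` holds the permuted-label mean
#'   probability per class and timepoint (or NULL).
#' @export
cross_condition_generalize <- function(train_ep, test_ep, train_labels,
                                       test_labels, C = 1,
                                       var_explained = 0.99,
                                       n_baseline_perm = 100, seed = NULL) {
  if (!isTRUE(all.equal(train_ep$times_ms, test_ep$times_ms)) ||
      dim(train_ep$data)[2] != dim(test_ep$data)[2])
    stop("train and test epochs must share the sensor/time grid")
  ytr <- as_binary(train_labels)
  yte <- as_binary(test_labels)
  if (length(unique(ytr)) < 2L || length(unique(yte)) < 2L)
    stop("both classes must be present in train and test sets")
  proj <- fit_projection(train_ep$data, var_explained)
  w <- balanced_weights(ytr)
  scores <- cpp_decode_raw(train_ep$data, proj$w, proj$shift, ytr, w,
                           test_ep$data, C)
  auc <- apply(scores, 2, compute_auc, labels = yte)
  prob <- rbind(low = colMeans(1 - scores[yte == 0L, , drop = FALSE]),
                high = colMeans(scores[yte == 1L, , drop = FALSE]))
  baseline <- NULL
  if (n_baseline_perm > 0) {
    if (!is.null(seed)) set.seed(seed)
    xtr <- project_epochs(train_ep$data, proj)
    xte <- project_epochs(test_ep$data, proj)
    acc <- matrix(0, 2, dim(xte)[3])
    for (b in seq_len(n_baseline_perm)) {
      yp <- ytr[sample.int(length(ytr))]
      sp <- cpp_decode_timepoints(xtr, yp, balanced_weights(yp), xte, C)
      acc <- acc + rbind(colMeans(1 - sp[yte == 0L, , drop = FALSE]),
                         colMeans(sp[yte == 1L, , drop = FALSE]))
    }
    baseline <- acc / n_baseline_perm
    rownames(baseline) <- c("low", "high")
  }
  decoding_result(train_ep$times_ms, auc, prob, proj$n_components,
                  proj$variance_explained, chance_baseline = baseline)
}

#' Pooled training with separate per-condition testing
#'
#' Stratified k-fold cross-validation over affirmative and negated trials
#' pooled together (stratified on the pole x negation cell), with the
#' held-out metrics computed separately for the affirmative and negated
#' trials of each test split. This yields paired AUC series that support a
#' direct affirmative-vs-negated contrast on the same trained models.
#'
#' @param ep a preprocessed `epoch_set` whose labels contain `pole` and
#'   `negated`.
#' @param k number of folds.
#' @param C,var_explained,seed as in [fit_temporal_decoder()].
#' @return list of class `decoding_pair` with `decoding_result` elements
#'   `aff` and `neg`.
#' @export
pooled_train_split_test <- function(ep, k = 10, C = 1, var_explained = 0.99,
                                    seed = NULL) {
  lab <- ep$labels
  if (!all(c("pole", "negated") %in% names(lab)))
    stop("labels must contain 'pole' and 'negated'")
  y <- as_binary(factor(lab$pole, levels = c("low", "high")))
  cell <- paste(lab$pole, lab$negated)
  if (length(unique(cell)) < 4L)
    stop("all four pole x negation cells must be present")
  if (!is.null(seed)) set.seed(seed)
  folds <- make_stratified_folds(cell, k)
  n <- dim(ep$data)[1]
  n_t <- dim(ep$data)[3]
  scores <- matrix(NA_real_, n, n_t)
  ncomp <- integer(0)
  for (f in sort(unique(folds))) {
    tr <- folds != f
    if (length(unique(cell[tr])) < 4L)
      stop("a pole x negation cell is absent from a training fold")
    proj <- fit_projection(ep$data[tr, , , drop = FALSE], var_explained)
    w <- balanced_weights(y[tr])
    scores[!tr, ] <- cpp_decode_raw(ep$data[tr, , , drop = FALSE], proj$w,
                                    proj$shift, y[tr], w,
                                    ep$data[!tr, , , drop = FALSE], C)
    ncomp <- c(ncomp, proj$n_components)
  }
  split_result <- function(idx) {
    s <- scores[idx, , drop = FALSE]
    yy <- y[idx]
    auc <- apply(s, 2, compute_auc, labels = yy)
    prob <- rbind(low = colMeans(1 - s[yy == 0L, , drop = FALSE]),
                  high = colMeans(s[yy == 1L, , drop = FALSE]))
    decoding_result(ep$times_ms, auc, prob, ncomp, NA_real_, folds[idx])
  }
  out <- list(aff = split_result(!lab$negated),
              neg = split_result(lab$negated))
  class(out) <- "decoding_pair"
  out
}

#' @export
print.decoding_pair <- function(x, ...) {
  cat("Pooled-training decoding, per-condition test metrics\n")
  cat(sprintf("  affirmative peak AUC %.3f, negated peak AUC %.3f\n",
              max(x$aff$auc), max(x$neg$auc)))
  invisible(x)
}
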