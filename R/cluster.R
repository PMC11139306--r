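#' One-sample cluster-based permutation test
#'
#' Nonparametric family-wise inference for participants x time effect series
#' already centered on their null value (e.g., per-participant AUC - 0.5, or
#' regression betas against 0). A one-sample t statistic is computed per
#' timepoint; contiguous supra-threshold runs form clusters whose statistic
#' is the sum of t values within the run; the null distribution is the
#' maximum cluster statistic under random per-participant sign flips, which
#' controls the family-wise error rate over the window. Two-sided tests form
#' positive (t > threshold) and negative (t < -threshold) clusters separately
#' and compare both against a common max-|mass| null.
#'
#' @param effects numeric matrix, participants x time.
#' @param times_ms time axis matching the columns.
#' @param window optional c(start, end) ms; the test is restricted to it.
#' @param n_perm number of random sign-flip permutations (ignored when
#'   `exact = TRUE`).
#' @param tail "two_sided", "greater" or "less".
#' @param alpha cluster-forming uncorrected alpha; the threshold is the
#'   corresponding t quantile for n - 1 degrees of freedom unless `threshold`
#'   is given explicitly.
#' @param threshold optional explicit cluster-forming t value.
#' @param seed optional integer; makes the permutations reproducible without
#'   disturbing the caller's RNG stream.
#' @param exact if TRUE, enumerate all 2^n sign flips (n <= 20) instead of
#'   sampling; p-values are then exact.
#' @return an object of class `cluster_test`: the observed t series, a
#'   data.frame of clusters (start_ms, end_ms, stat, p), the threshold, tail
#'   and permutation count. Cluster p-values use the (1 + exceedances) /
#'   (1 + n_perm) estimator, so p >= 1 / (n_perm + 1).
#' @export
one_sample_cluster_test <- function(effects, times_ms, window = NULL,
                                    n_perm = 10000,
                                    tail = c("two_sided", "greater", "less"),
                                    alpha = 0.05, threshold = NULL,
                                    seed = NULL, exact = FALSE) {
  tail <- match.arg(tail)
  effects <- as.matrix(effects)
  n_p <- nrow(effects)
  if (n_p < 2L) stop("need >= 2 participants")
  if (length(times_ms) != ncol(effects))
    stop("times_ms must match the columns of effects")
  if (!is.null(window)) {
    keep <- times_ms >= window[1] & times_ms <= window[2]
    if (!any(keep)) stop("window lies outside the time axis")
    effects <- effects[, keep, drop = FALSE]
    times_ms <- times_ms[keep]
  } else {
    window <- range(times_ms)
  }
  if (!exact && n_perm < 100) warning("n_perm < 100 gives coarse p-values")
  df <- n_p - 1L
  if (is.null(threshold)) {
    threshold <- if (tail == "two_sided") qt(1 - alpha / 2, df) else qt(1 - alpha, df)
  }
  n_t <- ncol(effects)
  ss <- colSums(effects^2)

  t_of_means <- function(m) {
    # m: permutations x time matrix of means; sum of squares is flip-invariant
    v <- sweep(-n_p * m^2, 2, ss, "+") / df
    v[v < 0] <- 0
    tt <- m / sqrt(v / n_p)
    tt[!is.finite(tt)] <- 0
    tt
  }

  t_obs <- as.numeric(t_of_means(matrix(colMeans(effects), 1)))
  obs <- find_clusters(t_obs, threshold, tail)

  if (exact) {
    if (n_p > 20L) stop("exact enumeration limited to 20 participants")
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n_p)))
  } else {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", globalenv()))
        get(".Random.seed", globalenv()) else NULL
      on.exit({
        if (!is.null(old)) assign(".Random.seed", old, globalenv())
      }, add = TRUE)
      set.seed(seed)
    }
    signs <- matrix(sample(c(-1, 1), n_perm * n_p, replace = TRUE),
                    n_perm, n_p)
  }
  t_perm <- t_of_means((signs %*% effects) / n_p)
  null_max <- max_cluster_mass(t_perm, threshold, tail)

  n_eff <- nrow(signs)
  if (nrow(obs)) {
    # sign patterns that mirror the observed one reproduce the observed mass
    # exactly; a relative slack keeps such ties counted as exceedances
    # regardless of floating-point noise
    slack <- function(m) m - (1e-9 * abs(m) + 1e-12)
    if (exact) {
      obs$p <- vapply(abs(obs$stat),
                      function(m) mean(null_max >= slack(m)), 0)
    } else {
      obs$p <- vapply(abs(obs$stat),
                      function(m) (1 + sum(null_max >= slack(m))) / (1 + n_eff), 0)
    }
  }
  structure(list(window = window, times_ms = times_ms, t = t_obs,
                 clusters = obs, threshold = threshold, tail = tail,
                 n_permutations = n_eff, alpha = alpha, seed = seed,
                 exact = exact),
            class = "cluster_test")
}

# Observed clusters of a single t series.
find_clusters <- function(t_obs, threshold, tail) {
  out <- data.frame(start = integer(0), end = integer(0),
                    sign = integer(0), stat = numeric(0), p = numeric(0))
  grab <- function(mask, sgn) {
    if (!any(mask)) return(NULL)
    r <- rle(mask)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    k <- which(r$values)
    data.frame(start = starts[k], end = ends[k], sign = sgn,
               stat = vapply(k, function(i)
                 sum(t_obs[starts[i]:ends[i]]), 0))
  }
  res <- NULL
  if (tail %in% c("two_sided", "greater"))
    res <- rbind(res, grab(t_obs > threshold, 1L))
  if (tail %in% c("two_sided", "less"))
    res <- rbind(res, grab(t_obs < -threshold, -1L))
  if (is.null(res) || !nrow(res)) return(out)
  res <- res[order(res$start), , drop = FALSE]
  data.frame(start = res$start, end = res$end, sign = res$sign,
             stat = res$stat, p = NA_real_)
}

# Maximum cluster mass per row of a permutations x time t matrix.
# Rows are flattened with a separator so one rle() call handles all runs.
max_cluster_mass <- function(t_mat, threshold, tail) {
  pos <- if (tail %in% c("two_sided", "greater"))
    row_max_mass(t_mat, threshold) else 0
  neg <- if (tail %in% c("two_sided", "less"))
    row_max_mass(-t_mat, threshold) else 0
  pmax(pos, neg)
}

row_max_mass <- function(t_mat, threshold) {
  nr <- nrow(t_mat)
  supra <- cbind(t_mat > threshold, FALSE)
  vec <- as.vector(t(supra))
  r <- rle(vec)
  runs <- which(r$values)
  out <- numeric(nr)
  if (!length(runs)) return(out)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  tv <- as.vector(t(cbind(t_mat, 0)))
  cs <- cumsum(tv)
  s <- starts[runs]
  e <- ends[runs]
  mass <- cs[e] - c(0, cs)[s]  # c(0, cs)[s] == cs[s - 1], with cs[0] -> 0
  row_id <- ((s - 1L) %/% (ncol(supra))) + 1L
  agg <- tapply(mass, row_id, max)
  out[as.integer(names(agg))] <- agg
  out
}

#' @export
print.cluster_test <- function(x, ...) {
  cat(sprintf("One-sample sign-flip cluster test (%s), window %g..%g ms\n",
              x$tail, x$window[1], x$window[2]))
  cat(sprintf("  threshold |t| > %.3f, %d %s\n", x$threshold,
              x$n_permutations,
              if (x$exact) "exact sign patterns" else "permutations"))
  if (!nrow(x$clusters)) {
    cat("  no clusters\n")
  } else {
    cl <- x$clusters
    for (i in seq_len(nrow(cl))) {
      cat(sprintf("  cluster %d: %g..%g ms, mass %.2f, p = %.4g\n", i,
                  x$times_ms[cl$start[i]], x$times_ms[cl$end[i]],
                  cl$stat[i], cl$p[i]))
    }
  }
  invisible(x)
}

#' Significant clusters of a cluster test
#'
#' @param x a `cluster_test`.
#' @param alpha significance level.
#' @param sign optional +1/-1 to restrict to positive/negative clusters.
#' @return the rows of `x$clusters` with p <= alpha (time indices plus
#'   start_ms/end_ms columns resolved against the window's time axis).
#' @export
significant_clusters <- function(x, alpha = 0.05, sign = NULL) {
  cl <- x$clusters
  if (!nrow(cl)) return(cl)
  keep <- !is.na(cl$p) & cl$p <= alpha
  if (!is.null(sign)) keep <- keep & cl$sign == sign
  cl <- cl[keep, , drop = FALSE]
  if (nrow(cl)) {
    cl$start_ms <- x$times_ms[cl$start]
    cl$end_ms <- x$times_ms[cl$end]
  }
  cl
}
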