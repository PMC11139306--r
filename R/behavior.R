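#' Filter trials by feedback and reaction-time range
#'
#' Keeps only positive-feedback trials whose RT lies within the participant's
#' median +/- `rt_sd_mult` standard deviations, where both the median and the
#' SD are computed per participant over that participant's positive-feedback
#' trials. With constant RTs (zero SD) the band collapses to the median and
#' all trials at the median are kept.
#'
#' @param trials a trial table with columns participant_id, rt_ms, feedback.
#' @param rt_sd_mult width of the RT band in SD units (default 2).
#' @return the filtered table. Attribute `removed` holds the counts removed
#'   by each rule; attribute `flagged_participants` names participants left
#'   with fewer than 2 trials (retained, with a warning).
#' @export
filter_trials <- function(trials, rt_sd_mult = 2) {
  stopifnot(all(c("participant_id", "rt_ms", "feedback") %in% names(trials)))
  pos <- trials$feedback == 1L
  keep <- logical(nrow(trials))
  for (p in unique(trials$participant_id)) {
    ip <- trials$participant_id == p & pos
    if (!any(ip)) next
    med <- median(trials$rt_ms[ip])
    s <- sd(trials$rt_ms[ip])
    if (is.na(s)) s <- 0
    lo <- med - rt_sd_mult * s
    hi <- med + rt_sd_mult * s
    keep[ip] <- trials$rt_ms[ip] >= lo & trials$rt_ms[ip] <= hi
  }
  removed <- c(feedback = sum(!pos),
               rt_range = sum(pos & !keep))
  out <- trials[keep, , drop = FALSE]
  tab <- table(out$participant_id)
  flagged <- names(tab)[tab < 2L]
  lost <- setdiff(unique(trials$participant_id), names(tab))
  flagged <- union(flagged, lost)
  if (length(flagged)) {
    warning(sprintf("participant(s) with < 2 surviving trials: %s",
                    paste(flagged, collapse = ", ")))
  }
  attr(out, "removed") <- removed
  attr(out, "flagged_participants") <- flagged
  out
}

#' 2x2 repeated-measures ANOVA
#'
#' Within-subject ANOVA for a fully crossed 2x2 design in which every
#' participant contributes one summary value per cell (e.g., the median RT or
#' the mean/SD of the rating endpoint). Returns the F(1, n-1) statistic,
#' exact p from the F distribution, and partial eta squared
#' eta_p^2 = SS_effect / (SS_effect + SS_error) for both main effects and the
#' interaction. For a 2x2 within design each F equals the squared paired t
#' statistic of the corresponding participant-level contrast.
#'
#' @param cells data.frame with columns participant, A, B (each two-level)
#'   and value; one row per participant x cell.
#' @param factor_names length-2 character, display names for A and B.
#' @return a data.frame of class `rm_anova` with columns effect, F, df1, df2,
#'   p, eta_p2.
#' @export
rm_anova_2x2 <- function(cells, factor_names = c("A", "B")) {
  stopifnot(all(c("participant", "A", "B", "value") %in% names(cells)))
  cells$participant <- factor(cells$participant)
  cells$A <- factor(cells$A)
  cells$B <- factor(cells$B)
  if (nlevels(cells$A) != 2L || nlevels(cells$B) != 2L)
    stop("both factors must have exactly 2 levels")
  counts <- table(cells$participant, cells$A, cells$B)
  if (any(counts != 1L)) {
    bad <- which(counts != 1L, arr.ind = TRUE)[1, ]
    stop(sprintf("participant %s is missing (or duplicates) cell %s x %s",
                 dimnames(counts)[[1]][bad[1]],
                 dimnames(counts)[[2]][bad[2]],
                 dimnames(counts)[[3]][bad[3]]))
  }
  fit <- aov(value ~ A * B + Error(participant / (A * B)), data = cells)
  sm <- summary(fit)
  ss_total <- sum((cells$value - mean(cells$value))^2)
  grab <- function(stratum, term) {
    tab <- sm[[stratum]][[1]]
    rn <- trimws(rownames(tab))
    i <- match(term, rn)
    j <- match("Residuals", rn)
    ss_e <- tab[i, "Sum Sq"]
    ss_r <- tab[j, "Sum Sq"]
    df1 <- tab[i, "Df"]
    df2 <- tab[j, "Df"]
    f <- (ss_e / df1) / (ss_r / df2)
    eta <- ss_e / (ss_e + ss_r)
    # constant data leave only floating-point dust in both sums of squares
    if (!is.finite(f) || ss_e <= 1e-12 * max(ss_total, 1e-12)) {
      f <- 0
      eta <- 0
    }
    data.frame(F = f, df1 = df1, df2 = df2,
               p = pf(f, df1, df2, lower.tail = FALSE),
               eta_p2 = eta)
  }
  out <- rbind(grab("Error: participant:A", "A"),
               grab("Error: participant:B", "B"),
               grab("Error: participant:A:B", "A:B"))
  out <- cbind(effect = c(factor_names[1], factor_names[2],
                          paste(factor_names, collapse = " x ")),
               out)
  rownames(out) <- NULL
  class(out) <- c("rm_anova", "data.frame")
  out
}

#' @export
print.rm_anova <- function(x, ...) {
  cat("Repeated-measures ANOVA (within-subject, 2 x 2)\n")
  y <- x
  y$F <- round(y$F, 2)
  y$p <- signif(y$p, 3)
  y$eta_p2 <- round(y$eta_p2, 3)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

#' Holm step-down correction for post hoc tests
#'
#' Thin wrapper around [stats::p.adjust()] that validates the inputs and
#' preserves the label order of the comparisons.
#'
#' @param pvalues numeric p-values in [0, 1].
#' @param labels optional character labels, same length.
#' @return named numeric vector of Holm-adjusted p-values.
#' @export
holm_posthoc <- function(pvalues, labels = NULL) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  adj <- p.adjust(pvalues, method = "holm")
  if (!is.null(labels)) names(adj) <- labels
  adj
}

#' Per-participant cell summaries for a 2x2 design
#'
#' @param trials filtered trial table.
#' @param value column to summarize.
#' @param fun summary function (e.g., median, mean, sd).
#' @return data.frame participant, A (= pole), B (= negation), value.
#' @keywords internal
cell_summaries <- function(trials, value, fun) {
  agg <- aggregate(trials[[value]],
                   by = list(participant = trials$participant_id,
                             A = trials$pole,
                             B = ifelse(trials$negated, "negated", "affirmative")),
                   FUN = fun)
  names(agg)[4] <- "value"
  agg
}

#' RT statistics: per-participant median RTs into a 2x2 RM-ANOVA
#'
#' @param trials filtered trial table.
#' @return an `rm_anova` for the antonym and negation factors.
#' @export
rt_stats <- function(trials) {
  rm_anova_2x2(cell_summaries(trials, "rt_ms", median),
               factor_names = c("antonym", "negation"))
}

#' Phrase-complexity RT analysis
#'
#' Complexity (1 vs 2 modifiers) crossed with negation through the same 2x2
#' within-subject machinery; no-modifier trials are excluded.
#'
#' @param trials filtered trial table with an `n_modifiers` column.
#' @return an `rm_anova` for the complexity and negation factors.
#' @export
complexity_stats <- function(trials) {
  t2 <- trials[trials$n_modifiers > 0L, , drop = FALSE]
  agg <- aggregate(t2$rt_ms,
                   by = list(participant = t2$participant_id,
                             A = ifelse(t2$n_modifiers == 2L, "two", "one"),
                             B = ifelse(t2$negated, "negated", "affirmative")),
                   FUN = median)
  names(agg)[4] <- "value"
  rm_anova_2x2(agg, factor_names = c("complexity", "negation"))
}

#' Endpoint statistics: location and variability of final interpretations
#'
#' Computes per-participant per-cell means and SDs of the rating endpoint and
#' feeds both into the 2x2 within-subject ANOVA: the means test where the
#' final interpretation sits on the scale (and the antonym x negation
#' interaction that signals mitigation), the SDs test whether negated
#' interpretations are more variable. Holm-corrected paired post hoc
#' comparisons of the four cell means are included.
#'
#' @param trials filtered trial table with endpoints.
#' @return list with elements `cell_means` (participant-level cell table),
#'   `anova_mean`, `anova_sd` (rm_anova objects) and `posthoc`
#'   (Holm-adjusted paired comparisons of cell means).
#' @export
endpoint_stats <- function(trials) {
  tr <- trials[!is.na(trials$endpoint), , drop = FALSE]
  means <- cell_summaries(tr, "endpoint", mean)
  sds <- cell_summaries(tr, "endpoint", sd)
  sds$value[is.na(sds$value)] <- 0
  a_mean <- rm_anova_2x2(means, factor_names = c("antonym", "negation"))
  a_sd <- rm_anova_2x2(sds, factor_names = c("antonym", "negation"))
  # all-pairs paired comparisons of the 4 cells, Holm corrected
  means$cell <- paste(means$B, means$A, sep = "_")
  wide <- reshape(means[, c("participant", "cell", "value")],
                  idvar = "participant", timevar = "cell",
                  direction = "wide")
  cn <- sub("^value\\.", "", names(wide)[-1])
  pairs <- utils::combn(seq_along(cn), 2)
  p <- numeric(ncol(pairs))
  lab <- character(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k] + 1L
    j <- pairs[2, k] + 1L
    d <- wide[[i]] - wide[[j]]
    if (sd(d) <= 1e-12 * (abs(mean(d)) + 1e-12)) {
      # constant differences: no within-pair variance to test against
      p[k] <- if (isTRUE(all.equal(mean(d), 0))) 1 else 0
    } else {
      p[k] <- stats::t.test(d)$p.value
    }
    lab[k] <- paste(cn[pairs[1, k]], "vs", cn[pairs[2, k]])
  }
  list(cell_means = means[, c("participant", "A", "B", "value")],
       anova_mean = a_mean, anova_sd = a_sd,
       posthoc = holm_posthoc(p, lab))
}

#' Feedback-score statistics
#'
#' Mean feedback score per participant and cell into the 2x2 within-subject
#' ANOVA (antonym x negation). Uses all trials (feedback is the outcome).
#'
#' @param trials trial table (unfiltered).
#' @return an `rm_anova`.
#' @export
feedback_stats <- function(trials) {
  rm_anova_2x2(cell_summaries(trials, "feedback", mean),
               factor_names = c("antonym", "negation"))
}
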