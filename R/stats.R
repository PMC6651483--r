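#' @title Group-level inference on non-similar fragment counts
#' @description One-sided pooled-variance two-sample t-tests on
#'   per-participant non-similar counts (overall and per intensity bin),
#'   similarity-threshold sweeps, and ROC/AUC with operating-point
#'   reporting.
#' @name group_stats
NULL

#' Summary statistics of a group's counts
#'
#' @param x Either a numeric vector of per-participant counts, or a
#'   pre-computed mean (then supply `sd` and `n`).
#' @param group Group label.
#' @param sd,n Sample SD and group size when `x` is a mean.
#' @return An object of class `group_summary` with `group`, `n`, `mean`,
#'   `sd`.
#' @export
group_summary <- function(x, group = NA_character_, sd = NULL, n = NULL) {
  if (length(x) > 1 || is.null(sd)) {
    out <- list(group = group, n = length(x), mean = mean(x),
                sd = stats::sd(x))
  } else {
    out <- list(group = group, n = as.integer(n), mean = x, sd = sd)
  }
  if (out$n < 2) stop_input("group '%s' needs n >= 2", group)
  structure(out, class = "group_summary")
}

#' One-sided pooled-variance two-sample t-test on counts
#'
#' Tests whether the case group (`b`) produces more non-similar fragments on
#' average than the reference group (`a`):
#' `t = (mean_b - mean_a) / (sp * sqrt(1/n_a + 1/n_b))` with the pooled SD
#' `sp` and `df = n_a + n_b - 2`; the p-value is one-sided for the
#' alternative `mean_b > mean_a`. The Welch variant (unpooled variances,
#' Welch-Satterthwaite df) is available via `var_equal = FALSE`.
#'
#' @param a Reference group: a [group_summary()] or numeric count vector.
#' @param b Case group: a [group_summary()] or numeric count vector.
#' @param var_equal Pool the variances (default `TRUE`).
#' @param bin Bin label carried into the result.
#' @param th Similarity threshold carried into the result.
#' @return An object of class `group_comparison`: a one-row data frame with
#'   `group_a`, `group_b`, `bin`, `th`, means, SDs, sizes, `t`, `df`, `p`
#'   (one-sided), and `degenerate` (zero variance with unequal means).
#' @export
t_test_counts <- function(a, b, var_equal = TRUE, bin = "all", th = NA_real_) {
  if (!inherits(a, "group_summary")) a <- group_summary(a, "a")
  if (!inherits(b, "group_summary")) b <- group_summary(b, "b")
  degenerate <- FALSE
  if (var_equal) {
    df <- a$n + b$n - 2
    sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / df
    se <- sqrt(sp2 * (1 / a$n + 1 / b$n))
  } else {
    va <- a$sd^2 / a$n
    vb <- b$sd^2 / b$n
    se <- sqrt(va + vb)
    df <- if (se > 0)
      (va + vb)^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1)) else NA_real_
  }
  delta <- b$mean - a$mean
  if (se == 0 || !is.finite(se)) {
    if (isTRUE(all.equal(delta, 0))) {
      tstat <- 0
      p <- 0.5
    } else {
      degenerate <- TRUE
      tstat <- sign(delta) * Inf
      p <- if (delta > 0) 0 else 1
    }
  } else {
    tstat <- delta / se
    p <- stats::pt(tstat, df, lower.tail = FALSE)
  }
  out <- data.frame(group_a = a$group, group_b = b$group, bin = bin,
                    th = th, n_a = a$n, n_b = b$n,
                    mean_a = a$mean, mean_b = b$mean,
                    sd_a = a$sd, sd_b = b$sd,
                    t = tstat, df = df, p = p, degenerate = degenerate)
  class(out) <- c("group_comparison", "data.frame")
  out
}

#' Per-intensity-bin group comparisons
#'
#' Runs [t_test_counts()] on the per-bin non-similar counts of each case
#' group against the control group, one comparison per (bin, case group).
#' Bins in which a group has no windows (or both groups have constant
#' counts) are flagged `undefined` rather than dropped.
#'
#' @param summaries A data frame of [summarize_participant()] rows with a
#'   `group` column.
#' @param bins The [intensity_bins()] used.
#' @param control Group label of the reference group.
#' @param case_groups Case group labels (default: every other group).
#' @param th Similarity threshold carried into the results.
#' @return A `group_comparison` data frame, one row per (bin, case group),
#'   with `bin_label` and `undefined` columns.
#' @export
per_bin_comparisons <- function(summaries, bins = intensity_bins(),
                                control = "control_test",
                                case_groups = NULL, th = NA_real_) {
  stopifnot(control %in% summaries$group)
  if (is.null(case_groups))
    case_groups <- setdiff(unique(summaries$group), control)
  labels <- bin_labels(bins)
  rows <- list()
  for (b in seq_len(bins$n_bins)) {
    col <- sprintf("nonsim_bin_%d", b)
    ctrl <- summaries[[col]][summaries$group == control]
    for (g in case_groups) {
      case <- summaries[[col]][summaries$group == g]
      cmp <- t_test_counts(group_summary(ctrl, control),
                           group_summary(case, g), bin = b, th = th)
      cmp$bin_label <- labels[b]
      cmp$undefined <- cmp$degenerate ||
        (stats::sd(ctrl) == 0 && stats::sd(case) == 0)
      rows[[length(rows) + 1]] <- cmp
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("group_comparison", "data.frame")
  out
}

#' Sweep the similarity threshold
#'
#' Recomputes per-participant non-similar counts and the group t-test at
#' each threshold of the grid from stored fragment correlations, without
#' re-running the forecaster.
#'
#' @param scores A data frame of fragment scores (rows from
#'   [score_windows()]) for all evaluated participants, with a `group`
#'   column.
#' @param th_grid Numeric vector of thresholds in (0, 1).
#' @param control Reference group label.
#' @param case_groups Case group labels (default: every other group).
#' @param bin Optional bin index to restrict the sweep to one intensity
#'   interval.
#' @return A `group_comparison` data frame with one row per (threshold,
#'   case group).
#' @export
threshold_sweep <- function(scores, th_grid = seq(0.3, 0.7, by = 0.1),
                            control = "control_test", case_groups = NULL,
                            bin = NULL) {
  if (any(th_grid <= 0 | th_grid >= 1))
    stop_input("thresholds must lie in (0, 1)")
  if (!is.null(bin)) scores <- scores[scores$bin == bin, , drop = FALSE]
  if (is.null(case_groups))
    case_groups <- setdiff(unique(scores$group), control)
  rows <- list()
  for (th in th_grid) {
    counts <- stats::aggregate(list(count = scores$r < th),
                               by = list(participant_id =
                                           scores$participant_id,
                                         group = scores$group),
                               FUN = sum)
    ctrl <- counts$count[counts$group == control]
    for (g in case_groups) {
      case <- counts$count[counts$group == g]
      rows[[length(rows) + 1]] <-
        t_test_counts(group_summary(ctrl, control),
                      group_summary(case, g),
                      bin = if (is.null(bin)) "all" else bin, th = th)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("group_comparison", "data.frame")
  out
}

#' Per-participant non-similar counts at a threshold
#'
#' @param scores Fragment scores with `participant_id` (and optionally
#'   `group`) columns.
#' @param th Similarity threshold.
#' @param bin Optional bin restriction.
#' @return Data frame `participant_id`, `group`, `count`.
#' @export
count_non_similar <- function(scores, th = 0.5, bin = NULL) {
  if (!is.null(bin)) scores <- scores[scores$bin == bin, , drop = FALSE]
  grp <- scores$group %||% rep(NA_character_, nrow(scores))
  stats::aggregate(list(count = scores$r < th),
                   by = list(participant_id = scores$participant_id,
                             group = grp),
                   FUN = sum)
}

#' ROC area and operating point for count-based separation
#'
#' AUC by pairwise comparison of case and control counts (ties count one
#' half; equal to the scaled Mann-Whitney U statistic). The operating point
#' is the smallest count threshold maximizing Youden's index
#' (sensitivity - false positive rate), classifying a participant as case
#' when their count exceeds the threshold.
#'
#' @param case_counts,control_counts Non-empty integer vectors of
#'   per-participant non-similar counts.
#' @return A list with `auc`, `threshold`, `sensitivity`, `fpr`, `k_case`
#'   (cases above threshold), `k_control`, `n_case`, `n_control`.
#' @export
roc_auc <- function(case_counts, control_counts) {
  if (length(case_counts) == 0 || length(control_counts) == 0)
    stop_input("both count vectors must be non-empty")
  cmp <- outer(case_counts, control_counts,
               function(a, b) (a > b) + 0.5 * (a == b))
  auc <- mean(cmp)
  cand <- sort(unique(c(case_counts, control_counts, -Inf)))
  sens <- vapply(cand, function(t) mean(case_counts > t), numeric(1))
  fpr <- vapply(cand, function(t) mean(control_counts > t), numeric(1))
  youden <- sens - fpr
  best <- which(youden == max(youden))[1] # smallest threshold at the max
  list(auc = auc, threshold = cand[best],
       sensitivity = sens[best], fpr = fpr[best],
       k_case = sum(case_counts > cand[best]),
       k_control = sum(control_counts > cand[best]),
       n_case = length(case_counts), n_control = length(control_counts))
}
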