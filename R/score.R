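#' @title Similarity scoring of forecast fragments
#' @description Pearson correlation between the predicted and observed
#'   2-second segments of every 8-second window, non-similar flagging at a
#'   similarity threshold, and per-participant counting overall and per
#'   intensity bin.
#' @name scoring
NULL

#' Pearson similarity of a prediction and its target
#'
#' Correlation of the two flattened 80-value vectors (channels
#' concatenated). If either vector is essentially constant (variance below
#' `1e-12`), the similarity is defined as 0: an uninformative prediction
#' never counts as a match.
#'
#' @param pred,actual Equal-shaped numeric matrices (20 x 4).
#' @return Pearson coefficient in `[-1, 1]`.
#' @export
pearson_similarity <- function(pred, actual) {
  pred <- as.matrix(pred)
  actual <- as.matrix(actual)
  if (!identical(dim(pred), dim(actual)))
    stop_input("pred and actual must have identical shapes")
  if (!all(is.finite(pred)) || !all(is.finite(actual)))
    stop_input("non-finite values in similarity inputs")
  a <- as.vector(pred)
  b <- as.vector(actual)
  if (stats::var(a) < 1e-12 || stats::var(b) < 1e-12) return(0)
  stats::cor(a, b)
}

# Vectorized row-wise Pearson between two n x k matrices; degenerate rows
# (variance < 1e-12) score 0.
rowwise_pearson <- function(p, a) {
  k <- ncol(p)
  pc <- p - rowMeans(p)
  ac <- a - rowMeans(a)
  vp <- rowSums(pc^2) / (k - 1)
  va <- rowSums(ac^2) / (k - 1)
  r <- numeric(nrow(p))
  ok <- vp >= 1e-12 & va >= 1e-12
  r[ok] <- rowSums(pc[ok, , drop = FALSE] * ac[ok, , drop = FALSE]) /
    sqrt(rowSums(pc[ok, , drop = FALSE]^2) *
           rowSums(ac[ok, , drop = FALSE]^2))
  r
}

#' Score every window of a participant
#'
#' Runs the trained forecaster on each window's 6-second input, computes the
#' Pearson similarity against the observed 2-second target, and flags
#' windows with `r < th` as non-similar (movement patterns absent from the
#' training population).
#'
#' @param windows A [segment_windows()] result.
#' @param models Either a single `forecaster_params` (applied to every
#'   window) or a list of per-bin models named/indexed by bin number.
#' @param th Similarity threshold (default 0.5).
#' @return A data frame of fragment scores: `participant_id`,
#'   `window_index`, `r`, `intensity_sd`, `bin`, `is_similar`.
#' @export
score_windows <- function(windows, models, th = 0.5) {
  stopifnot(inherits(windows, "window_set"))
  n <- windows$n_windows
  r <- numeric(n)
  if (n > 0) {
    y_flat <- matrix(windows$y, n, dim(windows$y)[2] * dim(windows$y)[3])
    if (inherits(models, "forecaster_params")) {
      yhat <- forward_batch(models, windows$x)
      r <- rowwise_pearson(yhat, y_flat)
    } else {
      for (b in sort(unique(windows$bin))) {
        model <- models[[b]]
        if (is.null(model) || !inherits(model, "forecaster_params"))
          stop_input("no model supplied for intensity bin %d", b)
        sel <- which(windows$bin == b)
        yhat <- forward_batch(model, windows$x[sel, , , drop = FALSE])
        r[sel] <- rowwise_pearson(yhat, y_flat[sel, , drop = FALSE])
      }
    }
  }
  data.frame(participant_id = windows$participant_id,
             window_index = windows$window_index,
             r = r, intensity_sd = windows$intensity_sd,
             bin = windows$bin,
             is_similar = r >= th)
}

#' Summarize non-similar counts for one participant
#'
#' @param scores A [score_windows()] data frame for one participant.
#' @param bins The [intensity_bins()] used for segmentation.
#' @param group Optional group label carried into the summary.
#' @return A one-row data frame: `participant_id`, `group`, `n_windows`,
#'   `non_similar_total`, and one `nonsim_bin_<k>` column per bin.
#' @export
summarize_participant <- function(scores, bins = intensity_bins(),
                                  group = NA_character_) {
  per_bin <- vapply(seq_len(bins$n_bins), function(b)
    sum(!scores$is_similar & scores$bin == b), integer(1))
  out <- data.frame(participant_id = scores$participant_id[1] %||%
                      NA_character_,
                    group = group,
                    n_windows = nrow(scores),
                    non_similar_total = sum(!scores$is_similar))
  for (b in seq_len(bins$n_bins))
    out[[sprintf("nonsim_bin_%d", b)]] <- per_bin[b]
  out
}

#' Score a participant and summarize
#'
#' @inheritParams score_windows
#' @param bins The [intensity_bins()] used for segmentation.
#' @param group Optional group label.
#' @return A list with `scores` (per-window data frame) and `summary`
#'   (one-row data frame of totals and per-bin counts).
#' @export
score_participant <- function(windows, models, th = 0.5,
                              bins = intensity_bins(),
                              group = NA_character_) {
  scores <- score_windows(windows, models, th)
  list(scores = scores,
       summary = summarize_participant(scores, bins, group))
}
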