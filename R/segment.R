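#' @title Windowing and intensity stratification
#' @description Splits synchronized recordings into non-overlapping 8-second
#'   windows, forms 6-s-input / 2-s-target forecasting pairs, and assigns
#'   each fragment a movement-intensity bin from the pooled standard
#'   deviation of all four channels.
#' @name segmentation
NULL

#' Movement-intensity bins
#'
#' Half-open intervals `[lo, hi)` of combined fragment SD in g. The defaults
#' cover rest through vigorous movement with a 0.2 g grid and an unbounded
#' top bin.
#'
#' @param edges Strictly increasing numeric vector of bin edges.
#' @return An object of class `intensity_bins`.
#' @export
intensity_bins <- function(edges = c(0, 0.2, 0.4, 0.6, 0.8, 1, Inf)) {
  if (any(diff(edges) <= 0)) stop_input("bin edges must be strictly increasing")
  structure(list(edges = edges, n_bins = length(edges) - 1L),
            class = "intensity_bins")
}

#' Labels for intensity bins
#'
#' @param bins An [intensity_bins()].
#' @return Character vector like `"[0.4,0.6)"`.
#' @export
bin_labels <- function(bins) {
  lo <- bins$edges[-length(bins$edges)]
  hi <- bins$edges[-1]
  sprintf("[%g,%s)", lo, ifelse(is.finite(hi), format(hi), "Inf"))
}

#' Combined standard deviation of a fragment
#'
#' Sample SD (denominator n - 1) pooled over every value of the 8-second
#' window across all four channels: the fragment's movement-intensity
#' measure.
#'
#' @param window Numeric matrix (samples x channels), or a `window_set` (in
#'   which case the stored per-window SDs are returned).
#' @return SD in g.
#' @export
combined_sd <- function(window) {
  if (inherits(window, "window_set")) return(window$intensity_sd)
  stats::sd(as.vector(window))
}

#' Assign intensity bins
#'
#' @param sd Numeric vector of combined SDs (>= 0).
#' @param bins An [intensity_bins()].
#' @return Integer bin indices; values below the first edge map to bin 1.
#' @export
assign_bin <- function(sd, bins = intensity_bins()) {
  if (any(sd < 0)) stop_input("intensity SD must be non-negative")
  pmax(1L, findInterval(sd, bins$edges))
}

#' Segment a synchronized recording into forecasting window pairs
#'
#' Divides the recording into `floor(L / 80)` non-overlapping 8-second
#' windows (any trailing remainder is discarded) and splits each into a
#' 6-second input and the immediately following 2-second target.
#'
#' @param recording A [synchronize()] result (or a plain n x 4 matrix).
#' @param bins An [intensity_bins()].
#' @param window_samples Samples per window (default 80 = 8 s at 10 Hz).
#' @param input_samples Input samples per window (default 60 = 6 s).
#' @return An object of class `window_set` with fields `x` (n x 60 x 4
#'   array), `y` (n x 20 x 4 array), `intensity_sd`, `bin`,
#'   `participant_id`, `window_index` (0-based), `n_windows`.
#' @export
segment_windows <- function(recording, bins = intensity_bins(),
                            window_samples = 80, input_samples = 60) {
  channels <- if (inherits(recording, "synchronized_recording"))
    recording$channels else as.matrix(recording)
  participant_id <- if (inherits(recording, "synchronized_recording"))
    recording$participant_id else NA_character_
  if (input_samples >= window_samples)
    stop_input("input_samples must be smaller than window_samples")
  n_ch <- ncol(channels)
  window_samples <- as.integer(window_samples)
  input_samples <- as.integer(input_samples)
  n_w <- nrow(channels) %/% window_samples
  target_samples <- window_samples - input_samples
  if (n_w == 0) {
    return(structure(list(
      x = array(0, c(0, input_samples, n_ch)),
      y = array(0, c(0, target_samples, n_ch)),
      intensity_sd = numeric(0), bin = integer(0),
      participant_id = participant_id, window_index = integer(0),
      n_windows = 0L, bins = bins), class = "window_set"))
  }
  used <- channels[seq_len(n_w * window_samples), , drop = FALSE]
  # samples x windows x channels, then window-major
  arr <- array(used, dim = c(window_samples, n_w, n_ch))
  arr <- aperm(arr, c(2, 1, 3))
  x <- arr[, seq_len(input_samples), , drop = FALSE]
  y <- arr[, input_samples + seq_len(target_samples), , drop = FALSE]
  flat <- matrix(arr, nrow = n_w) # n_w x (window_samples * n_ch)
  m <- rowMeans(flat)
  sds <- sqrt(rowSums((flat - m)^2) / (ncol(flat) - 1))
  structure(list(x = x, y = y, intensity_sd = sds,
                 bin = assign_bin(sds, bins),
                 participant_id = participant_id,
                 window_index = seq_len(n_w) - 1L,
                 n_windows = n_w, bins = bins),
            class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf("<window_set %s: %d windows (%d + %d samples x %d channels)>\n",
              x$participant_id, x$n_windows, dim(x$x)[2], dim(x$y)[2],
              dim(x$x)[3]))
  invisible(x)
}

#' Extract one window pair
#'
#' @param windows A [segment_windows()] result.
#' @param i Window number (1-based position in the set).
#' @return A list with `x` (60 x 4), `y` (20 x 4), `intensity_sd`, `bin`,
#'   `window_index`, `participant_id`.
#' @export
window_pair <- function(windows, i) {
  stopifnot(inherits(windows, "window_set"), i >= 1, i <= windows$n_windows)
  list(x = matrix(windows$x[i, , ], dim(windows$x)[2], dim(windows$x)[3]),
       y = matrix(windows$y[i, , ], dim(windows$y)[2], dim(windows$y)[3]),
       intensity_sd = windows$intensity_sd[i], bin = windows$bin[i],
       window_index = windows$window_index[i],
       participant_id = windows$participant_id)
}

# Row-bind several window sets (used to pool training participants).
combine_window_sets <- function(sets) {
  sets <- sets[vapply(sets, function(s) s$n_windows > 0, logical(1))]
  if (length(sets) == 0) stop_input("no windows to combine")
  d2x <- dim(sets[[1]]$x)[2:3]
  d2y <- dim(sets[[1]]$y)[2:3]
  n <- sum(vapply(sets, function(s) s$n_windows, integer(1)))
  x <- array(0, c(n, d2x))
  y <- array(0, c(n, d2y))
  off <- 0L
  for (s in sets) {
    idx <- off + seq_len(s$n_windows)
    x[idx, , ] <- s$x
    y[idx, , ] <- s$y
    off <- off + s$n_windows
  }
  structure(list(
    x = x, y = y,
    intensity_sd = unlist(lapply(sets, function(s) s$intensity_sd)),
    bin = unlist(lapply(sets, function(s) s$bin)),
    participant_id = NA_character_,
    window_index = unlist(lapply(sets, function(s) s$window_index)),
    n_windows = n, bins = sets[[1]]$bins), class = "window_set")
}
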