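# Independent reference implementations used as oracles. These are written
# scalar-by-scalar (no shared code with the package's vectorized /
# compiled paths) so they can certify the fast implementations.

sig_ref <- function(z) 1 / (1 + exp(-z))

# One LSTM cell update, straight from the gate equations.
oracle_cell_step <- function(x, h, c, p) {
  f <- sig_ref(as.numeric(t(p$Wf) %*% x + t(p$Uf) %*% h) + p$bf)
  i <- sig_ref(as.numeric(t(p$Wi) %*% x + t(p$Ui) %*% h) + p$bi)
  o <- sig_ref(as.numeric(t(p$Wo) %*% x + t(p$Uo) %*% h) + p$bo)
  g <- tanh(as.numeric(t(p$Wc) %*% x + t(p$Uc) %*% h) + p$bc)
  c_new <- f * c + i * g
  list(h = o * tanh(c_new), c = c_new)
}

# Step-by-step evaluation of the stacked forecaster from zero initial state.
oracle_forward <- function(params, x) {
  n_layers <- length(params$layers)
  states <- lapply(params$layers, function(p)
    list(h = rep(0, p$hidden_size), c = rep(0, p$hidden_size)))
  for (t in seq_len(nrow(x))) {
    inp <- x[t, ]
    for (l in seq_len(n_layers)) {
      states[[l]] <- oracle_cell_step(inp, states[[l]]$h, states[[l]]$c,
                                      params$layers[[l]])
      inp <- states[[l]]$h
    }
  }
  h_top <- states[[n_layers]]$h
  matrix(as.numeric(h_top %*% params$Wd) + params$bd,
         params$config$output_steps, params$config$input_size)
}

# Linear scan implementing the shake-end definition directly.
oracle_shake_end <- function(av, th1, th2, n_sync) {
  a <- abs(av)
  j0 <- NA
  for (i in seq_along(a)) if (a[i] >= th1) { j0 <- i; break }
  if (is.na(j0)) return(NA_integer_)
  w <- n_sync + 1
  if (j0 + 1 > length(a) - w + 1) return(NA_integer_)
  for (k in (j0 + 1):(length(a) - w + 1))
    if (mean(a[k:(k + n_sync)]) <= th2) return(k)
  NA_integer_
}

# Direct truncated-window mean, double loop.
oracle_moving_average <- function(x, n_window) {
  half <- n_window / 2
  out <- matrix(0, nrow(x), ncol(x))
  for (i in seq_len(nrow(x))) {
    lo <- max(1, i - half)
    hi <- min(nrow(x), i + half)
    for (j in seq_len(ncol(x))) out[i, j] <- mean(x[lo:hi, j])
  }
  out
}

# Mask excluding the moving-average transients of a generated participant:
# the lead-in/burst region and +/- half a filter window around every slot
# boundary.
interior_mask <- function(truth, sensor, n_total, half = 10) {
  k0 <- truth$shake_end[[sensor]]
  mask <- rep(TRUE, n_total)
  mask[seq_len(min(n_total, k0 + half))] <- FALSE
  bounds <- k0 - 1 + c(truth$schedule$start, truth$schedule$end + 1)
  for (b in bounds)
    mask[max(1, b - half):min(n_total, b + half)] <- FALSE
  mask[max(1, n_total - half):n_total] <- FALSE
  mask
}

# Small cohort spec for fast unit tests.
tiny_spec <- function(...) {
  args <- list(...)
  defaults <- list(n_per_group = 1, duration_s = 160, seed = 5)
  do.call(cohort_spec, utils::modifyList(defaults, args))
}

# Build a window_set whose targets are chosen 80-value vectors (inputs are
# arbitrary), by laying out windows in a channel matrix.
window_set_from_targets <- function(targets, input_value = 0) {
  n <- length(targets)
  channels <- matrix(input_value, n * 80, 4)
  set.seed(99)
  for (i in seq_len(n)) {
    rows <- (i - 1) * 80 + 1:60
    channels[rows, ] <- rnorm(240)
    channels[(i - 1) * 80 + 61:80, ] <- matrix(targets[[i]], 20, 4)
  }
  segment_windows(channels)
}
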