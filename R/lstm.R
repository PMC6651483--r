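#' @title Stacked LSTM forecaster
#' @description A two-layer LSTM over the 60-step, 4-channel input window
#'   followed by an affine map from the second layer's final hidden state to
#'   the 80 predicted values (20 steps x 4 channels). Gate dynamics:
#'   `f_t = sigmoid(Wf x_t + Uf h_{t-1} + bf)` (and likewise `i_t`, `o_t`),
#'   `c_t = f_t * c_{t-1} + i_t * tanh(Wc x_t + Uc h_{t-1} + bc)`,
#'   `h_t = o_t * tanh(c_t)`, with `*` elementwise and weights shared across
#'   time steps.
#' @name forecaster
NULL

#' Forecaster architecture configuration
#'
#' @param hidden_sizes Integer vector of LSTM layer widths, bottom to top
#'   (default `c(50, 20)`; a deeper variant such as `c(50, 50, 50)` is
#'   supported but not the default).
#' @param input_size Channels per time step (default 4).
#' @param input_steps Input sequence length (default 60 = 6 s at 10 Hz).
#' @param output_steps Predicted sequence length (default 20 = 2 s).
#' @return An object of class `forecaster_config`.
#' @export
forecaster_config <- function(hidden_sizes = c(50, 20), input_size = 4,
                              input_steps = 60, output_steps = 20) {
  if (length(hidden_sizes) < 1 || any(hidden_sizes < 1))
    stop_input("hidden_sizes must be positive")
  structure(list(hidden_sizes = as.integer(hidden_sizes),
                 input_size = as.integer(input_size),
                 input_steps = as.integer(input_steps),
                 output_steps = as.integer(output_steps)),
            class = "forecaster_config")
}

#' LSTM layer parameters
#'
#' Gate weight matrices (`Wf, Wi, Wo, Wc`: input to gate; `Uf, Ui, Uo, Uc`:
#' recurrent) and bias vectors (`bf, bi, bo, bc`), shared across time steps.
#'
#' @param input_size Input dimension of the layer.
#' @param hidden_size Number of memory units.
#' @param init Either `"zero"` or `"uniform"` (scaled uniform init).
#' @return An object of class `lstm_layer_params`.
#' @export
lstm_layer_params <- function(input_size, hidden_size, init = "uniform") {
  d <- as.integer(input_size)
  h <- as.integer(hidden_size)
  draw <- function(nr, nc) {
    if (init == "zero") matrix(0, nr, nc)
    else matrix(stats::runif(nr * nc, -1, 1) * sqrt(6 / (nr + nc)), nr, nc)
  }
  p <- list(Wf = draw(d, h), Wi = draw(d, h), Wo = draw(d, h),
            Wc = draw(d, h),
            Uf = draw(h, h), Ui = draw(h, h), Uo = draw(h, h),
            Uc = draw(h, h),
            # forget bias starts at 1 so early training retains memory
            bf = rep(if (init == "zero") 0 else 1, h),
            bi = rep(0, h), bo = rep(0, h), bc = rep(0, h),
            input_size = d, hidden_size = h)
  structure(p, class = "lstm_layer_params")
}

#' Initialize forecaster parameters
#'
#' @param config A [forecaster_config()].
#' @param seed Integer seed for the random initialization.
#' @param init `"uniform"` (default) or `"zero"`.
#' @return An object of class `forecaster_params`: one `lstm_layer_params`
#'   per layer in `layers`, the output map `Wd` (last hidden size x
#'   `output_steps * input_size`) and bias `bd`, plus training metadata.
#' @export
init_forecaster <- function(config = forecaster_config(), seed = 1,
                            init = "uniform") {
  out_dim <- config$output_steps * config$input_size
  with_seed(seed, {
    sizes <- c(config$input_size, config$hidden_sizes)
    layers <- lapply(seq_along(config$hidden_sizes), function(l)
      lstm_layer_params(sizes[l], sizes[l + 1], init))
    h_top <- config$hidden_sizes[length(config$hidden_sizes)]
    wd <- if (init == "zero") matrix(0, h_top, out_dim)
          else matrix(stats::runif(h_top * out_dim, -1, 1) *
                        sqrt(6 / (h_top + out_dim)), h_top, out_dim)
    structure(list(layers = layers, Wd = wd, bd = rep(0, out_dim),
                   config = config,
                   meta = list(seed = seed, epochs_trained = 0L,
                               bin = "all")),
              class = "forecaster_params")
  })
}

#' @export
print.forecaster_params <- function(x, ...) {
  cat(sprintf(
    "<forecaster_params: LSTM(%s) -> dense %d; trained %d epochs (bin %s)>\n",
    paste(x$config$hidden_sizes, collapse = ", "),
    length(x$bd), x$meta$epochs_trained, x$meta$bin))
  invisible(x)
}

#' One LSTM cell update
#'
#' Applies the gate equations to a single input vector and cell state.
#'
#' @param x Input vector (length `input_size`).
#' @param state List with `h` and `c` vectors of length `hidden_size`.
#' @param params An [lstm_layer_params()].
#' @return Updated state: list with `h` and `c`.
#' @export
lstm_cell_step <- function(x, state, params) {
  if (length(x) != params$input_size)
    stop_input("input length %d does not match layer input size %d",
               length(x), params$input_size)
  if (length(state$h) != params$hidden_size ||
      length(state$c) != params$hidden_size)
    stop_input("state dimension does not match hidden size %d",
               params$hidden_size)
  f <- sigmoid(drop(x %*% params$Wf) + drop(state$h %*% params$Uf) + params$bf)
  i <- sigmoid(drop(x %*% params$Wi) + drop(state$h %*% params$Ui) + params$bi)
  o <- sigmoid(drop(x %*% params$Wo) + drop(state$h %*% params$Uo) + params$bo)
  g <- tanh(drop(x %*% params$Wc) + drop(state$h %*% params$Uc) + params$bc)
  c_new <- f * state$c + i * g
  list(h = o * tanh(c_new), c = c_new)
}

# Compact per-layer weights for the batched fast paths: single gate-stacked
# matrices with column blocks ordered f, i, o, c.
compact_layer <- function(p) {
  list(W = cbind(p$Wf, p$Wi, p$Wo, p$Wc),
       U = cbind(p$Uf, p$Ui, p$Uo, p$Uc),
       b = c(p$bf, p$bi, p$bo, p$bc),
       d = p$input_size, h = p$hidden_size)
}

uncompact_layer <- function(cp) {
  h <- cp$h
  blk <- function(m, k) m[, (k - 1) * h + seq_len(h), drop = FALSE]
  structure(list(Wf = blk(cp$W, 1), Wi = blk(cp$W, 2), Wo = blk(cp$W, 3),
                 Wc = blk(cp$W, 4),
                 Uf = blk(cp$U, 1), Ui = blk(cp$U, 2), Uo = blk(cp$U, 3),
                 Uc = blk(cp$U, 4),
                 bf = cp$b[(0 * h) + seq_len(h)],
                 bi = cp$b[(1 * h) + seq_len(h)],
                 bo = cp$b[(2 * h) + seq_len(h)],
                 bc = cp$b[(3 * h) + seq_len(h)],
                 input_size = cp$d, hidden_size = cp$h),
            class = "lstm_layer_params")
}

# Stack a B x T x d array (or an already-stacked matrix) into a
# (B*T) x d matrix whose rows are ordered batch-fastest within time blocks.
stack_steps <- function(x) {
  if (is.matrix(x)) return(x)
  dims <- dim(x)
  matrix(x, dims[1] * dims[2], dims[3])
}

# Batched forward pass through one LSTM layer (compiled kernel).
# xmat: stacked (B*T) x d input (see stack_steps). Returns the stacked
# hidden states plus, with cache = TRUE, the stacked gate activations
# needed for backpropagation through time.
layer_forward_batch <- function(cp, xmat, b, tt, cache = FALSE) {
  lstm_layer_forward_cpp(cp$W, cp$U, cp$b, xmat, as.integer(b),
                         as.integer(tt), cache)
}

# Batched forward through the whole forecaster.
# x: B x input_steps x input_size. Returns B x (output_steps*input_size).
forward_batch <- function(params, x, cache = FALSE) {
  layers <- lapply(params$layers, compact_layer)
  b <- dim(x)[1]
  tt <- dim(x)[2]
  acts <- vector("list", length(layers))
  inp <- stack_steps(x)
  for (l in seq_along(layers)) {
    acts[[l]] <- layer_forward_batch(layers[[l]], inp, b, tt, cache)
    inp <- acts[[l]]$h
  }
  h_top <- acts[[length(acts)]]$h_final
  yhat <- h_top %*% params$Wd
  yhat <- yhat + rep(params$bd, each = b)
  if (cache) list(yhat = yhat, acts = acts, layers = layers)
  else yhat
}

#' Forecast the next 2 seconds from a 6-second input
#'
#' Runs the stacked LSTM over all input steps from zero initial state, feeds
#' each layer's per-step outputs to the next, and applies the affine output
#' map to the top layer's final hidden state.
#'
#' @param params A [init_forecaster()] or [train_forecaster()] result.
#' @param x Numeric `input_steps` x `input_size` matrix (g units).
#' @return Numeric `output_steps` x `input_size` matrix of predicted
#'   vertical acceleration. The 80-value output vector is laid out
#'   channel-major (all 20 steps of lf, then lh, rf, rh), matching
#'   `as.vector()` on the returned matrix.
#' @export
forecast <- function(params, x) {
  stopifnot(inherits(params, "forecaster_params"))
  x <- as.matrix(x)
  if (!all(is.finite(x))) stop_input("non-finite values in forecaster input")
  cfg <- params$config
  if (nrow(x) != cfg$input_steps || ncol(x) != cfg$input_size)
    stop_input("input must be %d x %d", cfg$input_steps, cfg$input_size)
  xb <- array(0, c(1, cfg$input_steps, cfg$input_size))
  xb[1, , ] <- x
  yhat <- forward_batch(params, xb)
  matrix(yhat[1, ], cfg$output_steps, cfg$input_size)
}
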