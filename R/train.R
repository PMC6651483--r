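#' @title Forecaster training
#' @description Mean-square-error training of the stacked LSTM forecaster on
#'   control-group window pairs: backpropagation through time, adaptive
#'   moment estimation (Adam), seeded initialization, and early stopping on a
#'   held-out validation split.
#' @name training
NULL

#' Training configuration
#'
#' @param learning_rate Adam step size.
#' @param batch_size Minibatch size.
#' @param max_epochs Maximum training epochs; 0 returns the seeded
#'   initialization unchanged.
#' @param patience Early-stopping patience in epochs without validation
#'   improvement.
#' @param validation_fraction Fraction of windows held out for validation,
#'   in (0, 1).
#' @param seed Seed for initialization, the validation split and batch
#'   shuffling.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-3, batch_size = 64,
                         max_epochs = 20, patience = 5,
                         validation_fraction = 0.1, seed = 1) {
  if (learning_rate <= 0 || batch_size < 1 || max_epochs < 0 || patience < 1)
    stop_input("training hyperparameters must be positive")
  if (validation_fraction <= 0 || validation_fraction >= 1)
    stop_input("validation_fraction must lie in (0, 1)")
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 validation_fraction = validation_fraction,
                 seed = as.integer(seed)),
            class = "train_config")
}

# Backpropagation through time for one LSTM layer (compiled kernel).
# xmat: stacked (B*T) x d input; dh_ext_final: gradient injected at the
# final hidden state; dh_ext_stack: stacked (B*T) x h per-step gradients
# from the layer above.
layer_backward_batch <- function(cp, xmat, fwd, b, tt, dh_ext_final = NULL,
                                 dh_ext_stack = NULL, want_dx = TRUE) {
  none <- matrix(0, 0, 0)
  out <- lstm_layer_backward_cpp(cp$W, cp$U, xmat,
                                 fwd$f, fwd$i, fwd$o, fwd$g, fwd$tc,
                                 fwd$hp, fwd$cp,
                                 dh_ext_final %||% none,
                                 dh_ext_stack %||% none,
                                 as.integer(b), as.integer(tt), want_dx)
  list(grads = out$grads, dx = out$dx %||% NULL)
}

# Full-model gradients of the mean squared error for one batch.
model_gradients <- function(layers, wd, bd, x, y) {
  n_layers <- length(layers)
  b <- dim(x)[1]
  tt <- dim(x)[2]
  acts <- vector("list", n_layers)
  xstacks <- vector("list", n_layers)
  inp <- stack_steps(x)
  for (l in seq_len(n_layers)) {
    xstacks[[l]] <- inp
    acts[[l]] <- layer_forward_batch(layers[[l]], inp, b, tt, cache = TRUE)
    inp <- acts[[l]]$h
  }
  h_top <- acts[[n_layers]]$h_final
  yhat <- h_top %*% wd
  yhat <- yhat + rep(bd, each = b)
  resid <- yhat - y
  loss <- mean(resid^2)
  dy <- 2 * resid / length(resid)
  g_wd <- crossprod(h_top, dy)
  g_bd <- colSums(dy)
  dh_top <- dy %*% t(wd)
  layer_grads <- vector("list", n_layers)
  dh_stack <- NULL
  dh_final <- dh_top
  for (l in n_layers:1) {
    bk <- layer_backward_batch(layers[[l]], xstacks[[l]], acts[[l]], b, tt,
                               dh_ext_final = dh_final,
                               dh_ext_stack = dh_stack, want_dx = l > 1)
    layer_grads[[l]] <- bk$grads
    dh_stack <- bk$dx
    dh_final <- NULL
  }
  list(loss = loss, layers = layer_grads, Wd = g_wd, bd = g_bd)
}

adam_init <- function(x) list(m = x * 0, v = x * 0)

adam_step <- function(theta, g, state, lr, t, b1 = 0.9, b2 = 0.999,
                      eps = 1e-8) {
  state$m <- b1 * state$m + (1 - b1) * g
  state$v <- b2 * state$v + (1 - b2) * g^2
  mhat <- state$m / (1 - b1^t)
  vhat <- state$v / (1 - b2^t)
  list(theta = theta - lr * mhat / (sqrt(vhat) + eps), state = state)
}

#' Train the forecaster on control-group windows
#'
#' Minimizes the empirical mean squared error of the 2-second forecast over
#' the supplied window pairs with minibatch Adam and backpropagation through
#' time. Initialization, the validation split and batch order are all seeded,
#' so identical data and configuration reproduce identical parameters.
#' Training stops early when the validation MSE has not improved for
#' `patience` epochs; the parameters with the best validation MSE are
#' returned (never worse on the training set than the initialization).
#'
#' @param windows A [segment_windows()] or combined window set.
#' @param model_config A [forecaster_config()].
#' @param config A [train_config()].
#' @param bin Optional intensity-bin index: train only on windows in that
#'   bin (one model per intensity interval).
#' @return A `forecaster_params` object; `$meta$log` holds the per-epoch
#'   train/validation MSE trace.
#' @export
train_forecaster <- function(windows, model_config = forecaster_config(),
                             config = train_config(), bin = NULL) {
  stopifnot(inherits(windows, "window_set"))
  idx <- seq_len(windows$n_windows)
  if (!is.null(bin)) idx <- idx[windows$bin == bin]
  if (length(idx) < 1)
    stop_input("no training windows%s",
               if (is.null(bin)) "" else sprintf(" in bin %d", bin))
  n <- length(idx)
  x <- windows$x[idx, , , drop = FALSE]
  y <- matrix(windows$y[idx, , , drop = FALSE], n,
              dim(windows$y)[2] * dim(windows$y)[3])
  params0 <- init_forecaster(model_config, seed = config$seed)
  params0$meta$bin <- if (is.null(bin)) "all" else bin
  if (config$max_epochs == 0L) return(params0)

  with_seed(derive_seed(config$seed, 7), {
    perm <- sample.int(n)
    n_val <- min(n - 1L, max(1L, floor(config$validation_fraction * n)))
    if (n_val < 1L || n - n_val < 1L) {
      val_idx <- perm
      tr_idx <- perm
    } else {
      val_idx <- perm[seq_len(n_val)]
      tr_idx <- perm[-seq_len(n_val)]
    }
    x_val <- x[val_idx, , , drop = FALSE]
    y_val <- y[val_idx, , drop = FALSE]

    layers <- lapply(params0$layers, compact_layer)
    wd <- params0$Wd
    bd <- params0$bd
    opt <- list(layers = lapply(layers, function(l)
      list(W = adam_init(l$W), U = adam_init(l$U), b = adam_init(l$b))),
      Wd = adam_init(wd), bd = adam_init(bd))

    val_mse <- function() {
      p <- params0
      p$layers <- lapply(layers, uncompact_layer)
      p$Wd <- wd
      p$bd <- bd
      mean((forward_batch(p, x_val) - y_val)^2)
    }
    v0 <- val_mse()
    log <- data.frame(epoch = 0L, train_mse = NA_real_, val_mse = v0)
    best <- list(layers = layers, Wd = wd, bd = bd, val = v0, epoch = 0L)
    wait <- 0L
    step <- 0L
    for (epoch in seq_len(config$max_epochs)) {
      order_e <- sample(tr_idx)
      batch_starts <- seq(1, length(order_e), by = config$batch_size)
      ep_loss <- 0
      for (bs in batch_starts) {
        bidx <- order_e[bs:min(bs + config$batch_size - 1, length(order_e))]
        gr <- model_gradients(layers, wd, bd,
                              x[bidx, , , drop = FALSE],
                              y[bidx, , drop = FALSE])
        ep_loss <- ep_loss + gr$loss * length(bidx)
        step <- step + 1L
        lr <- config$learning_rate
        for (l in seq_along(layers)) {
          for (nm in c("W", "U", "b")) {
            up <- adam_step(layers[[l]][[nm]], gr$layers[[l]][[nm]],
                            opt$layers[[l]][[nm]], lr, step)
            layers[[l]][[nm]] <- up$theta
            opt$layers[[l]][[nm]] <- up$state
          }
        }
        up <- adam_step(wd, gr$Wd, opt$Wd, lr, step)
        wd <- up$theta; opt$Wd <- up$state
        up <- adam_step(bd, gr$bd, opt$bd, lr, step)
        bd <- up$theta; opt$bd <- up$state
      }
      v <- val_mse()
      log <- rbind(log, data.frame(epoch = epoch,
                                   train_mse = ep_loss / length(order_e),
                                   val_mse = v))
      if (v < best$val - 1e-12) {
        best <- list(layers = layers, Wd = wd, bd = bd, val = v,
                     epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) break
      }
    }
    out <- params0
    out$layers <- lapply(best$layers, uncompact_layer)
    out$Wd <- best$Wd
    out$bd <- best$bd
    out$meta$epochs_trained <- best$epoch
    out$meta$log <- log
    out$meta$train_config <- unclass(config)
    # never return parameters worse than the initialization on the data
    mse_best <- mean((forward_batch(out, x) - y)^2)
    mse_init <- mean((forward_batch(params0, x) - y)^2)
    if (mse_init < mse_best) {
      params0$meta$log <- log
      return(params0)
    }
    out
  })
}

#' Serialize forecaster parameters to JSON
#'
#' Writes a self-describing JSON container (architecture, metadata and full
#' weight arrays at full precision).
#'
#' @param params A `forecaster_params` object.
#' @param path Output path.
#' @return `path` invisibly.
#' @export
save_forecaster <- function(params, path) {
  obj <- list(config = unclass(params$config),
              meta = params$meta[c("seed", "epochs_trained", "bin")],
              layers = lapply(params$layers, function(l)
                lapply(unclass(l)[c("Wf", "Wi", "Wo", "Wc", "Uf", "Ui",
                                    "Uo", "Uc", "bf", "bi", "bo", "bc")],
                       identity)),
              Wd = params$Wd, bd = params$bd)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load forecaster parameters saved by [save_forecaster()]
#'
#' @param path JSON path.
#' @return A `forecaster_params` object.
#' @export
load_forecaster <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  cfg <- forecaster_config(hidden_sizes = obj$config$hidden_sizes,
                           input_size = obj$config$input_size,
                           input_steps = obj$config$input_steps,
                           output_steps = obj$config$output_steps)
  layers <- lapply(seq_along(obj$layers), function(l) {
    raw <- obj$layers[[l]]
    p <- lapply(raw, function(m) if (is.matrix(m)) m else as.numeric(m))
    p$input_size <- nrow(raw$Wf)
    p$hidden_size <- ncol(raw$Wf)
    class(p) <- "lstm_layer_params"
    p
  })
  structure(list(layers = layers, Wd = obj$Wd, bd = as.numeric(obj$bd),
                 config = cfg,
                 meta = list(seed = obj$meta$seed,
                             epochs_trained = obj$meta$epochs_trained,
                             bin = obj$meta$bin)),
            class = "forecaster_params")
}
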