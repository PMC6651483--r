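test_that("cell step reproduces the gate equations in closed form", {
  # all-zero parameters: sigmoid(0) = 0.5, tanh(0) = 0
  p0 <- lstm_layer_params(2, 3, init = "zero")
  st <- lstm_cell_step(c(1, -1), list(h = rep(0, 3), c = rep(0, 3)), p0)
  expect_equal(st$c, rep(0, 3))
  expect_equal(st$h, rep(0, 3))

  # scalar cell, all weights 1, biases 0, x = 1, zero state
  p1 <- lstm_layer_params(1, 1, init = "zero")
  for (nm in c("Wf", "Wi", "Wo", "Wc", "Uf", "Ui", "Uo", "Uc"))
    p1[[nm]] <- matrix(1, 1, 1)
  st <- lstm_cell_step(1, list(h = 0, c = 0), p1)
  sg1 <- 1 / (1 + exp(-1))
  c_expect <- sg1 * tanh(1)
  expect_equal(st$c, c_expect, tolerance = 1e-14)
  expect_equal(st$h, sg1 * tanh(c_expect), tolerance = 1e-14)

  # saturated forget gate: the memory passes through
  p2 <- lstm_layer_params(1, 1, init = "zero")
  p2$bf <- 100
  st <- lstm_cell_step(0, list(h = 0, c = 2), p2)
  expect_equal(st$c, 2 + 0.5 * tanh(0), tolerance = 1e-12)

  expect_error(lstm_cell_step(c(1, 2, 3), list(h = 0, c = 0), p1),
               "input length")
})

test_that("forward pass equals the brute-force evaluation on random instances", {
  set.seed(10)
  for (case in 1:10) {
    cfg <- forecaster_config(hidden_sizes = sample(2:6, sample(2:3, 1),
                                                   replace = TRUE),
                             input_size = sample(2:4, 1),
                             input_steps = sample(3:8, 1),
                             output_steps = sample(2:4, 1))
    params <- init_forecaster(cfg, seed = 100 + case)
    x <- matrix(rnorm(cfg$input_steps * cfg$input_size), cfg$input_steps)
    expect_equal(forecast(params, x), oracle_forward(params, x),
                 tolerance = 1e-10)
  }
})

test_that("zero parameters forecast the output bias and runs are deterministic", {
  cfg <- forecaster_config(hidden_sizes = c(5, 3), input_steps = 6,
                           output_steps = 2)
  params <- init_forecaster(cfg, seed = 1, init = "zero")
  params$bd <- as.numeric(1:8)
  x <- matrix(rnorm(24), 6, 4)
  expect_equal(forecast(params, x), matrix(1:8, 2, 4))
  params2 <- init_forecaster(cfg, seed = 2)
  expect_identical(forecast(params2, x), forecast(params2, x))
  expect_error(forecast(params2, matrix(NA_real_, 6, 4)), "finite")
  expect_error(forecast(params2, matrix(0, 5, 4)), "must be")
})

test_that("gradients match finite differences on a tiny network", {
  set.seed(11)
  cfg <- forecaster_config(hidden_sizes = c(4, 3), input_size = 3,
                           input_steps = 5, output_steps = 2)
  params <- init_forecaster(cfg, seed = 11)
  xb <- array(rnorm(2 * 5 * 3), c(2, 5, 3))
  y <- matrix(rnorm(12), 2, 6)
  layers <- lapply(params$layers, actilstm:::compact_layer)
  gr <- actilstm:::model_gradients(layers, params$Wd, params$bd, xb, y)
  loss_at <- function(layers, wd, bd) {
    p <- params
    p$layers <- lapply(layers, actilstm:::uncompact_layer)
    p$Wd <- wd
    p$bd <- bd
    mean((actilstm:::forward_batch(p, xb) - y)^2)
  }
  eps <- 1e-6
  worst <- 0
  for (l in 1:2) {
    for (nm in c("W", "U", "b")) {
      theta <- layers[[l]][[nm]]
      for (k in sample(length(theta), min(6, length(theta)))) {
        lp <- layers; lp[[l]][[nm]][k] <- theta[k] + eps
        lm <- layers; lm[[l]][[nm]][k] <- theta[k] - eps
        num <- (loss_at(lp, params$Wd, params$bd) -
                  loss_at(lm, params$Wd, params$bd)) / (2 * eps)
        worst <- max(worst, abs(num - gr$layers[[l]][[nm]][k]))
      }
    }
  }
  for (k in sample(length(params$Wd), 6)) {
    wp <- params$Wd; wp[k] <- wp[k] + eps
    wm <- params$Wd; wm[k] <- wm[k] - eps
    num <- (loss_at(layers, wp, params$bd) -
              loss_at(layers, wm, params$bd)) / (2 * eps)
    worst <- max(worst, abs(num - gr$Wd[k]))
  }
  expect_lt(worst, 1e-7)
})

test_that("training is seeded, lazy at zero epochs, and never regresses", {
  set.seed(13)
  d <- motif_dictionary(2, seed = 77)
  tile <- function(noise_seed) {
    set.seed(noise_seed)
    do.call(rbind, lapply(1:30, function(i)
      d$motifs[[1]] * 0.6 + matrix(rnorm(320, sd = 0.01), 80, 4)))
  }
  windows <- segment_windows(tile(1))
  cfg <- forecaster_config(hidden_sizes = c(16, 8))
  tc <- train_config(max_epochs = 0, seed = 5)
  p0 <- train_forecaster(windows, cfg, tc)
  expect_identical(p0$layers, init_forecaster(cfg, seed = 5)$layers)
  expect_equal(p0$meta$epochs_trained, 0L)

  tc <- train_config(max_epochs = 3, batch_size = 16, seed = 5)
  pa <- train_forecaster(windows, cfg, tc)
  pb <- train_forecaster(windows, cfg, tc)
  expect_identical(pa$layers, pb$layers)
  expect_identical(pa$Wd, pb$Wd)
  # validation MSE no worse than at initialization
  log <- pa$meta$log
  expect_lte(min(log$val_mse), log$val_mse[1])
  expect_error(train_forecaster(windows, cfg, tc, bin = 6), "bin 6")
})

test_that("parameters survive a serialization round trip", {
  params <- init_forecaster(forecaster_config(hidden_sizes = c(6, 4)),
                            seed = 17)
  path <- withr::local_tempfile(fileext = ".json")
  save_forecaster(params, path)
  loaded <- load_forecaster(path)
  x <- matrix(rnorm(240), 60, 4)
  expect_equal(forecast(loaded, x), forecast(params, x), tolerance = 1e-12)
  expect_equal(loaded$layers[[1]]$Wf, params$layers[[1]]$Wf,
               ignore_attr = TRUE)
})

test_that("a learned motif is forecast well; an unseen motif is not", {
  d <- motif_dictionary(1, seed = 88)
  d_other <- motif_dictionary(1, seed = 89)
  tile <- function(dict, noise_seed) {
    set.seed(noise_seed)
    do.call(rbind, lapply(1:40, function(i)
      dict$motifs[[1]] * 0.6 + matrix(rnorm(320, sd = 0.01), 80, 4)))
  }
  train_w <- segment_windows(tile(d, 1))
  cfg <- forecaster_config(hidden_sizes = c(24, 12))
  model <- train_forecaster(train_w, cfg,
                            train_config(max_epochs = 60, batch_size = 32,
                                         patience = 10, seed = 3))
  heldout <- score_windows(segment_windows(tile(d, 2)), model)
  unseen <- score_windows(segment_windows(tile(d_other, 3)), model)
  expect_gt(mean(heldout$r), 0.95)
  expect_gt(mean(heldout$r), mean(unseen$r))
})
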