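test_that("gravity filter reproduces direct window averaging", {
  # constant trace: the mean of a constant is the constant
  tr <- triaxial_trace("lf", 10, matrix(rep(c(0, 0, 1), each = 60), 60, 3))
  g <- estimate_gravity(tr, 20)
  expect_equal(g$g, matrix(rep(c(0, 0, 1), each = 60), 60, 3))

  # alternating +/- eps on x: interior estimate within eps/21 of gravity
  eps <- 0.3
  n <- 100
  x <- cbind(eps * rep_len(c(1, -1), n), 0, 1)
  tr <- triaxial_trace("lf", 10, x)
  g <- estimate_gravity(tr, 20)
  expect_equal(g$g, oracle_moving_average(x, 20), tolerance = 1e-14)
  interior <- 11:(n - 11)
  expect_lte(max(abs(g$g[interior, 1])), eps / 21 + 1e-14)

  # boundary truncation: first estimate averages samples 1..11 only
  set.seed(1)
  x <- matrix(rnorm(300), 100, 3)
  tr <- triaxial_trace("lf", 10, x)
  g <- estimate_gravity(tr, 20)
  expect_equal(g$g[1, ], colMeans(x[1:11, ]))
  expect_equal(g$g[100, ], colMeans(x[90:100, ]))
  expect_equal(g$g, oracle_moving_average(x, 20), tolerance = 1e-13)

  expect_error(estimate_gravity(triaxial_trace("lf", 10, x[1:10, ]), 20),
               "shorter")
  expect_error(estimate_gravity(tr, 21), "even")
})

test_that("vertical projection handles orthogonal, parallel and degenerate cases", {
  n <- 50
  gmat <- matrix(rep(c(0, 0, 1), each = n), n, 3)
  gravity <- structure(list(g = gmat, window_n = 20L),
                       class = "gravity_estimate")
  # movement orthogonal to gravity: av identically zero
  orth <- cbind(sin(1:n), cos(1:n), 0)
  tr <- triaxial_trace("lf", 10, gmat + orth)
  expect_equal(vertical_projection(tr, gravity)$av, rep(0, n))
  # movement parallel to gravity
  tr <- triaxial_trace("lf", 10, matrix(rep(c(0, 0, 1.5), each = n), n, 3))
  expect_equal(vertical_projection(tr, gravity)$av, rep(0.5, n))
  # degenerate gravity names the offending sample
  bad <- gravity
  bad$g[17, ] <- c(0, 0, 1e-9)
  expect_error(vertical_projection(tr, bad), "17")
})

test_that("projection recovers ground-truth av under fixed rotations", {
  spec <- tiny_spec(noise_sd = 0, orientation_drift_rate = 0, seed = 61)
  d <- motif_dictionary(4, seed = 11)
  for (pseed in c(5, 6)) {
    p <- generate_participant(spec, d, NULL, "control", pseed)
    for (s in names(p$traces)) {
      g <- estimate_gravity(p$traces[[s]], 20)
      av <- vertical_projection(p$traces[[s]], g)$av
      truth <- p$truth$av_true[[s]]
      mask <- interior_mask(p$truth, s, length(truth))
      expect_lt(max(abs(av - truth)[mask]), 1e-6)
    }
  }
})

test_that("av is invariant to a fixed rotation of the sensor frame", {
  set.seed(3)
  for (rep_i in 1:5) {
    n <- 120
    # smooth random trace around gravity
    x <- cbind(0.3 * sin(2 * pi * (1:n) / 30),
               0.2 * cos(2 * pi * (1:n) / 17),
               1 + 0.4 * sin(2 * pi * (1:n) / 23)) +
      matrix(rnorm(3 * n, sd = 0.01), n, 3)
    rot <- with_seed(rep_i, actilstm:::random_rotation())
    tr1 <- triaxial_trace("lf", 10, x)
    tr2 <- triaxial_trace("lf", 10, x %*% t(rot))
    av1 <- vertical_projection(tr1, estimate_gravity(tr1, 20))$av
    av2 <- vertical_projection(tr2, estimate_gravity(tr2, 20))$av
    expect_lt(max(abs(av1 - av2)), 1e-9)
  }
})

test_that("movement decomposition is exactly orthogonal", {
  set.seed(4)
  n <- 150
  x <- cbind(0.5 * sin(1:n / 5), 0.3 * cos(1:n / 7), 1 + 0.2 * sin(1:n / 9))
  tr <- triaxial_trace("lf", 10, x)
  g <- estimate_gravity(tr, 20)
  dec <- movement_decomposition(tr, g)
  expect_equal(dec$amv + dec$amh, dec$am, tolerance = 1e-12)
  expect_lt(max(abs(rowSums(dec$amv * dec$amh))), 1e-9)
})

test_that("shake-end detection matches the linear-scan oracle", {
  params <- sync_params(th1 = 2, th2 = 0.1, n_sync = 10)
  mk <- function(av) vertical_signal(av, "lf", 10)
  # lead-in, burst, quiet: burst ends where the forward mean settles
  av <- c(rep(0.1, 50), rep(3.0, 30), rep(0.05, 40))
  k <- detect_shake_end(mk(av), params)
  expect_identical(k, oracle_shake_end(av, 2, 0.1, 10))
  expect_identical(k, 81L) # first post-burst sample (index 80, 0-based)
  # burst from the very first sample
  av <- c(rep(3.0, 30), rep(0.05, 40))
  k <- detect_shake_end(mk(av), params)
  expect_identical(k, oracle_shake_end(av, 2, 0.1, 10))
  expect_identical(k, 31L)
  # alternating-sign burst is still a burst (absolute values)
  av <- c(rep(0.1, 20), 3 * rep_len(c(1, -1), 30), rep(0.05, 40))
  expect_identical(detect_shake_end(mk(av), params),
                   oracle_shake_end(av, 2, 0.1, 10))
  # failure modes
  expect_error(detect_shake_end(mk(rep(0.1, 100)), params), "no shake")
  expect_error(detect_shake_end(mk(c(rep(0.1, 10), rep(3, 90))), params),
               "never ends")
})

test_that("synchronization realigns planted lead-ins exactly", {
  set.seed(7)
  content <- 0.4 * sin(2 * pi * (1:300) / 25) +
    0.1 * sin(2 * pi * (1:300) / 7)
  base <- c(rep(0.02, 10), rep(3, 30) * rep_len(c(1, -1), 30), content)
  offsets <- c(lf = 0, lh = 5, rf = 10, rh = 15)
  signals <- lapply(names(offsets), function(s)
    vertical_signal(c(rep(0.02, offsets[[s]]), base), s, 10))
  rec <- synchronize(signals, sync_params(), participant_id = "sync")
  expect_equal(unname(rec$origins - rec$origins[1]), unname(offsets))
  for (ch in 2:4)
    expect_equal(rec$channels[, ch], rec$channels[, 1])

  # four identical signals: output is the post-burst tail of any one
  same <- lapply(c("lf", "lh", "rf", "rh"), function(s)
    vertical_signal(base, s, 10))
  rec2 <- synchronize(same, sync_params())
  k <- detect_shake_end(same[[1]], sync_params())
  expect_equal(rec2$channels[, "rh"], base[k:length(base)])

  # a channel without a burst propagates an error naming the sensor
  broken <- signals
  broken[[3]] <- vertical_signal(rep(0.02, length(base) + 10), "rf", 10)
  expect_error(synchronize(broken, sync_params()), "rf")
  # duplicated sensors rejected
  expect_error(synchronize(signals[c(1, 1, 2, 3)], sync_params()),
               "exactly once")
})

test_that("random planted offsets re-align to within one sample", {
  set.seed(12)
  worst <- 0
  for (case in 1:20) {
    content <- 0.5 * sin(2 * pi * (1:200) / (10 + case)) +
      rnorm(200, sd = 0.02)
    base <- c(rep(3, 30) * rep_len(c(1, -1), 30), rep(0.02, 15), content)
    offsets <- sample(0:40, 4)
    signals <- lapply(1:4, function(i)
      vertical_signal(c(rnorm(offsets[i], sd = 0.02), base),
                      c("lf", "lh", "rf", "rh")[i], 10))
    rec <- synchronize(signals, sync_params())
    mis <- (rec$origins - offsets) - (rec$origins - offsets)[1]
    worst <- max(worst, max(abs(mis)))
  }
  expect_lte(worst, 1)
})
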