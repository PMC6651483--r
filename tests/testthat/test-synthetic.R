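test_that("motif dictionaries are deterministic given the seed", {
  d1 <- motif_dictionary(1, 2.0, seed = 7)
  d2 <- motif_dictionary(1, 2.0, seed = 7)
  expect_identical(d1, d2)
  d3 <- motif_dictionary(1, 2.0, seed = 8)
  expect_false(identical(d1$motifs, d3$motifs))
})

test_that("motifs are band-limited below 2 Hz (periodogram oracle)", {
  d <- motif_dictionary(5, 2.0, seed = 1)
  for (m in d$motifs) {
    for (ch in 1:4) {
      x <- m[, ch]
      n <- length(x)
      p <- abs(fft(x))^2
      freq <- (0:(n - 1)) * d$rate_hz / n
      f <- pmin(freq, d$rate_hz - freq)
      expect_gt(sum(p[f <= 2.0]) / sum(p), 0.95)
    }
  }
  # unit pooled SD and bounded peak: amplitude scaling maps linearly to SD
  for (m in d$motifs) {
    expect_equal(sd(as.vector(m)), 1, tolerance = 1e-12)
    expect_lte(max(abs(m)), 1.8)
  }
})

test_that("invalid motif counts are rejected", {
  expect_error(motif_dictionary(0, 2.0, seed = 1), "n_motifs")
})

test_that("zero divergence collapses the group distinction", {
  spec <- tiny_spec(divergence_fraction = 0)
  d <- motif_dictionary(4, seed = 11)
  dd <- motif_dictionary(4, seed = 12)
  p_ctrl <- generate_participant(spec, d, dd, "control", 321)
  p_atyp <- generate_participant(spec, d, dd, "atypical", 321)
  for (s in names(p_ctrl$traces))
    expect_identical(p_ctrl$traces[[s]]$samples, p_atyp$traces[[s]]$samples)
})

test_that("the shake burst dominates every raw sample", {
  spec <- tiny_spec(divergence_fraction = 0.5, seed = 9)
  d <- motif_dictionary(4, seed = 11)
  dd <- motif_dictionary(4, seed = 12)
  p <- generate_participant(spec, d, dd, "atypical", 55)
  for (s in names(p$traces)) {
    norms <- sqrt(rowSums(p$traces[[s]]$samples^2))
    k_max <- which.max(norms)
    burst <- (p$truth$shake_end[[s]] - round(3 * spec$rate_hz)):
      (p$truth$shake_end[[s]] - 1)
    expect_true(k_max %in% burst)
  }
})

test_that("fragment SD grows monotonically with the amplitude scale", {
  d <- motif_dictionary(3, seed = 21)
  for (m in d$motifs) {
    sds <- vapply(c(0.2, 0.5, 1.0), function(s) combined_sd(m * s),
                  numeric(1))
    expect_true(all(diff(sds) > 0))
    # exact homogeneity: doubling the amplitude doubles the SD
    expect_equal(combined_sd(m * 2), 2 * combined_sd(m), tolerance = 1e-12)
  }
})

test_that("cohorts have the advertised size, files and determinism", {
  dir <- withr::local_tempdir()
  spec <- tiny_spec(n_per_group = 2, duration_s = 96, seed = 31)
  cohort <- generate_cohort(spec, dir = dir)
  expect_equal(nrow(cohort$manifest), 6)
  expect_equal(sort(unique(cohort$manifest$group)),
               sort(c("control_train", "control_test", "atypical")))
  expect_length(list.files(dir, pattern = "_(lf|lh|rf|rh)\\.csv$"), 24)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_length(list.files(dir, pattern = "_truth\\.json$"), 6)
  cohort2 <- generate_cohort(spec)
  expect_identical(cohort$manifest, cohort2$manifest)
  expect_identical(cohort$participants[[1]]$traces$lf$samples,
                   cohort2$participants[[1]]$traces$lf$samples)
  # round trip through the CSV dialect
  loaded <- read_cohort(dir)
  expect_equal(loaded$participants[[1]]$traces$lf$samples,
               unname(cohort$participants[[1]]$traces$lf$samples),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("trace lengths follow the duration arithmetic", {
  spec <- tiny_spec(duration_s = 640, seed = 41)
  d <- motif_dictionary(4, seed = 11)
  p <- generate_participant(spec, d, NULL, "control", 77)
  shake_n <- round(spec$shake$duration_s * spec$rate_hz)
  for (i in seq_along(p$traces)) {
    expect_equal(nrow(p$traces[[i]]$samples),
                 6400 + shake_n + spec$shake$offsets[i])
  }
})

test_that("planted divergence separates raw in-band fragments", {
  # feature: best absolute correlation against the control dictionary --
  # control fragments match some template, divergent ones do not
  n_reject <- 0
  n_seeds <- 20
  for (s in seq_len(n_seeds)) {
    spec <- tiny_spec(duration_s = 240, divergence_fraction = 0.9,
                      scale_range = c(0.4, 1.0), rest_fraction = 0.1,
                      seed = s)
    d <- motif_dictionary(4, seed = 101 + s)
    dd <- motif_dictionary(4, seed = 201 + s)
    feature <- function(group, pseed) {
      p <- generate_participant(spec, d, dd, group, pseed)
      sch <- p$truth$schedule
      sch <- sch[sch$kind == "motif", ]
      av <- sapply(names(p$traces), function(sn) {
        k0 <- p$truth$shake_end[[sn]]
        p$truth$av_true[[sn]][k0:length(p$truth$av_true[[sn]])]
      })
      vapply(seq_len(nrow(sch)), function(i) {
        frag <- as.vector(av[sch$start[i]:sch$end[i], ])
        max(vapply(d$motifs, function(m) {
          tmpl <- as.vector(rbind(m, matrix(0, 80 - nrow(m), 4)))
          abs(cor(frag, tmpl))
        }, numeric(1)))
      }, numeric(1))
    }
    f_ctrl <- feature("control", 1000 + s)
    f_atyp <- feature("atypical", 2000 + s)
    p_val <- wilcox.test(f_atyp, f_ctrl, alternative = "less",
                         exact = FALSE)$p.value
    if (p_val < 0.05) n_reject <- n_reject + 1
  }
  expect_gte(n_reject, 0.8 * n_seeds)
})
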