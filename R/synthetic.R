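#' @title Synthetic multi-sensor accelerometer cohorts
#' @description Seeded generators for 4-sensor tri-axial recordings with known
#'   ground truth: a synchronization shake burst, gravity under per-sensor
#'   orientation (optionally drifting), band-limited movement motifs at mixed
#'   intensities, and a controllable fraction of group-specific divergent
#'   motifs confined to a chosen intensity band.
#' @name synthetic
NULL

SENSOR_IDS <- c("lf", "lh", "rf", "rh")

#' Construct a tri-axial trace
#'
#' @param sensor_id One of `"lf"`, `"lh"`, `"rf"`, `"rh"` (left/right,
#'   foot/hand).
#' @param rate_hz Sampling rate in Hz.
#' @param samples Numeric n x 3 matrix of raw sensor-frame acceleration in g.
#' @return An object of class `triaxial_trace`.
#' @export
triaxial_trace <- function(sensor_id, rate_hz, samples) {
  if (!sensor_id %in% SENSOR_IDS)
    stop_input("unknown sensor_id '%s'", sensor_id)
  samples <- as.matrix(samples)
  if (ncol(samples) != 3L)
    stop_input("trace samples must have 3 columns (x, y, z)")
  if (!is.numeric(rate_hz) || rate_hz <= 0)
    stop_input("rate_hz must be positive")
  structure(list(sensor_id = sensor_id, rate_hz = rate_hz,
                 samples = samples),
            class = "triaxial_trace")
}

#' @export
print.triaxial_trace <- function(x, ...) {
  cat(sprintf("<triaxial_trace %s: %d samples @ %g Hz>\n",
              x$sensor_id, nrow(x$samples), x$rate_hz))
  invisible(x)
}

# Sine-series basis on `period` samples, harmonics 1..k_max.  Every harmonic
# sums to exactly zero over any `period` consecutive samples, so a centered
# moving average of width `period` passes gravity untouched through signals
# built on this basis (the property the projection round-trip relies on).
sine_basis <- function(n, period, k_max) {
  i <- 0:(n - 1)
  sapply(seq_len(k_max), function(k) sin(2 * pi * k * i / period))
}

#' Generate a dictionary of band-limited movement motifs
#'
#' Motifs are 4-channel vertical-acceleration templates built from random
#' sine series with harmonics confined below `band_limit_hz` (voluntary limb
#' movement concentrates its power below about 2 Hz). The series period
#' equals `period_samples`, matching the default gravity-filter window so the
#' moving-average gravity estimate is exact inside motif interiors. Each
#' template is normalized to unit pooled standard deviation, so an amplitude
#' scale maps linearly onto fragment intensity.
#'
#' @param n_motifs Number of templates (>= 1).
#' @param band_limit_hz Spectral band limit in Hz (default 2).
#' @param seed Integer seed; the dictionary is a pure function of its
#'   arguments.
#' @param rate_hz Sampling rate in Hz (default 10).
#' @param duration_s Template duration in seconds (default 8, one analysis
#'   window).
#' @param n_channels Channels per template (default 4, one per sensor).
#' @param period_samples Fundamental period of the sine series in samples
#'   (default 21 = the default gravity window N + 1).
#' @param peak_cap Maximum absolute value allowed in a unit-SD template;
#'   draws exceeding it are rejected and redrawn so the synchronization burst
#'   always dominates motif amplitudes.
#' @return An object of class `motif_dictionary` with fields `motifs` (list
#'   of duration x channel matrices), `amplitude_scale`, `band_limit_hz`,
#'   `rate_hz`, `period_samples`.
#' @export
motif_dictionary <- function(n_motifs, band_limit_hz = 2, seed,
                             rate_hz = 10, duration_s = 8, n_channels = 4,
                             period_samples = 21, peak_cap = 1.8) {
  if (!is.numeric(n_motifs) || n_motifs < 1)
    stop_input("n_motifs must be >= 1")
  n_motifs <- as.integer(n_motifs)
  n <- as.integer(round(duration_s * rate_hz))
  k_max <- floor(band_limit_hz * period_samples / rate_hz)
  if (k_max < 1)
    stop_input("band_limit_hz too small for the chosen period")
  basis <- sine_basis(n, period_samples, k_max)
  motifs <- with_seed(seed, {
    lapply(seq_len(n_motifs), function(m) {
      repeat {
        # 1/k spectral decay keeps templates smooth at the 10 Hz rate
        coefs <- matrix(stats::rnorm(k_max * n_channels), k_max, n_channels) /
          seq_len(k_max)
        s <- basis %*% coefs
        pooled_sd <- stats::sd(as.vector(s))
        if (pooled_sd < 1e-8) next
        s <- s / pooled_sd
        if (max(abs(s)) <= peak_cap) return(unname(s))
      }
    })
  })
  structure(list(motifs = motifs,
                 amplitude_scale = rep(1, n_motifs),
                 band_limit_hz = band_limit_hz,
                 rate_hz = rate_hz,
                 period_samples = period_samples),
            class = "motif_dictionary")
}

#' @export
print.motif_dictionary <- function(x, ...) {
  cat(sprintf("<motif_dictionary: %d motifs, %d x %d, band limit %g Hz>\n",
              length(x$motifs), nrow(x$motifs[[1]]), ncol(x$motifs[[1]]),
              x$band_limit_hz))
  invisible(x)
}

#' Specify a synthetic cohort
#'
#' Bundles and validates every parameter of the synthetic study: group sizes,
#' recording duration, the fraction and intensity band of planted divergent
#' movement in the atypical group, rest behaviour, sensor noise, orientation
#' drift and the synchronization shake burst.
#'
#' @param n_per_group Participants per group (control_train, control_test,
#'   atypical).
#' @param duration_s Post-shake recording duration in seconds.
#' @param rate_hz Sampling rate in Hz; `duration_s * rate_hz` must be whole.
#' @param divergence_fraction Fraction (delta, in `[0, 1]`) of atypical-group
#'   motifs inside `divergence_band` drawn from the divergent dictionary.
#' @param divergence_band Intensity interval in g (half-open) where divergence
#'   is planted.
#' @param rest_fraction Fraction of 8-s slots containing no movement.
#' @param noise_sd White sensor noise SD in g per axis.
#' @param orientation_drift_rate Angular random-walk rate in rad/s (0 = fixed
#'   orientation).
#' @param shake List with `amplitude` (g), `duration_s`, and per-sensor
#'   lead-in `offsets` (samples, one per sensor lf/lh/rf/rh).
#' @param scale_range Range the per-slot motif amplitude scale is drawn from
#'   (uniform), in g of fragment SD.
#' @param n_motifs Dictionary size for both the control and divergent
#'   dictionaries.
#' @param seed Cohort master seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 9, duration_s = 600, rate_hz = 10,
                        divergence_fraction = 0,
                        divergence_band = c(0.4, 1.0),
                        rest_fraction = 0.3, noise_sd = 0.02,
                        orientation_drift_rate = 0.01,
                        shake = list(amplitude = 3, duration_s = 3,
                                     offsets = c(0, 5, 10, 15)),
                        scale_range = c(0.05, 1.1),
                        n_motifs = 8, seed = 1) {
  if (rate_hz <= 0) stop_input("rate_hz must be positive")
  n_content <- duration_s * rate_hz
  if (abs(n_content - round(n_content)) > 1e-9)
    stop_input("duration_s * rate_hz must be an integer number of samples")
  if (divergence_fraction < 0 || divergence_fraction > 1)
    stop_input("divergence_fraction must lie in [0, 1]")
  if (rest_fraction < 0 || rest_fraction > 1)
    stop_input("rest_fraction must lie in [0, 1]")
  if (length(shake$offsets) != 4L)
    stop_input("shake$offsets needs one lead-in per sensor (4 values)")
  if (diff(range(divergence_band)) <= 0)
    stop_input("divergence_band must be a nonempty interval")
  # burst must dominate every motif so threshold detection is unambiguous;
  # unit-SD templates are capped at peak 1.8 by motif_dictionary()
  if (shake$amplitude <= max(scale_range) * 1.8)
    stop_input("shake amplitude must strictly exceed the maximum motif amplitude")
  structure(list(n_per_group = as.integer(n_per_group),
                 duration_s = duration_s, rate_hz = rate_hz,
                 divergence_fraction = divergence_fraction,
                 divergence_band = divergence_band,
                 rest_fraction = rest_fraction, noise_sd = noise_sd,
                 orientation_drift_rate = orientation_drift_rate,
                 shake = shake, scale_range = scale_range,
                 n_motifs = as.integer(n_motifs), seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate one participant's 4-sensor recording with ground truth
#'
#' Lays movement motifs out in 8-second slots after a lead-in and a
#' synchronization shake burst, embeds the resulting world-frame acceleration
#' (gravity + vertical motif + horizontal band-limited noise) into a
#' per-sensor, optionally drifting orientation, and adds white sensor noise.
#' Atypical participants have a fraction `divergence_fraction` of their
#' motifs inside `divergence_band` replaced from the divergent dictionary;
#' control participants never draw from it. The random stream is consumed
#' identically for both groups, so with `divergence_fraction = 0` the two
#' groups produce sample-for-sample identical traces under the same seed.
#'
#' @param spec A [cohort_spec()].
#' @param dictionary Control [motif_dictionary()].
#' @param divergent_dictionary Disjoint dictionary used for planted
#'   divergence (may be `NULL` for control participants).
#' @param group `"control"` or `"atypical"`.
#' @param participant_seed Integer seed for this participant.
#' @return A list with `traces` (named list of four [triaxial_trace()]s) and
#'   `truth` (per-sensor true vertical acceleration, per-sensor shake end
#'   index, and the motif schedule).
#' @export
generate_participant <- function(spec, dictionary, divergent_dictionary,
                                 group = c("control", "atypical"),
                                 participant_seed) {
  group <- match.arg(group)
  if (group == "atypical" && is.null(divergent_dictionary))
    stop_input("atypical participants need a divergent dictionary")
  if (!is.null(divergent_dictionary) &&
      identical(dictionary$motifs, divergent_dictionary$motifs))
    stop_input("control and divergent dictionaries must be disjoint")
  rate <- spec$rate_hz
  n_content <- as.integer(round(spec$duration_s * rate))
  slot_n <- as.integer(round(8 * rate))
  motif_n <- nrow(dictionary$motifs[[1]])
  if (motif_n > slot_n)
    stop_input("motif templates longer than an 8-second slot")
  n_slots <- n_content %/% slot_n
  if (n_slots < 1) stop_input("recording shorter than one 8-second slot")
  shake_n <- as.integer(round(spec$shake$duration_s * rate))
  n_div <- if (is.null(divergent_dictionary)) 1L
           else length(divergent_dictionary$motifs)

  with_seed(participant_seed, {
    # --- schedule: identical RNG consumption for both groups -------------
    u_rest <- stats::runif(n_slots)
    motif_id <- sample.int(length(dictionary$motifs), n_slots, replace = TRUE)
    div_id <- sample.int(n_div, n_slots, replace = TRUE)
    scale <- stats::runif(n_slots, spec$scale_range[1], spec$scale_range[2])
    u_div <- stats::runif(n_slots)
    is_rest <- u_rest < spec$rest_fraction
    is_rest[1] <- TRUE # settle slot right after the burst
    in_band <- scale >= spec$divergence_band[1] &
      scale < spec$divergence_band[2]
    divergent <- !is_rest & group == "atypical" & in_band &
      u_div < spec$divergence_fraction

    # --- vertical content (shared world-frame across sensors) -----------
    av <- matrix(0, n_content, 4)
    for (s in seq_len(n_slots)) {
      if (is_rest[s]) next
      tmpl <- if (divergent[s]) divergent_dictionary$motifs[[div_id[s]]]
              else dictionary$motifs[[motif_id[s]]]
      rows <- (s - 1L) * slot_n + seq_len(motif_n)
      av[rows, ] <- tmpl * scale[s]
    }

    # --- horizontal movement: per-sensor band-limited noise at 30% of the
    #     vertical amplitude, zero during rest -----------------------------
    k_max <- max(1L, floor(dictionary$band_limit_hz *
                             dictionary$period_samples / rate))
    basis <- sine_basis(slot_n, dictionary$period_samples, k_max)
    horiz <- array(0, dim = c(n_content, 2, 4))
    for (s in seq_len(n_slots)) {
      rows <- (s - 1L) * slot_n + seq_len(slot_n)
      for (sensor in 1:4) {
        for (axis in 1:2) {
          coefs <- stats::rnorm(k_max) / seq_len(k_max)
          h <- basis %*% coefs
          hsd <- stats::sd(h)
          amp <- if (is_rest[s] || hsd < 1e-12) 0
                 else 0.3 * scale[s] / sqrt(2) / hsd
          horiz[rows, axis, sensor] <- h * amp
        }
      }
    }

    av_shake <- spec$shake$amplitude * rep_len(c(1, -1), shake_n)
    traces <- vector("list", 4)
    names(traces) <- SENSOR_IDS
    av_true <- vector("list", 4)
    names(av_true) <- SENSOR_IDS
    shake_end <- integer(4)
    names(shake_end) <- SENSOR_IDS

    for (sensor in 1:4) {
      offset <- as.integer(spec$shake$offsets[sensor])
      v <- c(rep(0, offset), av_shake, av[, sensor])
      hx <- c(rep(0, offset + shake_n), horiz[, 1, sensor])
      hy <- c(rep(0, offset + shake_n), horiz[, 2, sensor])
      n_total <- length(v)
      w <- cbind(hx, hy, 1 + v) # world frame, gravity = +z, units of g
      r0 <- random_rotation()
      if (spec$orientation_drift_rate > 0) {
        step_sd <- spec$orientation_drift_rate / rate / sqrt(3)
        theta <- apply(matrix(stats::rnorm(n_total * 3, sd = step_sd),
                              n_total, 3), 2, cumsum)
      } else {
        theta <- matrix(0, n_total, 3)
      }
      at <- rodrigues_rotate(w %*% r0, -theta)
      if (spec$noise_sd > 0)
        at <- at + matrix(stats::rnorm(n_total * 3, sd = spec$noise_sd),
                          n_total, 3)
      traces[[sensor]] <- triaxial_trace(SENSOR_IDS[sensor], rate, at)
      av_true[[sensor]] <- v
      shake_end[sensor] <- offset + shake_n + 1L # first content sample
    }

    schedule <- data.frame(
      slot = seq_len(n_slots),
      start = (seq_len(n_slots) - 1L) * slot_n + 1L,
      end = seq_len(n_slots) * slot_n,
      kind = ifelse(is_rest, "rest", "motif"),
      motif_id = ifelse(is_rest, NA_integer_,
                        ifelse(divergent, div_id, motif_id)),
      dictionary = ifelse(is_rest, NA_character_,
                          ifelse(divergent, "divergent", "control")),
      scale = ifelse(is_rest, 0, scale),
      divergent = divergent
    )
    list(traces = traces,
         truth = list(av_true = av_true, shake_end = shake_end,
                      schedule = schedule, group = group,
                      participant_seed = participant_seed))
  })
}

#' Generate a full synthetic cohort
#'
#' Produces `n_per_group` participants for each of the three study groups
#' (`control_train`, `control_test`, `atypical`) from per-participant seeds
#' derived deterministically from `spec$seed`, together with the control and
#' divergent motif dictionaries. With `dir` given, writes one CSV per sensor
#' per participant (`t_ms, ax_g, ay_g, az_g`), a manifest CSV and a
#' ground-truth JSON sidecar per participant.
#'
#' @param spec A [cohort_spec()].
#' @param dir Optional output directory; created if missing.
#' @return An object of class `cohort`: the spec, both dictionaries, a
#'   manifest data frame (`participant_id`, `group`, `seed`) and the named
#'   list of participants (`traces` + `truth`).
#' @export
generate_cohort <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  dict <- motif_dictionary(spec$n_motifs, seed = derive_seed(spec$seed, 1))
  div_dict <- motif_dictionary(spec$n_motifs,
                               seed = derive_seed(spec$seed, 2))
  groups <- c("control_train", "control_test", "atypical")
  manifest <- do.call(rbind, lapply(seq_along(groups), function(gi) {
    data.frame(
      participant_id = sprintf("%s_%02d", groups[gi],
                               seq_len(spec$n_per_group)),
      group = groups[gi],
      seed = vapply(seq_len(spec$n_per_group), function(i)
        derive_seed(spec$seed, 10L + gi, i), integer(1))
    )
  }))
  participants <- lapply(seq_len(nrow(manifest)), function(i) {
    grp <- if (manifest$group[i] == "atypical") "atypical" else "control"
    generate_participant(spec, dict, div_dict, grp, manifest$seed[i])
  })
  names(participants) <- manifest$participant_id
  cohort <- structure(list(spec = spec, dictionary = dict,
                           divergent_dictionary = div_dict,
                           manifest = manifest,
                           participants = participants),
                      class = "cohort")
  if (!is.null(dir)) write_cohort(cohort, dir)
  cohort
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort: %d participants (%s), %g s @ %g Hz, delta = %g>\n",
              nrow(x$manifest),
              paste(unique(x$manifest$group), collapse = "/"),
              x$spec$duration_s, x$spec$rate_hz,
              x$spec$divergence_fraction))
  invisible(x)
}

#' Write a cohort to disk in the package CSV dialect
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory.
#' @return The manifest (with file paths) invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop_input("cannot create output directory '%s'", dir)
  manifest <- cohort$manifest
  rate <- cohort$spec$rate_hz
  for (sensor in SENSOR_IDS)
    manifest[[paste0("file_", sensor)]] <- NA_character_
  for (i in seq_len(nrow(manifest))) {
    id <- manifest$participant_id[i]
    p <- cohort$participants[[id]]
    for (sensor in SENSOR_IDS) {
      path <- file.path(dir, sprintf("%s_%s.csv", id, sensor))
      tr <- p$traces[[sensor]]
      n <- nrow(tr$samples)
      data.table::fwrite(data.table::data.table(
        t_ms = round((seq_len(n) - 1) * 1000 / rate),
        ax_g = tr$samples[, 1], ay_g = tr$samples[, 2],
        az_g = tr$samples[, 3]), path)
      manifest[[paste0("file_", sensor)]][i] <- path
    }
    truth_path <- file.path(dir, sprintf("%s_truth.json", id))
    jsonlite::write_json(
      list(shake_end = as.list(p$truth$shake_end),
           schedule = p$truth$schedule, group = p$truth$group),
      truth_path, auto_unbox = TRUE, digits = NA)
  }
  data.table::fwrite(manifest, file.path(dir, "manifest.csv"))
  cohort$manifest <- manifest
  invisible(manifest)
}

#' Read one sensor CSV written by [write_cohort()]
#'
#' @param path CSV path with columns `t_ms, ax_g, ay_g, az_g`.
#' @param sensor_id Sensor label.
#' @param rate_hz Sampling rate (defaults to the rate implied by `t_ms`).
#' @return A [triaxial_trace()].
#' @export
read_trace_csv <- function(path, sensor_id, rate_hz = NULL) {
  if (!file.exists(path)) stop_input("trace file '%s' not found", path)
  d <- data.table::fread(path)
  need <- c("t_ms", "ax_g", "ay_g", "az_g")
  if (!all(need %in% names(d)))
    stop_input("malformed trace CSV '%s': expected columns %s", path,
               paste(need, collapse = ", "))
  if (is.null(rate_hz)) {
    dt <- stats::median(diff(d$t_ms))
    if (!is.finite(dt) || dt <= 0)
      stop_input("cannot infer sampling rate from '%s'", path)
    rate_hz <- 1000 / dt
  }
  triaxial_trace(sensor_id, rate_hz,
                 cbind(d$ax_g, d$ay_g, d$az_g))
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Directory containing `manifest.csv` and the per-sensor CSVs.
#' @return A list with `manifest` and `participants` (traces only).
#' @export
read_cohort <- function(dir) {
  mpath <- file.path(dir, "manifest.csv")
  if (!file.exists(mpath)) stop_input("no manifest.csv under '%s'", dir)
  manifest <- as.data.frame(data.table::fread(mpath))
  participants <- lapply(seq_len(nrow(manifest)), function(i) {
    traces <- lapply(SENSOR_IDS, function(sensor)
      read_trace_csv(manifest[[paste0("file_", sensor)]][i], sensor))
    names(traces) <- SENSOR_IDS
    list(traces = traces)
  })
  names(participants) <- manifest$participant_id
  list(manifest = manifest, participants = participants)
}
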