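#' @title Orientation-invariant preprocessing
#' @description Gravity estimation with a centered moving-average low-pass
#'   filter, decomposition of raw acceleration into movement components,
#'   signed projection onto the gravity direction (geo-referenced vertical
#'   acceleration), and shake-burst synchronization of the four sensors.
#' @name preprocessing
NULL

#' Estimate the gravity vector with a moving-average low-pass filter
#'
#' The gravity estimate at sample i is the mean of the raw tri-axial samples
#' over a centered window of `window_n + 1` samples; windows are truncated
#' (not padded) at the recording boundaries. Movement acceleration averages
#' out over the window while the slowly varying gravity component passes.
#'
#' @param trace A [triaxial_trace()].
#' @param window_n Even window parameter N; the window spans samples
#'   `i - N/2 .. i + N/2`. Default 20 (2.1 s at 10 Hz).
#' @return An object of class `gravity_estimate` with fields `g` (n x 3
#'   matrix) and `window_n`.
#' @export
estimate_gravity <- function(trace, window_n = 20) {
  stopifnot(inherits(trace, "triaxial_trace"))
  if (window_n %% 2 != 0) stop_input("window_n must be even")
  n <- nrow(trace$samples)
  if (n <= window_n)
    stop_input("trace (%d samples) shorter than filter window (%d)",
               n, window_n + 1)
  half <- window_n / 2
  cum <- rbind(0, apply(trace$samples, 2, cumsum))
  lo <- pmax(1, seq_len(n) - half)
  hi <- pmin(n, seq_len(n) + half)
  g <- (cum[hi + 1, , drop = FALSE] - cum[lo, , drop = FALSE]) /
    (hi - lo + 1)
  structure(list(g = g, window_n = as.integer(window_n)),
            class = "gravity_estimate")
}

#' Decompose raw acceleration into movement components
#'
#' Subtracts the gravity estimate to obtain the movement acceleration
#' `am = at - g'`, then splits it into the component parallel to the gravity
#' direction (`amv`) and the orthogonal remainder (`amh`).
#'
#' @param trace A [triaxial_trace()].
#' @param gravity Matching [estimate_gravity()] result.
#' @return A list with n x 3 matrices `am`, `amv`, `amh`.
#' @export
movement_decomposition <- function(trace, gravity) {
  av <- vertical_projection(trace, gravity)
  ghat <- gravity$g / sqrt(rowSums(gravity$g^2))
  am <- trace$samples - gravity$g
  amv <- av$av * ghat
  list(am = am, amv = amv, amh = am - amv)
}

#' Geo-referenced vertical acceleration
#'
#' Projects the movement acceleration onto the unit gravity direction,
#' returning the signed vertical component in g units:
#' `av(i) = (at(i) - g'(i)) . g'(i) / ||g'(i)||`. The projection is invariant
#' to any fixed rotation of the sensor frame, which is what makes recordings
#' from arbitrarily oriented sensors comparable.
#'
#' @param trace A [triaxial_trace()].
#' @param gravity Matching [estimate_gravity()] result.
#' @return An object of class `vertical_signal` with fields `av` (numeric
#'   vector, g), `sensor_id`, `rate_hz`.
#' @export
vertical_projection <- function(trace, gravity) {
  stopifnot(inherits(trace, "triaxial_trace"),
            inherits(gravity, "gravity_estimate"))
  if (nrow(gravity$g) != nrow(trace$samples))
    stop_input("gravity estimate and trace lengths differ")
  norms <- sqrt(rowSums(gravity$g^2))
  if (any(norms < 1e-6)) {
    bad <- which(norms < 1e-6)[1]
    stop_input("degenerate gravity estimate (norm < 1e-6) at sample %d", bad)
  }
  am <- trace$samples - gravity$g
  av <- rowSums(am * gravity$g) / norms
  vertical_signal(av, trace$sensor_id, trace$rate_hz)
}

#' Construct a vertical signal
#'
#' @param av Numeric vector of vertical acceleration in g.
#' @param sensor_id Sensor label.
#' @param rate_hz Sampling rate in Hz.
#' @return An object of class `vertical_signal`.
#' @export
vertical_signal <- function(av, sensor_id, rate_hz) {
  if (!all(is.finite(av))) stop_input("vertical signal has non-finite values")
  structure(list(av = as.numeric(av), sensor_id = sensor_id,
                 rate_hz = rate_hz),
            class = "vertical_signal")
}

#' Synchronization parameters
#'
#' @param th1 Burst entry threshold in g: between the pre-burst maximum and
#'   the in-burst amplitude.
#' @param th2 Burst exit threshold in g: below the mean in-burst amplitude
#'   and above the post-burst level.
#' @param n_sync Forward-mean window parameter N; the exit test averages
#'   `n_sync + 1` samples.
#' @return An object of class `sync_params`.
#' @export
sync_params <- function(th1 = 2, th2 = 0.5, n_sync = 10) {
  if (!(th1 > th2 && th2 > 0)) stop_input("need th1 > th2 > 0")
  if (n_sync < 1) stop_input("n_sync must be >= 1")
  structure(list(th1 = th1, th2 = th2, n_sync = as.integer(n_sync)),
            class = "sync_params")
}

#' Detect the end of the synchronization shake burst
#'
#' Scans the vertical signal for the first sample whose absolute value
#' reaches `th1` (burst entry), then returns the smallest later index k at
#' which the forward mean of `|av|` over `n_sync + 1` samples drops to
#' `th2` or below: the first sample after the burst. Everything before k is
#' lead-in plus burst and is discarded by [synchronize()].
#'
#' @param signal A [vertical_signal()].
#' @param params A [sync_params()].
#' @return Integer index (1-based) of the first post-burst sample.
#' @export
detect_shake_end <- function(signal, params = sync_params()) {
  stopifnot(inherits(signal, "vertical_signal"),
            inherits(params, "sync_params"))
  a <- abs(signal$av)
  n <- length(a)
  entry <- which(a >= params$th1)
  if (length(entry) == 0)
    stop_input("no shake detected on sensor %s (|av| never reaches th1 = %g)",
               signal$sensor_id, params$th1)
  w <- params$n_sync + 1L
  if (entry[1] + 1L > n - w + 1L)
    stop_input("shake burst never ends on sensor %s", signal$sensor_id)
  cum <- c(0, cumsum(a))
  ks <- (entry[1] + 1L):(n - w + 1L)
  fmean <- (cum[ks + w] - cum[ks]) / w
  hit <- which(fmean <= params$th2)
  if (length(hit) == 0)
    stop_input("shake burst never ends on sensor %s", signal$sensor_id)
  ks[hit[1]]
}

#' Synchronize the four vertical signals on their shake bursts
#'
#' Trims every channel to start at its own detected burst end and truncates
#' all four to the common minimum length, yielding one aligned 4-channel
#' recording with a shared time origin.
#'
#' @param signals List of four [vertical_signal()]s covering lf, lh, rf, rh
#'   exactly once (any order).
#' @param params A [sync_params()].
#' @param participant_id Identifier carried into the result.
#' @return An object of class `synchronized_recording` with fields
#'   `participant_id`, `channels` (n x 4 matrix ordered lf, lh, rf, rh),
#'   `rate_hz`, `origins` (per-channel burst-end index in the original
#'   signal).
#' @export
synchronize <- function(signals, params = sync_params(),
                        participant_id = NA_character_) {
  ids <- vapply(signals, function(s) s$sensor_id, character(1))
  if (!setequal(ids, SENSOR_IDS) || anyDuplicated(ids))
    stop_input("need each of lf, lh, rf, rh exactly once; got: %s",
               paste(ids, collapse = ", "))
  signals <- signals[match(SENSOR_IDS, ids)]
  origins <- vapply(signals, detect_shake_end, integer(1), params = params)
  tails <- lapply(seq_along(signals), function(i)
    signals[[i]]$av[origins[i]:length(signals[[i]]$av)])
  len <- min(lengths(tails))
  channels <- vapply(tails, function(x) x[seq_len(len)], numeric(len))
  colnames(channels) <- SENSOR_IDS
  names(origins) <- SENSOR_IDS
  structure(list(participant_id = participant_id, channels = channels,
                 rate_hz = signals[[1]]$rate_hz, origins = origins),
            class = "synchronized_recording")
}

#' @export
print.synchronized_recording <- function(x, ...) {
  cat(sprintf("<synchronized_recording %s: %d samples x 4 @ %g Hz>\n",
              x$participant_id, nrow(x$channels), x$rate_hz))
  invisible(x)
}

#' Full preprocessing chain for one participant
#'
#' Gravity estimation, vertical projection and shake synchronization for the
#' four raw traces of one participant.
#'
#' @param traces Named list of four [triaxial_trace()]s.
#' @param window_n Gravity filter window parameter N.
#' @param params A [sync_params()].
#' @param participant_id Identifier carried into the result.
#' @return A [synchronize()] result.
#' @export
preprocess_participant <- function(traces, window_n = 20,
                                   params = sync_params(),
                                   participant_id = NA_character_) {
  signals <- lapply(traces, function(tr)
    vertical_projection(tr, estimate_gravity(tr, window_n)))
  synchronize(signals, params, participant_id)
}

#' Write a synchronized recording as CSV
#'
#' @param recording A [synchronize()] result.
#' @param path Output CSV path (`t_index, lf, lh, rf, rh`).
#' @return `path` invisibly.
#' @export
write_recording_csv <- function(recording, path) {
  d <- data.table::data.table(t_index = seq_len(nrow(recording$channels)) - 1L)
  for (sensor in SENSOR_IDS) d[[sensor]] <- recording$channels[, sensor]
  data.table::fwrite(d, path)
  invisible(path)
}
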