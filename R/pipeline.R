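#' @title Pipeline orchestration
#' @description Ties the stages into a reproducible run: synthetic cohort
#'   generation (or reading recordings from disk), preprocessing,
#'   segmentation, training on the designated control-train participants,
#'   scoring of every evaluation participant, and group statistics. All
#'   randomness derives from one seed; identical configurations reproduce
#'   identical reports.
#' @name pipeline
NULL

#' Pipeline run configuration
#'
#' Every tunable of every stage in one validated container. Unknown
#' arguments are rejected.
#'
#' @param n_per_group Participants per group in the synthetic cohort.
#' @param duration_s Post-shake recording duration per participant (s).
#' @param rate_hz Sampling rate (Hz).
#' @param divergence_fraction Planted divergent-motif fraction (delta).
#' @param divergence_band Intensity band (g) where divergence is planted.
#' @param rest_fraction Fraction of rest slots.
#' @param noise_sd Sensor noise SD (g).
#' @param orientation_drift_rate Orientation random-walk rate (rad/s).
#' @param n_motifs Motif dictionary size.
#' @param window_n Gravity filter window parameter N (samples).
#' @param th1,th2,n_sync Shake synchronization parameters.
#' @param bin_edges Intensity bin edges (g).
#' @param hidden_sizes LSTM layer widths.
#' @param learning_rate,batch_size,max_epochs,patience,validation_fraction
#'   Training hyperparameters.
#' @param th Similarity threshold.
#' @param th_grid Threshold grid for the sweep stage.
#' @param train_per_bin Train one model per intensity bin instead of a
#'   single model on all windows.
#' @param input_dir Optional directory of recordings (written by
#'   [write_cohort()]); when `NULL` the cohort is simulated.
#' @param out_dir Optional output directory for summary CSVs, the stats
#'   JSON and the run log.
#' @param seed Master seed.
#' @return An object of class `run_config`.
#' @export
run_config <- function(n_per_group = 9, duration_s = 600, rate_hz = 10,
                       divergence_fraction = 0,
                       divergence_band = c(0.4, 1.0),
                       rest_fraction = 0.3, noise_sd = 0.02,
                       orientation_drift_rate = 0.01, n_motifs = 8,
                       window_n = 20, th1 = 2, th2 = 0.5, n_sync = 10,
                       bin_edges = c(0, 0.2, 0.4, 0.6, 0.8, 1, Inf),
                       hidden_sizes = c(50, 20),
                       learning_rate = 1e-3, batch_size = 64,
                       max_epochs = 20, patience = 5,
                       validation_fraction = 0.1,
                       th = 0.5, th_grid = seq(0.3, 0.7, by = 0.1),
                       train_per_bin = FALSE,
                       input_dir = NULL, out_dir = NULL, seed = 1) {
  cfg <- as.list(environment())
  # construct the stage parameter objects now so validation fails early
  cfg$spec <- cohort_spec(n_per_group = n_per_group, duration_s = duration_s,
                          rate_hz = rate_hz,
                          divergence_fraction = divergence_fraction,
                          divergence_band = divergence_band,
                          rest_fraction = rest_fraction, noise_sd = noise_sd,
                          orientation_drift_rate = orientation_drift_rate,
                          n_motifs = n_motifs, seed = derive_seed(seed, 100))
  cfg$sync <- sync_params(th1, th2, n_sync)
  cfg$bins <- intensity_bins(bin_edges)
  cfg$model <- forecaster_config(hidden_sizes = hidden_sizes)
  cfg$train <- train_config(learning_rate = learning_rate,
                            batch_size = batch_size,
                            max_epochs = max_epochs, patience = patience,
                            validation_fraction = validation_fraction,
                            seed = derive_seed(seed, 200))
  structure(cfg, class = "run_config")
}

#' Read a flat key-value run configuration file
#'
#' Lines of the form `key = value` (comments with `#`); vector values are
#' comma-separated. Unknown keys are rejected.
#'
#' @param path Configuration file path.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  args <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2)
      stop_input("malformed config line: '%s'", ln)
    key <- trimws(kv[1])
    val <- trimws(kv[2])
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(sub("^Inf$", "Inf", parts)))
    args[[key]] <- if (!anyNA(num)) num
    else if (all(parts %in% c("TRUE", "FALSE"))) as.logical(parts)
    else parts
  }
  known <- names(formals(run_config))
  unknown <- setdiff(names(args), known)
  if (length(unknown) > 0)
    stop_input("unknown configuration keys: %s",
               paste(unknown, collapse = ", "))
  do.call(run_config, args)
}

#' Run the full movement-pattern divergence pipeline
#'
#' Simulates (or reads) the cohort, preprocesses and segments every
#' participant, trains the forecaster on the pooled windows of the
#' `control_train` participants (per intensity bin if configured), scores
#' every other participant, and performs the group comparisons: overall
#' counts, per-bin counts, the threshold sweep, and ROC/AUC per case group
#' within the configured divergence band.
#'
#' @param config A [run_config()].
#' @return A report list: `manifest`, `summaries` (one row per evaluated
#'   participant), `overall` (t-tests on total counts), `per_bin`
#'   comparisons, `sweep`, `roc` (per case group, counts pooled over the
#'   divergence band), `scores`, `config`, and a text `log`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  log <- character(0)
  say <- function(fmt, ...) {
    msg <- sprintf("%s %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   sprintf(fmt, ...))
    log <<- c(log, msg)
  }
  say("run start: seed=%d delta=%g band=[%g,%g)", config$seed,
      config$divergence_fraction, config$divergence_band[1],
      config$divergence_band[2])

  if (is.null(config$input_dir)) {
    cohort <- generate_cohort(config$spec)
    manifest <- cohort$manifest
    participants <- cohort$participants
    say("simulated %d participants", nrow(manifest))
  } else {
    loaded <- read_cohort(config$input_dir)
    manifest <- loaded$manifest
    participants <- loaded$participants
    say("loaded %d participants from %s", nrow(manifest), config$input_dir)
  }
  if (!"control_train" %in% manifest$group)
    stop_input("manifest must designate a control_train group")
  if (length(setdiff(unique(manifest$group), "control_train")) < 1)
    stop_input("manifest needs at least one evaluation group")

  windows <- lapply(manifest$participant_id, function(id) {
    rec <- preprocess_participant(participants[[id]]$traces,
                                  window_n = config$window_n,
                                  params = config$sync,
                                  participant_id = id)
    segment_windows(rec, bins = config$bins)
  })
  names(windows) <- manifest$participant_id
  say("preprocessed and segmented (%d windows total)",
      sum(vapply(windows, function(w) w$n_windows, integer(1))))

  train_ids <- manifest$participant_id[manifest$group == "control_train"]
  eval_ids <- manifest$participant_id[manifest$group != "control_train"]
  train_set <- combine_window_sets(windows[train_ids])
  if (config$train_per_bin) {
    models <- vector("list", config$bins$n_bins)
    for (b in sort(unique(train_set$bin)))
      models[[b]] <- train_forecaster(train_set, config$model,
                                      config$train, bin = b)
    say("trained %d per-bin models", length(unique(train_set$bin)))
  } else {
    models <- train_forecaster(train_set, config$model, config$train)
    say("trained single model: %d epochs (val MSE %.5f)",
        models$meta$epochs_trained, min(models$meta$log$val_mse))
  }

  scores <- list()
  summaries <- list()
  for (id in eval_ids) {
    grp <- manifest$group[manifest$participant_id == id]
    sc <- score_participant(windows[[id]], models, th = config$th,
                            bins = config$bins, group = grp)
    sc$scores$group <- grp
    scores[[id]] <- sc$scores
    summaries[[id]] <- sc$summary
  }
  scores <- do.call(rbind, scores)
  rownames(scores) <- NULL
  summaries <- do.call(rbind, summaries)
  rownames(summaries) <- NULL
  say("scored %d participants at th=%g", length(eval_ids), config$th)

  control <- "control_test"
  case_groups <- setdiff(unique(summaries$group), control)
  overall <- do.call(rbind, lapply(case_groups, function(g)
    t_test_counts(
      group_summary(summaries$non_similar_total[summaries$group == control],
                    control),
      group_summary(summaries$non_similar_total[summaries$group == g], g),
      th = config$th)))
  per_bin <- per_bin_comparisons(summaries, config$bins, control,
                                 case_groups, th = config$th)
  sweep <- threshold_sweep(scores, config$th_grid, control, case_groups)

  band_bins <- which(config$bins$edges[-length(config$bins$edges)] >=
                       config$divergence_band[1] &
                     config$bins$edges[-1] <= config$divergence_band[2])
  roc <- lapply(case_groups, function(g) {
    cols <- sprintf("nonsim_bin_%d", band_bins)
    band_counts <- function(grp) {
      sub <- summaries[summaries$group == grp, cols, drop = FALSE]
      as.integer(rowSums(sub))
    }
    roc_auc(band_counts(g), band_counts(control))
  })
  names(roc) <- case_groups
  say("compared groups: %s vs %s", paste(case_groups, collapse = ","),
      control)

  report <- list(manifest = manifest, summaries = summaries,
                 overall = overall, per_bin = per_bin, sweep = sweep,
                 roc = roc, scores = scores, config = config, log = log)
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' Write a pipeline report to disk
#'
#' @param report A [run_pipeline()] result.
#' @param dir Output directory.
#' @return `dir` invisibly.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop_input("cannot create output directory '%s'", dir)
  data.table::fwrite(report$summaries, file.path(dir, "summaries.csv"))
  data.table::fwrite(report$scores, file.path(dir, "scores.csv"))
  stats_obj <- list(overall = report$overall, per_bin = report$per_bin,
                    sweep = report$sweep, roc = report$roc,
                    seed = report$config$seed)
  jsonlite::write_json(stats_obj, file.path(dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  writeLines(report$log, file.path(dir, "run.log"))
  invisible(dir)
}
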