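#' Default pipeline configuration
#'
#' Every tunable of the simulate-extract-fit-classify-evaluate pipeline
#' with its documented default. The configuration round-trips losslessly
#' through YAML ([write_config()] / [read_config()]), and every output
#' file is stamped with the MD5 hash of the configuration that produced
#' it.
#'
#' @return Nested list with sections `simulate` (per-stage signal models,
#'   acquisition offset/noise, sampling interval), `processing` (window
#'   length, band, spectral grid, peak rules), `scaling` (weight `W`),
#'   `classifier` (k, mode, labelling, k-means settings) and `evaluation`
#'   (windows per stage for the train/test split, sweep weights).
#' @export
default_config <- function() {
  m <- default_stage_models()
  list(
    simulate = list(
      models = lapply(split(m[, -1], m$stage)[m$stage], as.list),
      dc_offset = 2.5, noise_sd = 0.05, dt = 0.017),
    processing = list(
      window_length = 30, band = c(0.1, 0.5), resolution = 0.002,
      prominence_frac = 0.2, summary = "mean"),
    scaling = list(weight = 0.1),
    classifier = list(k = 5, mode = "kmeans", labeling = "lenient",
                      n_init = 10, max_iter = 300, tol = 1e-6),
    evaluation = list(n_train = 40, n_test = 40,
                      sweep_weights = c(1, 0.5, 0.2, 0.1, 0.05, 0.02, 0.01),
                      sweep_mode = "supervised"))
}

config_models <- function(config) {
  base <- default_stage_models()
  for (s in names(config$simulate$models)) {
    for (f in names(config$simulate$models[[s]]))
      base[s, f] <- config$simulate$models[[s]][[f]]
  }
  base
}

#' Read and write pipeline configurations
#'
#' @param config a configuration list (see [default_config()]).
#' @param path YAML file path.
#' @return `write_config` returns `path` invisibly; `read_config` returns
#'   the configuration list with defaults filled in for omitted fields.
#' @export
write_config <- function(config, path) {
  writeLines(yaml::as.yaml(config, precision = 15), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  merge_into <- function(base, over) {
    for (k in names(over)) {
      base[[k]] <- if (is.list(base[[k]]) && is.list(over[[k]]))
        merge_into(base[[k]], over[[k]]) else over[[k]]
    }
    base
  }
  merge_into(default_config(), user)
}

# Round-robin benchmark hypnogram: (n_train + n_test) epochs per stage of
# one window each, interleaved across stages.
benchmark_hypnogram <- function(n_per_stage, window_length = 30) {
  data.frame(stage = rep(stage_levels(), times = n_per_stage),
             duration_s = window_length)
}

#' Simulate the benchmark session and write its files
#'
#' Generates the default benchmark night (equal windows per stage,
#' stage-interleaved epochs) and writes the concatenated trace and the
#' ground-truth hypnogram as delimited text, each stamped with the config
#' hash.
#'
#' @param config configuration list (see [default_config()]).
#' @param seed integer seed.
#' @param out_dir output directory (created if missing).
#' @return Invisibly, a list with the `session` and the written `paths`.
#' @export
simulate_to_files <- function(config = default_config(), seed = 1,
                              out_dir = ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  n <- config$evaluation$n_train + config$evaluation$n_test
  hyp <- benchmark_hypnogram(n, config$processing$window_length)
  session <- synth_session(hyp, models = config_models(config),
                           dc_offset = config$simulate$dc_offset,
                           noise_sd = config$simulate$noise_sd,
                           dt = config$simulate$dt, seed = seed)
  stamp <- sprintf("config_hash: %s seed: %d", config_hash(config), seed)
  paths <- c(trace = file.path(out_dir, "trace.tsv"),
             hypnogram = file.path(out_dir, "hypnogram.tsv"))
  write_trace(session_trace(session), paths["trace"], comment = stamp)
  write_hypnogram(session$hypnogram, paths["hypnogram"], comment = stamp)
  invisible(list(session = session, paths = paths))
}

# Seeded stratified split: per stage, n_train window indices to train, the
# next n_test to test (sampled without replacement).
stratified_split <- function(features, n_train, n_test, seed) {
  with_seed(seed, {
    train_idx <- integer(0); test_idx <- integer(0)
    for (s in stage_levels()) {
      idx <- which(as.character(features$stage) == s)
      if (length(idx) < n_train + n_test)
        stop_respstage(sprintf("stage %s has %d windows, need %d",
                               s, length(idx), n_train + n_test),
                       "respstage_invalid_input")
      perm <- sample(idx)
      train_idx <- c(train_idx, perm[seq_len(n_train)])
      test_idx <- c(test_idx, perm[n_train + seq_len(n_test)])
    }
    list(train = sort(train_idx), test = sort(test_idx))
  })
}

#' Run the full sleep-staging pipeline
#'
#' The end-to-end benchmark: simulate a stage-balanced synthetic night,
#' extract per-window (respiration rate, output voltage) features, make a
#' seeded stratified train/test split, fit the nearest-centroid classifier
#' on the training windows, classify the test windows, and evaluate
#' per-stage and averaged accuracy. Optionally also runs the weight sweep.
#' Deterministic: a given (config, seed) yields identical artifacts.
#'
#' @param config configuration list (see [default_config()]).
#' @param seed integer master seed (drives simulation, split and k-means).
#' @param out_dir optional output directory; when given, the model file,
#'   feature tables, predicted hypnogram, report and sweep table are
#'   written there, each stamped with the config hash.
#' @param sweep run the weight sweep as well (default `TRUE`).
#' @return An object of class `stage_pipeline`: list with `features`,
#'   `split`, `fit` (a [stage_fit()]), `predicted` (hypnogram), `report`
#'   (a `stage_report`), `sweep` (data frame or `NULL`), `config`, `seed`.
#' @export
#' @examples
#' \donttest{
#' res <- run_pipeline(seed = 1)
#' res$report
#' }
run_pipeline <- function(config = default_config(), seed = 1, out_dir = NULL,
                         sweep = TRUE) {
  n <- config$evaluation$n_train + config$evaluation$n_test
  hyp <- benchmark_hypnogram(n, config$processing$window_length)
  session <- synth_session(hyp, models = config_models(config),
                           dc_offset = config$simulate$dc_offset,
                           noise_sd = config$simulate$noise_sd,
                           dt = config$simulate$dt, seed = seed)
  features <- extract_features(session,
                               window_length = config$processing$window_length,
                               band = config$processing$band,
                               resolution = config$processing$resolution,
                               prominence_frac = config$processing$prominence_frac,
                               summary = config$processing$summary)
  split <- stratified_split(features, config$evaluation$n_train,
                            config$evaluation$n_test, seed = seed + 1L)
  train <- features[split$train, ]
  test <- features[split$test, ]
  fit <- stage_fit(train, k = config$classifier$k,
                   weight = config$scaling$weight,
                   mode = config$classifier$mode,
                   labeling = config$classifier$labeling,
                   seed = seed + 2L, n_init = config$classifier$n_init,
                   max_iter = config$classifier$max_iter,
                   tol = config$classifier$tol)
  predicted <- classify_session(test, fit, config$processing$window_length)
  report <- evaluate(predicted$stage, test$stage)
  sweep_res <- NULL
  if (isTRUE(sweep)) {
    sweep_res <- weight_sweep(train, test,
                              weights = config$evaluation$sweep_weights,
                              k = config$classifier$k, seed = seed + 2L,
                              mode = config$evaluation$sweep_mode,
                              labeling = config$classifier$labeling)
  }
  out <- structure(list(features = features, split = split, fit = fit,
                        predicted = predicted, report = report,
                        sweep = sweep_res, config = config, seed = seed),
                   class = "stage_pipeline")
  if (!is.null(out_dir)) write_pipeline(out, out_dir)
  out
}

#' @export
print.stage_pipeline <- function(x, ...) {
  cat(sprintf("<stage_pipeline> seed %d: %d windows (%d train / %d test)\n\n",
              x$seed, nrow(x$features), length(x$split$train),
              length(x$split$test)))
  print(x$report)
  if (!is.null(x$sweep)) {
    cat("\nWeight sweep (averaged accuracy):\n")
    sw <- x$sweep
    sw$accuracy <- round(sw$accuracy, 4)
    print(sw, row.names = FALSE)
  }
  invisible(x)
}

write_pipeline <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stamp <- sprintf("config_hash: %s seed: %d", config_hash(result$config),
                   result$seed)
  write_features(result$features, file.path(out_dir, "features.tsv"),
                 comment = stamp)
  write_features(result$features[result$split$train, ],
                 file.path(out_dir, "features_train.tsv"), comment = stamp)
  write_features(result$features[result$split$test, ],
                 file.path(out_dir, "features_test.tsv"), comment = stamp)
  write_stager(result$fit, file.path(out_dir, "model.txt"), comment = stamp)
  write_hypnogram(result$predicted, file.path(out_dir, "predicted_hypnogram.tsv"),
                  comment = stamp)
  write_report(result$report, file.path(out_dir, "report.tsv"), comment = stamp)
  if (!is.null(result$sweep)) {
    con <- file(file.path(out_dir, "sweep.tsv"), "w")
    writeLines(c(paste0("# ", stamp), "weight\taccuracy",
                 sprintf("%g\t%.6f", result$sweep$weight,
                         result$sweep$accuracy)), con)
    close(con)
  }
  write_config(result$config, file.path(out_dir, "config.yml"))
  invisible(out_dir)
}
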