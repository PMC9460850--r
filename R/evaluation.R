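#' Per-stage and averaged classification accuracy
#'
#' Tallies a 5 x 5 confusion matrix (true stage x predicted stage) over
#' aligned windows. Per-stage accuracy is the diagonal count divided by
#' the row sum; the averaged accuracy is the *unweighted* mean of the five
#' per-stage accuracies (the convention under which per-stage accuracies
#' of 89.17/86.67/88.33/87.50/84.17% average to 87.17%).
#'
#' @param predicted predicted stages: a factor/character vector or a
#'   hypnogram data frame with a `stage` column.
#' @param truth true stages, same form and length.
#' @return An object of class `stage_report`: list with `confusion`
#'   (5 x 5 matrix), `per_stage_accuracy`, `averaged_accuracy`,
#'   `n_per_stage`.
#' @export
#' @examples
#' truth <- rep(stage_levels(), each = 4)
#' evaluate(truth, truth)$averaged_accuracy
evaluate <- function(predicted, truth) {
  if (is.data.frame(predicted)) predicted <- predicted$stage
  if (is.data.frame(truth)) truth <- truth$stage
  predicted <- as_stage(predicted)
  truth <- as_stage(truth)
  if (length(predicted) != length(truth))
    stop_respstage("predicted and truth hypnograms have different lengths",
                   "respstage_alignment_error")
  confusion <- table(truth = truth, predicted = predicted)
  n_per_stage <- rowSums(confusion)
  per_stage <- ifelse(n_per_stage > 0, diag(confusion) / n_per_stage, NA_real_)
  structure(list(confusion = unclass(confusion),
                 per_stage_accuracy = per_stage,
                 averaged_accuracy = mean(per_stage, na.rm = TRUE),
                 n_per_stage = n_per_stage),
            class = "stage_report")
}

#' @export
print.stage_report <- function(x, ...) {
  cat("Sleep-stage classification report\n\nConfusion (true x predicted):\n")
  print(x$confusion)
  cat("\nPer-stage accuracy (%):\n")
  print(round(100 * x$per_stage_accuracy, 2))
  cat(sprintf("\nAveraged accuracy: %.2f%%\n", 100 * x$averaged_accuracy))
  invisible(x)
}

#' Write a classification report to delimited text
#'
#' @param report a `stage_report` from [evaluate()].
#' @param path file path.
#' @param comment optional `#`-prefixed header comment lines.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  writeLines(paste(c("truth_stage", colnames(report$confusion),
                     "accuracy"), collapse = "\t"), con)
  for (s in rownames(report$confusion)) {
    writeLines(paste(c(s, report$confusion[s, ],
                       sprintf("%.6f", report$per_stage_accuracy[s])),
                     collapse = "\t"), con)
  }
  writeLines(sprintf("averaged\t%s\t%.6f",
                     paste(rep("", ncol(report$confusion)), collapse = "\t"),
                     report$averaged_accuracy), con)
  invisible(path)
}

#' Accuracy as a function of the respiration-rate weight
#'
#' For each candidate weight `W`, refits the classifier on the training
#' features (rescaled with that weight), reclassifies the test features
#' and records the averaged accuracy. Reproduces the weight-optimisation
#' experiment: with too large a `W` the rate axis dominates the distance,
#' with too small a `W` the relative voltage alone decides and accuracy
#' saturates; the optimum lies between.
#'
#' @param train,test labeled feature data frames (see
#'   [extract_features()]).
#' @param weights numeric vector of candidate weights.
#' @param k number of centroids.
#' @param seed k-means seed (unused in the default supervised mode).
#' @param mode,labeling passed to [stage_fit()]. The default is
#'   `"supervised"` (one centroid at each stage's labeled training mean),
#'   matching how the weight experiment is defined: the sweep compares
#'   distances to stage-featured centroids, and supervised centroids keep
#'   the comparison stable as the geometry collapses at small `W`.
#' @return Data frame with columns `weight` and `accuracy` (averaged
#'   accuracy), rows ordered as `weights`.
#' @export
weight_sweep <- function(train, test, weights = c(1, 0.5, 0.2, 0.1, 0.05, 0.02, 0.01),
                         k = 5, seed = 1, mode = "supervised", labeling = "lenient") {
  if (!length(weights))
    stop_respstage("weights must be non-empty", "respstage_invalid_parameter")
  acc <- vapply(weights, function(w) {
    fit <- stage_fit(train, k = k, weight = w, mode = mode,
                     labeling = labeling, seed = seed)
    evaluate(predict(fit, test), test$stage)$averaged_accuracy
  }, numeric(1))
  data.frame(weight = weights, accuracy = acc)
}

#' Session-to-session voltage differences: raw vs relative
#'
#' Quantifies why the relative output voltage is used: for each stage, the
#' absolute between-session difference of the raw voltage is compared with
#' the same difference after dividing by the global maximum voltage. The
#' relative differences are never larger.
#'
#' @param features feature data frame with columns `session`, `stage` and
#'   `voltage`; at least two sessions per stage.
#' @return Data frame with columns `stage`, `raw_diff`, `relative_diff`
#'   (mean absolute pairwise between-session difference per stage).
#' @export
relative_difference_report <- function(features) {
  ref <- fit_voltage_reference(features)
  split_stage <- split(features, as_stage(features$stage), drop = TRUE)
  rows <- lapply(names(split_stage), function(s) {
    d <- split_stage[[s]]
    per_session <- tapply(d$voltage, d$session, mean)
    if (length(per_session) < 2)
      stop_respstage(sprintf("stage %s has fewer than 2 sessions", s),
                     "respstage_invalid_input")
    pair_diff <- mean(abs(as.numeric(stats::dist(per_session))))
    data.frame(stage = s, raw_diff = pair_diff, relative_diff = pair_diff / ref)
  })
  out <- do.call(rbind, rows)
  out$stage <- as_stage(out$stage)
  out
}
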