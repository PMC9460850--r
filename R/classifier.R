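#' Attach sleep-stage labels to fitted centroids
#'
#' Each centroid receives the majority stage among the labeled training
#' points assigned to its cluster. In `"strict"` mode (default) a majority
#' tie, or one stage winning two clusters, raises an ambiguity error; in
#' `"lenient"` mode cluster-stage pairs are assigned greedily by descending
#' count (ties broken by lowest cluster index, then stage order), which
#' yields a one-to-one labelling when `k` equals the number of stages.
#'
#' @param centers k x 2 matrix of centroid coordinates (columns `x`, `y`).
#' @param cluster integer cluster assignment of each training point.
#' @param labels stage labels of the training points (parallel to
#'   `cluster`).
#' @param mode `"strict"` or `"lenient"`.
#' @return Data frame with columns `i`, `x`, `y`, `stage`.
#' @export
label_centroids <- function(centers, cluster, labels,
                            mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  k <- nrow(centers)
  labels <- as_stage(labels)
  ok <- !is.na(labels)
  counts <- table(factor(cluster[ok], levels = seq_len(k)), labels[ok])
  if (any(rowSums(counts) == 0))
    stop_respstage(sprintf("cluster(s) %s received no labeled point",
                           paste(which(rowSums(counts) == 0), collapse = ", ")),
                   "respstage_coverage_error")
  stage <- rep(NA_character_, k)
  if (mode == "strict") {
    for (j in seq_len(k)) {
      cj <- counts[j, ]
      top <- which(cj == max(cj))
      if (length(top) > 1)
        stop_respstage(sprintf("cluster %d has tied majority stages (%s)",
                               j, paste(colnames(counts)[top], collapse = ", ")),
                       "respstage_ambiguity_error")
      stage[j] <- colnames(counts)[top]
    }
    dup <- unique(stage[duplicated(stage)])
    if (length(dup))
      stop_respstage(sprintf("stage(s) %s claimed by more than one cluster",
                             paste(dup, collapse = ", ")),
                     "respstage_ambiguity_error")
  } else {
    m <- as.matrix(counts)
    while (any(is.na(stage)) && any(m > -1)) {
      open_cl <- which(is.na(stage))
      open_st <- which(!(colnames(m) %in% stage))
      if (!length(open_st)) break
      sub <- m[open_cl, open_st, drop = FALSE]
      best <- which(sub == max(sub), arr.ind = TRUE)
      best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
      stage[open_cl[best[1]]] <- colnames(sub)[best[2]]
    }
    for (j in which(is.na(stage)))  # more clusters than stages: plain majority
      stage[j] <- colnames(counts)[which.max(counts[j, ])]
  }
  data.frame(i = seq_len(k), x = centers[, 1], y = centers[, 2],
             stage = as_stage(stage))
}

#' Classify scaled feature points by nearest centroid
#'
#' Assigns each point `(a, b)` to the sleep stage of the centroid
#' minimizing the classification distance
#' `D_i = sqrt((x_i - a)^2 + (y_i - b)^2)`; an exact distance tie goes to
#' the lowest centroid index.
#'
#' @param points data frame or matrix with columns `x`, `y` (scaled
#'   features).
#' @param centroids labeled centroid data frame (`i`, `x`, `y`, `stage`),
#'   as produced by [label_centroids()] or stored in a [stage_fit()].
#' @return Factor of predicted stages, one per point.
#' @export
classify <- function(points, centroids) {
  if (inherits(points, "data.frame")) points <- as.matrix(points[, c("x", "y")])
  if (inherits(centroids, "stage_fit")) centroids <- centroids$centroids
  if (any(is.na(centroids$stage)))
    stop_respstage("centroids are not stage-labeled", "respstage_invalid_model")
  centers <- as.matrix(centroids[, c("x", "y")])
  idx <- assign_nearest(points, centers)
  centroids$stage[idx]
}

#' Fit a nearest-centroid sleep-stage classifier
#'
#' The package's model-fitting front end. Takes a labeled feature table
#' (respiration rate in breaths/minute and per-window output voltage, see
#' [extract_features()]), applies the two-step scaling (weight `W` on the
#' rate axis, relative voltage on the other), places `k = 5` centroids in
#' the scaled plane and labels them with sleep stages. New windows are
#' staged by the nearest centroid under the Euclidean classification
#' distance.
#'
#' Two centroid modes are available: `"kmeans"` (default) fits
#' unsupervised k-means via [fit_centroids()] and labels clusters by
#' majority vote over the training labels; `"supervised"` places one
#' centroid at the per-stage mean of the labeled training features.
#'
#' @param features feature data frame with columns `rate_bpm`, `voltage`
#'   and `stage` (labels required for labelling / supervised mode).
#' @param k number of centroids (default 5, one per stage).
#' @param weight weight `W` multiplied onto the respiration rate (default
#'   0.1).
#' @param mode `"kmeans"` or `"supervised"`.
#' @param labeling `"strict"` or `"lenient"` cluster labelling (see
#'   [label_centroids()]); only used in `"kmeans"` mode.
#' @param seed,n_init,max_iter,tol k-means settings, see
#'   [fit_centroids()].
#' @return An object of class `stage_fit` with components `centroids`
#'   (data frame `i`, `x`, `y`, `stage`), `k`, `scaling` (a
#'   [scaling_config()]), `mode`, `objective`, `trace`, `seed`, `n_init`
#'   and `call`. Methods: `print`, `summary`, `coef`, `predict`, `plot`.
#' @seealso [predict.stage_fit()], [evaluate()], [weight_sweep()]
#' @export
#' @examples
#' set.seed(1)
#' f <- data.frame(
#'   rate_bpm = rep(c(16.3, 12.6), each = 20) + rnorm(40, 0, 0.3),
#'   voltage = rep(c(7.9, 5.5), each = 20) + rnorm(40, 0, 0.2),
#'   stage = rep(c("AWAKE", "N3"), each = 20))
#' fit <- stage_fit(f, k = 2, seed = 1)
#' fit
#' predict(fit, data.frame(rate_bpm = 16.0, voltage = 7.8))
stage_fit <- function(features, k = 5, weight = 0.1,
                      mode = c("kmeans", "supervised"),
                      labeling = c("strict", "lenient"),
                      seed = 1, n_init = 10, max_iter = 300, tol = 1e-6) {
  mode <- match.arg(mode)
  labeling <- match.arg(labeling)
  scaling <- scaling_config(weight, fit_voltage_reference(features))
  scaled <- apply_scaling(features, scaling)
  if (mode == "kmeans") {
    km <- fit_centroids(scaled, k = k, seed = seed, n_init = n_init,
                        max_iter = max_iter, tol = tol)
    centroids <- if (all(is.na(scaled$stage))) {
      data.frame(i = seq_len(k), x = km$centers[, 1], y = km$centers[, 2],
                 stage = as_stage(rep(NA_character_, k)))
    } else {
      label_centroids(km$centers, km$cluster, scaled$stage, mode = labeling)
    }
    objective <- km$objective; trace <- km$trace; iterations <- km$iterations
  } else {
    if (all(is.na(scaled$stage)))
      stop_respstage("supervised mode requires stage labels",
                     "respstage_invalid_input")
    present <- levels(scaled$stage)[levels(scaled$stage) %in%
                                      as.character(scaled$stage)]
    centers <- t(vapply(present, function(s) {
      colMeans(as.matrix(scaled[which(scaled$stage == s), c("x", "y")]))
    }, numeric(2)))
    k <- length(present)
    centroids <- data.frame(i = seq_len(k), x = centers[, 1], y = centers[, 2],
                            stage = as_stage(present))
    cl <- match(as.character(scaled$stage), present)
    objective <- wss_objective(as.matrix(scaled[, c("x", "y")]), centers,
                               ifelse(is.na(cl), 1L, cl))
    trace <- objective; iterations <- 1L
  }
  structure(list(centroids = centroids, k = k, scaling = scaling, mode = mode,
                 labeling = labeling, objective = objective, trace = trace,
                 iterations = iterations, seed = seed, n_init = n_init,
                 n_obs = nrow(features), call = match.call()),
            class = "stage_fit")
}

#' @export
print.stage_fit <- function(x, digits = 4, ...) {
  cat("Nearest-centroid sleep-stage classifier\n")
  cat(sprintf("  mode: %s, k = %d, W = %g, voltage reference = %.4g V\n",
              x$mode, x$k, x$scaling$weight, x$scaling$voltage_reference))
  cat(sprintf("  fitted on %d windows, within-cluster SS = %.4g\n\n",
              x$n_obs, x$objective))
  cdf <- x$centroids
  cdf$x <- round(cdf$x, digits); cdf$y <- round(cdf$y, digits)
  print(cdf, row.names = FALSE)
  invisible(x)
}

#' @export
summary.stage_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.stage_fit")
}

#' @export
print.summary.stage_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("\nk-means: seed %s, %d restart(s), %d iteration(s), objective trace length %d\n",
              deparse(x$fit$seed), x$fit$n_init, x$fit$iterations,
              length(x$fit$trace)))
  invisible(x)
}

#' Centroid coordinates of a fitted classifier
#'
#' @param object a [stage_fit()].
#' @param ... unused.
#' @return k x 2 matrix of centroid coordinates in the scaled plane, rows
#'   named by stage where labeled.
#' @export
coef.stage_fit <- function(object, ...) {
  m <- as.matrix(object$centroids[, c("x", "y")])
  rownames(m) <- as.character(object$centroids$stage)
  m
}

#' Predict sleep stages for new windows
#'
#' Applies the fit's stored scaling (training weight and voltage
#' reference) to new raw features and classifies each window by nearest
#' centroid.
#'
#' @param object a [stage_fit()].
#' @param newdata feature data frame with columns `rate_bpm` and
#'   `voltage`; already-scaled data can be supplied as columns `x`, `y`
#'   with `scaled = TRUE`.
#' @param scaled set `TRUE` if `newdata` is already in the scaled plane.
#' @param ... unused.
#' @return Factor of predicted stages.
#' @export
predict.stage_fit <- function(object, newdata, scaled = FALSE, ...) {
  pts <- if (scaled) newdata else apply_scaling(newdata, object$scaling)
  classify(pts, object$centroids)
}

#' Plot a fitted classifier's feature plane
#'
#' @param x a [stage_fit()].
#' @param features optional raw feature data frame to overlay (scaled with
#'   the fit's scaling, colored by stage label).
#' @param ... passed to [graphics::plot()].
#' @export
plot.stage_fit <- function(x, features = NULL, ...) {
  cen <- x$centroids
  cols <- stats::setNames(grDevices::hcl.colors(5, "Dark 3"), stage_levels())
  if (!is.null(features)) {
    sc <- apply_scaling(features, x$scaling)
    graphics::plot(sc$x, sc$y, col = cols[as.character(sc$stage)], pch = 1,
                   xlab = "weighted respiration rate (W x b/min)",
                   ylab = "relative output voltage", ...)
    graphics::points(cen$x, cen$y, pch = 19, cex = 1.6,
                     col = cols[as.character(cen$stage)])
  } else {
    graphics::plot(cen$x, cen$y, pch = 19, cex = 1.6,
                   col = cols[as.character(cen$stage)],
                   xlab = "weighted respiration rate (W x b/min)",
                   ylab = "relative output voltage", ...)
  }
  graphics::text(cen$x, cen$y, labels = as.character(cen$stage), pos = 3)
  graphics::legend("topleft", legend = stage_levels(), col = cols, pch = 1,
                   bty = "n")
  invisible(x)
}

#' Classify every window of a session
#'
#' @param features feature data frame for the session's windows, in time
#'   order (see [extract_features()]).
#' @param fit a [stage_fit()].
#' @param window_length window length in seconds used for the hypnogram
#'   records.
#' @return Predicted hypnogram data frame (`start_s`, `duration_s`,
#'   `stage`).
#' @export
classify_session <- function(features, fit, window_length = 30) {
  if (nrow(features) == 0L)
    return(data.frame(start_s = numeric(0), duration_s = numeric(0),
                      stage = as_stage(character(0))))
  pred <- predict(fit, features)
  data.frame(start_s = features$window_start_s,
             duration_s = rep(window_length, nrow(features)),
             stage = pred)
}

#' Save and load a fitted classifier
#'
#' Plain-text key-value model file holding k, the scaling (W, voltage
#' reference), fit metadata and the labeled centroids, with full numeric
#' precision so that save/load round-trips are bit-stable.
#'
#' @param fit a [stage_fit()].
#' @param path file path.
#' @param comment optional `#`-prefixed header comment lines.
#' @return `write_stager` returns `path` invisibly; `read_stager` returns
#'   a [stage_fit()].
#' @export
write_stager <- function(fit, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  num <- function(x) sprintf("%.17g", x)
  writeLines(c("format: respstage-model-1",
               paste0("k: ", fit$k),
               paste0("mode: ", fit$mode),
               paste0("labeling: ", fit$labeling),
               paste0("weight: ", num(fit$scaling$weight)),
               paste0("voltage_reference: ", num(fit$scaling$voltage_reference)),
               paste0("seed: ", fit$seed),
               paste0("n_init: ", fit$n_init),
               paste0("objective: ", num(fit$objective)),
               paste0("n_obs: ", fit$n_obs)), con)
  st <- as.character(fit$centroids$stage)
  st[is.na(st)] <- "?"
  writeLines(sprintf("centroid: %d %s %s %s", fit$centroids$i,
                     num(fit$centroids$x), num(fit$centroids$y), st), con)
  invisible(path)
}

#' @rdname write_stager
#' @export
read_stager <- function(path) {
  lines <- grep("^#", readLines(path), invert = TRUE, value = TRUE)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, ": ", fixed = TRUE)
  keys <- vapply(kv, `[`, "", 1)
  vals <- vapply(kv, function(p) paste(p[-1], collapse = ": "), "")
  if (!identical(vals[keys == "format"], "respstage-model-1"))
    stop_respstage(sprintf("'%s' is not a respstage model file", path),
                   "respstage_parse_error")
  get1 <- function(key) vals[which(keys == key)[1]]
  cen <- do.call(rbind, strsplit(vals[keys == "centroid"], " ", fixed = TRUE))
  stage <- ifelse(cen[, 4] == "?", NA_character_, cen[, 4])
  centroids <- data.frame(i = as.integer(cen[, 1]), x = as.numeric(cen[, 2]),
                          y = as.numeric(cen[, 3]), stage = as_stage(stage))
  structure(list(centroids = centroids,
                 k = as.integer(get1("k")),
                 scaling = scaling_config(as.numeric(get1("weight")),
                                          as.numeric(get1("voltage_reference"))),
                 mode = get1("mode"), labeling = get1("labeling"),
                 objective = as.numeric(get1("objective")),
                 trace = as.numeric(get1("objective")), iterations = NA_integer_,
                 seed = as.integer(get1("seed")),
                 n_init = as.integer(get1("n_init")),
                 n_obs = as.integer(get1("n_obs")),
                 call = quote(read_stager())),
            class = "stage_fit")
}
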