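# Lloyd k-means with greedy farthest-point initialisation, deterministic
# tie-breaking and empty-cluster reseeding. Written in-package because the
# classifier needs a per-iteration objective trace, seeded farthest-point
# restarts and index-based tie-breaks that stock implementations do not
# expose.

#' Distance between a feature point and a centroid
#'
#' The classification distance between a scaled feature point `(a, b)` =
#' (weighted respiration rate, relative output voltage) and a centroid
#' `(x_i, y_i)`:
#' `D_i = sqrt((x_i - a)^2 + (y_i - b)^2)`.
#'
#' @param point numeric length-2 vector `(a, b)`.
#' @param centroid numeric length-2 vector `(x_i, y_i)`.
#' @return Non-negative distance `D_i`.
#' @export
#' @examples
#' stage_distance(c(17.5, 3.5), c(17.5, 0))  # 3.5
#' round(stage_distance(c(17.5, 3.5), c(13.5, 1)), 2)  # 4.72
stage_distance <- function(point, centroid) {
  check_finite(point, "point")
  check_finite(centroid, "centroid")
  sqrt(sum((centroid - point)^2))
}

# n x k matrix of distances between rows of `pts` and rows of `centers`.
distance_matrix <- function(pts, centers) {
  d2 <- outer(rowSums(pts^2), rep(1, nrow(centers))) +
    outer(rep(1, nrow(pts)), rowSums(centers^2)) -
    2 * pts %*% t(centers)
  sqrt(pmax(d2, 0))
}

# Nearest-centroid assignment; exact ties go to the lowest centroid index
# (max.col(-d, "first")).
assign_nearest <- function(pts, centers) {
  max.col(-distance_matrix(pts, centers), ties.method = "first")
}

wss_objective <- function(pts, centers, cluster) {
  sum((pts - centers[cluster, , drop = FALSE])^2)
}

# Greedy farthest-point spread: a seeded random first center, then each
# next center is the point farthest from the chosen set.
farthest_point_init <- function(pts, k, first) {
  idx <- integer(k)
  idx[1] <- first
  if (k > 1) {
    d <- distance_matrix(pts, pts[idx[1], , drop = FALSE])[, 1]
    for (j in 2:k) {
      idx[j] <- which.max(d)
      d <- pmin(d, distance_matrix(pts, pts[idx[j], , drop = FALSE])[, 1])
    }
  }
  pts[idx, , drop = FALSE]
}

lloyd_once <- function(pts, k, first, max_iter, tol) {
  centers <- farthest_point_init(pts, k, first)
  trace <- numeric(0)
  cluster <- assign_nearest(pts, centers)
  for (it in seq_len(max_iter)) {
    trace <- c(trace, wss_objective(pts, centers, cluster))
    new_centers <- centers
    for (j in seq_len(k)) {
      members <- cluster == j
      if (any(members)) {
        new_centers[j, ] <- colMeans(pts[members, , drop = FALSE])
      } else {
        # reseed an emptied cluster at the point farthest from its centroid
        d_own <- distance_matrix(pts, new_centers)[cbind(seq_len(nrow(pts)), cluster)]
        new_centers[j, ] <- pts[which.max(d_own), ]
      }
    }
    moved <- max(sqrt(rowSums((new_centers - centers)^2)))
    centers <- new_centers
    cluster <- assign_nearest(pts, centers)
    if (moved < tol) break
  }
  obj <- wss_objective(pts, centers, cluster)
  list(centers = centers, cluster = cluster, objective = obj,
       trace = c(trace, obj), iterations = it)
}

#' Fit k cluster centroids by k-means
#'
#' Lloyd iterations (assign each point to its nearest centroid by the
#' classification distance, recompute centroids as cluster means) run to
#' convergence from `n_init` seeded greedy farthest-point initialisations;
#' the restart with the lowest within-cluster sum of squares wins. Fully
#' deterministic for a fixed seed.
#'
#' @param points data frame or matrix with columns `x`, `y` (scaled
#'   features).
#' @param k number of clusters (default 5, one per sleep stage).
#' @param seed integer seed for the restarts.
#' @param n_init number of restarts.
#' @param max_iter maximum Lloyd iterations per restart.
#' @param tol convergence threshold on maximum centroid movement.
#' @return List with `centers` (k x 2 matrix), `cluster` (assignment of
#'   each point), `objective` (within-cluster sum of squares), `trace`
#'   (objective after each iteration of the winning restart) and
#'   `iterations`.
#' @export
fit_centroids <- function(points, k = 5, seed = 1, n_init = 10,
                          max_iter = 300, tol = 1e-6) {
  pts <- as.matrix(points[, c("x", "y")])
  check_finite(pts, "points")
  if (nrow(pts) < k)
    stop_respstage("need at least k points to fit k centroids",
                   "respstage_invalid_input")
  firsts <- with_seed(seed, sample.int(nrow(pts), min(n_init, nrow(pts)),
                                       replace = nrow(pts) < n_init))
  best <- NULL
  for (f in firsts) {
    fit <- lloyd_once(pts, k, f, max_iter, tol)
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  best
}
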