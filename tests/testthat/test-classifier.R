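test_that("the classification distance reproduces the worked example", {
  expect_identical(stage_distance(c(17.5, 3.5), c(17.5, 0)), 3.5)
  expect_identical(round(stage_distance(c(17.5, 3.5), c(13.5, 1)), 2), 4.72)
  expect_identical(stage_distance(c(1.2, 3.4), c(1.2, 3.4)), 0)
  expect_error(stage_distance(c(NA, 1), c(0, 0)),
               class = "respstage_invalid_input")
})

test_that("the distance satisfies the metric axioms", {
  set.seed(42)
  for (i in 1:200) {
    p <- stats::rnorm(2); q <- stats::rnorm(2); r <- stats::rnorm(2)
    dpq <- stage_distance(p, q)
    expect_gte(dpq, 0)
    expect_identical(dpq, stage_distance(q, p))
    expect_lte(stage_distance(p, r), dpq + stage_distance(q, r) + 1e-12)
  }
  expect_identical(stage_distance(c(0, 0), c(0, 0)), 0)
})

test_that("fit_centroids runs Lloyd iterations to a deterministic optimum", {
  set.seed(5)
  cl <- separated_clouds(n_per = 30, sd = 0.02)
  fit <- fit_centroids(cl$points, k = 5, seed = 1)
  # parameter recovery: each cloud mean found within 3 standard errors
  se <- 0.02 / sqrt(30)
  ord <- apply(respstage:::distance_matrix(as.matrix(cl$centers[, c("x", "y")]),
                                           fit$centers), 1, which.min)
  expect_length(unique(ord), 5)
  for (i in 1:5) {
    expect_lt(abs(fit$centers[ord[i], 1] - mean(cl$points$x[cl$points$stage == cl$centers$stage[i]])), 3 * se)
    expect_lt(abs(fit$centers[ord[i], 2] - mean(cl$points$y[cl$points$stage == cl$centers$stage[i]])), 3 * se)
  }
  # objective trace is non-increasing across Lloyd iterations
  expect_true(all(diff(fit$trace) <= 1e-9))
  # bit-identical refit under the same seed
  refit <- fit_centroids(cl$points, k = 5, seed = 1)
  expect_identical(fit$centers, refit$centers)
  expect_identical(fit$cluster, refit$cluster)

  # k = n: every point is its own centroid, objective 0
  tiny <- cl$points[c(1, 40, 80, 110, 140), ]
  fit0 <- fit_centroids(tiny, k = 5, seed = 2)
  expect_equal(fit0$objective, 0)

  expect_error(fit_centroids(cl$points[1:3, ], k = 5),
               class = "respstage_invalid_input")
})

test_that("fit_centroids agrees with stats::kmeans on well-separated data", {
  set.seed(6)
  cl <- separated_clouds(n_per = 40, sd = 0.03)
  ours <- fit_centroids(cl$points, k = 5, seed = 3)
  ref <- stats::kmeans(as.matrix(cl$points[, c("x", "y")]), centers = 5,
                       nstart = 10, iter.max = 100)
  sort_rows <- function(m) m[order(m[, 1], m[, 2]), , drop = FALSE]
  expect_equal(unname(sort_rows(ours$centers)),
               unname(sort_rows(ref$centers)), tolerance = 1e-6)
  expect_equal(ours$objective, ref$tot.withinss, tolerance = 1e-6)
})

test_that("label_centroids maps clusters to stages by majority vote", {
  centers <- matrix(c(0, 1, 0, 1), 2)
  # pure clusters: bijective map
  lab <- label_centroids(matrix(0, 5, 2), cluster = rep(1:5, each = 3),
                         labels = rep(stage_levels(), each = 3))
  expect_identical(as.character(lab$stage), stage_levels())

  # majority {N1:3, N2:1} -> N1
  lab2 <- label_centroids(centers, cluster = c(1, 1, 1, 1, 2, 2),
                          labels = c("N1", "N1", "N1", "N2", "N3", "N3"))
  expect_identical(as.character(lab2$stage), c("N1", "N3"))

  # strict mode: a tie is ambiguous
  expect_error(label_centroids(centers, cluster = c(1, 1, 1, 1, 2, 2),
                               labels = c("N1", "N1", "N2", "N2", "N3", "N3"),
                               mode = "strict"),
               class = "respstage_ambiguity_error")
  # strict mode: one stage claiming two clusters is ambiguous
  expect_error(label_centroids(centers, cluster = c(1, 1, 2, 2, 2),
                               labels = c("N1", "N1", "N1", "N1", "N2"),
                               mode = "strict"),
               class = "respstage_ambiguity_error")
  # lenient mode resolves both by largest count, then lowest cluster index
  len <- label_centroids(centers, cluster = c(1, 1, 2, 2, 2),
                         labels = c("N1", "N1", "N1", "N1", "N2"),
                         mode = "lenient")
  expect_identical(as.character(len$stage), c("N1", "N2"))

  # an unlabeled cluster is a coverage error
  expect_error(label_centroids(centers, cluster = c(1, 1),
                               labels = c("N1", "N1")),
               class = "respstage_coverage_error")
})

test_that("classify equals the brute-force nearest-centroid oracle", {
  set.seed(13)
  centroids <- data.frame(i = 1:5, x = stats::runif(5), y = stats::runif(5),
                          stage = as_stage(stage_levels()))
  pts <- data.frame(x = stats::runif(1000), y = stats::runif(1000))
  got <- classify(pts, centroids)
  oracle <- vapply(seq_len(nrow(pts)), function(j) {
    d <- vapply(seq_len(5), function(i)
      stage_distance(c(pts$x[j], pts$y[j]),
                     c(centroids$x[i], centroids$y[i])), numeric(1))
    as.character(centroids$stage[which.min(d)])
  }, character(1))
  expect_identical(as.character(got), oracle)

  # the worked example point goes to centroid A
  ab <- data.frame(i = 1:2, x = c(17.5, 13.5), y = c(0, 1),
                   stage = as_stage(c("AWAKE", "N1")))
  expect_identical(as.character(classify(data.frame(x = 17.5, y = 3.5), ab)),
                   "AWAKE")
  # a point on a centroid belongs to it; exact ties go to the lower index
  expect_identical(as.character(classify(data.frame(x = 13.5, y = 1), ab)),
                   "N1")
  tie <- data.frame(i = 1:2, x = c(-1, 1), y = c(0, 0),
                    stage = as_stage(c("N2", "N3")))
  expect_identical(as.character(classify(data.frame(x = 0, y = 0), tie)), "N2")

  unlab <- data.frame(i = 1:2, x = c(0, 1), y = c(0, 1),
                      stage = as_stage(c(NA, NA)))
  expect_error(classify(data.frame(x = 0, y = 0), unlab),
               class = "respstage_invalid_model")
})

test_that("stage_fit returns a working classed model object", {
  set.seed(8)
  cl <- separated_clouds(n_per = 20, sd = 0.02)
  f <- data.frame(rate_bpm = 10 + 2 * cl$points$x, voltage = 1 + cl$points$y,
                  stage = cl$points$stage)
  fit <- stage_fit(f, k = 5, weight = 0.1, seed = 1, labeling = "strict")
  expect_s3_class(fit, "stage_fit")
  expect_identical(sort(as.character(fit$centroids$stage)), sort(stage_levels()))
  expect_output(print(fit), "Nearest-centroid")
  expect_output(print(summary(fit)), "restart")
  expect_identical(dim(coef(fit)), c(5L, 2L))

  # predictions on the training data recover the labels on separated clouds
  expect_gt(mean(predict(fit, f) == as_stage(f$stage)), 0.95)

  # supervised mode puts centroids at per-stage means of scaled features
  sup <- stage_fit(f, mode = "supervised", weight = 0.1)
  sc <- apply_scaling(f, sup$scaling)
  for (s in stage_levels()) {
    expect_equal(sup$centroids$x[sup$centroids$stage == s],
                 mean(sc$x[as.character(sc$stage) == s]))
  }
})

test_that("model files round-trip bit-stably", {
  set.seed(9)
  cl <- separated_clouds(n_per = 10, sd = 0.02)
  f <- data.frame(rate_bpm = 10 + 2 * cl$points$x, voltage = 1 + cl$points$y,
                  stage = cl$points$stage)
  fit <- stage_fit(f, k = 5, seed = 4, labeling = "lenient")
  p1 <- tempfile(); p2 <- tempfile()
  write_stager(fit, p1)
  write_stager(fit, p2)
  expect_identical(readLines(p1), readLines(p2))
  back <- read_stager(p1)
  expect_identical(back$centroids, fit$centroids)
  expect_identical(back$scaling$weight, fit$scaling$weight)
  expect_identical(back$scaling$voltage_reference, fit$scaling$voltage_reference)
  p3 <- tempfile()
  write_stager(back, p3)
  expect_identical(readLines(p1), readLines(p3))
  expect_identical(as.character(predict(back, f)), as.character(predict(fit, f)))
})

test_that("classify_session emits one hypnogram record per window", {
  set.seed(10)
  cl <- separated_clouds(n_per = 10, sd = 0.02)
  f <- data.frame(rate_bpm = 10 + 2 * cl$points$x, voltage = 1 + cl$points$y,
                  stage = cl$points$stage)
  fit <- stage_fit(f, mode = "supervised")
  f$window_start_s <- 30 * (seq_len(nrow(f)) - 1)
  hyp <- classify_session(f, fit)
  expect_equal(nrow(hyp), nrow(f))
  expect_true(all(hyp$duration_s == 30))
  # composition: identical to window-by-window predict calls
  one_by_one <- vapply(seq_len(nrow(f)), function(i)
    as.character(predict(fit, f[i, ])), character(1))
  expect_identical(as.character(hyp$stage), one_by_one)

  empty <- classify_session(f[0, ], fit)
  expect_equal(nrow(empty), 0)
})

test_that("labeled-centroid classification is near-perfect on 4-sigma separated stages", {
  set.seed(14)
  cl <- separated_clouds(n_per = 40, sd = 0.25, sep = 2)  # 8 sd between centers
  # train/test split
  idx <- sample(nrow(cl$points), 100)
  f <- data.frame(rate_bpm = 10 + cl$points$x, voltage = 1 + cl$points$y,
                  stage = cl$points$stage)
  fit <- stage_fit(f[idx, ], k = 5, weight = 1, seed = 2, labeling = "lenient")
  acc <- mean(predict(fit, f[-idx, ]) == as_stage(f$stage[-idx]))
  expect_gte(acc, 0.95)
})
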