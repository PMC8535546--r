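# ---- K-means ------------------------------------------------------------

test_that("K-means is exact on separable toys", {
  X <- matrix(c(0, 1, 10, 11), ncol = 1)
  fit <- kmeans_fit(X, 2, n_restarts = 10, seed = 1)
  expect_equal(sort(fit$centroids[, 1]), c(0.5, 10.5))
  expect_equal(fit$sse, 1.0)
  # one point per cluster -> perfect fit
  Y <- matrix(c(0, 5, 9), ncol = 1)
  expect_equal(kmeans_fit(Y, 3, seed = 2)$sse, 0)
  expect_error(kmeans_fit(Y, 4), "k must be")
})

test_that("K-means attains the brute-force optimal SSE on small fixtures", {
  set.seed(17)
  for (case in 1:4) {
    n <- sample(5:8, 1)
    d <- sample(1:2, 1)
    X <- matrix(rnorm(n * d, sd = 3), n, d)
    for (k in 2:3) {
      fit <- kmeans_fit(X, k, n_restarts = 25, seed = case)
      expect_equal(fit$sse, brute_force_sse(X, k), tolerance = 1e-9)
    }
  }
})

test_that("K-means against the stats::kmeans reference on a planted mixture", {
  set.seed(23)
  X <- rbind(matrix(rnorm(40, 0), ncol = 2), matrix(rnorm(40, 6), ncol = 2))
  ours <- kmeans_fit(X, 2, n_restarts = 10, seed = 3)
  ref <- stats::kmeans(X, 2, nstart = 10)
  expect_equal(ours$sse, ref$tot.withinss, tolerance = 1e-8)
})

test_that("the SSE elbow curve is monotone and hits zero at k = n", {
  set.seed(9)
  X <- matrix(rnorm(12), 6, 2)
  curve <- sse_curve(X, 1:6, n_restarts = 25, seed = 4)
  expect_equal(curve$sse[6], 0, tolerance = 1e-12)
  expect_true(all(diff(curve$sse) <= 1e-9))
  expect_true(all(c(3, 4, 5) %in% curve$k))
})

# ---- BIRCH --------------------------------------------------------------

test_that("CF triples add exactly", {
  cf <- cf_merge(cf_triple(c(1, 0)), cf_triple(c(0, 1)))
  expect_equal(cf$n, 2L)
  expect_equal(cf$ls, c(1, 1))
  expect_equal(cf$ss, 2)
  cf2 <- cf_merge(cf, cf_triple(c(1, 1)))
  expect_equal(list(cf2$n, cf2$ls, cf2$ss), list(3L, c(2, 2), 4))
})

test_that("identical points collapse to one leaf CF of full count", {
  X <- matrix(rep(c(2, 3), each = 7), ncol = 2)
  fit <- birch_fit(X, threshold = 0.5, n_global_clusters = 3)
  expect_length(fit$leaves, 1L)
  expect_equal(fit$leaves[[1]]$n, 7L)
  expect_error(birch_fit(X, threshold = 0), "positive")
})

test_that("the root CF conserves the sum of all leaf CFs and radii obey the threshold", {
  set.seed(12)
  X <- matrix(rnorm(60 * 3), 60, 3)
  for (thr in c(0.4, 1.5)) {
    fit <- birch_fit(X, threshold = thr, branching = 4,
                     n_global_clusters = 4)
    acc <- Reduce(cf_merge, fit$leaves)
    expect_equal(acc$n, 60L)
    expect_equal(acc$ls, colSums(X))
    expect_equal(acc$ss, sum(X^2))
    expect_true(all(vapply(fit$leaves, cf_radius, numeric(1)) <= thr + 1e-12))
  }
})

test_that("the BIRCH threshold sweep spans the documented range", {
  set.seed(3)
  X <- rbind(matrix(rnorm(30, 0, .05), ncol = 2),
             matrix(rnorm(30, 4, .05), ncol = 2))
  for (thr in c(0.001, 0.1, 100)) {
    fit <- birch_fit(X, threshold = thr, n_global_clusters = 2)
    expect_true(all(fit$labels %in% 1:2))
  }
  # at a generous threshold the planted pair is still resolved globally
  fit <- birch_fit(X, threshold = 0.1, n_global_clusters = 2)
  expect_equal(length(unique(fit$labels[1:15])), 1L)
  expect_true(fit$labels[1] != fit$labels[16])
})

# ---- Affinity propagation ----------------------------------------------

test_that("similarities are negated squared distances with the preference on the diagonal", {
  X <- matrix(c(0, 1, 5), ncol = 1)
  S <- ap_similarity(X, "median")
  expect_equal(S[1, 2], -1)
  expect_equal(S[1, 3], -25)
  expect_equal(S[2, 3], -16)
  expect_equal(unname(diag(S)), rep(-16, 3))  # median off-diagonal
})

test_that("the first responsibility sweep matches the hand-computed value", {
  S <- ap_similarity(matrix(c(0, 1, 5), ncol = 1), "median")
  A <- matrix(0, 3, 3)
  R <- adherefit:::ap_responsibility(S, A)
  # r(1,2) = s(1,2) - max(s(1,1), s(1,3)) = -1 - (-16)
  expect_equal(R[1, 2], 15)
  expect_equal(R, naive_ap_responsibility(S, A), tolerance = 1e-12)
})

test_that("vectorized message updates equal the naive nested-loop oracle", {
  set.seed(21)
  for (n in 3:5) {
    X <- matrix(rnorm(n * 2), n, 2)
    S <- ap_similarity(X, "median")
    A <- matrix(rnorm(n * n), n, n); diag(A) <- abs(rnorm(n))
    R <- adherefit:::ap_responsibility(S, A)
    expect_equal(R, naive_ap_responsibility(S, A), tolerance = 1e-10)
    A2 <- adherefit:::ap_availability(R)
    expect_equal(A2, naive_ap_availability(R), tolerance = 1e-10)
  }
})

test_that("the criterion matrix is the sum of responsibilities and availabilities", {
  set.seed(6)
  X <- matrix(rnorm(16), 8, 2)
  fit <- ap_fit(X, damping = 0.7)
  expect_equal(fit$C, fit$R + fit$A)
})

test_that("degenerate AP cases behave as documented", {
  # a single point is its own exemplar
  one <- ap_fit(matrix(5, 1, 1))
  expect_equal(one$exemplars, 1L)
  expect_equal(one$labels, 1L)
  # uniform similarities with a lower preference give a single cluster
  X <- matrix(c(0, 2, 4), ncol = 1)  # equally spaced on a circle? no:
  # build uniform similarities directly: 3 points pairwise equidistant in 2D
  eq <- matrix(c(0, 0, 1, 0, 0.5, sqrt(3) / 2), 3, 2, byrow = TRUE)
  fit <- ap_fit(eq, damping = 0.8, preference = -10)
  expect_true(fit$converged)
  expect_equal(length(fit$exemplars), 1L)
  expect_equal(unique(fit$labels), 1L)
  expect_error(ap_fit(eq, damping = 0.3), "damping")
  expect_error(ap_fit(eq, damping = 1))
})

test_that("unconverged AP labels everything with the sentinel", {
  set.seed(2)
  X <- matrix(rnorm(20), 10, 2)
  fit <- ap_fit(X, damping = 0.9, max_iter = 3)
  expect_false(fit$converged)
  expect_equal(unique(fit$labels), -1L)
  expect_equal(assign_cluster(fit, X[1, ]), -1L)
})

# ---- assignment contract ------------------------------------------------

test_that("new points are assigned to the nearest centroid / leaf / exemplar", {
  km <- kmeans_fit(matrix(c(0, 0, 10, 10), ncol = 1), 2, seed = 1)
  lo <- which(km$centroids[, 1] == 0)
  hi <- which(km$centroids[, 1] == 10)
  expect_equal(assign_cluster(km, 4), lo)
  expect_equal(assign_cluster(km, 6), hi)
  expect_equal(assign_cluster(km, km$centroids[1, ]), 1L)
  expect_error(assign_cluster(km, c(1, 2)), "length")

  set.seed(14)
  X <- rbind(matrix(rnorm(20, 0, .1), ncol = 2),
             matrix(rnorm(20, 5, .1), ncol = 2))
  bi <- birch_fit(X, threshold = 0.5, n_global_clusters = 2)
  expect_equal(assign_cluster(bi, c(0, 0)), bi$labels[1])
  expect_equal(assign_cluster(bi, c(5, 5)), bi$labels[11])

  ap <- ap_fit(X, damping = 0.7)
  expect_true(ap$converged)
  expect_equal(assign_cluster(ap, c(0, 0)), ap$labels[1])
  expect_equal(assign_cluster(ap, c(5, 5)), ap$labels[11])
})
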