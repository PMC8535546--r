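# Independent oracles used across the suite.

# Exhaustive K-means oracle: minimum SSE over every assignment of n points
# to k groups (empty groups allowed, equivalent to <= k clusters).
brute_force_sse <- function(X, k) {
  X <- as.matrix(X)
  n <- nrow(X)
  best <- Inf
  assign <- rep(1L, n)
  repeat {
    sse <- 0
    for (j in unique(assign)) {
      pts <- X[assign == j, , drop = FALSE]
      ctr <- colMeans(pts)
      sse <- sse + sum(sweep(pts, 2, ctr)^2)
    }
    if (sse < best) best <- sse
    # odometer increment over k^n assignments
    i <- 1L
    while (i <= n && assign[i] == k) { assign[i] <- 1L; i <- i + 1L }
    if (i > n) break
    assign[i] <- assign[i] + 1L
  }
  best
}

# Naive nested-loop affinity-propagation updates, straight from the
# responsibility / availability definitions.
naive_ap_responsibility <- function(S, A) {
  n <- nrow(S)
  R <- matrix(0, n, n)
  for (i in 1:n) for (k in 1:n) {
    others <- setdiff(1:n, k)
    R[i, k] <- S[i, k] - max(A[i, others] + S[i, others])
  }
  R
}

naive_ap_availability <- function(R) {
  n <- nrow(R)
  A <- matrix(0, n, n)
  for (i in 1:n) for (k in 1:n) {
    if (i == k) {
      A[k, k] <- sum(pmax(0, R[setdiff(1:n, k), k]))
    } else {
      others <- setdiff(1:n, c(i, k))
      A[i, k] <- min(0, R[k, k] + sum(pmax(0, R[others, k])))
    }
  }
  A
}

# Stub forecasters for ensemble arithmetic tests. Values are emitted on a
# fixed seconds scale via a shared transform so the arithmetic is exact.
stub_scale <- 10000
make_stub_const <- function(value, user_id = "stub") {
  stopifnot(value >= 0, value <= stub_scale)
  m <- trained_regressor(kind = "stub_const",
                         fit = list(value = value),
                         spec = list(lookback = 7L),
                         transform = list(min = 0, range = stub_scale),
                         train_mae = 0)
  m
}
registerS3method("predict_one_step", "stub_const_regressor",
                 function(model, window, ...) {
                   rep(model$fit$value / stub_scale,
                       nrow(matrix(window, ncol = model$lookback)))
                 },
                 envir = asNamespace("adherefit"))

make_stub_echo <- function(user_id = "echo") {
  trained_regressor(kind = "stub_echo", fit = list(),
                    spec = list(lookback = 7L),
                    transform = list(min = 0, range = stub_scale),
                    train_mae = 0)
}
registerS3method("predict_one_step", "stub_echo_regressor",
                 function(model, window, ...) {
                   w <- matrix(window, ncol = model$lookback)
                   w[, ncol(w)]
                 },
                 envir = asNamespace("adherefit"))

# Build a framework_model directly from stub members (bypassing training).
stub_framework <- function(members, centroids, tau = 60,
                           preset = "missed_months") {
  clustering <- structure(list(centroids = centroids, k = nrow(centroids),
                               sse = 0, iterations = 1L,
                               labels = seq_len(nrow(centroids))),
                          class = "centroid_model")
  structure(list(clustering = clustering, method = "kmeans",
                 labels = vapply(members, `[[`, integer(1), "cluster"),
                 preset = preset, standardize = FALSE,
                 center = NULL, scale = NULL,
                 members = members, regressor_kind = "stub", tau = tau,
                 user_ids = vapply(members, `[[`, character(1), "user_id")),
            class = "framework_model")
}

# Tiny deterministic session fixtures.
sessions_csv_fixture <- function() {
  c("user_id,start_time,duration_s,finished",
    "u1,2021-03-01T10:00:00,300,true",
    "u1,2021-03-02T11:30:00,150,YES")
}

sessions_json_fixture <- function() {
  paste0('[',
    '{"user_id":"u1","start_time":"2021-03-01T10:00:00","duration_s":100,"finished":true},',
    '{"user_id":"u1","start_time":"2021-03-01T18:00:00","duration_s":50,"finished":true},',
    '{"user_id":"u1","start_time":"2021-03-03T10:00:00","duration_s":200,"finished":true},',
    '{"user_id":"u2","start_time":"2021-03-01T10:00:00","finished":true},',
    '{"user_id":"u2","start_time":"2021-03-02T10:00:00","duration_s":400,"finished":false}',
    ']')
}
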