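# K-means with k-means++ seeding and an explicit, restorable RNG stream.
# The objective is the sum of squared Euclidean distances of every point to
# its assigned centroid (SSE); assignment and centroid-update steps alternate
# until no assignment changes.

#' Fit K-means
#'
#' Lloyd iterations with k-means++ seeding, best of `n_restarts` by SSE.
#' An empty cluster arising mid-iteration is re-seeded at the point farthest
#' from its assigned centroid. Deterministic given `seed`.
#'
#' @param X numeric matrix (rows = points).
#' @param k number of clusters, `1 <= k <= nrow(X)`.
#' @param max_iter maximum Lloyd iterations per restart.
#' @param n_restarts independent seedings; the solution with lowest SSE wins.
#' @param seed integer seed for the seeding RNG.
#' @return A `centroid_model`: list with `centroids` (k x d), `labels`,
#'   `sse`, `iterations`, `k`.
#' @export
kmeans_fit <- function(X, k, max_iter = 100L, n_restarts = 10L, seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (k < 1L || k > n) stop("k must be in [1, nrow(X)]", call. = FALSE)
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      fit <- kmeans_once(X, k, max_iter)
      if (is.null(best) || fit$sse < best$sse) best <- fit
    }
  })
  structure(c(best, list(k = k)), class = "centroid_model")
}

kmeans_once <- function(X, k, max_iter) {
  n <- nrow(X)
  cent <- X[kmeanspp_init(X, k), , drop = FALSE]
  labels <- integer(n)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    d2 <- dist2_to_centroids(X, cent)
    new_labels <- max.col(-d2, ties.method = "first")
    # empty cluster: re-seed at the point farthest from its centroid
    for (j in seq_len(k)) {
      if (!any(new_labels == j)) {
        far <- which.max(d2[cbind(seq_len(n), new_labels)])
        cent[j, ] <- X[far, ]
        new_labels[far] <- j
      }
    }
    changed <- any(new_labels != labels)
    labels <- new_labels
    for (j in seq_len(k))
      cent[j, ] <- colMeans(X[labels == j, , drop = FALSE])
    if ((!changed && iter > 1L) || iter >= max_iter) break
  }
  d2 <- dist2_to_centroids(X, cent)
  labels <- max.col(-d2, ties.method = "first")
  sse <- sum(d2[cbind(seq_len(n), labels)])
  list(centroids = cent, labels = labels, sse = sse, iterations = iter)
}

# k-means++: first centre uniform, then proportional to squared distance
kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  idx <- sample.int(n, 1L)
  if (k > 1L) {
    for (j in 2:k) {
      d2 <- apply(dist2_to_centroids(X, X[idx, , drop = FALSE]), 1, min)
      if (sum(d2) == 0) {
        idx <- c(idx, sample.int(n, 1L))
      } else {
        idx <- c(idx, sample.int(n, 1L, prob = d2))
      }
    }
  }
  idx
}

# n x k matrix of squared Euclidean distances
dist2_to_centroids <- function(X, cent) {
  cp <- tcrossprod(X, cent)  # n x k
  xn <- rowSums(X^2)
  cn <- rowSums(cent^2)
  d2 <- outer(xn, cn, "+") - 2 * cp
  d2[d2 < 0] <- 0
  d2
}

#' @export
print.centroid_model <- function(x, ...) {
  cat("K-means model: k =", x$k, "- SSE", signif(x$sse, 6),
      "in", x$iterations, "iterations\n")
  invisible(x)
}

#' SSE elbow curve
#'
#' Best-of-restarts SSE for each candidate number of clusters, used to read
#' off the elbow when choosing k.
#'
#' @inheritParams kmeans_fit
#' @param k_range integer vector of candidate k values.
#' @return `data.frame(k, sse)`.
#' @export
sse_curve <- function(X, k_range, max_iter = 100L, n_restarts = 10L,
                      seed = 1L) {
  sse <- vapply(k_range, function(k)
    kmeans_fit(X, k, max_iter, n_restarts, seed)$sse, numeric(1))
  data.frame(k = as.integer(k_range), sse = sse)
}

# Evaluate an RNG-dependent expression under `seed`, restoring global state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
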