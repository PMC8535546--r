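# BIRCH: one pass over the data builds a CF tree whose leaf entries are
# cluster-feature triples (count, linear sum, squared sum); a second, global
# phase agglomerates the leaf-entry centroids into the requested number of
# clusters. A CF's radius is sqrt(ss/n - ||ls/n||^2) and every leaf entry is
# kept at or below the user threshold.

# ---- CF triple arithmetic ----------------------------------------------

#' Cluster-feature triple
#'
#' The BIRCH summary of a subcluster: how many points it holds (`n`), their
#' coordinate-wise linear sum (`ls`) and the scalar sum of squared
#' coordinates (`ss`). CF triples are additive: merging two subclusters sums
#' all three fields.
#'
#' @param x a point (numeric vector), or `NULL` for an empty CF of dimension
#'   `d`.
#' @param d dimension (only used when `x` is `NULL`).
#' @return A `cf_triple` list with fields `n`, `ls`, `ss`.
#' @export
cf_triple <- function(x = NULL, d = length(x)) {
  if (is.null(x)) {
    structure(list(n = 0L, ls = numeric(d), ss = 0), class = "cf_triple")
  } else {
    structure(list(n = 1L, ls = as.numeric(x), ss = sum(x^2)),
              class = "cf_triple")
  }
}

#' Merge two CF triples
#' @param a,b `cf_triple` objects.
#' @return Their sum (a `cf_triple`).
#' @export
cf_merge <- function(a, b) {
  structure(list(n = a$n + b$n, ls = a$ls + b$ls, ss = a$ss + b$ss),
            class = "cf_triple")
}

#' CF centroid and radius
#' @param cf a `cf_triple`.
#' @return `cf_centroid`: the mean vector; `cf_radius`: root-mean-square
#'   distance of the subcluster's points to that mean.
#' @export
cf_centroid <- function(cf) cf$ls / cf$n

#' @rdname cf_centroid
#' @export
cf_radius <- function(cf) {
  r2 <- cf$ss / cf$n - sum((cf$ls / cf$n)^2)
  sqrt(max(r2, 0))
}

# ---- CF tree ------------------------------------------------------------

# Nodes are environments so insertion can update CFs in place.
# node$leaf: logical; node$entries: list of list(cf = <cf_triple>,
# child = <node or NULL>).

new_node <- function(leaf) {
  e <- new.env(parent = emptyenv())
  e$leaf <- leaf
  e$entries <- list()
  e
}

node_cf <- function(node, d) {
  acc <- cf_triple(NULL, d)
  for (en in node$entries) acc <- cf_merge(acc, en$cf)
  acc
}

nearest_entry <- function(node, x) {
  best <- 1L; bd <- Inf
  for (i in seq_along(node$entries)) {
    cen <- cf_centroid(node$entries[[i]]$cf)
    d2 <- sum((x - cen)^2)
    if (d2 < bd) { bd <- d2; best <- i }
  }
  best
}

# Insert x into the subtree; returns NULL or a list of two replacement
# entries when the node split.
cf_insert <- function(node, x, threshold, branching) {
  if (node$leaf) {
    if (length(node$entries) > 0L) {
      i <- nearest_entry(node, x)
      cand <- cf_merge(node$entries[[i]]$cf, cf_triple(x))
      if (cf_radius(cand) <= threshold) {
        node$entries[[i]]$cf <- cand
        return(NULL)
      }
    }
    node$entries[[length(node$entries) + 1L]] <-
      list(cf = cf_triple(x), child = NULL)
  } else {
    i <- nearest_entry(node, x)
    split <- cf_insert(node$entries[[i]]$child, x, threshold, branching)
    if (is.null(split)) {
      node$entries[[i]]$cf <- cf_merge(node$entries[[i]]$cf, cf_triple(x))
      return(NULL)
    }
    node$entries[[i]] <- split[[1L]]
    node$entries[[length(node$entries) + 1L]] <- split[[2L]]
  }
  if (length(node$entries) > branching) return(split_node(node))
  NULL
}

# Split an overfull node around its two farthest-apart entry centroids.
split_node <- function(node) {
  cents <- t(vapply(node$entries, function(en) cf_centroid(en$cf),
                    numeric(length(node$entries[[1L]]$cf$ls))))
  dm <- as.matrix(dist(cents))
  far <- which(dm == max(dm), arr.ind = TRUE)[1L, ]
  n1 <- new_node(node$leaf); n2 <- new_node(node$leaf)
  for (i in seq_along(node$entries)) {
    tgt <- if (dm[i, far[1L]] <= dm[i, far[2L]]) n1 else n2
    tgt$entries[[length(tgt$entries) + 1L]] <- node$entries[[i]]
  }
  d <- length(node$entries[[1L]]$cf$ls)
  list(list(cf = node_cf(n1, d), child = n1),
       list(cf = node_cf(n2, d), child = n2))
}

collect_leaf_cfs <- function(node) {
  if (node$leaf) return(lapply(node$entries, function(en) en$cf))
  out <- list()
  for (en in node$entries) out <- c(out, collect_leaf_cfs(en$child))
  out
}

#' Fit BIRCH
#'
#' Phase 1 scans the data once, absorbing each point into the nearest leaf
#' CF entry whose radius stays at or below `threshold` (otherwise opening a
#' new entry; nodes split when they exceed the branching factor). Phase 2
#' agglomerates the leaf-entry centroids with average-linkage hierarchical
#' clustering into `n_global_clusters` global labels.
#'
#' @param X numeric matrix (rows = points).
#' @param threshold radius bound for leaf CF entries (> 0), in the units of
#'   `X` (raw seconds for unstandardized features).
#' @param branching maximum entries per tree node.
#' @param n_global_clusters number of clusters produced by the global phase.
#' @return A `cf_tree_model`: leaf CF triples, their centroids, global
#'   labels per leaf entry, the root CF, and per-point labels.
#' @export
birch_fit <- function(X, threshold, branching = 50L, n_global_clusters = 4L) {
  X <- as.matrix(X)
  if (!is.numeric(threshold) || threshold <= 0)
    stop("threshold must be positive", call. = FALSE)
  root <- new_node(leaf = TRUE)
  for (i in seq_len(nrow(X))) {
    split <- cf_insert(root, X[i, ], threshold, branching)
    if (!is.null(split)) {
      nr <- new_node(leaf = FALSE)
      nr$entries <- split
      root <- nr
    }
  }
  leaves <- collect_leaf_cfs(root)
  cents <- t(vapply(leaves, cf_centroid, numeric(ncol(X))))
  ng <- min(n_global_clusters, length(leaves))
  leaf_labels <- if (length(leaves) == 1L) 1L else
    cutree(hclust(dist(cents), method = "average"), k = ng)
  model <- structure(list(
    threshold = threshold, branching = branching,
    leaves = leaves, leaf_centroids = cents,
    leaf_labels = as.integer(leaf_labels),
    root_cf = node_cf(root, ncol(X)),
    n_clusters = ng, dim = ncol(X)
  ), class = "cf_tree_model")
  model$labels <- apply(X, 1, function(x) assign_cluster(model, x))
  model
}

#' @export
print.cf_tree_model <- function(x, ...) {
  cat("BIRCH model:", length(x$leaves), "leaf CFs, threshold", x$threshold,
    "->", x$n_clusters, "global clusters\n")
  invisible(x)
}
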