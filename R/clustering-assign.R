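#' Assign a new point to a fitted cluster
#'
#' Uniform assignment contract across the three clustering models:
#' * `centroid_model` (K-means): nearest centroid, ties to the lowest index;
#' * `cf_tree_model` (BIRCH): the global label of the nearest leaf-entry
#'   centroid;
#' * `ap_state` (affinity propagation): the cluster of the nearest exemplar,
#'   or the sentinel `-1` when the fit did not converge.
#'
#' @param model a fitted clustering model.
#' @param fv numeric vector with the model's feature dimension.
#' @param ... unused.
#' @return Integer cluster id.
#' @export
assign_cluster <- function(model, fv, ...) UseMethod("assign_cluster")

#' @export
assign_cluster.centroid_model <- function(model, fv, ...) {
  fv <- check_dim(fv, ncol(model$centroids))
  d2 <- colSums((t(model$centroids) - fv)^2)
  which.min(d2)  # which.min takes the lowest index on ties
}

#' @export
assign_cluster.cf_tree_model <- function(model, fv, ...) {
  fv <- check_dim(fv, model$dim)
  d2 <- colSums((t(model$leaf_centroids) - fv)^2)
  model$leaf_labels[which.min(d2)]
}

#' @export
assign_cluster.ap_state <- function(model, fv, ...) {
  if (!model$converged || length(model$exemplars) == 0L) return(-1L)
  fv <- check_dim(fv, model$dim)
  d2 <- colSums((t(model$exemplar_points) - fv)^2)
  which.min(d2)
}

check_dim <- function(fv, d) {
  fv <- as.numeric(fv)
  if (length(fv) != d)
    stop("feature vector has length ", length(fv), ", model expects ", d,
         call. = FALSE)
  fv
}

#' Number of clusters of a fitted model
#' @param model a fitted clustering model.
#' @return Integer count (AP: number of exemplars; 0 if unconverged).
#' @export
n_clusters <- function(model) UseMethod("n_clusters")

#' @export
n_clusters.centroid_model <- function(model) model$k

#' @export
n_clusters.cf_tree_model <- function(model) model$n_clusters

#' @export
n_clusters.ap_state <- function(model) length(model$exemplars)
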