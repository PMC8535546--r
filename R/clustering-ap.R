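# Affinity propagation. Similarity between distinct points is the negated
# sum of squared coordinate differences; the diagonal of S holds the
# preference p. Responsibilities and availabilities are updated in damped
# sweeps
#   r(i,k) <- s(i,k) - max_{k' != k} [ a(i,k') + s(i,k') ]
#   a(k,k) <- sum_{i' != k} max(0, r(i',k))
#   a(i,k) <- min(0, r(k,k) + sum_{i' not in {i,k}} max(0, r(i',k)))
# with new = lambda * old + (1 - lambda) * computed, until the exemplar set
# (points whose criterion diagonal r(k,k) + a(k,k) is positive) is stable
# for `convergence_iter` consecutive sweeps. On non-convergence every label
# is the sentinel -1.

#' Negative squared-distance similarity matrix
#'
#' @param X numeric matrix (rows = points).
#' @param preference value for the diagonal of S, or `"median"` for the
#'   median off-diagonal similarity (low preferences give few clusters).
#' @return n x n similarity matrix.
#' @export
ap_similarity <- function(X, preference = "median") {
  X <- as.matrix(X)
  S <- -dist2_to_centroids(X, X)
  if (identical(preference, "median")) {
    offdiag <- S[row(S) != col(S)]
    preference <- if (length(offdiag)) median(offdiag) else 0
  }
  diag(S) <- preference
  S
}

#' Fit affinity propagation
#'
#' @param X numeric matrix (rows = points).
#' @param damping message-damping factor lambda in `[0.5, 1)`.
#' @param preference diagonal of the similarity matrix (scalar or
#'   `"median"`, the default).
#' @param max_iter maximum sweeps.
#' @param convergence_iter sweeps the exemplar set must stay unchanged.
#' @param seed seed for the infinitesimal similarity jitter that breaks
#'   exact message ties (degenerate, perfectly symmetric inputs otherwise
#'   never elect an exemplar). Identical seeds give identical trajectories.
#' @return An `ap_state`: matrices `S`, `R`, `A`, criterion `C = R + A`,
#'   `exemplars` (row indices), `exemplar_points`, per-point `labels`
#'   (1-based cluster ids; all `-1` if unconverged), `converged`,
#'   `damping`, `preference`.
#' @export
ap_fit <- function(X, damping = 0.7, preference = "median",
                   max_iter = 200L, convergence_iter = 15L, seed = 0L) {
  if (damping < 0.5 || damping >= 1)
    stop("damping must be in [0.5, 1)", call. = FALSE)
  X <- as.matrix(X)
  n <- nrow(X)
  if (n == 1L) {  # a single point is trivially its own exemplar
    S <- ap_similarity(X, preference)
    return(structure(list(S = S, R = matrix(0, 1, 1), A = matrix(0, 1, 1),
                          C = matrix(0, 1, 1), exemplars = 1L,
                          exemplar_points = X, labels = 1L,
                          converged = TRUE, iterations = 0L,
                          damping = damping, preference = S[1, 1],
                          dim = ncol(X)),
                     class = "ap_state"))
  }
  S <- ap_similarity(X, preference)
  scale <- max(abs(S[is.finite(S)]), 1)
  S <- S + with_seed(seed, matrix(runif(n * n, -1, 1), n, n)) * 1e-10 * scale
  R <- matrix(0, n, n)
  A <- matrix(0, n, n)
  stable <- 0L
  prev_ex <- rep(FALSE, n)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    R <- damping * R + (1 - damping) * ap_responsibility(S, A)
    A <- damping * A + (1 - damping) * ap_availability(R)
    ex <- diag(R) + diag(A) > 0
    if (identical(ex, prev_ex) && any(ex)) stable <- stable + 1L
    else stable <- 0L
    prev_ex <- ex
    if (stable >= convergence_iter) { converged <- TRUE; break }
  }
  exemplars <- which(prev_ex)
  labels <- rep(-1L, n)
  if (converged && length(exemplars)) {
    # each point joins its most similar exemplar; exemplars keep their own
    Se <- S[, exemplars, drop = FALSE]
    labels <- max.col(Se, ties.method = "first")
    labels[exemplars] <- seq_along(exemplars)
  } else {
    exemplars <- integer(0)
    converged <- FALSE
  }
  structure(list(
    S = S, R = R, A = A, C = R + A,
    exemplars = exemplars,
    exemplar_points = X[exemplars, , drop = FALSE],
    labels = labels, converged = converged, iterations = it,
    damping = damping,
    preference = S[1L, 1L], dim = ncol(X)
  ), class = "ap_state")
}

# One full (undamped) responsibility update, vectorized over rows.
ap_responsibility <- function(S, A) {
  n <- nrow(S)
  AS <- A + S
  # per row: largest and second-largest of a(i,k') + s(i,k')
  first_idx <- max.col(AS, ties.method = "first")
  first_val <- AS[cbind(seq_len(n), first_idx)]
  AS2 <- AS
  AS2[cbind(seq_len(n), first_idx)] <- -Inf
  second_val <- AS2[cbind(seq_len(n), max.col(AS2, ties.method = "first"))]
  Rnew <- S - first_val            # subtract row max everywhere ...
  fix <- cbind(seq_len(n), first_idx)
  Rnew[fix] <- S[fix] - second_val # ... except at the argmax column
  Rnew
}

# One full (undamped) availability update.
ap_availability <- function(R) {
  n <- nrow(R)
  Rp <- pmax(R, 0)
  diag(Rp) <- diag(R)              # r(k,k) enters with its sign
  colsum <- colSums(Rp)
  Anew <- matrix(colsum, n, n, byrow = TRUE) - Rp
  dA <- diag(Anew)                 # a(k,k) = sum_{i' != k} max(0, r(i',k))
  Anew <- pmin(Anew, 0)
  diag(Anew) <- dA
  Anew
}

#' @export
print.ap_state <- function(x, ...) {
  cat("Affinity propagation:",
      if (x$converged) paste(length(x$exemplars), "exemplars in",
                             x$iterations, "sweeps")
      else paste("did not converge in", x$iterations, "sweeps (labels -1)"),
      "\n")
  invisible(x)
}
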