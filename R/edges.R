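#' Number of unique edges for a node count
#'
#' @param n_nodes Number of atlas nodes.
#' @return Integer count `n_nodes * (n_nodes - 1) / 2`.
#' @export
#' @examples
#' n_edges(268)
n_edges <- function(n_nodes) {
  stopifnot(length(n_nodes) == 1, n_nodes >= 2, n_nodes == round(n_nodes))
  as.integer(n_nodes * (n_nodes - 1) / 2)
}

# Inverse of n_edges(); errors when E is not a triangular number.
nodes_from_edges <- function(E) {
  n <- (1 + sqrt(1 + 8 * E)) / 2
  if (abs(n - round(n)) > 1e-8) {
    abort(sprintf("%d edges does not correspond to an integer node count", E))
  }
  as.integer(round(n))
}

#' Canonical edge ordering
#'
#' Every edge vector, mask, and export in the package uses one canonical
#' ordering of the unique node pairs: upper triangle with `node_i < node_j`,
#' row-major, i.e. (1,2), (1,3), ..., (1,n), (2,3), (2,4), ...
#' A single convention everywhere prevents silent mask misalignment.
#'
#' @param n_nodes Number of atlas nodes.
#' @return A tibble with columns `edge` (1-based position in the canonical
#'   vector), `node_i`, `node_j` (1-based node indices, `node_i < node_j`).
#' @export
#' @examples
#' edge_index(4)
edge_index <- function(n_nodes) {
  w <- which(lower.tri(matrix(0, n_nodes, n_nodes)), arr.ind = TRUE)
  # column-major traversal of the lower triangle visits (i, j) pairs, i < j,
  # in exactly the canonical row-major upper-triangle order
  tibble(
    edge = seq_len(nrow(w)),
    node_i = as.integer(w[, "col"]),
    node_j = as.integer(w[, "row"])
  )
}

#' Flatten a connectivity matrix into the canonical edge vector
#'
#' @param cm Symmetric numeric matrix with zero diagonal (e.g. from
#'   [build_connectome()]).
#' @param tol Symmetry/diagonal tolerance.
#' @return Numeric vector of length `n_nodes * (n_nodes - 1) / 2` in canonical
#'   edge order (see [edge_index()]).
#' @export
vectorize_edges <- function(cm, tol = 1e-8) {
  cm <- as.matrix(cm)
  if (nrow(cm) != ncol(cm)) abort("connectivity matrix must be square")
  if (max(abs(cm - t(cm))) > tol) abort("connectivity matrix is not symmetric")
  if (max(abs(diag(cm))) > tol) abort("connectivity matrix diagonal must be zero")
  cm[lower.tri(cm)]
}

#' Rebuild a connectivity matrix from a canonical edge vector
#'
#' Inverse of [vectorize_edges()].
#'
#' @param v Numeric edge vector in canonical order.
#' @param n_nodes Node count; inferred from `length(v)` when omitted.
#' @return Symmetric matrix with zero diagonal.
#' @export
devectorize_edges <- function(v, n_nodes = NULL) {
  if (is.null(n_nodes)) n_nodes <- nodes_from_edges(length(v))
  if (length(v) != n_edges(n_nodes)) {
    abort(sprintf(
      "edge vector length %d does not match %d nodes (expected %d)",
      length(v), n_nodes, n_edges(n_nodes)
    ))
  }
  m <- matrix(0, n_nodes, n_nodes)
  m[lower.tri(m)] <- v
  m + t(m)
}
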