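# Canonical undirected simple binary graph used by every other module.

#' Construct a binary graph from an adjacency matrix
#'
#' The package-wide graph container: an undirected simple graph with a
#' symmetric 0/1 adjacency matrix, zero diagonal, degree vector `k` and edge
#' count `m`. Node indexing is 1-based in R; labels are carried on the matrix
#' dimnames and in `node_labels`.
#'
#' @param A square numeric matrix with entries in \{0,1\}, symmetric, zero
#'   diagonal.
#' @param node_labels character vector of unique node labels; defaults to
#'   `rownames(A)` or `"v1"..."vn"`.
#' @return An object of class `graynet_graph`: a list with elements `n`,
#'   `node_labels`, `A`, `k` (degrees) and `m` (edge count).
#' @examples
#' g <- graph_from_adjacency(matrix(c(0, 1, 1, 0), 2, 2))
#' g$m
#' @export
graph_from_adjacency <- function(A, node_labels = NULL) {
  if (!is.matrix(A) || nrow(A) != ncol(A)) {
    stop("adjacency must be a square matrix", call. = FALSE)
  }
  n <- nrow(A)
  if (is.null(node_labels)) {
    node_labels <- if (!is.null(rownames(A))) rownames(A) else sprintf("v%d", seq_len(n))
  }
  if (length(node_labels) != n) stop("node_labels length must equal nrow(A)", call. = FALSE)
  if (anyDuplicated(node_labels)) stop("node labels must be unique", call. = FALSE)
  A <- A * 1  # coerce logical input
  if (!all(A %in% c(0, 1))) stop("adjacency entries must be 0 or 1", call. = FALSE)
  if (!isTRUE(all.equal(A, t(A), check.attributes = FALSE))) {
    stop("adjacency must be symmetric", call. = FALSE)
  }
  if (any(diag(A) != 0)) stop("self-loops are not allowed (diagonal must be zero)", call. = FALSE)
  dimnames(A) <- list(node_labels, node_labels)
  k <- as.numeric(rowSums(A))
  structure(
    list(n = n, node_labels = as.character(node_labels), A = A, k = k, m = sum(k) / 2),
    class = "graynet_graph"
  )
}

#' Construct a binary graph from an edge list
#'
#' Duplicate edges (in either orientation) collapse to a single edge with a
#' warning; self-loops and endpoints absent from `node_labels` are errors.
#'
#' @param edges two-column matrix or data frame of endpoint labels (may have
#'   zero rows).
#' @param node_labels ordered character vector of all node labels, including
#'   isolated nodes.
#' @return A `graynet_graph`.
#' @examples
#' graph_from_edges(cbind(c("a", "b"), c("b", "c")), c("a", "b", "c", "d"))
#' @export
graph_from_edges <- function(edges, node_labels) {
  node_labels <- as.character(node_labels)
  if (anyDuplicated(node_labels)) stop("node labels must be unique", call. = FALSE)
  n <- length(node_labels)
  A <- matrix(0, n, n, dimnames = list(node_labels, node_labels))
  if (!is.null(edges) && NROW(edges) > 0) {
    edges <- as.matrix(edges)
    if (ncol(edges) != 2) stop("edges must have two columns", call. = FALSE)
    i <- match(as.character(edges[, 1]), node_labels)
    j <- match(as.character(edges[, 2]), node_labels)
    if (anyNA(i) || anyNA(j)) {
      bad <- unique(c(edges[is.na(i), 1], edges[is.na(j), 2]))
      stop("unknown endpoint label(s): ", paste(bad, collapse = ", "), call. = FALSE)
    }
    if (any(i == j)) stop("self-loops are not allowed", call. = FALSE)
    key <- paste(pmin(i, j), pmax(i, j))
    if (anyDuplicated(key)) {
      warning(sum(duplicated(key)), " duplicate edge(s) collapsed", call. = FALSE)
    }
    A[cbind(i, j)] <- 1
    A[cbind(j, i)] <- 1
  }
  graph_from_adjacency(A, node_labels)
}

#' @export
print.graynet_graph <- function(x, ...) {
  cat(sprintf(
    "graynet_graph: %d nodes, %d edges (density %.3f)\n",
    x$n, x$m, if (x$n >= 2) x$m / choose(x$n, 2) else NA_real_
  ))
  invisible(x)
}

#' Connected components
#'
#' Breadth-first search partition of the node set. Singletons are included.
#' Components are ordered by their smallest member index and each component's
#' members are sorted.
#'
#' @param g a `graynet_graph`.
#' @return list of integer vectors of node indices.
#' @export
connected_components <- function(g) {
  stopifnot(inherits(g, "graynet_graph"))
  n <- g$n
  if (n == 0) return(list())
  comp <- integer(n)  # 0 = unvisited
  ncomp <- 0L
  for (start in seq_len(n)) {
    if (comp[start] != 0L) next
    ncomp <- ncomp + 1L
    queue <- start
    comp[start] <- ncomp
    while (length(queue) > 0) {
      v <- queue[1]
      queue <- queue[-1]
      nb <- which(g$A[v, ] == 1 & comp == 0L)
      comp[nb] <- ncomp
      queue <- c(queue, nb)
    }
  }
  unname(split(seq_len(n), comp))
}

#' Graph density and sparsity
#'
#' Density is m / (n(n-1)/2); sparsity is the complementary fraction of
#' absent edges. Both are reported because the literature uses "sparsity"
#' both ways.
#'
#' @param g a `graynet_graph` with at least 2 nodes.
#' @return list with `density` and `sparsity` (they sum to 1 exactly).
#' @export
density_and_sparsity <- function(g) {
  stopifnot(inherits(g, "graynet_graph"))
  if (g$n < 2) stop("density undefined for graphs with fewer than 2 nodes", call. = FALSE)
  d <- g$m / (g$n * (g$n - 1) / 2)
  list(density = d, sparsity = 1 - d)
}

# Internal: subgraph induced on a member index set, preserving labels.
induced_subgraph_bin <- function(g, members) {
  graph_from_adjacency(g$A[members, members, drop = FALSE], g$node_labels[members])
}

# Internal: edge list (i < j index pairs) of a graph.
edge_index_list <- function(g) {
  idx <- which(upper.tri(g$A) & g$A == 1, arr.ind = TRUE)
  idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
}
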