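# Newman spectral modularity: modularity matrix, shifted power-iteration
# bipartition, generalized subgraph matrices, Q-threshold recursive division.

#' Optimizer settings for spectral and ternary division
#'
#' @param restarts number of random initial vectors per division (>= 1).
#' @param tol convergence tolerance: L-infinity change of the normalized
#'   power-iteration iterate.
#' @param max_iter power-iteration cap; on non-convergence the best iterate
#'   is used with a warning, never an error.
#' @param refine apply a single Kernighan-Lin-style sign-flip pass after each
#'   spectral split.
#' @param exhaustive_cap largest n the brute-force oracles accept.
#' @return list of settings, class `opt_settings`.
#' @export
opt_settings <- function(restarts = 32L, tol = 1e-10, max_iter = 10000L,
                         refine = TRUE, exhaustive_cap = 12L) {
  stopifnot(restarts >= 1, tol > 0, max_iter >= 1)
  structure(list(restarts = as.integer(restarts), tol = tol,
                 max_iter = as.integer(max_iter), refine = isTRUE(refine),
                 exhaustive_cap = as.integer(exhaustive_cap)),
            class = "opt_settings")
}

#' Modularity matrix B = A - k k^T / (2m)
#'
#' Rows and columns of B sum to zero, so the all-ones assignment always
#' scores 0.
#'
#' @param g a `graynet_graph` with at least one edge.
#' @return object of class `modularity_matrix`: list with `B`, `m`, `n`.
#' @export
modularity_matrix <- function(g) {
  stopifnot(inherits(g, "graynet_graph"))
  if (g$m < 1) stop("modularity undefined for an edgeless graph", call. = FALSE)
  B <- g$A - tcrossprod(g$k) / (2 * g$m)
  structure(list(B = B, m = g$m, n = g$n), class = "modularity_matrix")
}

#' Generalized modularity matrix of a subgraph
#'
#' Newman's correction for recursive division: B^g_ij = B_ij - delta_ij *
#' sum_{l in members} B_il, so that rows of B^g sum to zero and division
#' contributions stay additive.
#'
#' @param B a `modularity_matrix` (of the full graph, or any matrix whose
#'   rows the members index).
#' @param members non-empty integer vector of node indices.
#' @return object of class `subgraph_modularity_matrix`: list with `B`
#'   (n_g x n_g), `m` (parent edge count), `members`, `n`.
#' @export
subgraph_modularity_matrix <- function(B, members) {
  stopifnot(inherits(B, c("modularity_matrix", "subgraph_modularity_matrix")))
  members <- as.integer(members)
  if (length(members) == 0) stop("member set must be non-empty", call. = FALSE)
  # Always correct from the matrix handed in; diagonal-only corrections
  # compose, so correcting B^g of a parent equals correcting B directly.
  Bsub <- B$B[members, members, drop = FALSE]
  diag(Bsub) <- diag(Bsub) - rowSums(Bsub)
  structure(list(B = Bsub, m = B$m, members = members, n = length(members)),
            class = "subgraph_modularity_matrix")
}

#' Modularity of a bipartition sign vector
#'
#' Q(s) = s^T B s / (4m) for s in \{-1,+1\}^n. No maximization is performed.
#'
#' @param B a `modularity_matrix` or `subgraph_modularity_matrix`.
#' @param s vector of -1/+1 of matching length.
#' @return scalar Q (or Delta-Q for a subgraph matrix).
#' @export
bipartition_score <- function(B, s) {
  stopifnot(inherits(B, c("modularity_matrix", "subgraph_modularity_matrix")))
  if (length(s) != nrow(B$B)) stop("sign vector length must match matrix order", call. = FALSE)
  if (!all(s %in% c(-1, 1))) stop("sign vector entries must be -1 or +1", call. = FALSE)
  as.numeric(s %*% B$B %*% s) / (4 * B$m)
}

#' Modularity of a ternary assignment vector
#'
#' Q_e(s_e) = s_e^T B s_e / (4m) for s_e in \{-1,0,+1\}^n. Restricted to
#' \{-1,+1\} entries this equals [bipartition_score()] exactly.
#'
#' @inheritParams bipartition_score
#' @param s_e vector of -1/0/+1 of matching length.
#' @return scalar Q_e (or Delta-Q_e for a subgraph matrix).
#' @export
ternary_score <- function(B, s_e) {
  stopifnot(inherits(B, c("modularity_matrix", "subgraph_modularity_matrix")))
  if (length(s_e) != nrow(B$B)) stop("vector length must match matrix order", call. = FALSE)
  if (!all(s_e %in% c(-1, 0, 1))) stop("entries must be -1, 0 or +1", call. = FALSE)
  as.numeric(s_e %*% B$B %*% s_e) / (4 * B$m)
}

# Internal: block power iteration for the most-positive eigenvector of B.
# The plain iteration converges to the eigenvalue of LARGEST MAGNITUDE, which
# can be the most negative one, so we iterate on B + shift*I with the
# Gershgorin bound shift = max_i sum_j |B_ij| making all eigenvalues
# non-negative. Columns of the returned matrix are the converged iterates for
# each restart.
power_leading <- function(B, restarts, tol, max_iter, seed) {
  n <- nrow(B)
  shift <- max(rowSums(abs(B)))
  X <- with_seed(seed, matrix(stats::rnorm(n * restarts), n, restarts))
  X <- sweep(X, 2, sqrt(colSums(X^2)), "/")
  if (shift == 0) return(X)  # B == 0: any vector is an eigenvector
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    Y <- B %*% X + shift * X
    nrm <- sqrt(colSums(Y^2))
    nrm[nrm == 0] <- 1
    Y <- sweep(Y, 2, nrm, "/")
    delta <- max(abs(Y - X))
    X <- Y
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warning("power iteration did not converge within max_iter; using best iterate",
            call. = FALSE)
  }
  X
}

# Internal: one greedy single-node sign-flip pass (Kernighan-Lin style) in a
# seeded random order. Flipping s_i changes s^T B s by -4 s_i g_i where
# g_i = (Bs)_i - B_ii s_i.
refine_flip_pass <- function(B, s, seed) {
  ord <- with_seed(seed, sample.int(length(s)))
  Bs <- as.numeric(B %*% s)
  for (i in ord) {
    g_i <- Bs[i] - B[i, i] * s[i]
    if (-4 * s[i] * g_i > 1e-12) {
      Bs <- Bs - 2 * s[i] * B[, i]
      s[i] <- -s[i]
    }
  }
  s
}

#' Leading spectral bipartition
#'
#' Shifted power iteration from `restarts` seeded random start vectors; each
#' converged vector is signed (zero components become +1), optionally
#' sharpened by one sign-flip refinement pass, and the best-scoring sign
#' vector is returned. Deterministic given `seed`. An all-equal sign vector
#' (score 0) signals an indivisible module.
#'
#' @param B a `modularity_matrix` or `subgraph_modularity_matrix`.
#' @param opt an [opt_settings()] list.
#' @param seed integer seed.
#' @return list with `s` (the sign vector) and `contribution` (its Q or
#'   Delta-Q).
#' @export
leading_bipartition <- function(B, opt = opt_settings(), seed = 1L) {
  stopifnot(inherits(B, c("modularity_matrix", "subgraph_modularity_matrix")))
  n <- nrow(B$B)
  if (n == 1) return(list(s = 1, contribution = as.numeric(B$B[1, 1]) / (4 * B$m)))
  X <- power_leading(B$B, opt$restarts, opt$tol, opt$max_iter, seed)
  S <- sign(X)
  S[S == 0] <- 1
  best_s <- NULL
  best_q <- -Inf
  for (r in seq_len(opt$restarts)) {
    s <- S[, r]
    if (opt$refine) s <- refine_flip_pass(B$B, s, derive_seed(seed, c(r, n)))
    q <- as.numeric(s %*% B$B %*% s) / (4 * B$m)
    if (q > best_q + 1e-12) {
      best_q <- q
      best_s <- s
    }
  }
  list(s = unname(best_s), contribution = best_q)
}

#' Exhaustive bipartition oracle
#'
#' Enumerates all 2^n sign vectors (the all-equal vectors, scoring 0, are
#' included) and returns the maximum of Q(s). Intended as an independent
#' test oracle for small graphs.
#'
#' @inheritParams leading_bipartition
#' @param cap refuse matrices larger than this (default 16).
#' @return list with `s` and `contribution`.
#' @export
brute_force_bipartition <- function(B, cap = 16L) {
  stopifnot(inherits(B, c("modularity_matrix", "subgraph_modularity_matrix")))
  n <- nrow(B$B)
  if (n > cap) stop("brute force capped at n = ", cap, call. = FALSE)
  S <- as.matrix(expand.grid(rep(list(c(-1, 1)), n), KEEP.OUT.ATTRS = FALSE))
  q <- rowSums((S %*% B$B) * S) / (4 * B$m)
  top <- which(q >= max(q) - 1e-12)
  pick <- top[do.call(order, as.data.frame(S[top, , drop = FALSE]))[1]]
  list(s = unname(S[pick, ]), contribution = max(q))
}

# Internal: build the full recursive division forest. Isolated (degree-zero)
# nodes become singleton leaves; the remaining graph -- connected or not --
# grows a single division tree from its whole-graph modularity matrix, so the
# first division of, e.g., two disjoint cliques is the root division with
# contribution Q. A node is expanded iff its best division is proper (both
# signs present) and its contribution >= bar. Per-division seeds derive from
# (seed, member set), so the forest built at bar = min(thresholds) prunes
# exactly to the forest recursive_divide would build at any larger threshold.
# method: "sign" (Q / Delta-Q) or "ternary" (Q_e / Delta-Q_e).
# gray_membership: where zero-assigned nodes go ("both" children or "neither").
build_division_forest <- function(g, bar, opt, seed, method = c("sign", "ternary"),
                                  gray_membership = c("both", "neither")) {
  method <- match.arg(method)
  gray_membership <- match.arg(gray_membership)

  divide <- function(Bmat_obj, members, depth) {
    # Bmat_obj$B is indexed in the order of `members` (original graph indices)
    node <- list(members = members, contribution = NA_real_, assignment = NULL,
                 children = NULL, depth = depth)
    if (length(members) == 1) return(node)
    dseed <- derive_seed(seed, members)
    res <- if (method == "sign") {
      leading_bipartition(Bmat_obj, opt, dseed)
    } else {
      optimize_ternary(Bmat_obj, opt, dseed)
    }
    s <- res$s
    node$contribution <- res$contribution
    node$assignment <- s
    proper <- any(s == 1) && any(s == -1)
    if (!proper || res$contribution < bar) return(node)
    if (method == "sign") {
      plus <- members[s == 1]
      minus <- members[s == -1]
    } else if (gray_membership == "both") {
      plus <- members[s >= 0]
      minus <- members[s <= 0]
    } else {
      plus <- members[s == 1]
      minus <- members[s == -1]
    }
    node$children <- lapply(list(plus, minus), function(ch) {
      Bchild <- subgraph_modularity_matrix(Bmat_obj, match(ch, members))
      divide(Bchild, ch, depth + 1)
    })
    node
  }

  isolated <- which(g$k == 0)
  active <- which(g$k > 0)
  forest <- lapply(isolated, function(v) {
    list(members = v, contribution = NA_real_, assignment = NULL,
         children = NULL, depth = 0)
  })
  if (length(active) > 0) {
    # B restricted to non-isolated nodes equals the whole-graph B there
    # (isolated rows/columns of B are zero), so m and k are unchanged.
    Bc <- modularity_matrix(induced_subgraph_bin(g, active))
    forest <- c(forest, list(divide(Bc, active, 0)))
  }
  forest
}

# Internal: collect final modules of a forest pruned at threshold tau.
forest_modules <- function(forest, tau) {
  walk <- function(node) {
    divided <- !is.null(node$children) && node$contribution >= tau
    if (!divided) return(list(node$members))
    unlist(lapply(node$children, walk), recursive = FALSE)
  }
  unlist(lapply(forest, walk), recursive = FALSE)
}

# Internal: gray nodes (zero-assigned in accepted divisions) pruned at tau.
# Returns list(gray = integer vector, by_depth = list depth -> integer vector).
forest_gray <- function(forest, tau) {
  by_depth <- list()
  walk <- function(node) {
    divided <- !is.null(node$children) && node$contribution >= tau
    if (!divided) return(invisible(NULL))
    zeros <- node$members[node$assignment == 0]
    d <- as.character(node$depth)
    by_depth[[d]] <<- sort(unique(c(by_depth[[d]], zeros)))
    lapply(node$children, walk)
    invisible(NULL)
  }
  lapply(forest, walk)
  gray <- sort(unique(unlist(by_depth)))
  list(gray = if (is.null(gray)) integer(0) else gray, by_depth = by_depth)
}

#' Recursive spectral division into modules
#'
#' Divides the graph by repeated leading bipartitions. The first division of
#' a connected component is accepted iff its modularity Q >= `q_threshold`;
#' each further division of a module is accepted iff its additive
#' contribution Delta-Q >= `q_threshold`. Singleton modules are never
#' divided. Disconnected inputs grow a single division tree (the recursion
#' separates components on its own when that pays); isolated nodes are
#' singleton modules from the start.
#'
#' @param g a `graynet_graph` with at least one edge.
#' @param q_threshold indivisibility threshold (>= 0).
#' @param opt an [opt_settings()] list.
#' @param seed integer seed; fixes the whole decomposition.
#' @return object of class `module_decomposition`: `modules` (list of node
#'   index vectors), `module_labels`, `tree` (the division forest),
#'   `q_threshold`.
#' @export
recursive_divide <- function(g, q_threshold, opt = opt_settings(), seed = 1L) {
  stopifnot(inherits(g, "graynet_graph"))
  if (g$m < 1) stop("recursive division requires at least one edge", call. = FALSE)
  if (q_threshold < 0) stop("q_threshold must be >= 0", call. = FALSE)
  forest <- build_division_forest(g, q_threshold, opt, seed, "sign")
  mods <- forest_modules(forest, q_threshold)
  structure(list(
    modules = mods,
    module_labels = lapply(mods, function(ix) g$node_labels[ix]),
    tree = forest, q_threshold = q_threshold, seed = seed
  ), class = "module_decomposition")
}

#' @export
print.module_decomposition <- function(x, ...) {
  cat(sprintf("module_decomposition: %d modules at Q-threshold %g (sizes: %s)\n",
              length(x$modules), x$q_threshold,
              paste(sort(lengths(x$modules), decreasing = TRUE), collapse = ", ")))
  invisible(x)
}

#' Module count across a Q-threshold sweep
#'
#' Builds the division forest once at the smallest threshold and prunes it at
#' each threshold; per-division seeds depend only on the member set, so this
#' equals running [recursive_divide()] at every threshold. Counts are
#' non-increasing in the threshold.
#'
#' @param g a `graynet_graph` with at least one edge.
#' @param thresholds ascending numeric vector of Q-thresholds (>= 0).
#' @param opt an [opt_settings()] list.
#' @param seed integer seed.
#' @return data.frame with columns `threshold`, `modules`.
#' @export
module_count_curve <- function(g, thresholds, opt = opt_settings(), seed = 1L) {
  if (is.unsorted(thresholds)) stop("thresholds must be ascending", call. = FALSE)
  forest <- build_division_forest(g, min(thresholds), opt, seed, "sign")
  data.frame(threshold = thresholds,
             modules = vapply(thresholds, function(tau) length(forest_modules(forest, tau)),
                              numeric(1)))
}

#' Direct multi-group modularity of a partition
#'
#' Q = sum_g [e_g/m - (d_g/(2m))^2] where e_g is the number of edges inside
#' group g and d_g its total degree. Used to check that recursive division
#' contributions are additive.
#'
#' @param g a `graynet_graph` with at least one edge.
#' @param modules list of node-index vectors partitioning the nodes.
#' @return scalar Q.
#' @export
partition_modularity <- function(g, modules) {
  stopifnot(inherits(g, "graynet_graph"), g$m >= 1)
  sum(vapply(modules, function(ix) {
    e_g <- sum(g$A[ix, ix, drop = FALSE]) / 2
    d_g <- sum(g$k[ix])
    e_g / g$m - (d_g / (2 * g$m))^2
  }, numeric(1)))
}
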