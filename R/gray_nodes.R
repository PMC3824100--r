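# Extended (ternary) modularity Q_e and gray-node identification.
#
# Q_e relaxes the bipartition sign vector to entries in {-1, 0, +1}; nodes
# assigned 0 in an accepted division are "gray": shared by both resulting
# modules at once (or, optionally, by neither). The proportion of gray nodes
# indexes the overlapping modular architecture of the network.

#' Heuristic ternary maximization of extended modularity
#'
#' No closed-form relaxation exists for the ternary problem, so a seeded
#' local search is used: the search starts from the sign vector returned by
#' [leading_bipartition()] (so the result never falls below the best
#' bipartition found) and sweeps nodes in a seeded random order, each time
#' re-assigning the node to the best of \{-1, 0, +1\} with the others held
#' fixed, until a local optimum; further restarts perturb the start vector.
#' The all-zero vector is rejected. Ties across restarts are broken toward
#' fewest zeros, then lexicographically.
#'
#' @param B a `modularity_matrix` or `subgraph_modularity_matrix`.
#' @param opt an [opt_settings()] list (`restarts` also controls the number
#'   of perturbed local searches).
#' @param seed integer seed; the result is deterministic given the seed.
#' @return list with `s` (ternary vector) and `contribution` (Q_e or
#'   Delta-Q_e).
#' @export
optimize_ternary <- function(B, opt = opt_settings(), seed = 1L) {
  stopifnot(inherits(B, c("modularity_matrix", "subgraph_modularity_matrix")))
  C <- B$B
  n <- nrow(C)
  fourm <- 4 * B$m
  if (n == 1) return(list(s = 1, contribution = as.numeric(C[1, 1]) / fourm))

  s0 <- leading_bipartition(B, opt, derive_seed(seed, 1L))$s

  sweep_to_optimum <- function(s, sweep_seed) {
    Cs <- as.numeric(C %*% s)
    for (pass in seq_len(200L)) {
      changed <- FALSE
      ord <- with_seed(derive_seed(sweep_seed, pass), sample.int(n))
      for (i in ord) {
        g_i <- Cs[i] - C[i, i] * s[i]
        # f(v) = C_ii v^2 + 2 v g_i + const for v in {-1, 0, +1}
        vals <- C[i, i] * c(1, 0, 1) + 2 * c(-1, 0, 1) * g_i
        cur <- C[i, i] * s[i]^2 + 2 * s[i] * g_i
        j <- which.max(vals)
        if (vals[j] > cur + 1e-12) {
          v <- c(-1, 0, 1)[j]
          Cs <- Cs + C[, i] * (v - s[i])
          s[i] <- v
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    s
  }

  best <- NULL
  best_q <- -Inf
  best_zeros <- Inf
  for (r in seq_len(opt$restarts)) {
    start <- if (r == 1) {
      s0
    } else {
      with_seed(derive_seed(seed, c(2L, r)), {
        pert <- s0
        flip <- stats::runif(n) < 0.15
        pert[flip] <- sample(c(-1, 0, 1), sum(flip), replace = TRUE)
        pert
      })
    }
    s <- sweep_to_optimum(start, derive_seed(seed, c(3L, r)))
    if (all(s == 0)) next  # degenerate division, rejected
    q <- as.numeric(s %*% C %*% s) / fourm
    nz <- sum(s == 0)
    better <- q > best_q + 1e-12 ||
      (abs(q - best_q) <= 1e-12 &&
         (nz < best_zeros ||
            (nz == best_zeros && !is.null(best) && lex_less(s, best))))
    if (better) {
      best <- s
      best_q <- q
      best_zeros <- nz
    }
  }
  if (is.null(best)) {  # every restart collapsed to all-zero; fall back
    best <- s0
    best_q <- as.numeric(s0 %*% C %*% s0) / fourm
  }
  list(s = best, contribution = best_q)
}

# Internal: strict lexicographic comparison of two numeric vectors.
lex_less <- function(a, b) {
  d <- a - b
  i <- which(d != 0)
  length(i) > 0 && d[i[1]] < 0
}

#' Exhaustive ternary oracle
#'
#' Enumerates all 3^n ternary vectors and returns the maximum of Q_e. Ties
#' are broken by fewest zeros, then lexicographic order. Independent test
#' oracle; refuses n above `cap`.
#'
#' @inheritParams optimize_ternary
#' @param cap refuse matrices larger than this (default 12).
#' @return list with `s` and `contribution`.
#' @export
brute_force_ternary <- function(B, cap = 12L) {
  stopifnot(inherits(B, c("modularity_matrix", "subgraph_modularity_matrix")))
  n <- nrow(B$B)
  if (n > cap) stop("brute force capped at n = ", cap, call. = FALSE)
  S <- as.matrix(expand.grid(rep(list(c(-1, 0, 1)), n), KEEP.OUT.ATTRS = FALSE))
  q <- rowSums((S %*% B$B) * S) / (4 * B$m)
  qmax <- max(q)
  top <- which(q >= qmax - 1e-12)
  zeros <- rowSums(S[top, , drop = FALSE] == 0)
  top <- top[zeros == min(zeros)]
  pick <- top[do.call(order, as.data.frame(S[top, , drop = FALSE]))[1]]
  list(s = unname(S[pick, ]), contribution = qmax)
}

#' Recursive division with gray nodes
#'
#' Same recursion as [recursive_divide()] but every division maximizes the
#' extended modularity Q_e (or Delta-Q_e) over ternary vectors. Nodes
#' assigned 0 at an accepted division are recorded as gray and, under the
#' default `gray_membership = "both"`, passed to both child modules, so the
#' final modules may overlap; under `"neither"` they are dropped from both
#' children.
#'
#' @inheritParams recursive_divide
#' @param gray_membership `"both"` (default) or `"neither"`.
#' @return object of class `gray_decomposition`: `modules` (possibly
#'   overlapping node-index sets), `module_labels`, `gray_nodes` (indices
#'   zeroed in at least one accepted division), `gray_labels`,
#'   `gray_proportion`, `gray_by_depth` (per-recursion-level breakdown),
#'   `tree`, `q_threshold`.
#' @export
recursive_divide_gray <- function(g, q_threshold, opt = opt_settings(), seed = 1L,
                                  gray_membership = c("both", "neither")) {
  stopifnot(inherits(g, "graynet_graph"))
  if (g$m < 1) stop("recursive division requires at least one edge", call. = FALSE)
  if (q_threshold < 0) stop("q_threshold must be >= 0", call. = FALSE)
  gray_membership <- match.arg(gray_membership)
  forest <- build_division_forest(g, q_threshold, opt, seed, "ternary", gray_membership)
  mods <- forest_modules(forest, q_threshold)
  gr <- forest_gray(forest, q_threshold)
  structure(list(
    modules = mods,
    module_labels = lapply(mods, function(ix) g$node_labels[ix]),
    gray_nodes = gr$gray,
    gray_labels = g$node_labels[gr$gray],
    gray_proportion = length(gr$gray) / g$n,
    gray_by_depth = gr$by_depth,
    tree = forest, q_threshold = q_threshold, seed = seed
  ), class = "gray_decomposition")
}

#' @export
print.gray_decomposition <- function(x, ...) {
  cat(sprintf(
    "gray_decomposition: %d modules at Q-threshold %g; %d gray node(s) (proportion %.3f)\n",
    length(x$modules), x$q_threshold, length(x$gray_nodes), x$gray_proportion))
  invisible(x)
}

#' Gray-node proportion across a Q-threshold sweep
#'
#' As [module_count_curve()] but for the proportion of gray nodes: the
#' ternary division forest is built once at the smallest threshold and
#' pruned per threshold.
#'
#' @inheritParams module_count_curve
#' @param gray_membership `"both"` (default) or `"neither"`.
#' @return data.frame with columns `threshold`, `gray_proportion`,
#'   `modules`.
#' @export
gray_proportion_curve <- function(g, thresholds, opt = opt_settings(), seed = 1L,
                                  gray_membership = c("both", "neither")) {
  if (is.unsorted(thresholds)) stop("thresholds must be ascending", call. = FALSE)
  gray_membership <- match.arg(gray_membership)
  forest <- build_division_forest(g, min(thresholds), opt, seed, "ternary", gray_membership)
  data.frame(
    threshold = thresholds,
    gray_proportion = vapply(thresholds, function(tau) {
      length(forest_gray(forest, tau)$gray) / g$n
    }, numeric(1)),
    modules = vapply(thresholds, function(tau) length(forest_modules(forest, tau)),
                     numeric(1))
  )
}
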