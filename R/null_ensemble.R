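# Degree-matched random-graph nulls and Monte-Carlo mean +/- sd curves.

#' Degree-preserving randomization by double edge swaps
#'
#' Repeatedly picks two distinct edges (a,b), (c,d) and rewires them to
#' (a,d), (c,b), rejecting any swap that would create a self-loop or a
#' duplicate edge. The degree sequence and edge count are preserved exactly.
#' Attempts (not successes) are counted: `swaps_per_edge * m` attempts are
#' made, capped at `100 * m`.
#'
#' @param g a `graynet_graph`.
#' @param swaps_per_edge attempted swaps per edge (default 10, a common
#'   burn-in for double-edge-swap randomization).
#' @param seed integer seed; output is deterministic given the seed.
#' @return a `graynet_graph` with the same labels, degrees and edge count.
#'   Graphs with fewer than 2 edges are returned unchanged with a warning.
#' @export
rewire_degree_preserving <- function(g, swaps_per_edge = 10L, seed = 1L) {
  stopifnot(inherits(g, "graynet_graph"))
  if (g$m < 2) {
    warning("fewer than 2 edges; returning the input unchanged", call. = FALSE)
    return(g)
  }
  A <- g$A
  E <- edge_index_list(g)
  m <- nrow(E)
  attempts <- min(swaps_per_edge * m, 100 * m)
  with_seed(seed, {
    pair_idx <- matrix(sample.int(m, 2 * attempts, replace = TRUE), ncol = 2)
    flip <- stats::runif(attempts) < 0.5
  })
  for (t in seq_len(attempts)) {
    e1 <- pair_idx[t, 1]
    e2 <- pair_idx[t, 2]
    if (e1 == e2) next
    a <- E[e1, 1]; b <- E[e1, 2]
    c <- E[e2, 1]; d <- E[e2, 2]
    if (flip[t]) { tmp <- c; c <- d; d <- tmp }
    # rewire to (a,d) and (c,b)
    if (a == d || c == b) next
    if (A[a, d] == 1 || A[c, b] == 1) next
    A[a, b] <- 0; A[b, a] <- 0
    A[c, d] <- 0; A[d, c] <- 0
    A[a, d] <- 1; A[d, a] <- 1
    A[c, b] <- 1; A[b, c] <- 1
    E[e1, ] <- c(min(a, d), max(a, d))
    E[e2, ] <- c(min(c, b), max(c, b))
  }
  graph_from_adjacency(A, g$node_labels)
}

#' Monte-Carlo null curves for a graph metric
#'
#' Generates `reps` independently rewired degree-matched random graphs
#' (child seeds derive from the master seed and replicate index) and
#' evaluates the metric curve on each, returning the per-threshold mean and
#' standard deviation, as used to draw the random-graph comparison curves
#' with 1-sigma error bars.
#'
#' @param g observed `graynet_graph`.
#' @param metric `"module_count"` or `"gray_proportion"`.
#' @param thresholds ascending Q-threshold sweep.
#' @param reps replicate count (default 1000).
#' @param seed master seed.
#' @param opt an [opt_settings()] list passed to the decomposition.
#' @param swaps_per_edge passed to [rewire_degree_preserving()].
#' @return object of class `null_ensemble_summary`: `metric_name`,
#'   `thresholds`, `mean`, `sd`, `skewness`, `reps`, `seed`.
#' @export
ensemble_curves <- function(g, metric = c("module_count", "gray_proportion"),
                            thresholds, reps = 1000L, seed = 1L,
                            opt = opt_settings(), swaps_per_edge = 10L) {
  metric <- match.arg(metric)
  stopifnot(reps >= 1)
  eval_metric <- function(gr, rep_seed) {
    if (metric == "module_count") {
      module_count_curve(gr, thresholds, opt, rep_seed)$modules
    } else {
      gray_proportion_curve(gr, thresholds, opt, rep_seed)$gray_proportion
    }
  }
  vals <- matrix(NA_real_, reps, length(thresholds))
  for (r in seq_len(reps)) {
    child <- derive_seed(seed, c(101L, r))
    gr <- rewire_degree_preserving(g, swaps_per_edge, child)
    vals[r, ] <- eval_metric(gr, derive_seed(seed, c(202L, r)))
  }
  mu <- colMeans(vals)
  sdv <- if (reps > 1) apply(vals, 2, stats::sd) else rep(0, length(thresholds))
  skew <- vapply(seq_along(thresholds), function(j) {
    x <- vals[, j]
    s <- stats::sd(x)
    if (reps < 3 || s == 0) return(0)
    mean((x - mean(x))^3) / s^3
  }, numeric(1))
  structure(list(metric_name = metric, thresholds = thresholds, mean = mu,
                 sd = sdv, skewness = skew, reps = as.integer(reps),
                 seed = as.integer(seed)),
            class = "null_ensemble_summary")
}

#' @export
print.null_ensemble_summary <- function(x, ...) {
  cat(sprintf("null_ensemble_summary: %s over %d degree-matched replicates, %d thresholds\n",
              x$metric_name, x$reps, length(x$thresholds)))
  invisible(x)
}

#' Compare an observed curve to its null ensemble
#'
#' z = (observed - null mean) / null sd per threshold; where sd = 0 the
#' z-score is undefined and flagged (`"equal, degenerate"` if the observed
#' value equals the degenerate null, `"unequal, degenerate"` otherwise).
#'
#' @param observed numeric vector aligned with `summary$thresholds`, or a
#'   data.frame from [module_count_curve()] / [gray_proportion_curve()].
#' @param summary a `null_ensemble_summary`.
#' @return data.frame with `threshold`, `observed`, `null_mean`, `null_sd`,
#'   `z`, `within_1sd`, `flag`.
#' @export
compare_to_null <- function(observed, summary) {
  stopifnot(inherits(summary, "null_ensemble_summary"))
  if (is.data.frame(observed)) {
    if (!isTRUE(all.equal(observed$threshold, summary$thresholds))) {
      stop("observed and null thresholds are misaligned", call. = FALSE)
    }
    observed <- observed[[if ("modules" %in% names(observed) &&
                              summary$metric_name == "module_count") "modules"
                          else "gray_proportion"]]
  }
  if (length(observed) != length(summary$thresholds)) {
    stop("observed and null thresholds are misaligned", call. = FALSE)
  }
  z <- ifelse(summary$sd > 0, (observed - summary$mean) / summary$sd, NA_real_)
  flag <- ifelse(summary$sd > 0, "ok",
                 ifelse(observed == summary$mean, "equal, degenerate",
                        "unequal, degenerate"))
  data.frame(threshold = summary$thresholds, observed = observed,
             null_mean = summary$mean, null_sd = summary$sd, z = z,
             within_1sd = abs(observed - summary$mean) <= summary$sd,
             flag = flag)
}
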