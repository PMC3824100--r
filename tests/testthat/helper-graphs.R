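# Fixture builders shared across test files. Everything is generated in code.

k4 <- function() {
  A <- matrix(1, 4, 4)
  diag(A) <- 0
  graph_from_adjacency(A)
}

# two disjoint complete graphs of size `size`
two_cliques <- function(size = 4) {
  n <- 2 * size
  A <- matrix(0, n, n)
  A[1:size, 1:size] <- 1
  A[(size + 1):n, (size + 1):n] <- 1
  diag(A) <- 0
  graph_from_adjacency(A)
}

# the shared-node illustration: two K4s sharing nodes 3 and 4 (6 nodes, 11 edges)
shared_clique_graph <- function() shared_node_modules(2, 4, 2)

# seeded Erdos-Renyi graph; optionally resample until connected
random_graph <- function(n, p, seed, connected = FALSE) {
  for (try in 0:200) {
    set.seed(seed + 1000L * try)
    A <- matrix(0, n, n)
    ut <- upper.tri(A)
    A[ut] <- as.numeric(stats::runif(sum(ut)) < p)
    A <- A + t(A)
    g <- graph_from_adjacency(A)
    if (!connected || length(connected_components(g)) == 1) return(g)
  }
  stop("could not sample a connected graph")
}

# small cohort spec used in pipeline tests: two blocks of 10 covering all regions
small_cohort_spec <- function(seed, rho_in = 0.8, rho_out = 0.1, scale_b = 1) {
  cohort_spec(n_subjects = 21L, regions = sprintf("parc_%02d", 1:20),
              blocks = list(1:10, 11:20), rho_in = rho_in, rho_out = rho_out,
              group_covariance_scale = scale_b, seed = seed)
}

# label-agnostic set-of-sets comparison
same_partition <- function(a, b) {
  norm <- function(x) {
    x <- lapply(x, sort)
    x[order(vapply(x, function(v) v[1], numeric(1)))]
  }
  isTRUE(all.equal(norm(a), norm(b)))
}

# reduced optimizer settings for simulation-heavy tests: fewer restarts (the
# shifted power iteration is start-insensitive) and a looser tolerance that
# still converges well before max_iter on the graphs used here
fast_opt <- function() opt_settings(restarts = 4L, tol = 1e-6, max_iter = 10000L)
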