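test_that("ternary_score extends bipartition_score consistently", {
  g <- shared_clique_graph()
  B <- modularity_matrix(g)

  # zero-free ternary vectors score identically to sign vectors
  set.seed(5)
  for (i in 1:10) {
    s <- sample(c(-1, 1), 6, replace = TRUE)
    expect_identical(ternary_score(B, s), bipartition_score(B, s))
  }
  expect_equal(ternary_score(B, rep(0, 6)), 0)

  # hand-evaluated fixture: zeroing the two shared nodes scores 1/11
  # (m = 11; s'Bs = 4 for s = (+1,+1,0,0,-1,-1))
  expect_equal(ternary_score(B, c(1, 1, 0, 0, -1, -1)), 1 / 11)
  expect_error(ternary_score(B, c(2, 0, 0, 0, 0, 0)), "-1, 0 or \\+1")
})

test_that("brute_force_ternary maximizes over the full ternary space", {
  gk2 <- graph_from_edges(cbind("a", "b"), c("a", "b"))
  res <- brute_force_ternary(modularity_matrix(gk2))
  expect_equal(res$contribution, 0)
  expect_equal(sum(res$s == 0), 0)  # tie-break prefers the zero-free vector

  # superset of the sign space: ternary max >= sign max
  for (seed in 1:8) {
    g <- random_graph(7, 0.45, seed, connected = TRUE)
    B <- modularity_matrix(g)
    expect_gte(brute_force_ternary(B)$contribution,
               brute_force_bipartition(B)$contribution - 1e-12)
  }

  # two disjoint K4s: the pure bipartition is already optimal, no gray nodes
  res2 <- brute_force_ternary(modularity_matrix(two_cliques(4)))
  expect_equal(res2$contribution, 0.5)
  expect_equal(sum(res2$s == 0), 0)

  # shared-clique graph: maximum 1/11 attained by zeroing the shared nodes
  res3 <- brute_force_ternary(modularity_matrix(shared_clique_graph()))
  expect_equal(res3$contribution, 1 / 11)
  expect_equal(which(res3$s == 0), c(3, 4))

  big <- modularity_matrix(random_graph(13, 0.3, 1))
  expect_error(brute_force_ternary(big), "capped")
})

test_that("optimize_ternary matches the exhaustive oracle on small graphs", {
  B_shared <- modularity_matrix(shared_clique_graph())
  res <- optimize_ternary(B_shared, seed = 7)
  expect_equal(res$contribution, brute_force_ternary(B_shared)$contribution)
  expect_equal(which(res$s == 0), c(3, 4))

  # feasibility bound: at least the best bipartition, never above the oracle
  for (seed in 1:10) {
    g <- random_graph(sample(5:8, 1), 0.5, seed * 31, connected = TRUE)
    B <- modularity_matrix(g)
    lower <- leading_bipartition(B, seed = seed)$contribution
    upper <- brute_force_ternary(B)$contribution
    got <- optimize_ternary(B, seed = seed)$contribution
    expect_gte(got, lower - 1e-12)
    expect_lte(got, upper + 1e-9)
  }

  res_2k4 <- optimize_ternary(modularity_matrix(two_cliques(4)), seed = 3)
  expect_gte(res_2k4$contribution, 0.5)
})

test_that("recursive_divide_gray records gray nodes from accepted divisions", {
  # no accepted division -> no gray nodes
  dec_k4 <- recursive_divide_gray(k4(), 0.01, seed = 7)
  expect_equal(dec_k4$gray_proportion, 0)
  expect_equal(length(dec_k4$modules), 1)

  # two disjoint K4s: clean split, empty gray set (oracle-confirmed above)
  dec2 <- recursive_divide_gray(two_cliques(4), 0.3, seed = 7)
  expect_true(same_partition(dec2$modules, list(1:4, 5:8)))
  expect_equal(length(dec2$gray_nodes), 0)

  # shared-clique graph: the two shared nodes are gray and join both modules
  dec3 <- recursive_divide_gray(shared_clique_graph(), 0.05, seed = 7)
  expect_equal(dec3$gray_nodes, c(3, 4))
  expect_equal(dec3$gray_proportion, 2 / 6)
  expect_true(same_partition(dec3$modules, list(1:4, 3:6)))
  expect_equal(dec3$gray_labels, c("v03", "v04"))

  # gray_membership = "neither" drops the shared nodes from both children
  dec4 <- recursive_divide_gray(shared_clique_graph(), 0.05, seed = 7,
                                gray_membership = "neither")
  expect_equal(dec4$gray_nodes, c(3, 4))
  expect_true(same_partition(dec4$modules, list(1:2, 5:6)))
})

test_that("gray_proportion_curve is bounded and tracks shared structure", {
  g <- shared_clique_graph()
  curve <- gray_proportion_curve(g, c(0.05, 0.2), seed = 7)
  expect_equal(curve$gray_proportion, c(2 / 6, 0))  # 1/11 < 0.2: indivisible
  expect_equal(curve$modules, c(2, 1))

  for (seed in 1:10) {
    g <- random_graph(12, 0.3, seed * 7)
    if (g$m < 1) next
    curve <- gray_proportion_curve(g, seq(0, 0.3, 0.1), fast_opt(), seed = seed)
    expect_true(all(curve$gray_proportion >= 0 & curve$gray_proportion <= 1))
    # no gray nodes whenever there is a single module
    expect_true(all(curve$gray_proportion[curve$modules == 1] == 0))
  }

  # shared-clique family: root-division gray count is non-decreasing in the
  # number of shared nodes (exhaustive ternary oracle at the root)
  zeros <- vapply(0:2, function(k) {
    g <- shared_node_modules(2, 4, k, add_bridges = (k == 0))
    sum(brute_force_ternary(modularity_matrix(g))$s == 0)
  }, numeric(1))
  expect_true(all(diff(zeros) >= 0))
})
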