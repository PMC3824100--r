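make_table <- function(values, age = NULL) {
  covs <- if (!is.null(age)) data.frame(age = age) else NULL
  thickness_table(values, covariates = covs)
}

test_that("residualize removes covariates by OLS", {
  set.seed(11)
  age <- runif(12, 35, 64)

  # constant covariate is equivalent to intercept-only: mean centering
  vals <- matrix(rnorm(12 * 3), 12, 3)
  tt <- make_table(vals, age = rep(50, 12))
  res <- residualize(tt, "age")
  expect_equal(res$values, scale(vals, scale = FALSE), ignore_attr = TRUE)

  # a region that is exactly linear in age residualizes to zero
  vals2 <- cbind(2 * age + 5, rnorm(12))
  res2 <- residualize(make_table(vals2, age), "age")
  expect_lt(max(abs(res2$values[, 1])), 1e-10)

  # residuals orthogonal to the covariate, and sum to zero per region
  vals3 <- matrix(0.3 * age + rnorm(12 * 4), 12, 4)
  res3 <- residualize(make_table(vals3, age), "age")
  expect_lt(max(abs(cor(res3$values, age))), 1e-10)
  expect_lt(max(abs(colSums(res3$values))), 1e-8)

  # idempotence
  res3b <- residualize(res3, "age")
  expect_lt(max(abs(res3b$values - res3$values)), 1e-10)

  # derived mean-overall-thickness covariate
  res4 <- residualize(make_table(vals3, age), c("age", "mean_overall_thickness"))
  gm <- rowMeans(vals3)
  fit <- lm(vals3 ~ age + gm)
  expect_equal(res4$values, unname(resid(fit)), ignore_attr = TRUE)

  # collinear (non-constant) covariates are named in the error
  tt5 <- thickness_table(vals3, covariates = data.frame(age = age, age2 = 2 * age))
  expect_error(residualize(tt5, c("age", "age2")), "age2")
})

test_that("pearson_matrix matches the textbook formula", {
  x <- c(1, 2, 3, 4)
  y <- c(1, 2, 4, 3)
  tt <- make_table(cbind(r1 = x, r2 = y, r3 = x, r4 = -x + 10))
  cm <- pearson_matrix(tt)
  hand_r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(cm$R["r1", "r2"], hand_r)
  expect_equal(cm$R["r1", "r3"], 1)       # duplicated region
  expect_equal(cm$R["r1", "r4"], -1)      # perfect anticorrelation
  expect_identical(cm$R, t(cm$R))
  expect_true(all(cm$R >= -1 & cm$R <= 1))
  expect_error(pearson_matrix(make_table(cbind(x, rep(1, 4)))), "zero-variance")
  expect_error(pearson_matrix(make_table(matrix(1:4, 2, 2))), "3 subjects")
})

test_that("fdr_binarize discards negatives and applies step-up FDR", {
  # all non-positive correlations -> empty graph
  R <- diag(4)
  R[upper.tri(R)] <- -0.5
  R[lower.tri(R)] <- -0.5
  cm <- correlation_matrix(R, 21)
  expect_equal(fdr_binarize(cm, 0.2)$m, 0)

  # hand-checked step-up: one-sided p-values {0.01, 0.02, 0.1, 0.3} against
  # BH cutoffs {0.05, 0.10, 0.15, 0.20} at q = 0.2 -> exactly 3 survivors.
  # (Under the one-sided r-to-t transform p < 0.5 iff r > 0, so target
  # p-values must be < 0.5; r is inverted from p by hand here.)
  n_sub <- 20
  p_target <- c(0.01, 0.02, 0.1, 0.3)
  tv <- qt(1 - p_target, df = n_sub - 2)
  r <- tv / sqrt(n_sub - 2 + tv^2)
  R2 <- diag(4)
  R2[cbind(c(1, 1, 1, 2), c(2, 3, 4, 3))] <- r   # four positive pairs
  R2[cbind(c(2, 3), c(4, 4))] <- -0.2            # two negative pairs
  R2[lower.tri(R2)] <- t(R2)[lower.tri(R2)]
  g <- fdr_binarize(correlation_matrix(R2, n_sub), 0.2)
  expect_equal(g$m, 3)
  expect_equal(g$A[1, 2], 1)  # p = 0.01
  expect_equal(g$A[1, 3], 1)  # p = 0.02
  expect_equal(g$A[1, 4], 1)  # p = 0.10 <= 3/4 * 0.2
  expect_equal(g$A[2, 3], 0)  # p = 0.30 >  4/4 * 0.2

  # |r| = 1 is p = 0 and always survives
  R3 <- diag(3); R3[1, 2] <- R3[2, 1] <- 1; R3[1, 3] <- R3[3, 1] <- 0.1
  g3 <- fdr_binarize(correlation_matrix(R3, 10), 0.05)
  expect_equal(g3$A[1, 2], 1)

  expect_error(fdr_binarize(cm, 1.5), "q must lie")

  # monotonicity of the step-up rule: edges at q = 0.05 subset of q = 0.2
  set.seed(42)
  sim <- generate_cohort(small_cohort_spec(seed = 5))
  cm4 <- pearson_matrix(sim$group_a)
  g_strict <- fdr_binarize(cm4, 0.05)
  g_loose <- fdr_binarize(cm4, 0.2)
  expect_true(all(g_loose$A[g_strict$A == 1] == 1))
})

test_that("threshold_sweep records monotone curves and isolated groups", {
  spec <- cohort_spec(n_subjects = 200L, regions = sprintf("p%02d", 1:20),
                      blocks = list(1:10, 11:20), rho_in = 0.8, rho_out = 0,
                      seed = 9)
  cm <- pearson_matrix(generate_cohort(spec)$group_a)

  sweep <- threshold_sweep(cm, c(seq(0.2, 0.9, 0.05), 1.0))
  expect_true(all(diff(sweep$edges) <= 0))
  expect_true(all(diff(sweep$components_all) >= 0))
  expect_identical(sweep$density + sweep$sparsity, rep(1, nrow(sweep)))

  # tau = 1: nothing exceeds 1 -> N singletons
  last <- sweep[nrow(sweep), ]
  expect_equal(last$edges, 0)
  expect_equal(last$components_all, 20)

  # tau in the between/within gap separates the two planted blocks
  mid <- sweep[sweep$threshold == 0.5, ]
  expect_equal(mid$components_nonsingleton, 2)

  # tau below every positive r of an all-positive matrix -> one component
  Rpos <- matrix(0.6, 5, 5); diag(Rpos) <- 1
  sw <- threshold_sweep(correlation_matrix(Rpos, 21), c(0.2, 0.7))
  expect_equal(sw$components_all, c(1, 5))

  expect_error(threshold_sweep(cm, c(0.5, 0.2)), "ascending")
})

test_that("pipeline separates two independent high-covariance blocks", {
  blocks <- list(1:10, 11:20)
  ok <- 0
  for (seed in 1:10) {
    spec <- cohort_spec(n_subjects = 21L, regions = sprintf("p%02d", 1:20),
                        blocks = blocks, rho_in = 0.8, rho_out = 0, seed = seed)
    tt <- generate_cohort(spec)$group_a
    res <- residualize(tt, c("age", "mean_overall_thickness"))
    g <- fdr_binarize(pearson_matrix(res), 0.2)
    comps <- connected_components(g)
    if (same_partition(comps, blocks)) ok <- ok + 1
  }
  expect_gte(ok, 9)
})
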