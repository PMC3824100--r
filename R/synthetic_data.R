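# Seeded generators: toy graphs with known community/overlap structure and
# synthetic two-group thickness cohorts, so every pipeline stage is testable
# without any imaging data.

#' Planted-partition (stochastic block) graph
#'
#' Within-block pairs are connected with probability `p_in`, between-block
#' pairs with `p_out`. Ground-truth blocks are attached as an attribute.
#'
#' @param sizes integer vector of block sizes.
#' @param p_in,p_out edge probabilities, 0 <= p_out <= p_in <= 1.
#' @param seed integer seed; the graph is deterministic given the seed.
#' @return a `graynet_graph` with attribute `"blocks"` (list of node-index
#'   vectors).
#' @export
planted_module_graph <- function(sizes, p_in, p_out, seed = 1L) {
  stopifnot(p_out >= 0, p_in <= 1, p_out <= p_in)
  n <- sum(sizes)
  block <- rep(seq_along(sizes), sizes)
  P <- ifelse(outer(block, block, "=="), p_in, p_out)
  A <- matrix(0, n, n)
  ut <- upper.tri(A)
  A[ut] <- with_seed(seed, as.numeric(stats::runif(sum(ut)) < P[ut]))
  A <- A + t(A)
  g <- graph_from_adjacency(A, sprintf("v%02d", seq_len(n)))
  attr(g, "blocks") <- unname(split(seq_len(n), block))
  g
}

#' Chain of complete modules sharing nodes
#'
#' `k_modules` fully connected modules of `module_size` nodes arranged in a
#' chain; adjacent modules share `n_shared` nodes. With `n_shared = 0` and
#' `add_bridges = TRUE` adjacent modules are instead joined by one bridge
#' edge. The two-module, four-node case illustrates the resource saving of
#' shared (gray) nodes: sharing 2 nodes gives 6 nodes and 11 edges versus 8
#' nodes and 13 edges for the bridged alternative.
#'
#' @param k_modules number of complete modules (>= 1).
#' @param module_size nodes per module.
#' @param n_shared nodes shared between adjacent modules
#'   (0 <= n_shared < module_size).
#' @param add_bridges join adjacent non-overlapping modules with one edge.
#' @return a `graynet_graph` with attribute `"modules"` (list of node-index
#'   vectors, overlapping if `n_shared > 0`).
#' @export
shared_node_modules <- function(k_modules, module_size, n_shared, add_bridges = FALSE) {
  stopifnot(k_modules >= 1, n_shared >= 0, n_shared < module_size)
  step <- module_size - n_shared
  n <- module_size + (k_modules - 1) * step
  A <- matrix(0, n, n)
  members <- vector("list", k_modules)
  for (b in seq_len(k_modules)) {
    ix <- seq((b - 1) * step + 1, length.out = module_size)
    members[[b]] <- ix
    A[ix, ix] <- 1
  }
  if (add_bridges && n_shared == 0 && k_modules > 1) {
    for (b in seq_len(k_modules - 1)) {
      i <- max(members[[b]]); j <- min(members[[b + 1]])
      A[i, j] <- 1; A[j, i] <- 1
    }
  }
  diag(A) <- 0
  g <- graph_from_adjacency(A, sprintf("v%02d", seq_len(n)))
  attr(g, "modules") <- members
  g
}

#' Specification of a synthetic two-group thickness cohort
#'
#' Defaults emulate the study design the package targets: 21 subjects per
#' group, 68 cortical regions, block-structured interregional covariance, an
#' age effect and a global (mean-thickness) factor, and a group difference
#' expressed as a scaling of the block-covariance strength in group B.
#'
#' @param n_subjects subjects per group (default 21).
#' @param regions region labels (default 68 generic parcel names).
#' @param blocks list of region-index vectors (disjoint); default two blocks
#'   of 10 regions, the rest unstructured.
#' @param rho_in,rho_out within-/between-block correlation targets
#'   (rho_out < rho_in <= 1).
#' @param age_slope thickness change per year of age (mm/yr, default -0.005:
#'   mild adult cortical thinning).
#' @param noise_sd residual thickness scale in mm (default 0.15).
#' @param group_covariance_scale multiplier on group B's block loadings
#'   (1 = identical structure, 0 = structure fully scrambled away).
#' @param mean_shift additive thickness offset for group B in mm (default 0;
#'   covariance scaling, not a mean shift, is the default group contrast).
#' @param seed integer seed.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 21L,
                        regions = sprintf("parc_%02d", 1:68),
                        blocks = list(1:10, 11:20),
                        rho_in = 0.8, rho_out = 0.1,
                        age_slope = -0.005, noise_sd = 0.15,
                        group_covariance_scale = 1, mean_shift = 0,
                        seed = 1L) {
  stopifnot(rho_out < rho_in, rho_in <= 1, rho_out >= 0, noise_sd > 0,
            n_subjects >= 3)
  if (length(blocks) > 1 && anyDuplicated(unlist(blocks))) {
    stop("blocks must be disjoint", call. = FALSE)
  }
  if (length(unlist(blocks)) > length(regions)) stop("blocks exceed region count", call. = FALSE)
  structure(list(n_subjects = as.integer(n_subjects), regions = regions,
                 blocks = blocks, rho_in = rho_in, rho_out = rho_out,
                 age_slope = age_slope, noise_sd = noise_sd,
                 group_covariance_scale = group_covariance_scale,
                 mean_shift = mean_shift, seed = as.integer(seed)),
            class = "cohort_spec")
}

# Internal: one group's thickness table under a latent-factor block model.
# Residual fluctuation x_j (unit variance) = sqrt(rho_in - rho_out)*f_block +
# sqrt(rho_out)*global + sqrt(1 - rho_in)*eps, giving within-block correlation
# rho_in and between-block (and block-to-unstructured) correlation rho_out
# without constructing a covariance matrix. Block loadings scale by `cscale`
# in group B; the lost variance is returned to the idiosyncratic term so the
# marginal variance stays noise_sd^2.
simulate_group <- function(spec, cscale, mean_shift, seed) {
  ns <- spec$n_subjects
  nr <- length(spec$regions)
  block_of <- rep(NA_integer_, nr)
  for (b in seq_along(spec$blocks)) block_of[spec$blocks[[b]]] <- b
  lam_b <- sqrt(spec$rho_in - spec$rho_out) * cscale
  lam_g <- sqrt(spec$rho_out)
  with_seed(seed, {
    age <- stats::runif(ns, 35, 64)
    f <- matrix(stats::rnorm(ns * length(spec$blocks)), ns)
    glob <- stats::rnorm(ns)
    eps <- matrix(stats::rnorm(ns * nr), ns, nr)
  })
  x <- matrix(0, ns, nr)
  for (j in seq_len(nr)) {
    lb <- if (is.na(block_of[j])) 0 else lam_b
    idio <- sqrt(max(0, 1 - lb^2 - lam_g^2))
    fac <- if (is.na(block_of[j])) 0 else f[, block_of[j]]
    x[, j] <- lb * fac + lam_g * glob + idio * eps[, j]
  }
  mu <- 2.5  # typical adult mean cortical thickness (mm)
  values <- mu + mean_shift + spec$age_slope * (age - 50) + spec$noise_sd * x
  thickness_table(values,
                  subjects = sprintf("s%02d", seq_len(ns)),
                  regions = spec$regions,
                  covariates = data.frame(age = age))
}

#' Generate a synthetic two-group cohort
#'
#' Draws per-subject latent block factors, a global factor, age and noise;
#' group B's block loadings are scaled by `group_covariance_scale` (and
#' optionally mean-shifted). Deterministic given `spec$seed`.
#'
#' @param spec a [cohort_spec()].
#' @return list with `group_a`, `group_b` (thickness tables) and `truth`
#'   (list with `blocks`, `rho_in`, `rho_out`, `group_covariance_scale`).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  ga <- simulate_group(spec, 1, 0, derive_seed(spec$seed, 11L))
  gb <- simulate_group(spec, spec$group_covariance_scale, spec$mean_shift,
                       derive_seed(spec$seed, 22L))
  list(group_a = ga, group_b = gb,
       truth = list(blocks = spec$blocks, rho_in = spec$rho_in,
                    rho_out = spec$rho_out,
                    group_covariance_scale = spec$group_covariance_scale))
}
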