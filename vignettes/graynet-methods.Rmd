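---
title: "Modularity and gray nodes in cortical thickness covariance networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modularity and gray nodes in cortical thickness covariance networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Structural covariance networks treat cortical regions as nodes and draw an
edge wherever a morphological measure — here FreeSurfer cortical thickness on
a 68-parcel atlas — correlates significantly across subjects. Such networks
are modular: subsets of regions are more densely connected internally than
externally. But a brain that worked as isolated modules would communicate
poorly; a plausible architecture shares some nodes between modules. graynet
implements both sides of that picture: Newman spectral modularity with a
Q-threshold-controlled recursive division, and an extended "gray node"
modularity in which a node may belong to both halves of a division at once.
Because observed metrics depend strongly on density and degree, every metric
is judged against degree-matched random graphs.

## Network construction

Input is a subjects-by-regions thickness table (mm). Per region, ordinary
least squares removes nuisance covariates — age, and each subject's mean
thickness across all regions ("mean overall thickness", derived on the fly) —
and the residuals replace the raw values. A covariate that is constant across
subjects is absorbed by the intercept and dropped; genuinely collinear
covariates are an error naming the columns. Pearson correlations of the
residuals over all C(N,2) distinct region pairs form the correlation matrix.
(The source study describes this count as "68 x 68/2 = 1431", which matches
neither C(68,2) = 2278 nor 68*68/2; we test all distinct pairs.)

Binarization discards negative and zero correlations first, then converts the
remaining r to one-sided (upper-tail) p-values through t = r sqrt(df/(1-r^2)),
df = n_subjects - 2, and applies Benjamini–Hochberg step-up FDR at q (default
0.2; the step-up rule makes the edge set monotone in q). One-sided testing is
the coherent choice once negatives are discarded: only positive association
is a candidate edge. |r| = 1 maps to p = 0. The FDR estimator is
configurable (`BH` or the more conservative `BY`).

`threshold_sweep()` additionally builds graphs with edge iff r > tau over a
threshold grid and records edges, density, sparsity (both complements are
reported because the literature uses "sparsity" in both senses) and isolated
group counts, with and without singleton nodes, since either convention may
be wanted.

## Spectral modularity

For a binary graph with adjacency A, degrees k and m edges, the modularity
matrix is B = A - k k^T / (2m); its rows sum to zero, so the undivided graph
scores 0. A bipartition s in {-1,+1}^n scores Q(s) = s^T B s / (4m), and the
leading relaxed maximizer is the most-positive eigenvector of B. Plain power
iteration converges to the eigenvalue of largest *magnitude*, which may be
the most negative one, so iteration runs on B + shift I with the Gershgorin
bound shift = max_i sum_j |B_ij|: all eigenvalues become non-negative and
the most-positive one dominates. Convergence is declared when the
L-infinity change of the normalized iterate falls below `tol` (default
1e-10; `max_iter` 10000); non-convergence returns the best iterate with a
warning, never an error. All `restarts` (default 32) random start vectors
iterate as one n x restarts block, so extra restarts are nearly free. Zero
components of the converged vector sign to +1. Each signed vector is then
sharpened by one greedy single-node sign-flip pass (Kernighan–Lin style, in
a seeded random order), which closes most of the gap to the exhaustive
optimum on small graphs.

Division recurses. A module g gets Newman's generalized matrix
B^g_ij = B_ij - delta_ij sum_{l in g} B_il (the study's own wording for the
diagonal correction is circular; this standard form keeps contributions
additive, and the diagonal-only correction composes so correcting a child of
a corrected parent equals correcting from B directly). The root division is
accepted iff Q >= q_threshold, later ones iff Delta-Q >= q_threshold, and a
division must be proper (both signs present) — otherwise the all-equal
vector, scoring exactly 0, would "divide" at threshold 0. Singletons never
divide. The final module count per threshold is the Figure-9-style sweep
statistic.

Two implementation choices matter for the sweep. First, a disconnected
input grows a *single* division tree from the whole-graph B (isolated nodes
are singleton modules from the start). The alternative — decomposing each
connected component independently — cannot reproduce the defining worked
example: two disjoint K4s have root Q = 0.5 and must count as *one* module
at threshold 0.6. The recursion separates components by itself whenever that
pays. Second, `module_count_curve()` builds the tree once at the smallest
threshold and prunes it per threshold. Because each division's RNG seed
derives from (master seed, member set), the pruned counts equal running
`recursive_divide()` independently at every threshold (tested), the counts
are exactly non-increasing in the threshold, and a 1000-replicate null
ensemble costs one tree per replicate instead of one per replicate-threshold
pair.

## Gray nodes

The extended modularity Q_e maximizes the same quadratic form over ternary
vectors s_e in {-1,0,+1}^n. Zero-assigned nodes in an accepted division are
*gray*: under the default `gray_membership = "both"` they join both child
modules (shared nodes), under `"neither"` they join neither. The study gives
no optimizer for the ternary problem, so graynet uses a seeded local search:
start from the spectral sign vector (hence the result never falls below the
best bipartition), sweep nodes in seeded random order re-assigning each to
the best of {-1,0,+1} with the rest fixed, repeat to a local optimum, and
restart from perturbed starts (15% of entries resampled). The all-zero
vector is rejected as a degenerate division. Ties break toward fewest zeros
(not inflating gray counts on plateaus), then lexicographically, so results
are reproducible. On all graphs small enough for the 3^n enumeration the
heuristic is checked to never exceed, and almost always to match, the
exhaustive maximum.

The canonical illustration is two K4s sharing two nodes (6 nodes, 11 edges
versus 8 nodes and 13 edges for two bridged K4s): the exhaustive ternary
optimum is 1/11, attained exactly by zeroing the two shared nodes, and the
gray decomposition returns the two overlapping K4s with gray proportion 2/6.

The per-threshold gray proportion counts nodes zeroed in *any* accepted
division, each node once; a per-recursion-level breakdown (`gray_by_depth`)
is also emitted because the published curves do not say which convention
they used.

## Null ensembles

Random graphs preserve the observed degree sequence exactly via double edge
swaps: swaps_per_edge x m attempted swaps (default 10 per edge, a common
burn-in), rejecting any that would create a loop or duplicate edge, capped
at 100 m attempts. Whether the original study rewired or used a stub-matching
configuration model is not stated; rewiring guarantees simplicity without
rejection sampling of whole graphs. `ensemble_curves()` evaluates
module-count or gray-proportion curves on `reps` (default 1000) replicates
with child seeds derived from the master seed, and reports per-threshold
mean, SD and skewness; `compare_to_null()` turns an observed curve into
z-scores, flagging degenerate (sd = 0) thresholds rather than dividing by
zero.

## Synthetic cohorts

`generate_cohort()` emulates the study's design — two groups of 21 subjects,
68 regions by default — with a latent-factor block model: region j in block b
fluctuates as sqrt(rho_in - rho_out) f_b + sqrt(rho_out) g + idiosyncratic
noise, which realizes within-block correlation rho_in and between-block
correlation rho_out while being positive semi-definite by construction. The
shared factor g doubles as the global mean-thickness component that
residualization removes. Age is uniform on [35, 64] years (the study's
sampling bands) with a default slope of -0.005 mm/yr, a mild adult thinning
rate; mean thickness is 2.5 mm and the residual scale 0.15 mm. The group
contrast defaults to scaling group B's block loadings
(`group_covariance_scale`), not shifting means, because the network pipeline
consumes correlations; a mean shift is available. What the generator does
*not* emulate: cortical geometry, spatially autocorrelated parcels,
heavy-tailed or heteroskedastic measurement error, and site/scanner effects
— so a green recovery test establishes correctness of the machinery, not
performance on real MRI data.

One synthetic subtlety: removing the per-subject mean thickness makes
between-block residual correlations strongly *negative* in a two-block world
(the mean is the sum of the block factors), which is precisely why the
negative-discarding pipeline separates planted blocks so cleanly. And with
only 21 subjects, residualizing even a pure-noise covariate perturbs
individual correlations by O(1/sqrt(n)) — the no-confound control is
therefore checked at n = 200, where the finite-sample term sits below the
0.02 tolerance.

## Cohort statistics

`pooled_t()` implements the pooled-variance two-sample t with df = n_a + n_b
- 2 and two-sided p, from summary statistics or (equivalently, tested to
1e-12) raw data. On the shipped two-neighbourhood summary table it
reproduces the published diet score (4.26), CRP (-3.16), alcohol (-0.55),
BMI (-0.99) and intracranial volume (0.642) statistics at printed precision;
several other rows do not recompute from their printed means/SDs under
pooled or Welch t (per-row n likely varied) and are reported but not
asserted.

## Numerical conventions

* Acceptance of a division uses `contribution >= q_threshold` with
  q_threshold >= 0, generalizing the original "divide iff positive" rule to
  the threshold sweep.
* A K4 is indivisible: every 2-2 split scores -1/6, the best proper split is
  the 3-1 split at -1/8, and the unrestricted maximum is 0 (the trivial
  all-equal vector).
* Brute-force oracles (`brute_force_bipartition`, `brute_force_ternary`)
  enumerate 2^n / 3^n assignments with the same tie-breaks as the heuristics
  and refuse n above their caps (16 / 12).
* All randomness flows through explicit integer seeds; derived seeds stay
  below 2^31 and depend only on (master seed, subproblem), so whole
  decompositions and ensembles are bit-reproducible and independent of
  evaluation order.

## Limitations

Weighted, directed or multigraphs are out of scope, as are partial
correlations, Louvain-type optimizers, and analytic null distributions. The
ternary search is a local heuristic: on large graphs its gray sets are
reproducible but not certified optimal. Q-threshold sweeps at thresholds
below the tree-building bar of a previously built forest require rebuilding
the forest (handled internally by always building at the smallest requested
threshold).
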