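# Subject x region thickness tables -> binary covariance networks.

#' Construct a thickness table
#'
#' Subjects-by-regions morphometric measurements (e.g., FreeSurfer cortical
#' thickness in mm per Desikan parcellation) with optional per-subject
#' covariates such as age.
#'
#' @param values numeric matrix, one row per subject, one column per region.
#' @param subjects character vector of subject ids (default `rownames`).
#' @param regions character vector of unique region labels (default
#'   `colnames`).
#' @param covariates data.frame of per-subject covariate columns, or NULL.
#' @return object of class `thickness_table`.
#' @export
thickness_table <- function(values, subjects = NULL, regions = NULL, covariates = NULL) {
  values <- as.matrix(values)
  if (is.null(subjects)) {
    subjects <- if (!is.null(rownames(values))) rownames(values) else sprintf("s%02d", seq_len(nrow(values)))
  }
  if (is.null(regions)) {
    regions <- if (!is.null(colnames(values))) colnames(values) else sprintf("r%02d", seq_len(ncol(values)))
  }
  if (anyDuplicated(regions)) stop("region labels must be unique", call. = FALSE)
  if (anyNA(values)) {
    bad <- which(is.na(values), arr.ind = TRUE)
    stop("missing values at (subject,region): ",
         paste(sprintf("(%s,%s)", subjects[bad[, 1]], regions[bad[, 2]])[seq_len(min(5, nrow(bad)))],
               collapse = " "),
         call. = FALSE)
  }
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != nrow(values)) stop("covariates must have one row per subject", call. = FALSE)
  }
  dimnames(values) <- list(subjects, regions)
  structure(
    list(subjects = as.character(subjects), regions = as.character(regions),
         values = values, covariates = covariates),
    class = "thickness_table"
  )
}

#' @export
print.thickness_table <- function(x, ...) {
  cat(sprintf("thickness_table: %d subjects x %d regions; covariates: %s\n",
              nrow(x$values), ncol(x$values),
              if (is.null(x$covariates) || ncol(x$covariates) == 0) "none"
              else paste(names(x$covariates), collapse = ", ")))
  invisible(x)
}

#' Regress covariates out of every region
#'
#' Ordinary least squares with intercept, fitted per region on the named
#' per-subject covariates; the residuals replace the raw values. The special
#' name `"mean_overall_thickness"` is derived as each subject's unweighted
#' mean thickness across all regions (computed from the current values,
#' before residualization).
#'
#' @param t a `thickness_table`.
#' @param covariate_names character vector naming covariate columns and/or
#'   `"mean_overall_thickness"`.
#' @return a `thickness_table` of residuals (same shape, same covariates).
#' @export
residualize <- function(t, covariate_names) {
  stopifnot(inherits(t, "thickness_table"))
  ns <- nrow(t$values)
  X <- matrix(1, ns, 1, dimnames = list(NULL, "(Intercept)"))
  for (nm in covariate_names) {
    col <- if (nm == "mean_overall_thickness") {
      rowMeans(t$values)
    } else {
      if (is.null(t$covariates) || !nm %in% names(t$covariates)) {
        stop("covariate not found: ", nm, call. = FALSE)
      }
      as.numeric(t$covariates[[nm]])
    }
    X <- cbind(X, col)
    colnames(X)[ncol(X)] <- nm
  }
  # a covariate constant across subjects is absorbed by the intercept;
  # drop it rather than flag the trivial collinearity
  const <- c(FALSE, apply(X[, -1, drop = FALSE], 2, function(v) stats::var(v) == 0))
  X <- X[, !const, drop = FALSE]
  if (ns <= ncol(X)) stop("need more subjects than covariates + intercept", call. = FALSE)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("collinear covariate column(s): ", paste(dropped, collapse = ", "), call. = FALSE)
  }
  res <- qr.resid(qx, t$values)
  dimnames(res) <- dimnames(t$values)
  thickness_table(res, t$subjects, t$regions, t$covariates)
}

#' Construct a correlation matrix object
#'
#' @param R symmetric numeric matrix with unit diagonal, entries in [-1, 1].
#' @param n_subjects sample size the correlations were computed from.
#' @param regions region labels (default `rownames(R)`).
#' @return object of class `correlation_matrix`.
#' @export
correlation_matrix <- function(R, n_subjects, regions = NULL) {
  R <- as.matrix(R)
  if (nrow(R) != ncol(R)) stop("R must be square", call. = FALSE)
  if (is.null(regions)) {
    regions <- if (!is.null(rownames(R))) rownames(R) else sprintf("r%02d", seq_len(nrow(R)))
  }
  if (max(abs(R - t(R))) > 1e-8) stop("R must be symmetric", call. = FALSE)
  R <- (R + t(R)) / 2
  if (max(abs(diag(R) - 1)) > 1e-8) stop("R must have unit diagonal", call. = FALSE)
  diag(R) <- 1
  if (any(R < -1 - 1e-12 | R > 1 + 1e-12)) stop("correlations must lie in [-1, 1]", call. = FALSE)
  R[R > 1] <- 1; R[R < -1] <- -1
  dimnames(R) <- list(regions, regions)
  structure(list(regions = as.character(regions), R = R, n_subjects = as.integer(n_subjects)),
            class = "correlation_matrix")
}

#' Interregional Pearson correlation matrix
#'
#' Pearson r of every unordered region pair across subjects.
#'
#' @param t a `thickness_table` with >= 3 subjects and positive variance in
#'   every region.
#' @return a `correlation_matrix`.
#' @export
pearson_matrix <- function(t) {
  stopifnot(inherits(t, "thickness_table"))
  if (nrow(t$values) < 3) stop("need at least 3 subjects for correlation", call. = FALSE)
  v <- apply(t$values, 2, stats::var)
  if (any(v <= 0)) {
    stop("zero-variance region(s): ", paste(t$regions[v <= 0], collapse = ", "), call. = FALSE)
  }
  R <- stats::cor(t$values)
  correlation_matrix(R, nrow(t$values), t$regions)
}

# Internal: one-sided (upper tail) p-value for Pearson r via the t transform,
# df = n - 2. |r| = 1 maps to p = 0 / 1 at the respective tail.
r_to_p_one_sided <- function(r, n_subjects) {
  df <- n_subjects - 2
  p <- numeric(length(r))
  exact <- abs(r) >= 1
  p[exact] <- ifelse(r[exact] > 0, 0, 1)
  tt <- r[!exact] * sqrt(df / (1 - r[!exact]^2))
  p[!exact] <- stats::pt(tt, df, lower.tail = FALSE)
  p
}

#' Binarize a correlation matrix by one-sided FDR
#'
#' Negative and zero correlations are discarded first; the remaining
#' upper-triangle correlations are converted to one-sided p-values through
#' the r-to-t transform (df = n_subjects - 2) and corrected at level `q`
#' (Benjamini-Hochberg by default). Surviving pairs become the edges of a
#' binary graph.
#'
#' @param c a `correlation_matrix` with `n_subjects >= 4`.
#' @param q FDR level in (0, 1); default 0.2.
#' @param variant `"BH"` (step-up, default) or `"BY"`.
#' @return a `graynet_graph` on the region labels.
#' @export
fdr_binarize <- function(c, q = 0.2, variant = c("BH", "BY")) {
  stopifnot(inherits(c, "correlation_matrix"))
  variant <- match.arg(variant)
  if (!(q > 0 && q < 1)) stop("q must lie in (0, 1)", call. = FALSE)
  if (c$n_subjects < 4) stop("need n_subjects >= 4", call. = FALSE)
  n <- nrow(c$R)
  A <- matrix(0, n, n)
  ut <- which(upper.tri(c$R), arr.ind = TRUE)
  r <- c$R[ut]
  pos <- r > 0
  if (any(pos)) {
    p <- r_to_p_one_sided(r[pos], c$n_subjects)
    keep <- stats::p.adjust(p, method = variant) <= q
    sel <- ut[pos, , drop = FALSE][keep, , drop = FALSE]
    A[sel] <- 1
    A[sel[, c(2, 1), drop = FALSE]] <- 1
  }
  graph_from_adjacency(A, c$regions)
}

#' Correlation-threshold sweep
#'
#' For each threshold tau, builds the graph with an edge iff r > tau
#' (negatives never survive) and records edge count, density, sparsity and
#' connected-component counts. `components_all` counts singleton nodes as
#' groups; `components_nonsingleton` does not.
#'
#' @param c a `correlation_matrix`.
#' @param thresholds ascending numeric vector in (0, 1].
#' @return data.frame with one row per threshold.
#' @export
threshold_sweep <- function(c, thresholds) {
  stopifnot(inherits(c, "correlation_matrix"))
  if (is.unsorted(thresholds)) stop("thresholds must be ascending", call. = FALSE)
  n <- nrow(c$R)
  out <- lapply(thresholds, function(tau) {
    A <- (c$R > tau) * 1
    diag(A) <- 0
    g <- graph_from_adjacency(A, c$regions)
    comps <- connected_components(g)
    ds <- density_and_sparsity(g)
    data.frame(threshold = tau, edges = g$m, density = ds$density, sparsity = ds$sparsity,
               components_all = length(comps),
               components_nonsingleton = sum(lengths(comps) > 1))
  })
  do.call(rbind, out)
}
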