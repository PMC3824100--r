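# Pooled two-sample comparison of cohort variables from summary statistics.

#' Group summary statistics
#'
#' @param label group label.
#' @param mean,sd,n sample mean, standard deviation (>= 0) and size (>= 2).
#' @return object of class `group_summary`.
#' @export
group_summary <- function(label, mean, sd, n) {
  stopifnot(sd >= 0, n >= 2)
  structure(list(label = as.character(label), mean = as.numeric(mean),
                 sd = as.numeric(sd), n = as.integer(n)),
            class = "group_summary")
}

#' Pooled-variance two-sample t test from summaries
#'
#' s_p^2 = ((n_a - 1) s_a^2 + (n_b - 1) s_b^2) / (n_a + n_b - 2);
#' t = (mean_a - mean_b) / (s_p sqrt(1/n_a + 1/n_b)); df = n_a + n_b - 2;
#' p is two-sided. A zero pooled variance gives t = 0 (equal means) or an
#' infinite-t flag (unequal means).
#'
#' @param a,b `group_summary` objects.
#' @return list with `t`, `df`, `p` and `flag` (`"ok"` or `"infinite-t"`).
#' @export
pooled_t <- function(a, b) {
  stopifnot(inherits(a, "group_summary"), inherits(b, "group_summary"))
  df <- a$n + b$n - 2L
  sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / df
  se <- sqrt(sp2) * sqrt(1 / a$n + 1 / b$n)
  if (se == 0) {
    if (a$mean == b$mean) {
      return(list(t = 0, df = df, p = 1, flag = "ok"))
    }
    return(list(t = sign(a$mean - b$mean) * Inf, df = df, p = 0, flag = "infinite-t"))
  }
  tt <- (a$mean - b$mean) / se
  list(t = tt, df = df, p = 2 * stats::pt(-abs(tt), df), flag = "ok")
}

#' Pooled t statistics for a table of paired summaries
#'
#' Applies [pooled_t()] row-wise to a table with columns `variable`,
#' `mean_a`, `sd_a`, `n_a`, `mean_b`, `sd_b`, `n_b` (as shipped in
#' `system.file("extdata", "glasgow_cohort_summaries.tsv", package =
#' "graynet")`, the demographic and clinical summary table of the
#' two-neighbourhood deprivation cohort, 21 men per group).
#'
#' @param rows data.frame with the columns above.
#' @return data.frame with `variable`, `t`, `df`, `p`, `flag`.
#' @export
table_report <- function(rows) {
  rows <- as.data.frame(rows)
  need <- c("variable", "mean_a", "sd_a", "n_a", "mean_b", "sd_b", "n_b")
  if (!all(need %in% names(rows))) {
    stop("missing column(s): ", paste(setdiff(need, names(rows)), collapse = ", "),
         call. = FALSE)
  }
  if (nrow(rows) < 1) stop("need at least one row", call. = FALSE)
  out <- lapply(seq_len(nrow(rows)), function(i) {
    res <- pooled_t(
      group_summary("a", rows$mean_a[i], rows$sd_a[i], rows$n_a[i]),
      group_summary("b", rows$mean_b[i], rows$sd_b[i], rows$n_b[i])
    )
    data.frame(variable = rows$variable[i], t = res$t, df = res$df, p = res$p,
               flag = res$flag)
  })
  do.call(rbind, out)
}
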