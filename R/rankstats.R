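# Rank statistics used for the cross-cohort method comparisons.

#' Mann-Whitney U test (first-sample convention)
#'
#' U is the number of pairs with `x_i > y_j` plus half the number of exact
#' ties — the statistic of the first sample, so `U(x, y) + U(y, x) = n1 * n2`.
#' The p-value comes from [stats::wilcox.test()] (exact when the sample sizes
#' allow and no ties are present, otherwise the tie-corrected normal
#' approximation); the computed U is identical to its `W` statistic.
#'
#' @param x,y Numeric samples.
#' @return A `rank_test` list: `u`, `p_value`, `n1`, `n2`.
#' @export
mann_whitney_u <- function(x, y) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  u <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  wt <- suppressWarnings(stats::wilcox.test(x, y))
  structure(list(u = u, p_value = wt$p.value,
                 n1 = length(x), n2 = length(y)),
            class = "rank_test")
}

#' @export
print.rank_test <- function(x, ...) {
  cat(sprintf("<rank_test> U = %g (n1 = %d, n2 = %d), p = %.4g\n",
              x$u, x$n1, x$n2, x$p_value))
  invisible(x)
}

#' Spearman rank correlation
#'
#' Pearson correlation of the average ranks, with the p-value from
#' [stats::cor.test()]'s t-approximation. Constant input yields an undefined
#' (`NA`) coefficient rather than an error.
#'
#' @param x,y Paired numeric samples of equal length (>= 3).
#' @return List with `rho` and `p_value`.
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p_value = NA_real_))
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  list(rho = unname(ct$estimate), p_value = ct$p.value)
}
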