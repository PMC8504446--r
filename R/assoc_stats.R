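# Rank-based association statistics: Spearman correlation and the
# two-sample Wilcoxon rank-sum (Mann-Whitney U) statistic, with the tie
# conventions used by standard statistical software (U reported for the
# first sample; average ranks for ties).

#' Average ranks with midrank ties
#' @param values numeric vector.
#' @return ranks 1..n, ties receiving the average of their span.
#' @export
rank_average <- function(values) {
  if (length(values) == 0) stop("empty input")
  rank(values, ties.method = "average")
}

#' Spearman rank correlation
#'
#' rho is the Pearson correlation of average ranks; the p-value uses the t
#' approximation with n - 2 degrees of freedom.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with `rho`, `p`, `n`, `ties` (logical).
#' @export
spearman_rho <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 3) stop("need at least 3 observations")
  rx <- rank_average(x); ry <- rank_average(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop("undefined correlation: zero rank variance")
  rho <- stats::cor(rx, ry)
  tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  list(rho = rho, p = p, n = n,
       ties = anyDuplicated(x) > 0 || anyDuplicated(y) > 0)
}

#' Mann-Whitney U (Wilcoxon rank-sum) test
#'
#' U is reported for the first sample: the number of pairs (i, j) with
#' x_i > y_j plus half the number of exact ties. The p-value is exact (by
#' distribution enumeration) when n1 + n2 <= 20 and there are no ties,
#' otherwise a normal approximation with tie correction and continuity
#' correction is used.
#'
#' @param x,y numeric samples (n1, n2 >= 1).
#' @return list with `U`, `p`, `method`, `n1`, `n2`.
#' @export
mann_whitney_u <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1 || n2 < 1) stop("both samples must be non-empty")
  r <- rank_average(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  has_ties <- anyDuplicated(c(x, y)) > 0
  exact <- (n1 + n2 <= 20) && !has_ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact, correct = TRUE))
  list(U = U, p = wt$p.value,
       method = if (exact) "exact" else "normal-approx-tie-corrected",
       n1 = n1, n2 = n2)
}

#' Pairwise rank correlations among genome and region characteristics
#'
#' Convenience wrapper computing [spearman_rho()] for every pair of columns
#' of a numeric table (e.g. genome size, region sizes and GC contents across
#' samples).
#'
#' @param table data frame or matrix of numeric columns.
#' @return data frame (var1, var2, rho, p, n).
#' @export
correlation_table <- function(table) {
  table <- as.data.frame(table)
  vars <- names(table)
  out <- list()
  for (i in seq_along(vars)) for (j in seq_along(vars)) {
    if (j <= i) next
    res <- tryCatch(spearman_rho(table[[i]], table[[j]]),
                    error = function(e) list(rho = NA_real_, p = NA_real_,
                                             n = length(table[[i]])))
    out[[length(out) + 1]] <- data.frame(var1 = vars[i], var2 = vars[j],
                                         rho = res$rho, p = res$p, n = res$n)
  }
  do.call(rbind, out)
}
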