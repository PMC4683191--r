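#' Pearson chi-square test on a 2x2 policy-count table
#'
#' Compares policy-class proportions between two groups with the Pearson
#' chi-square statistic on 1 degree of freedom. The Yates continuity
#' correction is off by default (the convention used for the reported
#' analyses); it can be enabled with `correct = TRUE`.
#'
#' @param table a 2x2 matrix of nonnegative counts (rows = groups).
#' @param correct apply the continuity correction.
#' @return list with `statistic`, `df`, `p_value`, and `min_expected` (the
#'   smallest expected cell count, for judging the asymptotic p-value).
#' @examples
#' proportion_chisq(matrix(c(8, 8, 3, 13), 2, byrow = TRUE))
#' @export
proportion_chisq <- function(table, correct = FALSE) {
  table <- as.matrix(table)
  stop_if_not(all(dim(table) == c(2, 2)), "table must be 2x2")
  stop_if_not(all(table >= 0) && sum(table) > 0, "counts must be nonnegative")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero marginal in contingency table", call. = FALSE)
  # the Pearson statistic is exact arithmetic; the p-value is asymptotic, so
  # instead of base R's small-count warning the minimum expected count is
  # returned for the caller to judge
  ht <- suppressWarnings(stats::chisq.test(table, correct = correct))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, min_expected = min(ht$expected))
}

#' Pooled two-sample t-test on parameter estimates
#'
#' Independent two-sample t-test with pooled variance and
#' `n_A + n_B - 2` degrees of freedom (Welch's unpooled variant available
#' behind `pooled = FALSE`).
#'
#' @param values_A,values_B numeric vectors (each n >= 2).
#' @param pooled use the pooled-variance statistic (default).
#' @return list with `statistic`, `df`, `p_value`, `mean_A`, `mean_B`.
#' @examples
#' two_sample_t(c(1, 2, 3), c(2, 3, 4))
#' @export
two_sample_t <- function(values_A, values_B, pooled = TRUE) {
  stop_if_not(length(values_A) >= 2 && length(values_B) >= 2,
              "each group needs n >= 2")
  if (stats::var(values_A) == 0 && stats::var(values_B) == 0) {
    if (mean(values_A) == mean(values_B))
      return(list(statistic = 0,
                  df = length(values_A) + length(values_B) - 2,
                  p_value = 1, mean_A = mean(values_A),
                  mean_B = mean(values_B)))
    stop("zero pooled variance with unequal means: t is infinite",
         call. = FALSE)
  }
  ht <- stats::t.test(values_A, values_B, var.equal = pooled)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, mean_A = mean(values_A), mean_B = mean(values_B))
}

#' Two-tailed critical t value
#'
#' @param df degrees of freedom (>= 1).
#' @param alpha two-tailed significance level.
#' @return the `1 - alpha/2` quantile of the t distribution.
#' @examples
#' critical_t(30)  # ~2.04
#' @export
critical_t <- function(df, alpha = 0.05) {
  stop_if_not(df >= 1, "df must be >= 1")
  stop_if_not(alpha > 0 && alpha < 1, "alpha must be in (0, 1)")
  stats::qt(1 - alpha / 2, df = df)
}
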