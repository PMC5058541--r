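# Habitat comparisons, effect sizes and proportion tests.

#' Kruskal-Wallis rank test across groups
#'
#' Midranks for ties and the tie-corrected H statistic (H divided by
#' 1 - sum(t^3 - t)/(N^3 - N)), referred to a chi-square distribution on
#' (number of groups - 1) degrees of freedom. Groups of identical constants
#' yield H = 0.
#'
#' @param groups list of two or more non-empty numeric vectors.
#' @return list with `H`, `df`, `p`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (any(vapply(groups, length, 0L) == 0L)) stop_f("empty group")
  x <- unlist(groups)
  if (length(x) < 3L) stop_f("need at least 3 observations in total")
  g <- factor(rep(seq_along(groups), vapply(groups, length, 0L)))
  if (length(unique(x)) == 1L)
    return(list(H = 0, df = length(groups) - 1L, p = 1))
  kt <- stats::kruskal.test(x, g)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value)
}

#' Cohen's d with pooled standard deviation
#'
#' d = (mean1 - mean2) / s_pooled with
#' s_pooled = sqrt(((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2)); the sign
#' follows the argument order. The attached `magnitude` attribute uses the
#' conventional thresholds |d| < 0.2 negligible, < 0.5 small, < 0.8 medium,
#' otherwise large.
#'
#' @param group1,group2 numeric vectors (n1 >= 2, n2 >= 1).
#' @return the effect size d, with attribute `"magnitude"`.
#' @export
cohens_d <- function(group1, group2) {
  n1 <- length(group1); n2 <- length(group2)
  stopifnot(n1 >= 2L, n2 >= 1L)
  v1 <- stats::var(group1)
  v2 <- if (n2 >= 2L) stats::var(group2) else 0
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  if (sp2 <= 0) stop_f("pooled variance is zero")
  d <- (mean(group1) - mean(group2)) / sqrt(sp2)
  mag <- if (abs(d) < 0.2) "negligible" else if (abs(d) < 0.5) "small"
         else if (abs(d) < 0.8) "medium" else "large"
  structure(d, magnitude = mag)
}

#' Two-proportion chi-square test with Yates continuity correction
#'
#' 2x2 test of k1/n1 versus k2/n2 with the continuity term (|O - E| - 0.5)
#' truncated at zero, so identical tables give chi2 = 0 exactly.
#'
#' @param k1,n1,k2,n2 successes and totals of the two samples.
#' @return list with `chi2`, `df` (= 1), `p`.
#' @export
two_proportion_yates <- function(k1, n1, k2, n2) {
  stopifnot(n1 > 0, n2 > 0, k1 >= 0, k2 >= 0, k1 <= n1, k2 <= n2)
  if (k1 + k2 == 0 || (n1 - k1) + (n2 - k2) == 0)
    stop_f("a margin of the 2x2 table is zero")
  pt <- suppressWarnings(stats::prop.test(c(k1, k2), c(n1, n2)))
  list(chi2 = unname(pt$statistic), df = unname(pt$parameter),
       p = pt$p.value)
}

#' Welch's unequal-variance t test
#'
#' @param group1,group2 numeric vectors with at least two values each and
#'   positive variance in at least one.
#' @return list with `t`, `df` (Welch-Satterthwaite) and two-sided `p`.
#' @export
welch_t <- function(group1, group2) {
  stopifnot(length(group1) >= 2L, length(group2) >= 2L)
  if (stats::var(group1) + stats::var(group2) <= 0)
    stop_f("both groups have zero variance")
  tt <- stats::t.test(group1, group2)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values, capped at 1, in the input order.
#'
#' @param pvalues numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values.
#' @export
bh_adjust <- function(pvalues) {
  stopifnot(is.numeric(pvalues), length(pvalues) >= 1L)
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop_f("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}
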