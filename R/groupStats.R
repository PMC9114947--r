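#' Two-sample comparison between habitat groups
#'
#' Two-sided comparison of a diversity or environmental statistic between
#' two groups of populations. In `auto` mode a Shapiro-Wilk screen (alpha =
#' 0.05 on each group) selects Welch's unequal-variance t test when both
#' groups pass and the Wilcoxon-Mann-Whitney test (exact when feasible)
#' otherwise; the branch taken is recorded so either choice can be audited.
#' `force` pins the branch.
#'
#' @param x,y numeric samples, each of length >= 2.
#' @param force "auto", "t" (Welch) or "wilcoxon".
#' @return list: statistic, p, method, and (in auto mode) the Shapiro p's.
#' @examples
#' twoSampleTest(c(0.54, 0.55, 0.52, 0.51, 0.57),
#'               c(0.57, 0.61, 0.56, 0.57, 0.56), force = "t")
#' @export
twoSampleTest <- function(x, y, force = c("auto", "t", "wilcoxon")) {
  force <- match.arg(force)
  stopifnot(length(x) >= 2, length(y) >= 2)
  if (stats::sd(x) == 0 && stats::sd(y) == 0 && mean(x) == mean(y)) {
    warning("both groups constant and equal; p = 1")
    return(list(statistic = 0, p = 1, method = "degenerate"))
  }
  shapiro <- NULL
  if (force == "auto") {
    shapiro <- c(x = stats::shapiro.test(x)$p.value,
                 y = stats::shapiro.test(y)$p.value)
    force <- if (all(shapiro > 0.05)) "t" else "wilcoxon"
  }
  if (force == "t") {
    ht <- stats::t.test(x, y, alternative = "two.sided", var.equal = FALSE)
    out <- list(statistic = unname(ht$statistic), p = ht$p.value,
                method = "Welch t")
  } else {
    ht <- suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided"))
    out <- list(statistic = unname(ht$statistic), p = ht$p.value,
                method = "Wilcoxon-Mann-Whitney")
  }
  if (!is.null(shapiro)) out$shapiro_p <- shapiro
  out
}

#' Paired t test
#'
#' Classical two-sided paired t test, used e.g. to contrast genetic and
#' epigenetic Shannon diversity measured on the same populations.
#'
#' @param x,y paired numeric vectors of equal length >= 2.
#' @return list: t, df, p.
#' @export
pairedTTest <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  d <- x - y
  if (stats::sd(d) <= 1e-10 * max(abs(d), 1))
    stop("differences have zero variance; paired t undefined")
  ht <- stats::t.test(x, y, paired = TRUE, alternative = "two.sided")
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' Correlation test
#'
#' Pearson correlation with the two-sided t-based p-value on n - 2 degrees
#' of freedom; a Spearman rank variant is available since reported
#' rank/product-moment usage in the literature is not always explicit.
#'
#' @param x,y numeric vectors, length >= 3, nonzero variance.
#' @param method "pearson" or "spearman".
#' @return list: r, p, method.
#' @export
correlationTest <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input; correlation undefined")
  ht <- suppressWarnings(stats::cor.test(x, y, method = method,
                                         alternative = "two.sided"))
  list(r = unname(ht$estimate), p = ht$p.value, method = method)
}
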