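#' Wilcoxon signed-rank test for paired decoder accuracies
#'
#' Paired comparison of two methods across replicates (subjects or
#' simulated datasets). Zero differences are discarded (Wilcoxon's
#' convention); the exact signed-rank distribution is used for n <= 25
#' without ties among the absolute differences, otherwise the normal
#' approximation with tie correction.
#'
#' @param x,y paired accuracy vectors of equal length (>= 5 non-zero
#'   differences required).
#' @param alternative `"two.sided"` or `"greater"` (x tends larger than y).
#' @return list with `statistic` (V, sum of positive ranks), `p`, `n`
#'   (non-zero differences used), `exact` (logical).
#' @export
wilcoxon_signed_rank <- function(x, y,
                                 alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  stopifnot(length(x) == length(y))
  d <- x - y
  d <- d[d != 0]
  if (length(d) == 0) {
    warning("all paired differences are zero; p = 1")
    return(list(statistic = NA_real_, p = 1, n = 0L, exact = FALSE))
  }
  if (length(d) < 5)
    stop("need at least 5 non-zero paired differences")
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  exact <- length(d) <= 25 && !any(duplicated(abs(d)))
  suppressWarnings(
    ht <- stats::wilcox.test(d, alternative = alternative, exact = exact,
                             correct = !exact)
  )
  list(statistic = unname(v), p = unname(ht$p.value), n = length(d),
       exact = exact)
}

#' Bonferroni correction
#'
#' @param p raw p-value(s).
#' @param m number of comparisons (>= 1).
#' @return `min(1, p * m)`, vectorised over `p`.
#' @examples
#' bonferroni(0.001, 90)  # 0.09
#' @export
bonferroni <- function(p, m) {
  if (m < 1) stop("`m` must be >= 1")
  pmin(1, p * m)
}

#' Binomial chance band for a multiclass decoder
#'
#' Two-sided interval containing the empirical accuracy of an uninformed
#' classifier with probability `level`: exact binomial quantiles at success
#' probability `1/n_classes` over `n_eval` evaluation trials, divided by
#' `n_eval`. When several accuracies are checked jointly (e.g. every
#' sliding window of a time course), divide the miss probability across
#' the family first (`level = 1 - (1 - level)/m`).
#'
#' @param n_classes number of classes.
#' @param n_eval number of evaluation trials (>= 1).
#' @param level coverage level.
#' @return named vector `c(lo, hi)`.
#' @export
chance_band <- function(n_classes, n_eval, level = 0.95) {
  stopifnot(n_eval >= 1, n_classes >= 2)
  a <- (1 - level) / 2
  p <- 1 / n_classes
  c(lo = stats::qbinom(a, n_eval, p) / n_eval,
    hi = stats::qbinom(1 - a, n_eval, p) / n_eval)
}
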