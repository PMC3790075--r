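#' Mann-Whitney U test (two-sided)
#'
#' Rank-sum U statistic with midranks for ties.  The p-value is exact (by
#' enumeration of labelings) when the combined sample size is at most 12
#' and there are no ties, and otherwise uses the normal approximation with
#' tie and continuity corrections.  This is the sentence-level test used to
#' compare familiarity scores between the familiar and novel conditions.
#'
#' @param x,y Non-empty numeric samples.
#' @return List with `U` (the statistic for `x`) and `p_two_sided`.
#' @export
mann_whitney_u <- function(x, y) {
  if (!length(x) || !length(y)) stop_param("samples must be non-empty")
  if (any(!is.finite(c(x, y)))) stop_param("samples must be finite")
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- !ties && (length(x) + length(y)) <= 12L
  ht <- stats::wilcox.test(x, y, exact = exact, correct = TRUE,
                           alternative = "two.sided")
  list(U = unname(ht$statistic), p_two_sided = ht$p.value)
}

#' Two-sample t-test on listening times
#'
#' Welch's statistic with Welch--Satterthwaite degrees of freedom by
#' default (the safer choice under unequal variances); the pooled-variance
#' variant is available via `pooled = TRUE`.
#'
#' @param x,y Numeric samples of size at least 2; at least one must have
#'   nonzero variance.
#' @param pooled Use the pooled-variance (Student) variant.
#' @return List with `t`, `df` and `p_two_sided`.
#' @export
welch_t <- function(x, y, pooled = FALSE) {
  if (length(x) < 2L || length(y) < 2L) {
    stop_param("each sample needs at least 2 observations")
  }
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    stop_param("both samples are constant; t statistic undefined")
  }
  ht <- stats::t.test(x, y, var.equal = pooled, alternative = "two.sided")
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_two_sided = ht$p.value)
}
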