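#' Equivalence of a group mean to zero
#'
#' Tests whether a group's mean outcome is equivalent to zero within a margin
#' `delta`, i.e. H0: |mu| >= delta against H1: |mu| < delta, by the
#' intersection-union of two one-sided t tests (TOST). The p-value is
#'
#'   p = max( P(T_df <= (estimate - delta)/se),
#'            P(T_df >= (estimate + delta)/se) )
#'
#' so a small p supports equivalence. In the growth setting `delta` is the
#' expected-growth half-width (0.67 change-in-Z-score units): rejecting H0
#' declares the group's mean change in Z-score consistent with expected
#' growth. Student's t with the group's own degrees of freedom is used
#' because pattern groups can be small.
#'
#' @param estimate Sample mean (outcome units).
#' @param se Positive standard error of the mean.
#' @param df Degrees of freedom (n - 1 for a one-sample mean).
#' @param delta Positive equivalence margin, same units as `estimate`.
#' @return One-row tibble: `estimate`, `se`, `df`, `delta`, `p_value`.
#' @examples
#' equivalence_to_zero(0, se = 0.1, df = 50, delta = 0.67)
#' @export
equivalence_to_zero <- function(estimate, se, df, delta) {
  if (!is.numeric(se) || any(se <= 0) || anyNA(se)) {
    stop("`se` must be > 0.", call. = FALSE)
  }
  if (!is.numeric(delta) || any(delta <= 0) || anyNA(delta)) {
    stop("`delta` must be > 0.", call. = FALSE)
  }
  if (!is.numeric(df) || any(df < 1) || anyNA(df)) {
    stop("`df` must be >= 1.", call. = FALSE)
  }
  p <- pmax(stats::pt((estimate - delta) / se, df),
            stats::pt((estimate + delta) / se, df, lower.tail = FALSE))
  tibble::tibble(estimate = estimate, se = se, df = df,
                 delta = delta, p_value = p)
}

#' One-sample difference-from-zero test
#'
#' Two-sided one-sample t test of mean zero, used by the post-hoc screen to
#' check that a crude-contrast group genuinely deviates from expected growth.
#'
#' @param outcomes Numeric vector, n >= 2, with non-zero variance.
#' @return The two-sided p-value.
#' @export
one_sample_difference <- function(outcomes) {
  outcomes <- outcomes[!is.na(outcomes)]
  if (length(outcomes) < 2L) {
    stop("need at least 2 non-missing observations.", call. = FALSE)
  }
  if (stats::sd(outcomes) == 0) {
    stop("degenerate sample: zero variance.", call. = FALSE)
  }
  stats::t.test(outcomes, mu = 0)$p.value
}

#' Welch two-sample test
#'
#' Two-sided Welch t test (Satterthwaite degrees of freedom) of equal means,
#' used by the post-hoc screen to compare a significant pattern's group with
#' its crude-contrast group without assuming equal variances.
#'
#' @param group_a,group_b Numeric vectors, each n >= 2; at least one with
#'   non-zero variance.
#' @return The two-sided p-value.
#' @export
welch_two_sample <- function(group_a, group_b) {
  group_a <- group_a[!is.na(group_a)]
  group_b <- group_b[!is.na(group_b)]
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("both groups need at least 2 non-missing observations.",
         call. = FALSE)
  }
  if (stats::sd(group_a) == 0 && stats::sd(group_b) == 0) {
    stop("degenerate samples: zero variance in both groups.", call. = FALSE)
  }
  stats::t.test(group_a, group_b, var.equal = FALSE)$p.value
}
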