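#' Summarize one group of diversity values
#'
#' Mean, sample standard deviation (n - 1 denominator) and group size, plus
#' the Anderson-Darling normality p-value when the group is large enough.
#' Following the reporting convention for small-n group summaries, the AD
#' p-value is not computed when `n < 8` (`ad_p` is `NA` and `ad_note` says
#' why). A zero-variance group is flagged degenerate rather than erroring,
#' since the summary itself is still well defined.
#'
#' @param values Numeric vector of per-sample index values.
#' @param group Group label, `"disturbed"` or `"control"` (free-form allowed).
#' @return A `group_summary`: list with `group`, `mean`, `sd`, `n`, `ad_p`,
#'   `ad_note` (`""`, `"not computed"`, or `"degenerate"`).
#' @export
summarize_group <- function(values, group = "group") {
  if (length(values) == 0) stop("cannot summarize an empty group")
  if (anyNA(values)) stop("group values contain NA")
  n <- length(values)
  ad_p <- NA_real_
  ad_note <- ""
  if (n < 8) {
    ad_note <- "not computed"
  } else {
    ad <- tryCatch(anderson_darling_normality(values),
                   error = function(e) NULL)
    if (is.null(ad)) ad_note <- "degenerate" else ad_p <- ad$p
  }
  structure(
    list(group = group, mean = mean(values), sd = if (n > 1) sd(values) else 0,
         n = n, ad_p = ad_p, ad_note = ad_note),
    class = "group_summary"
  )
}

#' Construct a group summary from printed statistics
#'
#' Builds a `group_summary` directly from (mean, sd, n) so published summary
#' rows can be fed to [welch_t_test()] without the raw data.
#'
#' @param mean,sd,n Group mean, sample SD and size.
#' @param group Group label.
#' @return A `group_summary` (with `ad_p = NA`).
#' @export
group_summary <- function(mean, sd, n, group = "group") {
  if (n < 1) stop("group size must be >= 1")
  if (sd < 0) stop("sd must be >= 0")
  structure(
    list(group = group, mean = mean, sd = sd, n = n,
         ad_p = NA_real_, ad_note = "not computed"),
    class = "group_summary"
  )
}

#' Two-tailed Welch t-test from group summaries
#'
#' Welch's unequal-variance t-test computed from (mean, sd, n) pairs:
#' \deqn{t = \frac{\bar{x}_1 - \bar{x}_2}{\sqrt{s_1^2/n_1 + s_2^2/n_2}},
#'   \qquad \nu = \frac{(s_1^2/n_1 + s_2^2/n_2)^2}
#'   {\frac{(s_1^2/n_1)^2}{n_1 - 1} + \frac{(s_2^2/n_2)^2}{n_2 - 1}}}
#' (Welch-Satterthwaite degrees of freedom), with the two-tailed p-value from
#' the Student-t distribution. Operating on summaries means published
#' (mean, SD, n) table rows are directly testable.
#'
#' @param summary1,summary2 `group_summary` objects (each `n >= 2`); the sign
#'   of `t` follows `mean1 - mean2`.
#' @param alpha Significance threshold for the `significant` flag
#'   (default 0.05).
#' @return A `welch_result`: list with `t`, `df`, `p`, `significant`, `alpha`.
#' @examples
#' welch_t_test(group_summary(199, 16.5, 6), group_summary(116, 33.4, 8))
#' @export
welch_t_test <- function(summary1, summary2, alpha = 0.05) {
  stopifnot(inherits(summary1, "group_summary"), inherits(summary2, "group_summary"))
  if (summary1$n < 2 || summary2$n < 2)
    stop("Welch's t-test needs n >= 2 in both groups")
  a <- summary1$sd^2 / summary1$n
  b <- summary2$sd^2 / summary2$n
  if (a + b == 0) {
    if (summary1$mean == summary2$mean)
      stop("Welch's t-test undefined: both groups have zero variance and equal means")
    t <- sign(summary1$mean - summary2$mean) * Inf
    df <- summary1$n + summary2$n - 2
    p <- 0
  } else {
    t <- (summary1$mean - summary2$mean) / sqrt(a + b)
    df <- (a + b)^2 / (a^2 / (summary1$n - 1) + b^2 / (summary2$n - 1))
    p <- 2 * min(pt(abs(t), df, lower.tail = FALSE), 0.5)
  }
  structure(
    list(t = t, df = df, p = p, significant = p < alpha, alpha = alpha),
    class = "welch_result"
  )
}

#' @export
print.welch_result <- function(x, ...) {
  cat(sprintf("<welch_result> t=%.4f  df=%.3f  p=%.4g  %s at alpha=%g\n",
              x$t, x$df, x$p,
              if (x$significant) "significant" else "not significant", x$alpha))
  invisible(x)
}

#' Anderson-Darling normality test
#'
#' Case-3 Anderson-Darling test (mean and variance estimated from the data),
#' with the small-sample adjusted statistic
#' \eqn{A^{*2} = A^2 (1 + 0.75/n + 2.25/n^2)} and the D'Agostino-Stephens
#' piecewise-exponential p-value approximation, as implemented by
#' [nortest::ad.test()]. Matching the reporting convention for small groups,
#' `n < 8` returns a "not computed" sentinel rather than a p-value.
#'
#' @param values Numeric vector.
#' @return An `ad_result`: list with `computed` (logical), and when computed
#'   `A2`, `A2_star`, `p`, `n`.
#' @export
anderson_darling_normality <- function(values) {
  n <- length(values)
  if (n < 8) {
    return(structure(list(computed = FALSE, n = n), class = "ad_result"))
  }
  if (sd(values) == 0)
    stop("Anderson-Darling statistic undefined for zero-variance data")
  ad <- nortest::ad.test(values)
  A2 <- unname(ad$statistic)
  structure(
    list(computed = TRUE, A2 = A2,
         A2_star = A2 * (1 + 0.75 / n + 2.25 / n^2),
         p = ad$p.value, n = n),
    class = "ad_result"
  )
}

#' Compare two groups of diversity values
#'
#' Bundles the per-group summaries (with the AD screen) and the two-tailed
#' Welch t-test into one report row. The Welch test is run regardless of the
#' AD outcome; normality p-values are reported, not gating.
#'
#' @param disturbed,control Numeric vectors of per-sample index values
#'   (each `n >= 2`).
#' @param alpha Significance threshold (default 0.05).
#' @return A `group_comparison`: list with `disturbed`, `control`
#'   (`group_summary`) and `welch` (`welch_result`).
#' @export
compare_groups <- function(disturbed, control, alpha = 0.05) {
  s1 <- summarize_group(disturbed, "disturbed")
  s2 <- summarize_group(control, "control")
  structure(
    list(disturbed = s1, control = s2,
         welch = welch_t_test(s1, s2, alpha = alpha)),
    class = "group_comparison"
  )
}
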