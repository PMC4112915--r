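# Paired and pooled-variance two-sample t tests. These mirror stats::t.test
# but return the light-weight result records the pipeline, the effect-size
# converters and the Bayes-factor engine consume, and they surface
# degenerate inputs (zero-variance differences, zero pooled variance) as
# errors instead of NaN.

new_crowd_t <- function(t, df, p_value, mean_diff, design, n = NULL,
                        n_1 = NULL, n_2 = NULL) {
  structure(
    list(t = t, df = as.integer(df), p_value = p_value,
         mean_diff = mean_diff, design = design, n = n, n_1 = n_1, n_2 = n_2),
    class = "crowd_t"
  )
}

#' @export
print.crowd_t <- function(x, ...) {
  cat(sprintf("t(%d) = %.3f, two-tailed p = %.4g, mean difference = %.3f [%s]\n",
              x$df, x$t, x$p_value, x$mean_diff, x$design))
  invisible(x)
}

#' Two-tailed t-test for paired observations
#'
#' @param x,y Numeric vectors of equal length (the paired observations).
#' @return A `crowd_t` result with the t-statistic, `df = n - 1`, the
#'   two-tailed p-value from the central t distribution, and the mean
#'   difference `mean(x - y)`.
#' @examples
#' paired_t(c(1, 2, 4), c(0, 1, 2)) # t = 4, df = 2
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) {
    stop("length mismatch: x has ", length(x), " values, y has ", length(y),
         call. = FALSE)
  }
  n <- length(x)
  if (n < 2) stop("need at least 2 pairs", call. = FALSE)
  d <- x - y
  sd_d <- stats::sd(d)
  if (!is.finite(sd_d) || sd_d <= .Machine$double.eps * max(1, abs(mean(d)))) {
    stop("zero-variance differences: paired t-statistic is undefined",
         call. = FALSE)
  }
  t <- mean(d) / (sd_d / sqrt(n))
  df <- n - 1
  new_crowd_t(t, df, 2 * stats::pt(-abs(t), df), mean(d), "paired", n = n)
}

#' Pooled-variance two-sample (Student) t-test from group summaries
#'
#' Uses the classical pooled-variance form with
#' \eqn{df = n_1 + n_2 - 2} (not Welch).
#'
#' @param s An [independent_summary()].
#' @return A `crowd_t` result; `mean_diff` is `mean_1 - mean_2`.
#' @export
independent_t <- function(s) {
  stopifnot(inherits(s, "independent_summary"))
  sp2 <- ((s$n_1 - 1) * s$sd_1^2 + (s$n_2 - 1) * s$sd_2^2) / (s$n_1 + s$n_2 - 2)
  if (sp2 <= 0) stop("zero pooled variance: t-statistic is undefined",
                     call. = FALSE)
  se <- sqrt(sp2 * (1 / s$n_1 + 1 / s$n_2))
  t <- (s$mean_1 - s$mean_2) / se
  df <- s$n_1 + s$n_2 - 2
  new_crowd_t(t, df, 2 * stats::pt(-abs(t), df), s$mean_1 - s$mean_2,
              "independent", n_1 = s$n_1, n_2 = s$n_2)
}

#' Summarise two vectors for an independent-groups comparison
#'
#' Convenience builder for [independent_t()] and
#' [d_independent_from_summary()] from raw group vectors.
#'
#' @param x,y Numeric vectors; `x` is group 1.
#' @return An [independent_summary()].
#' @export
summarize_groups <- function(x, y) {
  independent_summary(mean(x), mean(y), stats::sd(x), stats::sd(y),
                      length(x), length(y))
}
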