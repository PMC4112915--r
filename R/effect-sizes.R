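# Effect sizes for paired and independent two-group designs.
#
# The paired-design effect size is Cohen's d_z: the mean difference divided
# by the standard deviation of the paired differences,
#   d_z = (mu_X - mu_Y) / sqrt(sd_X^2 + sd_Y^2 - 2 sd_X sd_Y rho_XY),
# estimable from a paired t-statistic as t / sqrt(n). Its sampling variance
# for fixed-effect pooling is (1/n + d_z^2 / (2n)) * 2 (1 - rho_XY).

#' Summary statistics of a paired comparison
#'
#' Bundles the five numbers that determine Cohen's \eqn{d_z} for dependent
#' groups: the two group means, the two group standard deviations, the
#' correlation between the paired observations, and the number of pairs.
#'
#' @param mean_x,mean_y Group means (e.g. mean MSE of a single guess and of
#'   the averaged guess).
#' @param sd_x,sd_y Group standard deviations; must be positive.
#' @param r_xy Correlation between the pairs of observations, in \[-1, 1\].
#' @param n Number of pairs (at least 2).
#' @return An object of class `paired_summary`.
#' @seealso [dz_from_summary()]
#' @examples
#' paired_summary(555, 508, 361, 305, r_xy = 0.88, n = 255)
#' @export
paired_summary <- function(mean_x, mean_y, sd_x, sd_y, r_xy, n) {
  stopifnot(is.numeric(mean_x), is.numeric(mean_y), is.numeric(sd_x),
            is.numeric(sd_y), is.numeric(r_xy), is.numeric(n))
  if (sd_x <= 0 || sd_y <= 0) {
    stop("standard deviations must be strictly positive (sd_x = ", sd_x,
         ", sd_y = ", sd_y, ")", call. = FALSE)
  }
  if (r_xy < -1 || r_xy > 1) {
    stop("r_xy must lie in [-1, 1], got ", r_xy, call. = FALSE)
  }
  n <- as.integer(n)
  if (is.na(n) || n < 2) stop("need at least 2 pairs, got n = ", n, call. = FALSE)
  structure(
    list(mean_x = as.numeric(mean_x), mean_y = as.numeric(mean_y),
         sd_x = as.numeric(sd_x), sd_y = as.numeric(sd_y),
         r_xy = as.numeric(r_xy), n = n),
    class = "paired_summary"
  )
}

#' Summary statistics of two independent groups
#'
#' @param mean_1,mean_2 Group means.
#' @param sd_1,sd_2 Group standard deviations; must be positive.
#' @param n_1,n_2 Group sizes (each at least 2).
#' @return An object of class `independent_summary`.
#' @seealso [d_independent_from_summary()], [independent_t()]
#' @export
independent_summary <- function(mean_1, mean_2, sd_1, sd_2, n_1, n_2) {
  if (sd_1 <= 0 || sd_2 <= 0) {
    stop("standard deviations must be strictly positive", call. = FALSE)
  }
  n_1 <- as.integer(n_1); n_2 <- as.integer(n_2)
  if (is.na(n_1) || is.na(n_2) || n_1 < 2 || n_2 < 2) {
    stop("both group sizes must be at least 2", call. = FALSE)
  }
  structure(
    list(mean_1 = as.numeric(mean_1), mean_2 = as.numeric(mean_2),
         sd_1 = as.numeric(sd_1), sd_2 = as.numeric(sd_2),
         n_1 = n_1, n_2 = n_2),
    class = "independent_summary"
  )
}

#' Construct a standardized mean difference estimate
#'
#' Builds a bare effect-size object from a value and its design, e.g. to
#' attach a confidence interval with [effect_ci()] to an estimate taken
#' from a published table.
#'
#' @param value The standardized mean difference.
#' @param design `"paired"` or `"independent"`.
#' @param n Number of pairs (paired design).
#' @param n_1,n_2 Group sizes (independent design).
#' @return An object of class `effect_size`.
#' @examples
#' effect_ci(effect_size(dz_from_t(8.48, 140), "paired", n = 140))
#' @export
effect_size <- function(value, design = c("paired", "independent"), n = NULL,
                        n_1 = NULL, n_2 = NULL) {
  design <- match.arg(design)
  if (design == "paired" && !is.null(n) && n < 2) {
    stop("n must be >= 2", call. = FALSE)
  }
  new_effect_size(as.numeric(value), design,
                  n = if (is.null(n)) NULL else as.integer(n),
                  n_1 = if (is.null(n_1)) NULL else as.integer(n_1),
                  n_2 = if (is.null(n_2)) NULL else as.integer(n_2))
}

new_effect_size <- function(value, design, n = NULL, n_1 = NULL, n_2 = NULL,
                            variance = NA_real_, ci_level = NA_real_,
                            ci_low = NA_real_, ci_high = NA_real_) {
  structure(
    list(value = value, design = design, n = n, n_1 = n_1, n_2 = n_2,
         variance = variance, ci_level = ci_level,
         ci_low = ci_low, ci_high = ci_high),
    class = "effect_size"
  )
}

#' @export
print.effect_size <- function(x, ...) {
  lab <- if (x$design == "paired") "d_z" else "d"
  cat(sprintf("%s = %.3f (%s design", lab, x$value, x$design))
  if (!is.null(x$n)) cat(sprintf(", n = %d", x$n))
  if (!is.null(x$n_1)) cat(sprintf(", n1 = %d, n2 = %d", x$n_1, x$n_2))
  cat(")\n")
  if (!is.na(x$ci_level)) {
    cat(sprintf("%.0f%% CI [%.3f, %.3f]\n", 100 * x$ci_level, x$ci_low, x$ci_high))
  }
  invisible(x)
}

#' Cohen's d_z from paired summary statistics
#'
#' Computes the standardized mean difference for dependent groups,
#' \eqn{d_z = (\mu_X - \mu_Y) / \sqrt{\sigma_X^2 + \sigma_Y^2 -
#' 2\sigma_X\sigma_Y\rho_{XY}}}, together with its pooling variance
#' ([var_dz()]) and a confidence interval ([effect_ci()]).
#'
#' @param s A [paired_summary()].
#' @param ci_level Confidence level for the interval (default 0.95).
#' @return An [`effect_size`][dz_from_summary] object with `design = "paired"`.
#' @examples
#' dz_from_summary(paired_summary(555, 508, 361, 305, 0.88, 255))
#' @export
dz_from_summary <- function(s, ci_level = 0.95) {
  stopifnot(inherits(s, "paired_summary"))
  sd_diff2 <- s$sd_x^2 + s$sd_y^2 - 2 * s$sd_x * s$sd_y * s$r_xy
  if (sd_diff2 <= .Machine$double.eps * (s$sd_x^2 + s$sd_y^2)) {
    stop("degenerate pairs: sd_x = ", s$sd_x, ", sd_y = ", s$sd_y,
         ", r_xy = ", s$r_xy, " give a zero difference SD", call. = FALSE)
  }
  value <- (s$mean_x - s$mean_y) / sqrt(sd_diff2)
  est <- new_effect_size(value, "paired", n = s$n,
                         variance = var_dz(value, s$n, s$r_xy))
  effect_ci(est, ci_level)
}

#' Cohen's d_z from a paired t-statistic
#'
#' The standardized mean difference for dependent groups can be estimated
#' from the t-statistic of the paired test as \eqn{\hat d_z = t / \sqrt{n}}.
#'
#' @param t Paired t-statistic.
#' @param n Number of pairs (at least 2).
#' @return The estimate \eqn{t/\sqrt{n}} as a bare number; sign preserved.
#' @examples
#' dz_from_t(4.41, 255) # ~0.28
#' @export
dz_from_t <- function(t, n) {
  n <- as.integer(n)
  if (is.na(n) || n < 2) stop("invalid sample size: n must be >= 2", call. = FALSE)
  t / sqrt(n)
}

#' Sampling variance of Cohen's d_z
#'
#' Variance of the paired-design standardized mean difference used for
#' inverse-variance pooling:
#' \eqn{v = (1/n + d_z^2/(2n)) \cdot 2(1 - r_{XY})}. The pooling weight is
#' its reciprocal.
#'
#' @param d_z Effect-size estimate.
#' @param n Number of pairs.
#' @param r_xy Correlation between the paired observations.
#' @return The variance; 0 when `r_xy = 1` (perfectly correlated pairs), in
#'   which case [pool_effects()] refuses the implied infinite weight.
#' @export
var_dz <- function(d_z, n, r_xy) {
  n <- as.integer(n)
  if (is.na(n) || n < 2) stop("invalid sample size: n must be >= 2", call. = FALSE)
  if (r_xy < -1 || r_xy > 1) stop("r_xy must lie in [-1, 1]", call. = FALSE)
  (1 / n + d_z^2 / (2 * n)) * 2 * (1 - r_xy)
}

#' A single study's paired effect for pooling
#'
#' @param label Study label.
#' @param d_z Paired-design effect size.
#' @param n Number of pairs.
#' @param r_xy Correlation between the paired observations.
#' @return An object of class `study_effect`.
#' @export
study_effect <- function(label, d_z, n, r_xy) {
  n <- as.integer(n)
  if (is.na(n) || n < 2) stop("n must be >= 2", call. = FALSE)
  if (r_xy < -1 || r_xy > 1) stop("r_xy must lie in [-1, 1]", call. = FALSE)
  structure(list(label = as.character(label), d_z = as.numeric(d_z),
                 n = n, r_xy = as.numeric(r_xy)),
            class = "study_effect")
}

#' Fixed-effect inverse-variance pooling of paired effect sizes
#'
#' Pools study-level \eqn{d_z} estimates as
#' \eqn{\bar d_z = \sum_i w_i \hat d_{zi} / \sum_i w_i} with
#' \eqn{w_i = 1/v_i} from [var_dz()].
#'
#' @param studies One of: a data frame with columns `label`, `t`, `n`, `r`
#'   (the effect-table CSV layout; \eqn{d_z} is recomputed as
#'   \eqn{t/\sqrt n}), a data frame with columns `label`, `d_z`, `n`, `r_xy`,
#'   or a list of [study_effect()] objects.
#' @return An object of class `pooled_effect` with fields `value`, `k`,
#'   `weights`, `total_weight` and the normalized `studies` table.
#' @examples
#' studies <- data.frame(
#'   label = c("a", "b", "c"),
#'   t = c(4.41, 2.15, 1.71),
#'   n = c(255, 170, 201),
#'   r = c(0.88, 0.91, 0.95)
#' )
#' pool_effects(studies) # ~0.17
#' @export
pool_effects <- function(studies) {
  df <- normalize_studies(studies)
  if (nrow(df) == 0) stop("empty study list: nothing to pool", call. = FALSE)
  v <- mapply(var_dz, df$d_z, df$n, df$r_xy)
  if (any(v <= 0)) {
    bad <- df$label[v <= 0]
    stop("zero effect-size variance (r_xy = 1?) implies an infinite pooling ",
         "weight for: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  w <- 1 / v
  value <- sum(w * df$d_z) / sum(w)
  df$variance <- v
  df$weight <- w
  structure(
    list(value = value, k = nrow(df), weights = w, total_weight = sum(w),
         studies = df),
    class = "pooled_effect"
  )
}

normalize_studies <- function(studies) {
  if (is.data.frame(studies)) {
    df <- studies
    if (is.null(df$label)) df$label <- paste0("study_", seq_len(nrow(df)))
    if (is.null(df$r_xy)) df$r_xy <- df$r
    if (is.null(df$d_z)) {
      if (is.null(df$t)) {
        stop("study table needs either a d_z or a t column", call. = FALSE)
      }
      df$d_z <- mapply(dz_from_t, df$t, df$n)
    }
    if (is.null(df$n) || is.null(df$r_xy)) {
      stop("study table needs n and r (or r_xy) columns", call. = FALSE)
    }
    df[, c("label", "d_z", "n", "r_xy")]
  } else if (is.list(studies)) {
    if (!all(vapply(studies, inherits, logical(1), "study_effect"))) {
      stop("expected a data frame or a list of study_effect objects",
           call. = FALSE)
    }
    do.call(rbind, lapply(studies, function(s) {
      data.frame(label = s$label, d_z = s$d_z, n = s$n, r_xy = s$r_xy)
    }))
  } else {
    stop("expected a data frame or a list of study_effect objects",
         call. = FALSE)
  }
}

#' @export
print.pooled_effect <- function(x, ...) {
  cat(sprintf("Pooled d_z = %.3f over k = %d studies (fixed effect)\n",
              x$value, x$k))
  print(x$studies, row.names = FALSE)
  invisible(x)
}

#' Independent-groups effect size from summary statistics
#'
#' Standardized mean difference for two independent groups using the pooled
#' standard deviation with \eqn{n-1} weights:
#' \eqn{d = (m_1 - m_2) / s_p}, \eqn{s_p^2 = ((n_1-1)s_1^2 +
#' (n_2-1)s_2^2)/(n_1+n_2-2)}.
#'
#' @param s An [independent_summary()].
#' @param ci_level Confidence level for the interval.
#' @return An [`effect_size`][dz_from_summary] object with
#'   `design = "independent"`.
#' @examples
#' d_independent_from_summary(independent_summary(121, 73, 169, 155, 140, 471))
#' @export
d_independent_from_summary <- function(s, ci_level = 0.95) {
  stopifnot(inherits(s, "independent_summary"))
  sp2 <- ((s$n_1 - 1) * s$sd_1^2 + (s$n_2 - 1) * s$sd_2^2) / (s$n_1 + s$n_2 - 2)
  if (sp2 <= 0) stop("degenerate groups: pooled SD is zero", call. = FALSE)
  value <- (s$mean_1 - s$mean_2) / sqrt(sp2)
  N <- s$n_1 + s$n_2
  est <- new_effect_size(value, "independent", n_1 = s$n_1, n_2 = s$n_2,
                         variance = N / (s$n_1 * s$n_2) + value^2 / (2 * N))
  effect_ci(est, ci_level)
}

#' Independent-groups effect size from a t-statistic
#'
#' @param t Pooled-variance two-sample t-statistic.
#' @param n_1,n_2 Group sizes.
#' @return The estimate \eqn{t \sqrt{1/n_1 + 1/n_2}}.
#' @examples
#' d_independent_from_t(1.56, 255, 173) # ~0.15
#' @export
d_independent_from_t <- function(t, n_1, n_2) {
  n_1 <- as.integer(n_1); n_2 <- as.integer(n_2)
  if (is.na(n_1) || is.na(n_2) || n_1 < 2 || n_2 < 2) {
    stop("invalid sample size: both groups need n >= 2", call. = FALSE)
  }
  t * sqrt(1 / n_1 + 1 / n_2)
}

#' Confidence interval for a standardized mean difference
#'
#' Default method is the normal approximation on the effect-size scale with
#' variance \eqn{1/n + d^2/(2n)} (paired) or
#' \eqn{(n_1+n_2)/(n_1 n_2) + d^2/(2(n_1+n_2))} (independent). An exact
#' noncentral-t inversion is available as an optional mode.
#'
#' @param e An [`effect_size`][dz_from_summary] object with its sample size
#'   set.
#' @param level Confidence level in (0, 1).
#' @param method `"normal"` (default) or `"noncentral"`.
#' @return The effect-size object with `ci_level`, `ci_low`, `ci_high` set.
#' @export
effect_ci <- function(e, level = 0.95, method = c("normal", "noncentral")) {
  stopifnot(inherits(e, "effect_size"))
  method <- match.arg(method)
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)", call. = FALSE)
  paired <- identical(e$design, "paired")
  if (paired && is.null(e$n)) {
    stop("incomplete estimate: paired effect size needs n", call. = FALSE)
  }
  if (!paired && (is.null(e$n_1) || is.null(e$n_2))) {
    stop("incomplete estimate: independent effect size needs n_1 and n_2",
         call. = FALSE)
  }
  d <- e$value
  if (method == "normal") {
    V <- if (paired) {
      1 / e$n + d^2 / (2 * e$n)
    } else {
      (e$n_1 + e$n_2) / (e$n_1 * e$n_2) + d^2 / (2 * (e$n_1 + e$n_2))
    }
    z <- stats::qnorm((1 + level) / 2)
    e$ci_low <- d - z * sqrt(V)
    e$ci_high <- d + z * sqrt(V)
  } else {
    # invert the noncentral-t CDF for the noncentrality parameter, then map
    # back to the effect-size scale through the design's scaling factor
    scale <- if (paired) sqrt(e$n) else sqrt(e$n_1 * e$n_2 / (e$n_1 + e$n_2))
    df <- if (paired) e$n - 1 else e$n_1 + e$n_2 - 2
    t_obs <- d * scale
    e$ci_low <- ncp_root(t_obs, df, 1 - (1 - level) / 2) / scale
    e$ci_high <- ncp_root(t_obs, df, (1 - level) / 2) / scale
  }
  e$ci_level <- level
  e
}

# smallest ncp with P(T_{df, ncp} <= t_obs) = prob. pt() warns about its
# last digits at extreme noncentrality; the root is only needed to ~1e-8.
ncp_root <- function(t_obs, df, prob) {
  f <- function(ncp) suppressWarnings(stats::pt(t_obs, df, ncp = ncp)) - prob
  lo <- t_obs - 10 - 5 * abs(t_obs)
  hi <- t_obs + 10 + 5 * abs(t_obs)
  stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
}
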