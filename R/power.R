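# Exact power analysis for the paired t-test via the noncentral t
# distribution, plus the detectability effect size d_33%: the effect an
# original study had 33% power to detect. A replication whose estimate is
# significantly below d_33% fails the detectability criterion even if its
# own test rejects the null.

#' Exact power of the paired t-test
#'
#' Power is computed from the noncentral t distribution with noncentrality
#' \eqn{\delta = d_z \sqrt n} and \eqn{df = n - 1}; the rejection region
#' comes from the central t at `alpha`. No normal approximation is used, so
#' small-n planning cases are exact.
#'
#' @param d_z True paired-design effect size.
#' @param n Number of pairs (at least 2).
#' @param alpha Type-I error rate (default 0.05).
#' @param tails `"two"` (default) or `"one"`. One-tailed power puts the
#'   whole rejection region on the side of `d_z`'s sign.
#' @return The rejection probability. Equals `alpha` at `d_z = 0`
#'   (two-tailed).
#' @examples
#' paired_t_power(0.10, 255) # ~0.33
#' @export
paired_t_power <- function(d_z, n, alpha = 0.05, tails = c("two", "one")) {
  tails <- match.arg(tails)
  n <- as.integer(n)
  if (is.na(n) || n < 2) stop("invalid sample size: n must be >= 2", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  df <- n - 1
  ncp <- d_z * sqrt(n)
  if (tails == "two") {
    tc <- stats::qt(1 - alpha / 2, df)
    stats::pt(-tc, df, ncp = ncp) + stats::pt(tc, df, ncp = ncp,
                                              lower.tail = FALSE)
  } else {
    tc <- stats::qt(1 - alpha, df)
    if (d_z >= 0) {
      stats::pt(tc, df, ncp = ncp, lower.tail = FALSE)
    } else {
      stats::pt(-tc, df, ncp = ncp)
    }
  }
}

#' Smallest sample size reaching a target power
#'
#' Monotone search for the smallest integer \eqn{n \ge 2} whose exact
#' paired-t power ([paired_t_power()]) is at least `power` (the usual
#' ceiling convention in planning).
#'
#' @param d_z Assumed true effect size; must be nonzero.
#' @param power Target power in (alpha, 1).
#' @param alpha,tails Test settings, as in [paired_t_power()].
#' @return The planned number of pairs.
#' @examples
#' required_n(0.56, power = 0.95)
#' @export
required_n <- function(d_z, power, alpha = 0.05, tails = c("two", "one")) {
  tails <- match.arg(tails)
  if (d_z == 0) {
    stop("unattainable power: d_z = 0 never exceeds alpha", call. = FALSE)
  }
  if (power <= alpha || power >= 1) {
    stop("target power must lie in (alpha, 1)", call. = FALSE)
  }
  # geometric bracket then binary search; power is increasing in n
  hi <- 2L
  while (paired_t_power(d_z, hi, alpha, tails) < power) {
    hi <- hi * 2L
    if (hi > 1e7) stop("required n exceeds 1e7; check inputs", call. = FALSE)
  }
  lo <- max(2L, hi %/% 2L)
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (paired_t_power(d_z, mid, alpha, tails) >= power) hi <- mid else lo <- mid + 1L
  }
  hi
}

#' Effect size detectable at a given power (d_33% and friends)
#'
#' Finds the positive \eqn{d} solving `paired_t_power(d, n) = power` by
#' bracketed root-finding. With `power = 0.33` this is the detectability
#' benchmark \eqn{d_{33\%}} evaluated at the original study's sample size.
#'
#' @param n Number of pairs in the reference study.
#' @param power Target power; must exceed the attainable floor (`alpha` for
#'   a two-tailed test).
#' @param alpha,tails Test settings, as in [paired_t_power()].
#' @param tol Root-finding tolerance on \eqn{d} (default 1e-8).
#' @return The positive effect size; 0 when `power == alpha` (two-tailed).
#' @examples
#' detectable_effect(255, power = 0.33) # ~0.10
#' @export
detectable_effect <- function(n, power = 0.33, alpha = 0.05,
                              tails = c("two", "one"), tol = 1e-8) {
  tails <- match.arg(tails)
  n <- as.integer(n)
  if (is.na(n) || n < 2) stop("invalid sample size: n must be >= 2", call. = FALSE)
  floor_power <- if (tails == "two") alpha else alpha
  if (power < floor_power || power >= 1) {
    stop("no root: target power must lie in [alpha, 1)", call. = FALSE)
  }
  if (power == floor_power) return(0)
  hi <- 1
  while (paired_t_power(hi, n, alpha, tails) < power) hi <- hi * 2
  stats::uniroot(function(d) paired_t_power(d, n, alpha, tails) - power,
                 c(0, hi), tol = tol)$root
}
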