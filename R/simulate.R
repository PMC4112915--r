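# Synthetic cohorts under the internal-sampling account of repeated
# guessing: each answer is drawn around a participant-specific belief, so
# two guesses share a bias component but carry partly independent sampling
# noise, and averaging them cancels part of that noise.
#
# Generative model, participant i, question q:
#   guess_k(i, q) = truth_q + b_iq + e_k(i, q),        k = 1, 2
#   b_iq ~ N(0, tau^2)
#   (e_1, e_2) ~ bivariate normal, sd sigma (guess 2: sigma * g2_sd_inflation),
#                correlation rho
# Unclipped closed forms (g2_sd_inflation = 1):
#   E[MSE single]  = tau^2 + sigma^2
#   E[MSE average] = tau^2 + sigma^2 (1 + rho) / 2
#   benefit        = sigma^2 (1 - rho) / 2
# A shorter delay between guesses means less independent sampling, i.e. a
# larger rho and a smaller benefit of averaging.

#' Parameters of a synthetic guessing cohort
#'
#' Defaults are calibrated to the scale of published inner-crowd MSE
#' summaries: `tau^2 = 450` (squared-percent bias variance), `sigma^2 = 150`
#' (per-guess sampling noise), `rho = 0.36` for an immediate second guess
#' (implied averaging benefit `sigma^2 (1 - rho) / 2 = 48`), and a mild
#' guess-2 noise inflation of 1.05 reproducing the observation that second
#' guesses are slightly worse than first guesses. For a delayed second
#' guess use a smaller `rho` (e.g. 0.10): delay increases the independence
#' of the two samples.
#'
#' @param n_participants Number of participants.
#' @param n_questions Number of questions (default 8).
#' @param truths True answers in percent; default the current answer key of
#'   [default_questions()].
#' @param tau SD of the participant-by-question bias `b`, percent units.
#' @param sigma SD of the per-guess sampling noise, percent units.
#' @param rho Correlation of the two guesses' noise terms, in \[-1, 1\].
#' @param condition Condition label stamped on the records.
#' @param clip If `TRUE`, clamp guesses into \[0, 100\]. Off by default:
#'   the analytic expectations in [expected_mse()] hold only unclipped.
#' @param exclusion_rates Named proportions (`incomplete`, `looked_up`,
#'   `defocused`) with which the corresponding flags are drawn; all 0 by
#'   default.
#' @param g2_sd_inflation Multiplier (>= 1 typically) on the guess-2 noise
#'   SD; 1.05 by default.
#' @param bias `"participant_question"` (default): an independent bias per
#'   participant-question cell. `"participant"`: one shared bias per
#'   participant across questions, which makes (tau^2, sigma^2, rho)
#'   jointly identifiable from second moments (see
#'   [estimate_cohort_params()]).
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @return A list of class `cohort_params`.
#' @export
cohort_params <- function(n_participants,
                          n_questions = 8,
                          truths = default_questions()$truth,
                          tau = sqrt(450),
                          sigma = sqrt(150),
                          rho = 0.36,
                          condition = c("immediate", "delayed"),
                          clip = FALSE,
                          exclusion_rates = c(incomplete = 0, looked_up = 0,
                                              defocused = 0),
                          g2_sd_inflation = 1.05,
                          bias = c("participant_question", "participant"),
                          seed = NULL) {
  condition <- match.arg(condition)
  bias <- match.arg(bias)
  if (tau < 0 || sigma < 0) stop("tau and sigma must be nonnegative", call. = FALSE)
  if (rho < -1 || rho > 1) stop("rho must lie in [-1, 1]", call. = FALSE)
  if (length(truths) != n_questions) {
    stop("need one truth per question", call. = FALSE)
  }
  if (any(truths < 0 | truths > 100)) {
    stop("truths must be percentages in [0, 100]", call. = FALSE)
  }
  rates <- c(incomplete = 0, looked_up = 0, defocused = 0)
  rates[names(exclusion_rates)] <- exclusion_rates
  if (any(rates < 0 | rates > 1)) stop("exclusion rates must be proportions",
                                       call. = FALSE)
  if (g2_sd_inflation < 0) stop("g2_sd_inflation must be nonnegative",
                                call. = FALSE)
  structure(
    list(n_participants = as.integer(n_participants),
         n_questions = as.integer(n_questions),
         truths = as.numeric(truths), tau = tau, sigma = sigma, rho = rho,
         condition = condition, clip = clip, exclusion_rates = rates,
         g2_sd_inflation = g2_sd_inflation, bias = bias, seed = seed),
    class = "cohort_params"
  )
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Draw a synthetic cohort
#'
#' Samples guesses under the additive bias-plus-noise model described in
#' [cohort_params()], draws exclusion flags, and returns records in the
#' standard cohort layout. Fully reproducible from `p$seed`; the caller's
#' RNG state is restored afterwards.
#'
#' @param p A [cohort_params()] object.
#' @return A cohort data frame (one row per participant) with flag,
#'   demographic and guess columns.
#' @examples
#' head(sample_cohort(cohort_params(20, seed = 1)))
#' @export
sample_cohort <- function(p) {
  stopifnot(inherits(p, "cohort_params"))
  with_seed(p$seed, {
    n <- p$n_participants
    nq <- p$n_questions
    b <- if (p$bias == "participant_question") {
      matrix(stats::rnorm(n * nq, 0, p$tau), n, nq)
    } else {
      matrix(rep(stats::rnorm(n, 0, p$tau), nq), n, nq)
    }
    z1 <- matrix(stats::rnorm(n * nq), n, nq)
    z2 <- matrix(stats::rnorm(n * nq), n, nq)
    e1 <- p$sigma * z1
    e2 <- p$g2_sd_inflation * p$sigma *
      (p$rho * z1 + sqrt(1 - p$rho^2) * z2)
    truth <- matrix(p$truths, n, nq, byrow = TRUE)
    g1 <- truth + b + e1
    g2 <- truth + b + e2
    if (isTRUE(p$clip)) {
      g1 <- pmin(pmax(g1, 0), 100)
      g2 <- pmin(pmax(g2, 0), 100)
    }
    rates <- p$exclusion_rates
    cohort <- data.frame(
      participant_id = sprintf("%s_%04d", substr(p$condition, 1, 3), seq_len(n)),
      condition = p$condition,
      completed = stats::runif(n) >= rates[["incomplete"]],
      looked_up = stats::runif(n) < rates[["looked_up"]],
      defocused = stats::runif(n) < rates[["defocused"]],
      sex = sample(c("f", "m"), n, replace = TRUE, prob = c(0.84, 0.16)),
      age = pmax(18L, as.integer(round(stats::rnorm(n, 20, 2.5)))),
      stringsAsFactors = FALSE
    )
    colnames(g1) <- guess_cols(nq, 1)
    colnames(g2) <- guess_cols(nq, 2)
    cbind(cohort, as.data.frame(g1), as.data.frame(g2))
  })
}

#' Analytic MSE expectations under the generator
#'
#' Closed forms for the unclipped model (with `lambda = g2_sd_inflation`):
#' `E[mse_g1] = tau^2 + sigma^2`, `E[mse_g2] = tau^2 + lambda^2 sigma^2`,
#' `E[mse_avg] = tau^2 + sigma^2 (1 + lambda^2 + 2 rho lambda) / 4`; the
#' benefit of averaging relative to either guess is the corresponding
#' difference. At `lambda = 1` these reduce to the familiar
#' `tau^2 + sigma^2 (1 + rho) / 2` and benefit `sigma^2 (1 - rho) / 2`.
#'
#' @param p A [cohort_params()] with `clip = FALSE` (the closed forms do
#'   not hold under clamping, so clipped parameter sets are refused).
#' @return A list with `mse_g1`, `mse_g2`, `mse_avg`, `benefit_g1`,
#'   `benefit_g2`.
#' @examples
#' expected_mse(cohort_params(100, rho = 0.36, g2_sd_inflation = 1))
#' @export
expected_mse <- function(p) {
  stopifnot(inherits(p, "cohort_params"))
  if (isTRUE(p$clip)) {
    stop("expected_mse holds only for unclipped cohorts (clip = FALSE)",
         call. = FALSE)
  }
  lam <- p$g2_sd_inflation
  s2 <- p$sigma^2
  mse_g1 <- p$tau^2 + s2
  mse_g2 <- p$tau^2 + lam^2 * s2
  mse_avg <- p$tau^2 + s2 * (1 + lam^2 + 2 * p$rho * lam) / 4
  list(mse_g1 = mse_g1, mse_g2 = mse_g2, mse_avg = mse_avg,
       benefit_g1 = mse_g1 - mse_avg, benefit_g2 = mse_g2 - mse_avg)
}

#' Two-condition synthetic study
#'
#' Concatenates an immediate and a delayed cohort sharing the same
#' questions. Defaults mirror a two-condition replication with final
#' samples of 471 (immediate, `rho = 0.36`) and 140 (delayed,
#' `rho = 0.10`). When the delayed parameters carry no seed, it is derived
#' deterministically from the immediate seed (`seed + 1`).
#'
#' @param p_immediate,p_delayed [cohort_params()] for the two conditions;
#'   truths must match. Typically `p_delayed$rho <= p_immediate$rho`, since
#'   delay increases the independence of the two guesses.
#' @return A cohort data frame with both conditions stacked.
#' @export
make_two_condition_fixture <- function(
    p_immediate = cohort_params(471, condition = "immediate", rho = 0.36,
                                seed = 42),
    p_delayed = cohort_params(140, condition = "delayed", rho = 0.10)) {
  stopifnot(inherits(p_immediate, "cohort_params"),
            inherits(p_delayed, "cohort_params"))
  if (!isTRUE(all.equal(p_immediate$truths, p_delayed$truths))) {
    stop("the two conditions must share the same question truths",
         call. = FALSE)
  }
  if (is.null(p_delayed$seed) && !is.null(p_immediate$seed)) {
    p_delayed$seed <- p_immediate$seed + 1L
  }
  rbind(sample_cohort(p_immediate), sample_cohort(p_delayed))
}

#' Moment recovery of generator parameters from a cohort
#'
#' Method-of-moments estimates of `tau^2`, `sigma^2` and `rho` from the
#' error covariance structure of a *shared-bias* cohort
#' (`bias = "participant"`, `clip = FALSE`, `g2_sd_inflation = 1`). Under
#' the default per-question bias the second moments of the two error series
#' only identify `tau^2 + sigma^2` and `tau^2 + rho sigma^2`, so the three
#' parameters cannot be separated; the shared bias adds the cross-question
#' covariance (`tau^2`) that completes the system.
#'
#' @param cohort A cohort generated with `bias = "participant"`.
#' @param questions The [question_set()] used to generate it.
#' @return A list with `tau2`, `sigma2`, `rho`.
#' @export
estimate_cohort_params <- function(cohort, questions = default_questions()) {
  nq <- validate_cohort(cohort, require_flags = FALSE)
  truth <- matrix(questions$truth, nrow(cohort), nq, byrow = TRUE)
  err1 <- guess_matrix(cohort, 1, nq) - truth
  err2 <- guess_matrix(cohort, 2, nq) - truth
  off_diag_mean <- function(m) mean(m[row(m) != col(m)])
  c11 <- stats::cov(err1)
  c22 <- stats::cov(err2)
  c12 <- stats::cov(err1, err2)
  tau2 <- mean(c(off_diag_mean(c11), off_diag_mean(c22), off_diag_mean(c12)))
  total <- mean(c(diag(c11), diag(c22)))   # tau^2 + sigma^2
  sigma2 <- total - tau2
  rho <- (mean(diag(c12)) - tau2) / sigma2
  list(tau2 = tau2, sigma2 = sigma2, rho = rho)
}
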