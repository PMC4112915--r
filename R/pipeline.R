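# The confirmatory analysis pipeline: pre-registered cleaning, MSE accuracy
# scoring, within-condition paired tests, between-condition comparison of
# the averaging benefit, and the two replication verdicts (traditional
# significance and d_33% detectability).
#
# A cohort is a plain data frame, one row per participant, with columns
# participant_id, condition ("immediate"/"delayed"), completed, looked_up,
# defocused, optional sex/age, and guess columns q1_g1..qK_g1, q1_g2..qK_g2
# holding percentages in [0, 100] (NA = blank answer).

cohort_n_questions <- function(cohort) {
  nq <- sum(grepl("^q[0-9]+_g1$", names(cohort)))
  if (nq == 0) stop("no guess columns (q<k>_g1) found", call. = FALSE)
  nq
}

guess_cols <- function(nq, guess) paste0("q", seq_len(nq), "_g", guess)

guess_matrix <- function(cohort, guess, nq = cohort_n_questions(cohort)) {
  as.matrix(cohort[, guess_cols(nq, guess), drop = FALSE])
}

validate_cohort <- function(cohort, require_flags = TRUE) {
  required <- c("participant_id", "condition")
  if (require_flags) required <- c(required, "completed", "looked_up", "defocused")
  missing <- setdiff(required, names(cohort))
  if (length(missing)) {
    stop("cohort is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  nq <- cohort_n_questions(cohort)
  missing_g2 <- setdiff(guess_cols(nq, 2), names(cohort))
  if (length(missing_g2)) {
    stop("cohort is missing guess-2 column(s): ",
         paste(missing_g2, collapse = ", "), call. = FALSE)
  }
  invisible(nq)
}

#' Apply the pre-registered cleaning plan to a cohort
#'
#' Participant-level exclusions are applied in the order incomplete ->
#' defocused -> looked-up, each participant counted once under the first
#' rule it matches. The question-level rule then blanks *both* guesses of
#' any question with an impossible (outside \[0, 100\]) or blank answer, so
#' later MSE scoring averages over that participant's retained questions
#' only. Cleaning never fails; it only excludes.
#'
#' @param cohort A cohort data frame (see [read_cohort_csv()] for the
#'   schema).
#' @param questions A [question_set()]; used to validate alignment.
#' @param rules Named logical list switching individual rules on or off:
#'   `incomplete`, `defocused`, `looked_up`, `question_level` (all `TRUE` by
#'   default).
#' @return A list with `retained` (the cleaned cohort) and `log` (an
#'   `exclusion_log` with per-rule counts and ids).
#' @export
clean_cohort <- function(cohort, questions = default_questions(),
                         rules = list()) {
  nq <- validate_cohort(cohort)
  if (nq != nrow(questions)) {
    stop("cohort has ", nq, " questions but the question set has ",
         nrow(questions), call. = FALSE)
  }
  rules <- utils::modifyList(
    list(incomplete = TRUE, defocused = TRUE, looked_up = TRUE,
         question_level = TRUE),
    rules
  )
  n_in <- nrow(cohort)
  excluded_by <- rep(NA_character_, n_in)
  flag <- function(cond, rule) {
    hit <- is.na(excluded_by) & cond
    excluded_by[hit] <<- rule
  }
  if (isTRUE(rules$incomplete)) flag(!as.logical(cohort$completed), "incomplete")
  if (isTRUE(rules$defocused))  flag(as.logical(cohort$defocused), "defocused")
  if (isTRUE(rules$looked_up))  flag(as.logical(cohort$looked_up), "looked_up")

  keep <- is.na(excluded_by)
  retained <- cohort[keep, , drop = FALSE]
  ids <- split(as.character(cohort$participant_id[!keep]),
               excluded_by[!keep])

  question_removed <- 0L
  participants_affected <- 0L
  if (isTRUE(rules$question_level) && nrow(retained) > 0) {
    g1 <- guess_matrix(retained, 1, nq)
    g2 <- guess_matrix(retained, 2, nq)
    bad <- is.na(g1) | is.na(g2) | g1 < 0 | g1 > 100 | g2 < 0 | g2 > 100
    question_removed <- sum(bad)
    participants_affected <- sum(rowSums(bad) > 0)
    g1[bad] <- NA_real_
    g2[bad] <- NA_real_
    retained[, guess_cols(nq, 1)] <- g1
    retained[, guess_cols(nq, 2)] <- g2
  }

  counts <- c(incomplete = 0L, defocused = 0L, looked_up = 0L)
  tab <- table(excluded_by[!keep])
  counts[names(tab)] <- as.integer(tab)

  log <- structure(
    list(input = n_in, retained = nrow(retained), counts = counts,
         ids = ids,
         question_level = list(questions_removed = question_removed,
                               participants_affected = participants_affected)),
    class = "exclusion_log"
  )
  stopifnot(log$retained + sum(log$counts) == log$input)
  list(retained = retained, log = log)
}

#' @export
print.exclusion_log <- function(x, ...) {
  cat(sprintf("Cleaning: %d in, %d retained\n", x$input, x$retained))
  for (rule in names(x$counts)) {
    cat(sprintf("  excluded %-10s %d\n", paste0(rule, ":"), x$counts[[rule]]))
  }
  cat(sprintf("  question-level: %d question(s) blanked across %d participant(s)\n",
              x$question_level$questions_removed,
              x$question_level$participants_affected))
  invisible(x)
}

#' Per-participant accuracy table (MSE of guess 1, guess 2, and the average)
#'
#' For each participant, the error on each retained question is guess minus
#' truth, and the MSE is the mean squared error over that participant's
#' retained questions. The averaged guess is scored by first averaging
#' guess 1 and guess 2 per question and then computing the MSE
#' (average-then-score), which is what makes the within-person crowd
#' possible: by convexity `mse_avg <= (mse_g1 + mse_g2) / 2` always holds.
#'
#' @param cohort A cleaned cohort data frame.
#' @param questions A [question_set()] aligned with the guess columns.
#' @return A data frame with one row per scored participant:
#'   `participant_id`, `condition`, `n_questions`, `mse_g1`, `mse_g2`,
#'   `mse_avg`. Participants with no retained questions are dropped with a
#'   warning.
#' @export
accuracy_table <- function(cohort, questions = default_questions()) {
  nq <- validate_cohort(cohort, require_flags = FALSE)
  if (nq != nrow(questions)) {
    stop("cohort has ", nq, " questions but the question set has ",
         nrow(questions), call. = FALSE)
  }
  truth <- matrix(questions$truth, nrow = nrow(cohort), ncol = nq, byrow = TRUE)
  g1 <- guess_matrix(cohort, 1, nq)
  g2 <- guess_matrix(cohort, 2, nq)
  # a question counts only when both guesses are present
  joint_na <- is.na(g1) | is.na(g2)
  g1[joint_na] <- NA_real_
  g2[joint_na] <- NA_real_
  n_used <- rowSums(!joint_na)

  mse <- function(gm) rowMeans((gm - truth)^2, na.rm = TRUE)
  out <- data.frame(
    participant_id = as.character(cohort$participant_id),
    condition = as.character(cohort$condition),
    n_questions = n_used,
    mse_g1 = mse(g1),
    mse_g2 = mse(g2),
    mse_avg = mse((g1 + g2) / 2),
    stringsAsFactors = FALSE
  )
  if (any(n_used == 0)) {
    warning(sum(n_used == 0), " participant(s) had no retained questions ",
            "and were dropped from the accuracy table")
    out <- out[n_used > 0, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Within-condition paired comparisons
#'
#' Runs the three paired t-tests of one condition: average vs guess 1,
#' average vs guess 2, and guess 1 vs guess 2. The sign convention puts the
#' single guess first, so t > 0 means the single guess had the larger MSE
#' (averaging helped). Each comparison carries its \eqn{d_z} estimate
#' (\eqn{t/\sqrt n}), a confidence interval, and a one-sample JZS Bayes
#' factor.
#'
#' @param acc An [accuracy_table()] for a single condition.
#' @param ci_level Confidence level for effect-size intervals.
#' @param bf_scale Cauchy prior scale for the Bayes factors.
#' @return A list of class `condition_tests` with elements `avg_vs_g1`,
#'   `avg_vs_g2`, `g1_vs_g2` (each holding `test`, `effect`, `bf`), plus
#'   `n` and `condition`.
#' @export
within_condition_tests <- function(acc, ci_level = 0.95, bf_scale = 1) {
  n <- nrow(acc)
  if (n < 2) stop("need at least 2 participants", call. = FALSE)
  one <- function(x, y) {
    test <- paired_t(x, y)
    effect <- new_effect_size(dz_from_t(test$t, n), "paired", n = n)
    effect <- effect_ci(effect, ci_level)
    effect$variance <- 1 / n + effect$value^2 / (2 * n)
    list(test = test,
         effect = effect,
         bf = jzs_bf01_one_sample(test$t, n, bf_scale))
  }
  structure(
    list(avg_vs_g1 = one(acc$mse_g1, acc$mse_avg),
         avg_vs_g2 = one(acc$mse_g2, acc$mse_avg),
         g1_vs_g2 = one(acc$mse_g1, acc$mse_g2),
         n = n,
         condition = unique(as.character(acc$condition))),
    class = "condition_tests"
  )
}

#' Between-condition comparison of the averaging benefit
#'
#' The per-participant benefit of averaging is the MSE of the reference
#' guess minus the MSE of the averaged guess (positive = averaging helps).
#' The delayed and immediate benefit distributions are compared with a
#' pooled-variance unpaired Student t-test (df = n1 + n2 - 2), oriented
#' delayed minus immediate, with an independent-groups effect size and a
#' two-sample JZS Bayes factor.
#'
#' @param acc_immediate,acc_delayed [accuracy_table()]s of the two
#'   conditions.
#' @param reference `"guess1"` (the confirmatory comparison) or `"guess2"`
#'   (post-hoc).
#' @param ci_level Confidence level for the effect-size interval.
#' @param bf_scale Cauchy prior scale.
#' @return A list with `reference`, `test` (`crowd_t`), `effect`
#'   (`effect_size`), `bf` (`bayes_factor`) and the two benefit summaries.
#' @export
between_condition_test <- function(acc_immediate, acc_delayed,
                                   reference = c("guess1", "guess2"),
                                   ci_level = 0.95, bf_scale = 1) {
  reference <- match.arg(reference)
  if (nrow(acc_immediate) == 0 || nrow(acc_delayed) == 0) {
    stop("both accuracy tables must be nonempty", call. = FALSE)
  }
  col <- if (reference == "guess1") "mse_g1" else "mse_g2"
  benefit_imm <- acc_immediate[[col]] - acc_immediate$mse_avg
  benefit_del <- acc_delayed[[col]] - acc_delayed$mse_avg
  s <- summarize_groups(benefit_del, benefit_imm)
  test <- independent_t(s)
  list(reference = reference,
       test = test,
       effect = d_independent_from_summary(s, ci_level),
       bf = jzs_bf01_two_sample(test$t, s$n_1, s$n_2, bf_scale),
       benefit_delayed = list(mean = s$mean_1, sd = s$sd_1, n = s$n_1),
       benefit_immediate = list(mean = s$mean_2, sd = s$sd_2, n = s$n_2))
}

#' Replication verdicts for one condition
#'
#' Two evaluation standards. *Traditional*: both averaging comparisons
#' (average vs guess 1 and average vs guess 2) have t > 0 and two-tailed
#' p < `alpha`. *Detectability*: the traditional criterion holds and
#' neither \eqn{d_z} estimate is significantly below \eqn{d_{33\%}} -- the
#' effect the original study had `detect_power` power to detect at its
#' sample size -- judged by a one-sided z-test at `alpha` on the
#' effect-size scale with the normal-approximation standard error
#' \eqn{\sqrt{1/n + d^2/(2n)}}.
#'
#' @param cond A [within_condition_tests()] result.
#' @param original_n Sample size of the original study in this condition
#'   (e.g. 255 immediate, 173 delayed). `NULL` marks the detectability
#'   verdict unavailable.
#' @param alpha Significance level for both criteria.
#' @param detect_power Power level defining the detectable effect
#'   (default 0.33).
#' @return A list with `traditional` (logical), `detectability` (logical or
#'   `NA` when unavailable), `d_33`, and per-comparison detail.
#' @export
evaluate_replication <- function(cond, original_n = NULL, alpha = 0.05,
                                 detect_power = 0.33) {
  stopifnot(inherits(cond, "condition_tests"))
  avg_tests <- cond[c("avg_vs_g1", "avg_vs_g2")]
  rejected <- vapply(avg_tests, function(cmp) {
    cmp$test$t > 0 && cmp$test$p_value < alpha
  }, logical(1))
  traditional <- all(rejected)

  if (is.null(original_n)) {
    return(list(traditional = traditional, detectability = NA, d_33 = NA_real_,
                comparisons = list(rejected = rejected)))
  }
  d33 <- detectable_effect(original_n, power = detect_power, alpha = alpha)
  below <- vapply(avg_tests, function(cmp) {
    d <- cmp$effect$value
    se <- sqrt(1 / cond$n + d^2 / (2 * cond$n))
    stats::pnorm((d - d33) / se) < alpha  # significantly smaller than d_33%
  }, logical(1))
  list(traditional = traditional,
       detectability = traditional && !any(below),
       d_33 = d33,
       comparisons = list(rejected = rejected, significantly_below_d33 = below))
}

#' Run the full confirmatory and post-hoc analysis
#'
#' Orchestrates cleaning, MSE scoring, the three within-condition paired
#' tests per condition, the between-condition benefit comparisons (vs
#' guess 1 confirmatory, vs guess 2 post-hoc), Bayes factors, and the
#' replication verdicts. Deterministic given its inputs.
#'
#' @param cohort A cohort data frame covering one or both conditions.
#' @param questions A [question_set()].
#' @param alpha Significance level.
#' @param ci_level Confidence level for effect-size intervals.
#' @param bf_scale Cauchy prior scale for Bayes factors.
#' @param original_n Named numeric vector giving the original study's
#'   sample size per condition, used for the detectability verdict.
#' @param detect_power Power level defining \eqn{d_{33\%}}.
#' @param rules Cleaning-rule toggles passed to [clean_cohort()].
#' @return A `replication_report`: exclusion log, per-condition tests and
#'   verdicts, and (when both conditions are present) the between-condition
#'   comparisons.
#' @examples
#' cohort <- make_two_condition_fixture(
#'   cohort_params(60, condition = "immediate", seed = 7),
#'   cohort_params(40, condition = "delayed", rho = 0.10)
#' )
#' analyze_study(cohort)
#' @export
analyze_study <- function(cohort, questions = default_questions(),
                          alpha = 0.05, ci_level = 0.95, bf_scale = 1,
                          original_n = c(immediate = 255, delayed = 173),
                          detect_power = 0.33, rules = list()) {
  cleaned <- clean_cohort(cohort, questions, rules)
  acc <- accuracy_table(cleaned$retained, questions)
  conditions <- intersect(c("immediate", "delayed"), unique(acc$condition))
  if (length(conditions) == 0) stop("no analyzable condition after cleaning",
                                    call. = FALSE)

  per_condition <- lapply(conditions, function(cc) {
    acc_c <- acc[acc$condition == cc, , drop = FALSE]
    tests <- within_condition_tests(acc_c, ci_level, bf_scale)
    orig_n <- if (cc %in% names(original_n)) original_n[[cc]] else NULL
    list(n = nrow(acc_c),
         mean_mse = c(g1 = mean(acc_c$mse_g1), g2 = mean(acc_c$mse_g2),
                      avg = mean(acc_c$mse_avg)),
         sd_mse = c(g1 = stats::sd(acc_c$mse_g1), g2 = stats::sd(acc_c$mse_g2),
                    avg = stats::sd(acc_c$mse_avg)),
         tests = tests,
         verdicts = evaluate_replication(tests, orig_n, alpha, detect_power))
  })
  names(per_condition) <- conditions

  between <- NULL
  if (all(c("immediate", "delayed") %in% conditions)) {
    acc_i <- acc[acc$condition == "immediate", , drop = FALSE]
    acc_d <- acc[acc$condition == "delayed", , drop = FALSE]
    between <- list(
      guess1 = between_condition_test(acc_i, acc_d, "guess1", ci_level, bf_scale),
      guess2 = between_condition_test(acc_i, acc_d, "guess2", ci_level, bf_scale)
    )
  }

  structure(
    list(schema_version = "1.0",
         settings = list(alpha = alpha, ci_level = ci_level,
                         bf_scale = bf_scale,
                         original_n = as.list(original_n),
                         detect_power = detect_power),
         exclusions = cleaned$log,
         conditions = per_condition,
         between = between),
    class = "replication_report"
  )
}

#' @export
print.replication_report <- function(x, ...) {
  cat("Inner-crowd replication report\n")
  print(x$exclusions)
  for (cc in names(x$conditions)) {
    cond <- x$conditions[[cc]]
    cat(sprintf("\n%s condition (n = %d):\n", cc, cond$n))
    cat(sprintf("  mean MSE: guess 1 = %.0f, guess 2 = %.0f, average = %.0f\n",
                cond$mean_mse[["g1"]], cond$mean_mse[["g2"]],
                cond$mean_mse[["avg"]]))
    for (cmp in c("avg_vs_g1", "avg_vs_g2", "g1_vs_g2")) {
      e <- cond$tests[[cmp]]
      cat(sprintf("  %-9s t(%d) = %.2f, p = %.3g, d_z = %.2f [%.2f, %.2f], BF01 = %.3g\n",
                  cmp, e$test$df, e$test$t, e$test$p_value, e$effect$value,
                  e$effect$ci_low, e$effect$ci_high, e$bf$bf01))
    }
    v <- cond$verdicts
    cat(sprintf("  verdicts: traditional %s, detectability %s (d_33%% = %s)\n",
                verdict_word(v$traditional), verdict_word(v$detectability),
                if (is.na(v$d_33)) "unavailable" else sprintf("%.2f", v$d_33)))
  }
  if (!is.null(x$between)) {
    cat("\nBetween conditions (delayed - immediate benefit):\n")
    for (ref in names(x$between)) {
      b <- x$between[[ref]]
      cat(sprintf("  vs %-7s t(%d) = %.2f, p = %.3g, d = %.2f [%.2f, %.2f], BF01 = %.3g\n",
                  b$reference, b$test$df, b$test$t, b$test$p_value,
                  b$effect$value, b$effect$ci_low, b$effect$ci_high, b$bf$bf01))
    }
  }
  invisible(x)
}

verdict_word <- function(v) {
  if (is.na(v)) "unavailable" else if (v) "success" else "failure"
}
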