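#' The eight world-knowledge percentage questions
#'
#' Question identifiers and true answers (percentages in \[0, 100\]) for the
#' eight general-knowledge questions used in inner-crowd guessing studies.
#' Two answer keys are available: the updated `"current"` answers (the
#' default, from The World Factbook at the time of the replication) and the
#' `"original"` answers used in the first study of the effect.
#'
#' @param answers Which answer key to use: `"current"` (default) or
#'   `"original"`.
#' @return A data frame with columns `question_id` (`q1`..`q8`) and `truth`.
#' @examples
#' default_questions()
#' @export
default_questions <- function(answers = c("current", "original")) {
  answers <- match.arg(answers)
  truth <- switch(answers,
    current  = c(6.3, 43.3, 32.3, 13.4, 53.6, 54.8, 26.4, 22.4),
    original = c(6.3, 44.4, 30.3, 10.5, 58.0, 72.4, 18.9, 20.3)
  )
  question_set(paste0("q", seq_along(truth)), truth)
}

#' Build a question set
#'
#' @param question_id Unique question identifiers, in presentation order.
#' @param truth True answers, percentages in \[0, 100\].
#' @return A data frame of class `question_set`.
#' @export
question_set <- function(question_id, truth) {
  question_id <- as.character(question_id)
  if (anyDuplicated(question_id)) stop("question ids must be unique", call. = FALSE)
  if (length(question_id) != length(truth)) {
    stop("question_id and truth lengths differ", call. = FALSE)
  }
  truth <- as.numeric(truth)
  if (any(!is.finite(truth)) || any(truth < 0 | truth > 100)) {
    stop("truths must be percentages in [0, 100]", call. = FALSE)
  }
  structure(data.frame(question_id = question_id, truth = truth,
                       stringsAsFactors = FALSE),
            class = c("question_set", "data.frame"))
}
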