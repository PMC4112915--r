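# Readers and writers for the package's plain-text formats: cohort CSV,
# question CSV, effect-table CSV (for pooling), and the JSON replication
# report. CSVs are comma-separated UTF-8 with a header row and decimal
# points; guesses are stored as plain percentages 0-100.

#' Read a cohort CSV
#'
#' Expected columns: `participant_id`, `condition`, `completed`,
#' `looked_up`, `defocused`, optional `sex`/`age`, and guess columns
#' `q1_g1..qK_g1`, `q1_g2..qK_g2`. Empty guess cells become `NA` (blank
#' answers, handled by the question-level cleaning rule). Out-of-range
#' guesses are loaded as-is but flagged in the `"impossible_cells"`
#' attribute (row, column); [clean_cohort()] excludes them.
#'
#' @param path Path to the CSV file.
#' @return A cohort data frame.
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (nrow(raw) == 0 || ncol(raw) <= 1) {
    stop("schema error: ", path, " has no data rows", call. = FALSE)
  }
  required <- c("participant_id", "condition", "completed", "looked_up",
                "defocused")
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    stop("schema error: missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  gcols <- grep("^q[0-9]+_g[12]$", names(raw), value = TRUE)
  if (length(gcols) == 0) {
    stop("schema error: no guess columns (q<k>_g1/q<k>_g2) found",
         call. = FALSE)
  }
  out <- raw
  for (col in c("completed", "looked_up", "defocused")) {
    out[[col]] <- parse_flag(raw[[col]], col)
  }
  impossible <- NULL
  for (col in gcols) {
    v <- trimws(raw[[col]])
    v[v == ""] <- NA_character_
    num <- suppressWarnings(as.numeric(v))
    bad <- !is.na(v) & is.na(num)
    if (any(bad)) {
      stop("parse error: non-numeric guess ", dQuote(v[bad][1]), " at row ",
           which(bad)[1], ", column ", col, call. = FALSE)
    }
    out[[col]] <- num
    oor <- which(!is.na(num) & (num < 0 | num > 100))
    if (length(oor)) {
      impossible <- rbind(impossible,
                          data.frame(row = oor, column = col,
                                     value = num[oor]))
    }
  }
  if ("age" %in% names(out)) {
    out$age <- suppressWarnings(as.numeric(out$age))
  }
  attr(out, "impossible_cells") <- impossible
  out
}

parse_flag <- function(x, col) {
  v <- tolower(trimws(x))
  res <- rep(NA, length(v))
  res[v %in% c("true", "t", "1", "yes")] <- TRUE
  res[v %in% c("false", "f", "0", "no")] <- FALSE
  if (anyNA(res)) {
    stop("parse error: non-logical value in column ", col, " at row ",
         which(is.na(res))[1], call. = FALSE)
  }
  res
}

#' Write a cohort CSV
#'
#' @param cohort A cohort data frame.
#' @param path Output path.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a question-set CSV (columns `question_id`, `truth`)
#'
#' @param path Path to the CSV file.
#' @return A [question_set()].
#' @export
read_questions_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("question_id", "truth"), names(df))
  if (length(missing)) {
    stop("schema error: missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  question_set(df$question_id, df$truth)
}

#' Read an effect-table CSV for pooling (columns `label`, `t`, `n`, `r`)
#'
#' @param path Path to the CSV file.
#' @return A data frame suitable for [pool_effects()].
#' @export
read_effect_table_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("t", "n", "r"), names(df))
  if (length(missing)) {
    stop("schema error: missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df
}

# ---- report serialization ----------------------------------------------

round_display <- function(x, digits) as.numeric(formatC(x, digits = digits,
                                                        format = "f"))

test_to_list <- function(x) {
  out <- list(t = x$t, df = x$df, p_value = x$p_value,
              mean_diff = x$mean_diff, design = x$design)
  if (!is.null(x$n)) out$n <- x$n
  if (!is.null(x$n_1)) { out$n_1 <- x$n_1; out$n_2 <- x$n_2 }
  out$display <- list(t = round_display(x$t, 2),
                      p_value = round_display(x$p_value, 3))
  out
}

effect_to_list <- function(x) {
  out <- list(value = x$value, design = x$design)
  if (!is.null(x$n)) out$n <- x$n
  if (!is.null(x$n_1)) { out$n_1 <- x$n_1; out$n_2 <- x$n_2 }
  out$variance <- x$variance
  out$ci_level <- x$ci_level
  out$ci_low <- x$ci_low
  out$ci_high <- x$ci_high
  out$display <- list(value = round_display(x$value, 2),
                      ci_low = round_display(x$ci_low, 2),
                      ci_high = round_display(x$ci_high, 2))
  out
}

bf_to_list <- function(x) {
  list(bf01 = x$bf01, bf10 = x$bf10, design = x$design,
       scale_r = x$scale_r, integration_error = x$integration_error,
       display = list(bf01 = round_display(x$bf01, 3)))
}

comparison_to_list <- function(cmp) {
  list(test = test_to_list(cmp$test),
       effect = effect_to_list(cmp$effect),
       bf = bf_to_list(cmp$bf))
}

verdict_to_json <- function(v) {
  if (is.na(v)) "unavailable" else v
}

as_report_list <- function(report) {
  stopifnot(inherits(report, "replication_report"))
  conditions <- lapply(report$conditions, function(cond) {
    list(
      n = cond$n,
      mean_mse = as.list(cond$mean_mse),
      sd_mse = as.list(cond$sd_mse),
      tests = lapply(cond$tests[c("avg_vs_g1", "avg_vs_g2", "g1_vs_g2")],
                     comparison_to_list),
      verdicts = list(
        traditional = verdict_to_json(cond$verdicts$traditional),
        detectability = verdict_to_json(cond$verdicts$detectability),
        d_33 = if (is.na(cond$verdicts$d_33)) "unavailable"
               else cond$verdicts$d_33
      )
    )
  })
  between <- if (is.null(report$between)) NULL else {
    lapply(report$between, function(b) {
      c(list(reference = b$reference), comparison_to_list(b),
        list(benefit_delayed = b$benefit_delayed,
             benefit_immediate = b$benefit_immediate))
    })
  }
  log <- report$exclusions
  out <- list(
    schema_version = report$schema_version,
    settings = report$settings,
    exclusions = list(input = log$input, retained = log$retained,
                      counts = as.list(log$counts),
                      question_level = log$question_level),
    conditions = conditions
  )
  if (!is.null(between)) out$between <- between
  out
}

#' Serialize a replication report to JSON
#'
#' Writes the report with stable key order, full-precision numbers plus
#' display-rounded twins (2 dp effects and t, 3 dp p-values and Bayes
#' factors), a stamped schema version, and an explicit `"unavailable"`
#' marker for verdicts that could not be computed. A raw list (as returned
#' by [read_report_json()]) is re-serialized unchanged, so
#' write-read-write produces identical bytes.
#'
#' @param report A `replication_report` from [analyze_study()], or a list
#'   previously read back with [read_report_json()].
#' @param path Output path.
#' @export
write_report_json <- function(report, path) {
  lst <- if (inherits(report, "replication_report")) as_report_list(report)
         else report
  json <- jsonlite::toJSON(lst, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                           null = "null")
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' Read a JSON replication report
#'
#' @param path Path written by [write_report_json()].
#' @return The report as a nested list (not simplified to vectors, so that
#'   re-serialization is byte-stable).
#' @export
read_report_json <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  jsonlite::fromJSON(path, simplifyVector = FALSE)
}
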