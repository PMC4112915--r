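# Cohort fixtures built in code.

# A cohort with exact exclusion-flag counts assigned to disjoint blocks of
# participants, mirroring an enrollment narrative (total enrolled, so many
# incomplete, so many defocused, so many who looked answers up).
make_cleaning_fixture <- function(n_total, n_incomplete = 0, n_defocused = 0,
                                  n_looked_up = 0, condition = "immediate",
                                  seed = 1) {
  cohort <- sample_cohort(cohort_params(n_total, condition = condition,
                                        clip = TRUE, seed = seed))
  stopifnot(n_incomplete + n_defocused + n_looked_up <= n_total)
  i <- 0
  take <- function(k) {
    idx <- if (k > 0) seq(i + 1, i + k) else integer(0)
    i <<- i + k
    idx
  }
  cohort$completed[take(n_incomplete)] <- FALSE
  cohort$defocused[take(n_defocused)] <- TRUE
  cohort$looked_up[take(n_looked_up)] <- TRUE
  cohort
}

# single-participant cohort over an arbitrary question set
one_participant_cohort <- function(g1, g2, condition = "immediate") {
  nq <- length(g1)
  row <- data.frame(participant_id = "p1", condition = condition,
                    completed = TRUE, looked_up = FALSE, defocused = FALSE,
                    stringsAsFactors = FALSE)
  for (q in seq_len(nq)) row[[paste0("q", q, "_g1")]] <- g1[q]
  for (q in seq_len(nq)) row[[paste0("q", q, "_g2")]] <- g2[q]
  row
}
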