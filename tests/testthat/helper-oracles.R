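# Independent oracles used across the suite. Each re-derives a quantity by
# a route separate from the implementation: plain-formula evaluation for
# the paired t, noncentral-t simulation for power, and Monte-Carlo
# integration over the Cauchy mixing prior for the JZS Bayes factor.

# paired t by direct formula evaluation (no shared code with paired_t)
brute_paired_t <- function(x, y) {
  d <- x - y
  n <- length(d)
  m <- sum(d) / n
  s <- sqrt(sum((d - m)^2) / (n - 1))
  t <- m / (s / sqrt(n))
  list(t = t, df = n - 1, p_value = 2 * stats::pt(-abs(t), n - 1))
}

# two-tailed paired-t power by simulating the t statistic from its
# noncentral distribution
mc_paired_power <- function(d, n, reps = 1e5, alpha = 0.05) {
  tc <- stats::qt(1 - alpha / 2, n - 1)
  mean(abs(stats::rt(reps, n - 1, ncp = d * sqrt(n))) > tc)
}

# JZS BF01 by Monte-Carlo integration over the prior mixing variable:
# g ~ InverseGamma(1/2, r^2/2), i.e. g = r^2 / chisq(1)
mc_bf01 <- function(t, N, nu, scale_r = 1, reps = 1e6) {
  g <- scale_r^2 / stats::rchisq(reps, df = 1)
  log_lr <- -0.5 * log1p(N * g) -
    ((nu + 1) / 2) * (log1p(t^2 / ((1 + N * g) * nu)) - log1p(t^2 / nu))
  1 / mean(exp(log_lr))
}

# per-participant MSE recomputed with explicit loops
brute_accuracy <- function(cohort, questions) {
  nq <- nrow(questions)
  out <- NULL
  for (i in seq_len(nrow(cohort))) {
    se1 <- se2 <- sea <- c()
    for (q in seq_len(nq)) {
      g1 <- cohort[[paste0("q", q, "_g1")]][i]
      g2 <- cohort[[paste0("q", q, "_g2")]][i]
      if (is.na(g1) || is.na(g2)) next
      truth <- questions$truth[q]
      se1 <- c(se1, (g1 - truth)^2)
      se2 <- c(se2, (g2 - truth)^2)
      sea <- c(sea, ((g1 + g2) / 2 - truth)^2)
    }
    if (length(se1) == 0) next
    out <- rbind(out, data.frame(
      participant_id = as.character(cohort$participant_id[i]),
      mse_g1 = mean(se1), mse_g2 = mean(se2), mse_avg = mean(sea)
    ))
  }
  out
}
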