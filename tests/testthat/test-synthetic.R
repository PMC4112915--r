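# The synthetic cohort generator and its analytic companion.

test_that("the generator is reproducible and parameter-validated", {
  p <- cohort_params(30, seed = 123)
  expect_identical(sample_cohort(p), sample_cohort(p))
  p2 <- cohort_params(30, seed = 124)
  expect_false(identical(sample_cohort(p), sample_cohort(p2)))
  # the caller's RNG stream is left untouched
  set.seed(55); before <- rnorm(1)
  set.seed(55); invisible(sample_cohort(p)); after <- rnorm(1)
  expect_identical(before, after)

  expect_error(cohort_params(10, tau = -1), "nonnegative")
  expect_error(cohort_params(10, rho = 1.2), "rho")
  expect_error(cohort_params(10, truths = c(10, 120), n_questions = 2),
               "percentages")
  expect_error(cohort_params(10, exclusion_rates = c(incomplete = 2)),
               "proportions")
})

test_that("perfectly correlated noise makes the two guesses identical", {
  cohort <- sample_cohort(cohort_params(40, rho = 1, g2_sd_inflation = 1,
                                        seed = 2))
  g1 <- as.matrix(cohort[, paste0("q", 1:8, "_g1")])
  g2 <- as.matrix(cohort[, paste0("q", 1:8, "_g2")])
  expect_equal(unname(g1), unname(g2), tolerance = 1e-12)
  acc <- accuracy_table(cohort)
  expect_equal(acc$mse_avg, acc$mse_g1, tolerance = 1e-12)
})

test_that("expected_mse algebra covers the degenerate corners", {
  p <- cohort_params(10, rho = 1, g2_sd_inflation = 1)
  expect_equal(expected_mse(p)$benefit_g1, 0)
  p <- cohort_params(10, sigma = 0)
  em <- expected_mse(p)
  expect_equal(em$mse_g1, 450)
  expect_equal(em$mse_avg, 450)
  # the defaults' implied benefit sits on the scale of the observed one
  p <- cohort_params(10, rho = 0.36, g2_sd_inflation = 1)
  expect_equal(expected_mse(p)$benefit_g1, 150 * (1 - 0.36) / 2)
  expect_equal(expected_mse(p)$benefit_g1, 48)
  expect_error(expected_mse(cohort_params(10, clip = TRUE)), "unclipped")
})

test_that("empirical MSE means match the closed forms across a grid", {
  set.seed(606)
  n <- 2000
  for (sigma2 in c(75, 150, 300)) {
    for (rho in c(0.1, 0.36, 0.7)) {
      p <- cohort_params(n, sigma = sqrt(sigma2), rho = rho,
                         g2_sd_inflation = 1, seed = sample.int(1e6, 1))
      acc <- accuracy_table(sample_cohort(p))
      em <- expected_mse(p)
      for (col in c("mse_g1", "mse_avg")) {
        se <- sd(acc[[col]]) / sqrt(n)
        expect_lt(abs(mean(acc[[col]]) - em[[col]]), 3 * se)
      }
    }
  }
})

test_that("defaults land on the study's summary scale", {
  p <- cohort_params(2000, seed = 42)
  acc <- accuracy_table(sample_cohort(p))
  em <- expected_mse(p)
  # guess-2 inflation is part of the default expectation
  for (col in c("mse_g1", "mse_g2", "mse_avg")) {
    se <- sd(acc[[col]]) / sqrt(nrow(acc))
    expect_lt(abs(mean(acc[[col]]) - em[[col]]), 3 * se)
  }
  expect_gt(em$mse_g2, em$mse_g1)  # second guesses slightly worse
  # per-participant MSE location and spread match published summaries
  expect_gt(mean(acc$mse_g1), 450); expect_lt(mean(acc$mse_g1), 650)
  expect_gt(sd(acc$mse_g1), 260);   expect_lt(sd(acc$mse_g1), 380)
  # single-guess and average-guess MSE series are strongly correlated
  expect_gt(cor(acc$mse_g1, acc$mse_avg), 0.8)
  expect_lt(cor(acc$mse_g1, acc$mse_avg), 0.98)
})

test_that("moment estimates recover the generator parameters within 5%", {
  p <- cohort_params(2000, bias = "participant", g2_sd_inflation = 1,
                     rho = 0.36, seed = 2718)
  est <- estimate_cohort_params(sample_cohort(p))
  expect_lt(abs(est$tau2 - 450) / 450, 0.05)
  expect_lt(abs(est$sigma2 - 150) / 150, 0.05)
  expect_lt(abs(est$rho - 0.36) / 0.36, 0.05)
})

test_that("the averaging benefit falls as the guesses grow dependent", {
  set.seed(11)
  rhos <- c(0, 0.25, 0.5, 0.75, 0.95)
  benefit <- sapply(seq_along(rhos), function(i) {
    acc <- accuracy_table(sample_cohort(
      cohort_params(2000, rho = rhos[i], g2_sd_inflation = 1,
                    seed = 5000 + i)))
    mean(acc$mse_g1 - acc$mse_avg)
  })
  expect_true(all(diff(benefit) < 0))
  expect_lt(cor(rhos, benefit, method = "spearman"), 0)
})

test_that("clamping guesses into range can only shrink errors", {
  p_off <- cohort_params(300, clip = FALSE, seed = 8)
  p_on <- cohort_params(300, clip = TRUE, seed = 8)
  acc_off <- accuracy_table(sample_cohort(p_off))
  acc_on <- accuracy_table(sample_cohort(p_on))
  expect_true(all(acc_on$mse_g1 <= acc_off$mse_g1 + 1e-12))
  expect_true(all(acc_on$mse_g2 <= acc_off$mse_g2 + 1e-12))
})

test_that("the two-condition fixture shares truths and offsets seeds", {
  expect_error(make_two_condition_fixture(
    cohort_params(20, seed = 1),
    cohort_params(20, condition = "delayed", truths = rep(50, 8))),
    "same question truths")
  cohort <- make_two_condition_fixture(
    cohort_params(30, condition = "immediate", seed = 10),
    cohort_params(20, condition = "delayed", rho = 0.10))
  expect_equal(table(cohort$condition)[["immediate"]], 30)
  expect_equal(table(cohort$condition)[["delayed"]], 20)
  # derived delayed seed is deterministic
  again <- make_two_condition_fixture(
    cohort_params(30, condition = "immediate", seed = 10),
    cohort_params(20, condition = "delayed", rho = 0.10))
  expect_identical(cohort, again)

  # a lower delayed rho implies a strictly larger expected benefit
  b_imm <- expected_mse(cohort_params(10, rho = 0.36))$benefit_g1
  b_del <- expected_mse(cohort_params(10, rho = 0.10,
                                      condition = "delayed"))$benefit_g1
  expect_gt(b_del, b_imm)
})

test_that("equal-parameter conditions give a between t centered on zero", {
  ts <- sapply(1:20, function(s) {
    cohort <- make_two_condition_fixture(
      cohort_params(80, condition = "immediate", seed = 100 + s),
      cohort_params(80, condition = "delayed", rho = 0.36))
    acc <- accuracy_table(cohort)
    between_condition_test(acc[acc$condition == "immediate", ],
                           acc[acc$condition == "delayed", ])$test$t
  })
  expect_lt(abs(mean(ts)), 3 / sqrt(20))
})
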