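# Cohen's d_z, independent-groups d, pooling, confidence intervals, and
# the underlying t-tests.

test_that("d_z from paired summaries follows the difference-SD formula", {
  # published planning row: summaries 555/508, SDs 361/305, r = .88, n = 255
  est <- dz_from_summary(paired_summary(555, 508, 361, 305, 0.88, 255))
  expect_equal(est$value, 0.27336, tolerance = 1e-4)
  # agrees with the 2-dp d_z printed alongside those (rounded) summaries
  expect_lt(abs(est$value - 0.28), 0.015)
  expect_identical(est$design, "paired")
  expect_equal(est$variance, var_dz(est$value, 255, 0.88))

  # identical means give a zero effect whatever the spread
  expect_equal(dz_from_summary(paired_summary(10, 10, 3, 7, 0.2, 30))$value, 0)
  # equal SDs with r = 0.5 collapse the denominator to sigma
  expect_equal(dz_from_summary(paired_summary(14, 11, 6, 6, 0.5, 30))$value,
               (14 - 11) / 6)
  # perfectly correlated equal-SD pairs have no difference SD
  expect_error(dz_from_summary(paired_summary(1, 2, 3, 3, 1, 30)),
               "degenerate")
})

test_that("d_z from t reproduces published conversions", {
  expect_equal(round(dz_from_t(4.41, 255), 2), 0.28)
  expect_equal(round(dz_from_t(9.85, 173), 2), 0.75)
  expect_equal(round(dz_from_t(8.69, 471), 2), 0.40)
  expect_equal(round(dz_from_t(8.48, 140), 2), 0.72)
  expect_equal(dz_from_t(0, 37), 0)
  expect_equal(dz_from_t(-3, 100), -0.3)
  expect_error(dz_from_t(2, 1), "invalid sample size")
})

test_that("summary-based and t-based d_z agree algebraically", {
  set.seed(41)
  for (i in 1:25) {
    n <- sample(5:500, 1)
    s <- paired_summary(rnorm(1, 50, 20), rnorm(1, 50, 20),
                        runif(1, 1, 30), runif(1, 1, 30),
                        runif(1, -0.9, 0.95), n)
    dz <- dz_from_summary(s)$value
    sd_diff <- sqrt(s$sd_x^2 + s$sd_y^2 - 2 * s$sd_x * s$sd_y * s$r_xy)
    t_stat <- (s$mean_x - s$mean_y) / (sd_diff / sqrt(n))
    expect_equal(dz, dz_from_t(t_stat, n), tolerance = 1e-10)
  }
})

test_that("var_dz matches its closed form and handles the r = 1 edge", {
  expect_equal(var_dz(0, 100, 0.5), 0.01)
  expect_equal(var_dz(4.41 / sqrt(255), 255, 0.88), 0.000977066,
               tolerance = 1e-5)
  expect_equal(var_dz(0.9, 50, 1), 0)
  expect_error(var_dz(0.2, 1, 0.5), "invalid sample size")
})

test_that("pooling reproduces the planning-stage pooled effects", {
  g1 <- read_effect_table_csv(
    system.file("extdata", "planning_effects_guess1.csv",
                package = "innercrowd"))
  g2 <- read_effect_table_csv(
    system.file("extdata", "planning_effects_guess2.csv",
                package = "innercrowd"))
  expect_equal(round(pool_effects(g1)$value, 2), 0.17)
  expect_equal(round(pool_effects(g2)$value, 2), 0.56)
})

test_that("pooling is a weighted mean: range, order, identical studies", {
  same <- list(study_effect("a", 0.4, 100, 0.5),
               study_effect("b", 0.4, 250, 0.8),
               study_effect("c", 0.4, 30, 0.1))
  expect_equal(pool_effects(same)$value, 0.4)

  set.seed(7)
  for (i in 1:20) {
    k <- sample(2:6, 1)
    df <- data.frame(label = letters[1:k], d_z = runif(k, -0.5, 1),
                     n = sample(10:400, k), r_xy = runif(k, -0.5, 0.95))
    pooled <- pool_effects(df)
    expect_gte(pooled$value, min(df$d_z))
    expect_lte(pooled$value, max(df$d_z))
    shuffled <- pool_effects(df[sample(k), ])
    expect_equal(pooled$value, shuffled$value, tolerance = 1e-12)
  }
})

test_that("pooling weight grows with the pairing correlation", {
  w <- function(r) 1 / var_dz(0.3, 120, r)
  rs <- c(-0.5, 0, 0.4, 0.8, 0.95)
  expect_true(all(diff(sapply(rs, w)) > 0))
})

test_that("pooling rejects infinite weights and empty input", {
  expect_error(pool_effects(data.frame(label = "a", d_z = 0.2, n = 50,
                                       r_xy = 1)),
               "infinite pooling")
  expect_error(pool_effects(data.frame(label = character(), d_z = numeric(),
                                       n = integer(), r_xy = numeric())),
               "empty")
})

test_that("independent-groups d reproduces the post-hoc comparisons", {
  # benefit-of-averaging summaries: delayed (121, 169, 140) vs immediate
  # (73, 155, 471), and the original-data reanalysis (164, 218, 173) vs
  # (131, 211, 255)
  d1 <- d_independent_from_summary(
    independent_summary(121, 73, 169, 155, 140, 471))
  expect_equal(round(d1$value, 2), 0.30)
  d2 <- d_independent_from_summary(
    independent_summary(164, 131, 218, 211, 173, 255))
  expect_equal(round(d2$value, 2), 0.15)
  expect_equal(d_independent_from_summary(
    independent_summary(5, 5, 2, 3, 20, 20))$value, 0)

  expect_equal(round(d_independent_from_t(1.56, 255, 173), 2), 0.15)
  expect_equal(round(d_independent_from_t(3.14, 471, 140), 2), 0.30)
  expect_equal(d_independent_from_t(0, 50, 80), 0)
  expect_error(d_independent_from_t(1, 1, 50), "invalid sample size")
})

test_that("confidence intervals reproduce the printed intervals", {
  # delayed guess-2 effect: t = 8.48, n = 140 -> d_z = 0.72 [0.53, 0.90]
  e <- effect_ci(effect_size(dz_from_t(8.48, 140), "paired", n = 140))
  expect_equal(round(c(e$ci_low, e$ci_high), 2), c(0.53, 0.90))
  # immediate guess-1 effect: t = 8.69, n = 471 -> 0.40 [0.31, 0.49]
  e <- effect_ci(effect_size(dz_from_t(8.69, 471), "paired", n = 471))
  expect_equal(round(c(e$ci_low, e$ci_high), 2), c(0.31, 0.49))
  # guess 1 vs guess 2, immediate: t = -2.25, n = 471 -> [-0.19, -0.01]
  e <- effect_ci(effect_size(dz_from_t(-2.25, 471), "paired", n = 471))
  expect_equal(round(c(e$ci_low, e$ci_high), 2), c(-0.19, -0.01))
  # independent between-condition effect: [0.11, 0.49] around 0.30
  e <- d_independent_from_summary(
    independent_summary(121, 73, 169, 155, 140, 471))
  expect_equal(round(c(e$ci_low, e$ci_high), 2), c(0.11, 0.49))
})

test_that("a null effect gets a symmetric interval and width shrinks in n", {
  e <- effect_ci(effect_size(0, "paired", n = 60))
  expect_equal(e$ci_low, -e$ci_high)
  widths <- sapply(c(10, 40, 160, 640, 2560), function(n) {
    e <- effect_ci(effect_size(0.4, "paired", n = n))
    e$ci_high - e$ci_low
  })
  expect_true(all(diff(widths) < 0))
})

test_that("noncentral-t intervals bracket the estimate and match normal ones loosely", {
  e_n <- effect_ci(effect_size(0.4, "paired", n = 200), method = "normal")
  e_t <- effect_ci(effect_size(0.4, "paired", n = 200), method = "noncentral")
  expect_lt(e_t$ci_low, 0.4)
  expect_gt(e_t$ci_high, 0.4)
  expect_equal(e_t$ci_low, e_n$ci_low, tolerance = 0.02)
  expect_equal(e_t$ci_high, e_n$ci_high, tolerance = 0.02)
})

test_that("paired t matches hand calculation, a brute-force oracle, and t.test", {
  res <- paired_t(c(1, 2, 4), c(0, 1, 2))
  expect_equal(res$t, 4)
  expect_equal(res$df, 2L)
  expect_equal(res$mean_diff, 4 / 3)

  set.seed(11)
  for (i in 1:10) {
    x <- rnorm(20, 50, 10)
    y <- rnorm(20, 48, 12)
    res <- paired_t(x, y)
    oracle <- brute_paired_t(x, y)
    expect_equal(res$t, oracle$t, tolerance = 1e-12)
    expect_equal(res$p_value, oracle$p_value, tolerance = 1e-12)
    ref <- t.test(x, y, paired = TRUE)
    expect_equal(res$t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(res$p_value, ref$p.value, tolerance = 1e-12)
  }

  expect_error(paired_t(c(1, 2), c(1, 2, 3)), "length mismatch")
  expect_error(paired_t(c(1, 2, 3), c(1, 2, 3)), "zero-variance")
  expect_error(paired_t(c(1, 2, 3), c(0, 1, 2)), "zero-variance")
})

test_that("pooled-variance independent t matches hand values and t.test", {
  res <- independent_t(summarize_groups(c(1, 2, 3), c(3, 4, 5)))
  # diff -2, pooled SD 1, se sqrt(2/3) -> t ~ -2.449
  expect_equal(res$t, -2 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(res$df, 4L)
  ref <- t.test(c(1, 2, 3), c(3, 4, 5), var.equal = TRUE)
  expect_equal(res$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-12)

  expect_equal(independent_t(independent_summary(5, 5, 2, 3, 20, 30))$t, 0)
  # study-sized groups give the printed degrees of freedom
  expect_equal(independent_t(independent_summary(50, 48, 147, 119,
                                                 140, 471))$df, 609L)
  expect_error(independent_t(independent_summary(1, 2, 1e-300, 1e-300,
                                                 5, 5)))
})
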