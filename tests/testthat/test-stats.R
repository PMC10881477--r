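test_that("contrast tables pair trials and count rows as expected", {
  f <- toy_features(n_per_group = 14, delta = 1, noise = 0.01)
  ct <- build_contrasts(f, unit = "trial_pair")
  expect_identical(nrow(ct[ct$feedback_type == "vo", ]), 56L)  # 2 x 28
  cp <- build_contrasts(f, unit = "participant")
  expect_identical(nrow(cp[cp$feedback_type == "vo", ]), 28L)
  # identical high and low features give all-zero deltas
  f0 <- toy_features(n_per_group = 4, delta = 0, noise = 0)
  ct0 <- build_contrasts(f0)
  expect_true(all(ct0$delta_tremor_power == 0))
})

test_that("the between-group t-test matches the hand-computed textbook case", {
  ct <- data.frame(pid = sprintf("S%d", 1:6),
                   group = rep(c("pET", "HC"), each = 3),
                   feedback_type = "vo", pair_index = 1,
                   delta_tremor_power = c(1, 2, 3, 4, 5, 6))
  r <- group_ttest(ct, "vo")
  expect_equal(r$value, -3.674, tolerance = 1e-3)
  expect_equal(r$df, 4)
  expect_equal(r$p_value, 2 * pt(-3.674235, 4), tolerance = 1e-5)
})

test_that("the paired gain test reports its branch and respects symmetry", {
  f <- toy_features(n_per_group = 8, delta = 1, noise = 0.2, seed = 2)
  r <- paired_gain_test(f, "pET", "vo")
  expect_true(r$p_value < 0.05)
  expect_match(r$branch, "Shapiro")
  # sign flip leaves |statistic| and p unchanged
  f2 <- f
  f2$tremor_power <- -f2$tremor_power
  r2 <- paired_gain_test(f2, "pET", "vo")
  expect_equal(abs(r2$value), abs(r$value), tolerance = 1e-10)
  expect_equal(r2$p_value, r$p_value, tolerance = 1e-10)
  # identical high/low values: reported as no effect
  f3 <- toy_features(n_per_group = 4, delta = 0, noise = 0)
  r3 <- paired_gain_test(f3, "pET", "vo")
  expect_identical(r3$p_value, 1)
})

test_that("the paired test has power against a one-SD shift at n = 14", {
  set.seed(99)
  hits <- replicate(500, {
    f <- data.frame(pid = rep(sprintf("S%02d", 1:14), each = 2),
                    group = "pET", feedback_type = "vo",
                    trial = rep(1:2, 14),
                    gain_level = rep(c("low", "high"), 14))
    # per-participant high-low difference ~ N(1, 1): shift of one SD
    f$tremor_power <- rnorm(nrow(f), sd = sqrt(1 / 2)) +
      (f$gain_level == "high")
    paired_gain_test(f, "pET", "vo")$p_value < 0.05
  })
  expect_gte(mean(hits), 0.8)
})

test_that("trial-level ANOVAs report per-factor F and df", {
  f <- toy_features(n_per_group = 14, delta = 0, noise = 0.1, seed = 3)
  av <- anova_trials(f, outcome = "rmse")
  expect_length(av, 2)
  expect_identical(av[[1]]$df, c(1, 334))      # group: 2 levels, 336 trials
  expect_identical(av[[2]]$df, c(2, 333))      # feedback type: 3 levels
  # constant outcome: F = 0 by convention
  f$rmse <- 0.05
  av0 <- anova_trials(f, outcome = "rmse")
  expect_identical(av0[[1]]$value, 0)
  expect_error(anova_trials(f[f$group == "pET", ], factors = "group"), "levels")
})

test_that("an injected main effect is picked up by its factor only", {
  set.seed(4)
  f <- toy_features(n_per_group = 14, delta = 0, noise = 0.1)
  f$rmse <- f$rmse + 0.5 * (f$group == "pET")
  av <- anova_trials(f, outcome = "rmse")
  expect_lt(av[[1]]$p_value, 0.001)
  expect_gt(av[[2]]$p_value, 0.001)
})

test_that("covariate comparison gates between t and Mann-Whitney", {
  # complete separation: U hits its floor
  r <- compare_covariates(c(1, 2, 3, 4, 5), c(6, 7, 8, 9, 10),
                          test = "mann-whitney")
  expect_identical(r$statistic, "U")
  expect_identical(unname(r$value), 0)
  # heavily skewed data fail the gate and route to U automatically
  rs <- compare_covariates(c(0.1, 0.1, 0.2, 0.3, 30, 40),
                           c(1, 1.1, 1.2, 55, 60, 70))
  expect_identical(rs$statistic, "U")
  set.seed(5)
  branches <- replicate(400, {
    compare_covariates(rnorm(14), rnorm(14))$statistic
  })
  expect_gte(mean(branches == "t"), 0.85)      # Shapiro passes most normal draws
  # constant group forces the nonparametric branch
  rc <- compare_covariates(rep(3, 10), rnorm(10))
  expect_identical(rc$statistic, "U")
})

test_that("correlation gates, detects exact linearity, and partials out a covariate", {
  set.seed(6)
  x <- rnorm(30)
  r <- correlate(x, 2 * x)
  expect_equal(unname(r$value), 1)
  expect_lt(r$p_value, 1e-10)
  expect_error(correlate(x, rep(1, 30)), "constant")
  # x and y share a strong covariate; partialling recovers the core association
  z <- rnorm(200)
  core_x <- rnorm(200); core_y <- rnorm(200)
  x2 <- core_x + 3 * z
  y2 <- core_y + 3 * z
  raw <- correlate(x2, y2)
  part <- correlate(x2, y2, partial_covariate = z)
  expect_gt(unname(raw$value), 0.7)
  expect_lt(abs(part$value - cor(core_x, core_y)), 0.05)
  expect_identical(part$df, 197)
})

test_that("scale-free statistics are invariant to affine rescaling of outcomes", {
  f <- toy_features(n_per_group = 10, delta = 0.5, noise = 0.2, seed = 7)
  ct <- build_contrasts(f, outcomes = "tremor_power")
  r1 <- group_ttest(ct, "va")
  f2 <- f
  f2$tremor_power <- f2$tremor_power * 17  # common scale: deltas scale too
  r2 <- group_ttest(build_contrasts(f2, outcomes = "tremor_power"), "va")
  expect_equal(r2$value, r1$value, tolerance = 1e-10)
  expect_equal(r2$p_value, r1$p_value, tolerance = 1e-10)
  # relabelling participants leaves every statistic unchanged
  f3 <- f
  f3$pid <- sub("S", "Q", f3$pid)
  r3 <- group_ttest(build_contrasts(f3, outcomes = "tremor_power"), "va")
  expect_equal(r3$value, r1$value, tolerance = 1e-12)
})
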