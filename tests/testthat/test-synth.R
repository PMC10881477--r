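test_that("a noise-free trial is a pure sinusoid at the tremor frequency", {
  p <- fixed_participant(beta = 0, amp0 = 0.02)
  tr <- simulate_force_trial(p, "vo", "low", seed = 1)
  f_t <- target_force(p$maxf)
  x <- tr$task / f_t - 1
  tt <- (seq_along(x) - 1) / 80
  # fit amplitude/phase by least squares; residual must vanish
  fit <- lm(x ~ sin(2 * pi * 6 * tt) + cos(2 * pi * 6 * tt) - 1)
  expect_lt(max(abs(resid(fit))), 1e-10)
  expect_equal(sqrt(sum(coef(fit)^2)), 0.02, tolerance = 1e-10)
})

test_that("trial simulation is deterministic under a fixed seed", {
  p <- fixed_participant(drift = 0.05, noise = 0.007, trial_sdlog = 0.1)
  expect_identical(simulate_force_trial(p, "va", "high", seed = 7),
                   simulate_force_trial(p, "va", "high", seed = 7))
  expect_identical(simulate_pupil_trial(p, "va", "high", seed = 7),
                   simulate_pupil_trial(p, "va", "high", seed = 7))
})

test_that("noise-free pupil trials sit at the baseline diameter", {
  p <- fixed_participant(blink_rate = 0, pupil_noise = 0)
  pt <- simulate_pupil_trial(p, "vo", "low", seed = 2)
  expect_equal(unique(pt$samples$diameter), 4.5)
  expect_true(all(pt$samples$confidence >= 0.9))
})

test_that("blink construction honours the detectability contract", {
  p <- fixed_participant(blink_rate = 0.2, pupil_noise = 0)
  pt <- simulate_pupil_trial(p, "vo", "low", seed = 8)
  expect_gt(nrow(pt$blinks), 0)
  for (i in seq_len(nrow(pt$blinks))) {
    inb <- pt$samples$t_rel >= pt$blinks[i, 1] & pt$samples$t_rel < pt$blinks[i, 2]
    expect_true(all(pt$samples$confidence[inb] < 0.3))
  }
})

test_that("blink time fraction matches rate x duration", {
  p <- fixed_participant(blink_rate = 0.1, blink_dur = 0.2)
  frac <- vapply(1:100, function(s) {
    pt <- simulate_pupil_trial(p, "vo", "low", seed = s)
    sum(pt$blinks[, 2] - pt$blinks[, 1]) / 60
  }, numeric(1))
  # expected fraction 0.02 (minus a little merging loss), binomial-scale error
  expect_lt(abs(mean(frac) - 0.1 * 0.2), 0.004)
})

test_that("cohorts have the right shape and are reproducible", {
  co <- simulate_cohort(3, seed = 5, level = "signal")
  expect_length(co$sessions, 6)
  expect_identical(nrow(co$participants), 6L)
  expect_true(all(vapply(co$sessions, function(s) nrow(s$schedule), integer(1)) == 12))
  expect_true(all(table(co$participants$group) == 3))
  # every session yields exactly 12 extractable 30 s task epochs
  ep <- epoch_stream(co$sessions[[1]]$force$force, co$sessions[[1]]$force$time,
                     co$sessions[[1]]$markers)
  expect_length(ep, 12)
  co2 <- simulate_cohort(3, seed = 5, level = "signal")
  expect_identical(co$sessions[[2]]$force, co2$sessions[[2]]$force)
  expect_identical(co$sessions[[4]]$pupil, co2$sessions[[4]]$pupil)
})

test_that("feature-level and signal-level samplers agree in distribution", {
  eff <- cohort_effects()
  sig <- extract_features(simulate_cohort(6, eff, seed = 31, level = "signal"))
  fea <- simulate_cohort(24, eff, seed = 32, level = "feature")$features
  for (g in c("pET", "HC")) {
    s <- sig[sig$group == g, ]; f <- fea[fea$group == g, ]
    # geometric-mean tremor power per gain level: same parameterisation
    for (gl in c("low", "high")) {
      ms <- mean(log(s$tremor_power[s$gain_level == gl]))
      mf <- mean(log(f$tremor_power[f$gain_level == gl]))
      expect_lt(abs(ms - mf), 0.45)     # log-scale agreement
    }
    expect_lt(abs(mean(s$rmse) / mean(f$rmse) - 1), 0.2)
    expect_lt(abs(mean(s$pupil_mean) - mean(f$pupil_mean)), 0.05)
  }
})

test_that("null cohorts carry no group differences", {
  co <- simulate_cohort(10, cohort_effects(null = TRUE), seed = 6,
                        level = "feature")
  f <- co$features
  expect_equal(mean(f$tremor_power[f$group == "pET"]),
               mean(f$tremor_power[f$group == "HC"]), tolerance = 0.2)
  expect_true(all(f$pupil_mean[f$gain_level == "high"] %in% f$pupil_mean))
  ct <- build_contrasts(f, outcomes = "pupil_mean")
  # pupil arousal identically zero at null: deltas are pure noise around 0
  expect_lt(abs(mean(ct$delta_pupil_mean)), 0.05)
})
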