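test_that("normalisation maps the target force to exactly one", {
  expect_equal(normalize_force(rep(0.15 * 40, 10), 40), rep(1, 10))
  expect_equal(normalize_force(numeric(10), 40), numeric(10))
  expect_equal(normalize_force(30, 100), 2)
  expect_error(normalize_force(1:10, 0), "positive")
})

test_that("mean force and RMSE follow their definitions on the unfiltered trace", {
  expect_equal(trial_error_stats(rep(1, 100)), list(mean_force = 1, rmse = 0))
  expect_equal(trial_error_stats(rep(1.5, 100)),
               list(mean_force = 1.5, rmse = 0.5))
  expect_equal(trial_error_stats(c(0, 2)), list(mean_force = 1, rmse = 1))
  expect_error(trial_error_stats(numeric(0)), "empty")
})

test_that("epoching cuts half-open 30 s windows keyed by markers", {
  p <- fixed_participant()
  s <- simulate_session(p, seed = 5)
  ep <- epoch_stream(s$force$force, s$force$time, s$markers)
  expect_length(ep, 12)
  expect_true(all(vapply(ep, function(e) length(e$task), integer(1)) == 2400))
  expect_true(all(vapply(ep, function(e) length(e$rest), integer(1)) == 2400))
  # shuffled markers give identical epochs (sorted on use)
  shuf <- s$markers[sample(nrow(s$markers)), ]
  expect_identical(epoch_stream(s$force$force, s$force$time, shuf), ep)
  expect_identical(epoch_stream(1:10, (1:10) / 80, s$markers[0, ]), list())
  bad <- s$markers
  bad$time[bad$label == "task_offset" & bad$trial == 1] <- 10  # before onset
  expect_error(epoch_stream(s$force$force, s$force$time, bad), "trial 1")
})

test_that("pure-sinusoid trials recover tremor band power A^2/2 through the chain", {
  set.seed(33)
  for (i in 1:8) {
    # inside the flat part of the pass band the full chain preserves A^2/2
    f0 <- runif(1, 4.5, 9.5)
    p <- fixed_participant(tremor_freq = f0, amp0 = 0.02, beta = 0.5)
    s <- simulate_session(p, seed = 100 + i)
    ff <- force_features(s)
    amps <- attr(s, "amps")
    expect_lt(max(abs(ff$tremor_power / (amps^2 / 2) - 1)), 0.10)
  }
  # near the 12 Hz corner the shortfall is exactly the double-pass filter gain
  p <- fixed_participant(tremor_freq = 10.8, amp0 = 0.02, beta = 0)
  s <- simulate_session(p, seed = 200)
  ff <- force_features(s)
  g2 <- tremorfb:::butter_bandpass_gain2(10.8, 5, 0.1, 12, 80)^2
  expect_lt(max(abs(ff$tremor_power / (0.02^2 / 2 * g2) - 1)), 0.10)
})

test_that("an isolated 8 Hz epoch leaks under 1% into the voluntary band", {
  t <- seq(0, 30 - 1 / 80, by = 1 / 80)
  x <- 0.02 * sin(2 * pi * 8 * t + 0.3)
  filt <- bandpass_force(x)
  s <- welch_psd(filt, 80)
  expect_lt(band_power(s, 0, 3), 0.01 * band_power(s, 4, 12))
})

test_that("high-gain trials carry the (1 + beta w)^2 power ratio", {
  p <- fixed_participant(amp0 = 0.02, beta = 0.5)
  s <- simulate_session(p, seed = 9)
  ff <- force_features(s)
  for (ft in c("vo", "va", "ao")) {
    hi <- mean(ff$tremor_power[ff$feedback_type == ft & ff$gain_level == "high"])
    lo <- mean(ff$tremor_power[ff$feedback_type == ft & ff$gain_level == "low"])
    want <- (1 + 0.5 * p$feedback_weight[[ft]])^2
    expect_lt(abs(hi / lo - want) / want, 0.05)
  }
})

test_that("features are invariant to a common rescaling of force and MaxF", {
  p <- fixed_participant(drift = 0.05, noise = 0.007)
  s <- simulate_session(p, seed = 21)
  f1 <- force_features(s)
  s2 <- s
  s2$force$force <- s$force$force * 7.3
  s2$maxf <- s$maxf * 7.3
  f2 <- force_features(s2)
  for (col in c("tremor_power", "voluntary_power", "mean_force", "rmse"))
    expect_equal(f2[[col]], f1[[col]], tolerance = 1e-12)
})

test_that("feature extraction is deterministic on identical input", {
  p <- fixed_participant(drift = 0.05, noise = 0.007)
  s <- simulate_session(p, seed = 4)
  expect_identical(force_features(s), force_features(s))
})
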