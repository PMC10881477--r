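test_that("MaxF is the maximum of the three one-second press means", {
  fs <- 80
  expect_equal(compute_max_force(list(rep(10, fs), rep(12, fs), rep(11, fs)), fs),
               12)
  expect_equal(compute_max_force(list(rep(5, 100), rep(5, 90), rep(5, 80)), fs),
               5)
  # ramp press whose first-second mean equals the constant presses
  ramp <- 8.2 + sin(seq(0, 2 * pi, length.out = fs))  # mean over one period
  ramp_mean <- mean(ramp[1:fs])
  got <- compute_max_force(list(ramp, rep(8.2, fs), rep(8.2, fs)), fs)
  expect_equal(got, max(ramp_mean, 8.2))
  # only the first second counts, even when the press runs longer
  long <- c(rep(2, fs), rep(100, fs))
  expect_equal(compute_max_force(list(long, rep(1, fs), rep(1, fs)), fs), 2)
})

test_that("calibration rejects malformed presses", {
  expect_error(compute_max_force(list(rep(1, 80), rep(1, 80)), 80), "three")
  expect_error(compute_max_force(list(rep(1, 40), rep(1, 80), rep(1, 80)), 80),
               "shorter")
})

test_that("target force is 15% of MaxF and rejects non-positive MaxF", {
  expect_equal(target_force(100), 15)
  expect_equal(target_force(20), 3)
  expect_error(target_force(0), "positive")
})

test_that("cursor position is affine in produced force and anchored at the target", {
  expect_equal(feedback_position(2, 1, 3), 4)
  for (g in c(0, 0.04, 1, 6.9)) {
    expect_equal(feedback_position(7.5, 7.5, g), 7.5)  # alignment at match
    # affine with slope g
    f <- c(0, 1, 4, 9)
    expect_equal(diff(feedback_position(f, 2, g)), g * diff(f))
  }
  expect_equal(feedback_position(c(1, 5), 3, 0), c(3, 3))  # zero gain pins cursor
})

test_that("tone mapping hits its anchors, clips, and is monotone", {
  cfg <- feedback_config()
  expect_identical(tone_frequency(15, 15, 1, cfg), 440)
  expect_identical(tone_frequency(15, 15, cfg$audio_gain_high, cfg), 440)
  expect_equal(tone_frequency(0, 15, 1, cfg), 120)
  expect_equal(tone_frequency(1e6, 15, 1, cfg), 880)
  expect_equal(tone_frequency(-1e6, 15, 1, cfg), 120)
  f <- tone_frequency(seq(-5, 50, by = 0.5), 15, 3, cfg)
  expect_true(all(diff(f) >= 0))
  expect_true(all(f >= 120 & f <= 880))
})

test_that("schedules have the fixed block order and balanced gains", {
  s1 <- build_schedule(42)
  expect_s3_class(s1, "trial_schedule")
  expect_identical(nrow(s1), 12L)
  expect_identical(s1, build_schedule(42))      # deterministic under seed
  for (seed in 0:99) {
    s <- build_schedule(seed)
    expect_identical(as.character(unique(s$feedback_type)), c("vo", "va", "ao"))
    tab <- table(s$feedback_type, s$gain_level)
    expect_true(all(tab == 2))
  }
})

test_that("within-block gain orders are uniform over the six permutations", {
  orders <- character(0)
  for (seed in 1:1000) {
    s <- build_schedule(seed)
    orders <- c(orders, vapply(c("vo", "va", "ao"), function(ft)
      paste(s$gain_level[s$feedback_type == ft], collapse = ""), character(1)))
  }
  tab <- table(orders)
  expect_identical(length(tab), 6L)
  expect_gt(chisq.test(tab)$p.value, 0.001)
})
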