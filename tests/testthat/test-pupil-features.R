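make_pupil_session <- function(seed, blink_rate = 0.1, arousal = NULL,
                               pupil_noise = 0.15) {
  p <- fixed_participant(blink_rate = blink_rate, arousal = arousal,
                         pupil_noise = pupil_noise)
  simulate_session(p, seed = seed)
}

test_that("constant, confident, still-gaze recordings give an empty mask", {
  pupil <- data.frame(time = (0:4799) / 240, diameter = 4.2, confidence = 1,
                      gaze_x = 960, gaze_y = 540)
  bm <- detect_blinks(pupil)
  expect_false(any(bm$mask))
  expect_identical(nrow(bm$intervals), 0L)
})

test_that("zero confidence masks the entire recording and rejects epochs", {
  s <- make_pupil_session(2, blink_rate = 0)
  s$pupil$confidence[] <- 0
  bm <- detect_blinks(s$pupil)
  expect_true(all(bm$mask))
  pf <- pupil_features(s)
  expect_true(all(pf$rejected))
  expect_true(all(is.na(pf$pupil_mean)))
})

test_that("injected blinks are detected with few false positives", {
  det <- fp <- numeric(0)
  for (seed in 1:5) {
    s <- make_pupil_session(seed)
    bm <- detect_blinks(s$pupil)
    truth <- rep(FALSE, nrow(s$pupil))
    bl <- attr(s, "blinks")
    for (i in seq_len(nrow(bl)))
      truth[s$pupil$time >= bl[i, 1] & s$pupil$time < bl[i, 2]] <- TRUE
    det <- c(det, mean(bm$mask[truth]))
    fp <- c(fp, mean(bm$mask[!truth]))
  }
  expect_gte(mean(det), 0.95)
  expect_lt(mean(fp), 0.02)
})

test_that("every injected blink interval is covered by a detected interval", {
  s <- make_pupil_session(3)
  bm <- detect_blinks(s$pupil)
  bl <- attr(s, "blinks")
  covered <- vapply(seq_len(nrow(bl)), function(i)
    any(bm$intervals[, 1] <= bl[i, 1] + 1e-6 &
          bm$intervals[, 2] >= bl[i, 2] - 1e-6), logical(1))
  expect_true(all(covered))
})

test_that("gap interpolation is the identity on complete data", {
  x <- sin(seq(0, 10, length.out = 2000))
  expect_identical(interpolate_gaps(x), x)
})

test_that("gap interpolation reconstructs a linear ramp within 2% of range", {
  fs <- 240
  x <- seq(0, 1, length.out = 20 * fs)     # ramp, range 1
  xg <- x
  gap <- 2000:(2000 + 0.3 * fs)            # 0.3 s gap
  xg[gap] <- NA
  rec <- interpolate_gaps(xg)
  expect_lt(max(abs(rec[gap] - x[gap])), 0.02)
  expect_identical(rec[-gap], x[-gap])     # valid samples untouched
})

test_that("gap interpolation reconstructs a slow sinusoid across random gaps", {
  set.seed(12)
  fs <- 240
  t <- seq(0, 30, by = 1 / fs)
  x <- 4 + 0.5 * sin(2 * pi * 0.2 * t)
  xg <- x
  for (i in 1:10) {
    g0 <- sample(length(t) - 0.2 * fs, 1)
    xg[g0:(g0 + 0.2 * fs)] <- NA
  }
  rec <- interpolate_gaps(xg)
  bad <- which(is.na(xg))
  expect_lt(sqrt(mean((rec[bad] - x[bad])^2)), 0.05 * 0.5)
})

test_that("interpolation rejects traces that are mostly missing", {
  x <- rnorm(1000)
  x[1:501] <- NA
  expect_error(interpolate_gaps(x), "half")
})

test_that("baseline correction subtracts the [-10, -2) window mean", {
  t_rel <- seq(-30, 30 - 1 / 240, by = 1 / 240)
  ep <- data.frame(t_rel = t_rel, diameter = rep(4.2, length(t_rel)))
  cor1 <- baseline_correct_epoch(ep)
  expect_equal(cor1$diameter, numeric(length(t_rel)))
  # step epoch: baseline 3, task 3.5
  ep2 <- data.frame(t_rel = t_rel, diameter = ifelse(t_rel < 0, 3, 3.5))
  cor2 <- baseline_correct_epoch(ep2)
  expect_equal(unique(cor2$diameter[t_rel >= 0]), 0.5)
  inb <- t_rel >= -10 & t_rel < -2
  expect_lt(abs(mean(cor2$diameter[inb])), 1e-12)
  # missing baseline coverage is an error
  expect_error(baseline_correct_epoch(ep2[t_rel > -5, ]), "baseline")
})

test_that("the trial mean is invariant to adding any constant to the raw trace", {
  t_rel <- seq(-30, 30 - 1 / 240, by = 1 / 240)
  set.seed(3)
  ep <- data.frame(t_rel = t_rel, diameter = 4 + rnorm(length(t_rel), 0, 0.1))
  m1 <- pupil_trial_mean(baseline_correct_epoch(ep))
  ep$diameter <- ep$diameter + 123.456
  m2 <- pupil_trial_mean(baseline_correct_epoch(ep))
  expect_equal(m1, m2, tolerance = 1e-10)
})

test_that("arousal contrasts survive the full pupil chain", {
  arous <- c(vo.low = 0, vo.high = 0, va.low = 0, va.high = 0,
             ao.low = 0, ao.high = 0.3)
  s <- make_pupil_session(6, blink_rate = 0.1, arousal = arous,
                          pupil_noise = 0.02)
  pf <- pupil_features(s)
  sched <- s$schedule
  hi <- mean(pf$pupil_mean[sched$feedback_type == "ao" & sched$gain_level == "high"])
  lo <- mean(pf$pupil_mean[sched$feedback_type == "ao" & sched$gain_level == "low"])
  want <- 0.3 * tremorfb:::arousal_ramp_mean(2, 30)
  expect_lt(abs((hi - lo) - want), 0.1 * want)
})
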