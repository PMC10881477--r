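# Synthetic-cohort generator. Two levels share one parameterisation:
# "signal" emits raw timestamped streams (force 80 Hz, pupil 240 Hz, event
# markers) that are pushed through the full processing chain; "feature"
# samples per-trial features directly from the distribution the signal model
# induces, for Monte-Carlo work where only the statistical layer is under
# study. Consistency of the two levels is checked in the test suite.

#' Group-level simulation parameters
#'
#' Defines the distributions from which virtual participants are drawn.
#' Tremor amplitude is log-normal per group; the feedback-gain effect is a
#' multiplicative amplitude factor `(1 + beta * weight[type])` under high
#' gain, so tremor band power scales as its square. Defaults encode the
#' qualitative effect structure of the study the package models: patients
#' (pET) respond to high gain in all three feedback types (strongest under
#' combined audio-visual feedback) and dilate their pupils under high-gain
#' conditions involving audition; controls (HC) show a small tremor response
#' only under combined feedback and no pupil response.
#'
#' @param pET,HC per-group parameter lists; entries replace the defaults.
#' @param shared parameters common to both groups (drift, sensor noise,
#'   pupil noise, blinks, MaxF); entries replace the defaults.
#' @param null logical; `TRUE` zeroes every group effect *and* all
#'   between-participant heterogeneity, giving the exchangeable null used
#'   for type-I-error calibration.
#' @return An object of class `cohort_effects`.
#' @export
cohort_effects <- function(pET = list(), HC = list(), shared = list(),
                           null = FALSE) {
  g_pet <- list(
    tremor_freq_mean = 6, tremor_freq_sd = 1, tremor_freq_range = c(4, 10),
    amp0_meanlog = log(0.02), amp0_sdlog = 0.25,
    beta_meanlog = log(0.5), beta_sdlog = 0.2,
    feedback_weight = c(vo = 1, va = 1.2, ao = 1),
    arousal_low_mm = 0.10,
    arousal_delta_mm = c(vo = 0, va = 0.35, ao = 0.35),
    arousal_delta_sd = 0.10,
    age_mean = 58, age_sd = 12,
    tetras_mean = 40, tetras_sd = 8,
    bdi_mean = 8, bdi_sd = 4)
  g_hc <- utils::modifyList(g_pet, list(
    tremor_freq_mean = 9, tremor_freq_range = c(6, 12),
    amp0_meanlog = log(0.008),
    beta_meanlog = log(0.25),
    feedback_weight = c(vo = 0, va = 1, ao = 0),
    arousal_delta_mm = c(vo = 0, va = 0, ao = 0),
    age_mean = 66, age_sd = 8,
    tetras_mean = 0, tetras_sd = 0,
    bdi_mean = 1, bdi_sd = 1))
  sh <- list(
    maxf_meanlog = log(40), maxf_sdlog = 0.2,
    drift_meanlog = log(0.08), drift_sdlog = 0.2, drift_cutoff_hz = 1.5,
    noise_meanlog = log(0.007), noise_sdlog = 0.1,
    trial_amp_sdlog = 0.08,
    pupil_base_mean = 4.5, pupil_base_sd = 0.4,
    pupil_noise_sd = 0.15, pupil_noise_cutoff_hz = 0.5,
    pupil_trial_sd = 0.06,           # feature-level per-trial noise (mm)
    arousal_tau_s = 2,
    blink_rate_hz = 0.1, blink_dur_s = 0.2)
  g_pet <- utils::modifyList(g_pet, pET)
  g_hc <- utils::modifyList(g_hc, HC)
  sh <- utils::modifyList(sh, shared)
  if (null) {
    zero <- list(amp0_sdlog = 0, beta_meanlog = -Inf, beta_sdlog = 0,
                 feedback_weight = c(vo = 0, va = 0, ao = 0),
                 arousal_delta_mm = c(vo = 0, va = 0, ao = 0),
                 arousal_delta_sd = 0, tremor_freq_sd = 0)
    g_pet <- utils::modifyList(g_pet, c(zero, list(amp0_meanlog = log(0.01))))
    g_hc <- utils::modifyList(g_hc, c(zero, list(
      amp0_meanlog = log(0.01), tremor_freq_mean = g_pet$tremor_freq_mean,
      tremor_freq_range = g_pet$tremor_freq_range)))
    sh <- utils::modifyList(sh, list(drift_sdlog = 0, noise_sdlog = 0,
                                     pupil_base_sd = 0))
  }
  structure(list(pET = g_pet, HC = g_hc, shared = sh), class = "cohort_effects")
}

rnorm_clip <- function(n, mean, sd, lo = -Inf, hi = Inf)
  pmin(pmax(stats::rnorm(n, mean, sd), lo), hi)

#' Draw one virtual participant
#'
#' @param pid participant identifier.
#' @param group `"pET"` or `"HC"`.
#' @param effects a [cohort_effects()] object.
#' @param seed integer seed.
#' @return An object of class `virtual_participant`.
#' @export
sample_participant <- function(pid, group = c("pET", "HC"),
                               effects = cohort_effects(), seed = 1) {
  group <- match.arg(group)
  local_rng(seed)
  g <- effects[[group]]
  sh <- effects$shared
  arousal <- c(vo.low = g$arousal_low_mm, vo.high = g$arousal_low_mm,
               va.low = g$arousal_low_mm, va.high = g$arousal_low_mm,
               ao.low = g$arousal_low_mm, ao.high = g$arousal_low_mm)
  for (ft in c("vo", "va", "ao")) {
    # a zero specified effect is exactly zero; truncation of the participant
    # scatter must not manufacture a positive mean where none is specified
    d <- if (g$arousal_delta_mm[[ft]] > 0)
      max(0, stats::rnorm(1, g$arousal_delta_mm[[ft]], g$arousal_delta_sd))
    else 0
    arousal[[paste0(ft, ".high")]] <- arousal[[paste0(ft, ".high")]] + d
  }
  beta <- if (is.finite(g$beta_meanlog))
    stats::rlnorm(1, g$beta_meanlog, g$beta_sdlog) else 0
  p <- list(
    pid = pid, group = group,
    maxf = stats::rlnorm(1, sh$maxf_meanlog, sh$maxf_sdlog),
    tremor_freq_hz = rnorm_clip(1, g$tremor_freq_mean, g$tremor_freq_sd,
                                g$tremor_freq_range[1], g$tremor_freq_range[2]),
    tremor_amp0 = stats::rlnorm(1, g$amp0_meanlog, g$amp0_sdlog),
    gain_beta = beta,
    feedback_weight = g$feedback_weight,
    trial_amp_sdlog = sh$trial_amp_sdlog,
    drift_amp = stats::rlnorm(1, sh$drift_meanlog, sh$drift_sdlog),
    drift_cutoff_hz = sh$drift_cutoff_hz,
    noise_sd = stats::rlnorm(1, sh$noise_meanlog, sh$noise_sdlog),
    pupil_base_mm = rnorm_clip(1, sh$pupil_base_mean, sh$pupil_base_sd, 2, 8),
    pupil_arousal_mm = arousal,
    pupil_noise_sd = sh$pupil_noise_sd,
    pupil_noise_cutoff_hz = sh$pupil_noise_cutoff_hz,
    arousal_tau_s = sh$arousal_tau_s,
    blink_rate_hz = sh$blink_rate_hz, blink_dur_s = sh$blink_dur_s,
    age = rnorm_clip(1, g$age_mean, g$age_sd, 25, 85),
    tetras = if (group == "pET") rnorm_clip(1, g$tetras_mean, g$tetras_sd, 0, 64) else NA_real_,
    bdi = rnorm_clip(1, g$bdi_mean, g$bdi_sd, 0, 63))
  stopifnot(p$tremor_freq_hz >= 4, p$tremor_freq_hz <= 12,
            p$tremor_amp0 > 0, p$gain_beta >= 0, p$blink_dur_s > 0)
  structure(p, class = "virtual_participant")
}

#' @export
print.virtual_participant <- function(x, ...) {
  cat(sprintf("Virtual participant %s (%s): MaxF %.1f, tremor %.1f Hz amp %.3g, beta %.2f\n",
              x$pid, x$group, x$maxf, x$tremor_freq_hz, x$tremor_amp0,
              x$gain_beta))
  invisible(x)
}

# Gaussian noise band-limited below cutoff_hz, rescaled to standard
# deviation sd (FFT brick-wall; the spectral shape below the cutoff is flat).
lowpass_noise <- function(n, fs, cutoff_hz, sd) {
  if (sd <= 0 || n < 4) return(numeric(n))
  z <- stats::rnorm(n)
  sp <- stats::fft(z)
  f <- c(seq(0, floor(n / 2)), seq(ceiling(n / 2) - 1, 1)) * fs / n
  sp[f > cutoff_hz] <- 0
  x <- Re(stats::fft(sp, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s == 0) return(numeric(n))
  (x - mean(x)) * (sd / s)
}

# Tremor amplitude (as a fraction of the target force) for one trial.
trial_tremor_amp <- function(p, feedback_type, gain_level, jitter = 0) {
  w <- p$feedback_weight[[as.character(feedback_type)]]
  amp <- p$tremor_amp0 * (1 + p$gain_beta * w * (gain_level == "high"))
  amp * exp(jitter)
}

#' Simulate the force stream of one trial
#'
#' Task-window force is `F_t * (1 + drift + A sin(2 pi f t + phi) + eps)`:
#' the target force modulated by a slow voluntary tracking drift (band
#' limited below `drift_cutoff_hz`), a tremor sinusoid in the 4-12 Hz band
#' whose amplitude grows under high feedback gain, and white sensor noise.
#' The rest window is near-zero force with sensor noise; the final second of
#' rest ramps smoothly up to the initial task force so the band-pass filter
#' is not driven by a step.
#'
#' @param p a [sample_participant()] object.
#' @param feedback_type,gain_level trial condition (`vo`/`va`/`ao`,
#'   `low`/`high`).
#' @param seed integer seed.
#' @param fs sampling rate in Hz.
#' @param rest_s,task_s epoch durations in seconds.
#' @return list with numeric vectors `rest` and `task` (raw force units) and
#'   the realised tremor amplitude `amp` (normalised units).
#' @export
simulate_force_trial <- function(p, feedback_type, gain_level, seed,
                                 fs = 80, rest_s = 30, task_s = 30) {
  local_rng(seed)
  n_task <- round(task_s * fs)
  n_rest <- round(rest_s * fs)
  f_t <- target_force(p$maxf)
  jit <- if (p$trial_amp_sdlog > 0) stats::rnorm(1, 0, p$trial_amp_sdlog) else 0
  amp <- trial_tremor_amp(p, feedback_type, gain_level, jit)
  phi <- stats::runif(1, 0, 2 * pi)
  tt <- (0:(n_task - 1)) / fs
  drift <- lowpass_noise(n_task, fs, p$drift_cutoff_hz, p$drift_amp)
  eps <- if (p$noise_sd > 0) stats::rnorm(n_task, 0, p$noise_sd) else numeric(n_task)
  task <- f_t * (1 + drift + amp * sin(2 * pi * p$tremor_freq_hz * tt + phi) + eps)
  rest <- f_t * (if (p$noise_sd > 0) stats::rnorm(n_rest, 0, p$noise_sd) else numeric(n_rest))
  # smooth onset: the last seconds of rest ramp to the first task sample, so
  # the band-pass filter sees no step (its slow transient would otherwise
  # bleed into the task epoch in both directions under zero-phase filtering)
  n_ramp <- min(n_rest, 3 * fs)
  u <- seq_len(n_ramp) / n_ramp
  s <- 3 * u^2 - 2 * u^3
  idx <- (n_rest - n_ramp + 1):n_rest
  rest[idx] <- rest[idx] * (1 - s) + s * task[1]
  list(rest = rest, task = task, amp = amp)
}

#' Simulate the pupil stream of one trial
#'
#' Diameter is a participant baseline plus a condition-dependent arousal
#' response (saturating exponential ramp during the task window, exponential
#' decay from `arousal_in` during rest) plus slow band-limited noise. Blinks
#' arrive as a Poisson process: the diameter collapses towards zero with
#' 20 ms ramps, confidence drops below 0.3, and the gaze trace carries an
#' acceleration transient; elsewhere confidence stays at or above 0.9.
#'
#' @inheritParams simulate_force_trial
#' @param arousal_in arousal level (mm) carried over at rest onset.
#' @return list with data frame `samples` (`t_rel` seconds relative to task
#'   onset, `diameter`, `confidence`, `gaze_x`, `gaze_y`), matrix `blinks`
#'   of injected (start, end) times on the same axis, and `arousal_out`.
#' @export
simulate_pupil_trial <- function(p, feedback_type, gain_level, seed,
                                 fs = 240, rest_s = 30, task_s = 30,
                                 arousal_in = 0) {
  local_rng(seed)
  n <- round((rest_s + task_s) * fs)
  t_rel <- (0:(n - 1)) / fs - rest_s
  level <- p$pupil_arousal_mm[[paste(feedback_type, gain_level, sep = ".")]]
  tau <- p$arousal_tau_s
  arousal <- ifelse(t_rel < 0,
                    arousal_in * exp(-(t_rel + rest_s) / tau),
                    level * (1 - exp(-t_rel / tau)))
  noise <- lowpass_noise(n, fs, p$pupil_noise_cutoff_hz, p$pupil_noise_sd)
  diameter <- p$pupil_base_mm + arousal + noise
  confidence <- pmin(1, 0.95 + stats::rnorm(n, 0, 0.015))
  confidence <- pmax(confidence, 0.9)
  gaze_x <- 960 + lowpass_noise(n, fs, 4, 1)
  gaze_y <- 540 + lowpass_noise(n, fs, 4, 1)
  # blinks: Poisson count, uniform onsets, overlaps merged
  blinks <- matrix(numeric(0), ncol = 2)
  if (p$blink_rate_hz > 0) {
    k <- stats::rpois(1, p$blink_rate_hz * (rest_s + task_s))
    if (k > 0) {
      st <- sort(stats::runif(k, -rest_s, task_s - p$blink_dur_s))
      en <- st + p$blink_dur_s
      keep <- c(TRUE, st[-1] > en[-k] + 0.1)
      st <- st[keep]; en <- en[keep]
      blinks <- cbind(st, en)
      ramp_s <- 0.02
      for (i in seq_along(st)) {
        inb <- t_rel >= st[i] & t_rel < en[i]
        tb <- t_rel[inb]
        depth <- pmin(1, pmin(tb - st[i], en[i] - tb) / ramp_s)
        diameter[inb] <- diameter[inb] * (1 - depth) + 0.05 * depth
        confidence[inb] <- stats::runif(sum(inb), 0.02, 0.25)
        # saccade-like gaze deflection -> acceleration transient
        gaze_x[inb] <- gaze_x[inb] + 25 * sin(pi * (tb - st[i]) / p$blink_dur_s)
      }
    }
  }
  dimnames(blinks) <- list(NULL, c("start", "end"))
  list(samples = data.frame(t_rel = t_rel, diameter = diameter,
                            confidence = confidence,
                            gaze_x = gaze_x, gaze_y = gaze_y),
       blinks = blinks,
       arousal_out = arousal[n])
}

#' Simulate one complete session
#'
#' Builds the participant's seeded 12-trial schedule and concatenates the
#' per-trial force and pupil segments into continuous streams on one common
#' clock, together with the event-marker stream (trial_start, rest_onset,
#' task_onset, task_offset per trial).
#'
#' @param p a [sample_participant()] object.
#' @param seed integer seed (drives schedule and every trial).
#' @param fs_force,fs_pupil stream sampling rates in Hz.
#' @return An object of class `stream_set`: list with data frames `force`
#'   (`time`, `force`), `pupil` (`time`, `diameter`, `confidence`, `gaze_x`,
#'   `gaze_y`), `markers` (`time`, `label`, `trial`, `feedback_type`,
#'   `gain_level`), the `schedule`, and attributes `blinks` (injected blink
#'   intervals, session clock) and `amps` (realised tremor amplitudes).
#' @export
simulate_session <- function(p, seed, fs_force = 80, fs_pupil = 240) {
  schedule <- build_schedule(child_seed(seed, 0L))
  n_tr <- nrow(schedule)
  force_segs <- vector("list", n_tr)
  pupil_segs <- vector("list", n_tr)
  blink_list <- vector("list", n_tr)
  amps <- numeric(n_tr)
  arousal <- 0
  markers <- vector("list", n_tr)
  for (i in seq_len(n_tr)) {
    tr <- schedule[i, ]
    t0 <- (i - 1) * (tr$rest_duration + tr$task_duration)
    ft <- simulate_force_trial(p, tr$feedback_type, tr$gain_level,
                               child_seed(seed, i, 1L), fs = fs_force,
                               rest_s = tr$rest_duration, task_s = tr$task_duration)
    pt <- simulate_pupil_trial(p, tr$feedback_type, tr$gain_level,
                               child_seed(seed, i, 2L), fs = fs_pupil,
                               rest_s = tr$rest_duration, task_s = tr$task_duration,
                               arousal_in = arousal)
    arousal <- pt$arousal_out
    if (i > 1L) {
      # release ramp: the previous task's final force decays smoothly over
      # the first seconds of this rest, avoiding a step at the epoch edge
      prev_end <- force_segs[[i - 1]][length(force_segs[[i - 1]])]
      n_down <- min(length(ft$rest), 3 * fs_force)
      u <- seq_len(n_down) / n_down
      ft$rest[seq_len(n_down)] <- ft$rest[seq_len(n_down)] +
        prev_end * (1 - (3 * u^2 - 2 * u^3))
    }
    force_segs[[i]] <- c(ft$rest, ft$task)
    amps[i] <- ft$amp
    pupil_segs[[i]] <- pt$samples
    if (nrow(pt$blinks))
      blink_list[[i]] <- pt$blinks + t0 + tr$rest_duration
    markers[[i]] <- data.frame(
      time = t0 + c(0, 0, tr$rest_duration, tr$rest_duration + tr$task_duration),
      label = c("trial_start", "rest_onset", "task_onset", "task_offset"),
      trial = tr$index,
      feedback_type = as.character(tr$feedback_type),
      gain_level = as.character(tr$gain_level))
  }
  force <- unlist(force_segs)
  pupil <- do.call(rbind, pupil_segs)
  out <- list(
    force = data.frame(time = (seq_along(force) - 1) / fs_force, force = force),
    pupil = data.frame(time = (seq_len(nrow(pupil)) - 1) / fs_pupil,
                       diameter = pupil$diameter,
                       confidence = pupil$confidence,
                       gaze_x = pupil$gaze_x, gaze_y = pupil$gaze_y),
    markers = do.call(rbind, markers),
    schedule = schedule,
    fs_force = fs_force, fs_pupil = fs_pupil,
    pid = p$pid, maxf = p$maxf)
  attr(out, "blinks") <- do.call(rbind, blink_list)
  attr(out, "amps") <- amps
  class(out) <- "stream_set"
  out
}

#' @export
print.stream_set <- function(x, ...) {
  cat(sprintf("Stream set %s: force %d samples @ %g Hz, pupil %d samples @ %g Hz, %d trials\n",
              x$pid, nrow(x$force), x$fs_force, nrow(x$pupil), x$fs_pupil,
              nrow(x$schedule)))
  invisible(x)
}

participant_row <- function(p) {
  data.frame(pid = p$pid, group = p$group, maxf = p$maxf,
             tremor_freq_hz = p$tremor_freq_hz, tremor_amp0 = p$tremor_amp0,
             gain_beta = p$gain_beta, age = p$age, tetras = p$tetras,
             bdi = p$bdi)
}

# Analytic mean of the saturating arousal ramp over the task window.
arousal_ramp_mean <- function(tau, task_s = 30)
  1 - tau / task_s * (1 - exp(-task_s / tau))

# Feature-level sampler: per-trial features drawn from the distribution the
# signal model induces (sinusoid band power A^2/2, white-noise floor
# sigma^2 * band / Nyquist with Welch averaging scatter, pupil ramp mean).
simulate_features_one <- function(p, schedule, seed, fs = 80,
                                  n_segments = 14) {
  local_rng(seed)
  n <- nrow(schedule)
  jit <- if (p$trial_amp_sdlog > 0) stats::rnorm(n, 0, p$trial_amp_sdlog) else numeric(n)
  amp <- vapply(seq_len(n), function(i)
    trial_tremor_amp(p, schedule$feedback_type[i], schedule$gain_level[i], jit[i]),
    numeric(1))
  noise_floor <- p$noise_sd^2 * (12 - 4) / (fs / 2)
  # zero-phase band-pass attenuates tremor near the 12 Hz corner; the
  # realised band power carries the squared double-pass gain
  g2 <- butter_bandpass_gain2(p$tremor_freq_hz, fs = fs)^2
  tremor <- g2 * amp^2 / 2 +
    noise_floor * stats::rgamma(n, shape = n_segments, rate = n_segments)
  voluntary <- 0.9 * p$drift_amp^2 *
    stats::rgamma(n, shape = 6, rate = 6) +
    p$noise_sd^2 * 3 / (fs / 2)
  mean_force <- 1 + stats::rnorm(n, 0, p$drift_amp / 6)
  rmse <- sqrt(p$drift_amp^2 + amp^2 / 2 + p$noise_sd^2) * exp(stats::rnorm(n, 0, 0.05))
  ramp <- arousal_ramp_mean(p$arousal_tau_s, schedule$task_duration[1])
  level <- vapply(seq_len(n), function(i)
    p$pupil_arousal_mm[[paste(schedule$feedback_type[i],
                              schedule$gain_level[i], sep = ".")]], numeric(1))
  pupil <- level * ramp + stats::rnorm(n, 0, p$pupil_trial_sd %||% 0.06)
  data.frame(pid = p$pid, group = p$group, trial = schedule$index,
             feedback_type = as.character(schedule$feedback_type),
             gain_level = as.character(schedule$gain_level),
             tremor_power = tremor, voluntary_power = voluntary,
             mean_force = mean_force, rmse = rmse, pupil_mean = pupil)
}

#' Simulate a cohort
#'
#' Draws `n_per_group` participants per group (pET, HC) and either their full
#' raw stream sets (`level = "signal"`) or their per-trial feature table
#' sampled from the induced distribution (`level = "feature"`), under one
#' master seed.
#'
#' @param n_per_group participants per group (>= 2; the study the package
#'   models enrolled 14 per group).
#' @param effects a [cohort_effects()] object.
#' @param seed master integer seed.
#' @param level `"signal"` for raw streams, `"feature"` for the fast
#'   feature-level sampler.
#' @return `level = "signal"`: list with `participants` (data frame),
#'   `sessions` (list of `stream_set`), and `participant_objects`.
#'   `level = "feature"`: list with `participants` and `features` (tidy
#'   per-trial feature table).
#' @export
simulate_cohort <- function(n_per_group = 14, effects = cohort_effects(),
                            seed = 1, level = c("signal", "feature")) {
  level <- match.arg(level)
  stopifnot(n_per_group >= 2)
  groups <- rep(c("pET", "HC"), each = n_per_group)
  pids <- sprintf("%s%02d", ifelse(groups == "pET", "P", "C"),
                  c(seq_len(n_per_group), seq_len(n_per_group)))
  ps <- lapply(seq_along(pids), function(i)
    sample_participant(pids[i], groups[i], effects, child_seed(seed, i, 10L)))
  ptab <- do.call(rbind, lapply(ps, participant_row))
  sh <- effects$shared
  ps <- lapply(ps, function(p) { p$pupil_trial_sd <- sh$pupil_trial_sd; p })
  if (level == "signal") {
    sessions <- lapply(seq_along(ps), function(i)
      simulate_session(ps[[i]], child_seed(seed, i, 20L)))
    list(participants = ptab, sessions = sessions, participant_objects = ps)
  } else {
    feats <- lapply(seq_along(ps), function(i) {
      p <- ps[[i]]
      p$pupil_trial_sd <- sh$pupil_trial_sd
      schedule <- build_schedule(child_seed(child_seed(seed, i, 20L), 0L))
      simulate_features_one(p, schedule, child_seed(seed, i, 30L))
    })
    list(participants = ptab, features = do.call(rbind, feats))
  }
}
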