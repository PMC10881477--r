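#' Feedback configuration
#'
#' Bundles the display and audio parameters of the force-matching task: the
#' two visual display gains (low and high), the three anchor frequencies of
#' the auditory pitch mapping, and the audio gain applied to the force
#' deviation before it is turned into pitch.
#'
#' The visual gains are stored as dimensionless multipliers numerically equal
#' to the visual angles (in degrees) subtended by the cursor excursion on the
#' original display; the analysis never needs the screen geometry itself.
#' The audio gains preserve the low:high ratio of the visual gains
#' (`audio_gain_high = gain_high / gain_low` when left `NULL`).
#'
#' @param gain_low,gain_high display gains for the low and high feedback
#'   conditions (defaults 0.04 and 6.9).
#' @param tone_target_hz frequency of the constant target tone (Hz).
#' @param tone_min_hz,tone_max_hz clipping range of the varying tone (Hz).
#' @param audio_gain_low,audio_gain_high dimensionless audio gains;
#'   `audio_gain_high = NULL` derives the high gain from the visual ratio.
#' @return An object of class `feedback_config`.
#' @examples
#' cfg <- feedback_config()
#' cfg$gain_high / cfg$gain_low  # 172.5
#' @export
feedback_config <- function(gain_low = 0.04, gain_high = 6.9,
                            tone_target_hz = 440,
                            tone_min_hz = 120, tone_max_hz = 880,
                            audio_gain_low = 1, audio_gain_high = NULL) {
  if (!(gain_low < gain_high))
    stop("gain_low must be smaller than gain_high")
  if (!(tone_min_hz < tone_target_hz && tone_target_hz < tone_max_hz))
    stop("tone anchors must satisfy tone_min_hz < tone_target_hz < tone_max_hz")
  if (is.null(audio_gain_high)) audio_gain_high <- gain_high / gain_low
  structure(list(gain_low = gain_low, gain_high = gain_high,
                 tone_target_hz = tone_target_hz,
                 tone_min_hz = tone_min_hz, tone_max_hz = tone_max_hz,
                 audio_gain_low = audio_gain_low,
                 audio_gain_high = audio_gain_high),
            class = "feedback_config")
}

#' @export
print.feedback_config <- function(x, ...) {
  cat("Feedback configuration\n")
  cat(sprintf("  display gain  low/high : %.3g / %.3g\n", x$gain_low, x$gain_high))
  cat(sprintf("  tone target / range    : %g Hz in [%g, %g] Hz\n",
              x$tone_target_hz, x$tone_min_hz, x$tone_max_hz))
  cat(sprintf("  audio gain low/high    : %.3g / %.3g\n",
              x$audio_gain_low, x$audio_gain_high))
  invisible(x)
}

#' Maximum voluntary force from three calibration presses
#'
#' The participant presses the sensor at maximum effort three times for one
#' second; each press is summarised by the mean of its first second of
#' samples and the calibration value MaxF is the maximum of the three means.
#'
#' @param presses list of three numeric force traces, each covering at least
#'   one second at `fs`.
#' @param fs sampling rate in Hz.
#' @return MaxF in the raw force units of the traces.
#' @examples
#' compute_max_force(list(rep(10, 80), rep(12, 80), rep(11, 80)), fs = 80)
#' @export
compute_max_force <- function(presses, fs) {
  if (!is.list(presses) || length(presses) != 3L)
    stop("calibration requires exactly three presses")
  n1s <- round(fs * 1.0)
  means <- vapply(presses, function(p) {
    if (length(p) < n1s)
      stop("calibration press shorter than 1 s at the stated sampling rate")
    mean(p[seq_len(n1s)])
  }, numeric(1))
  max(means)
}

#' Target force from MaxF
#'
#' The task target is 15 percent of the individual maximum voluntary force.
#'
#' @param maxf maximum voluntary force (positive).
#' @return target force, `0.15 * maxf`.
#' @export
target_force <- function(maxf) {
  if (!is.numeric(maxf) || any(maxf <= 0))
    stop("maxf must be positive")
  0.15 * maxf
}

#' Visual cursor position under a display gain
#'
#' The displayed cursor position is `(f_p - f_t) * g + f_t`: the deviation of
#' the produced force from the target, magnified by the gain, re-centred on
#' the target. When the produced force equals the target the cursor aligns
#' with the target bar for any gain.
#'
#' @param f_p produced force.
#' @param f_t target force (positive).
#' @param g display gain.
#' @return cursor position on the same axis as `f_t`. Vectorised over `f_p`.
#' @export
feedback_position <- function(f_p, f_t, g) {
  if (any(f_t <= 0)) stop("target force must be positive")
  (f_p - f_t) * g + f_t
}

#' Pitch of the varying feedback tone
#'
#' The varying tone's frequency is linearly related to the (signed) deviation
#' of the produced force from the target force, anchored at the 440 Hz target
#' tone when the forces match, and clipped to the audible feedback range.
#' The slope is fixed so that zero force at unit audio gain maps to the lower
#' anchor: forces below target lower the pitch, forces above raise it.
#'
#' @param f_p produced force. Vectorised.
#' @param f_t target force (positive).
#' @param audio_gain dimensionless audio gain (>= 0).
#' @param cfg a [feedback_config()].
#' @return tone frequency in Hz, always within
#'   `[cfg$tone_min_hz, cfg$tone_max_hz]`.
#' @examples
#' tone_frequency(15, 15, 1)   # 440 Hz: matched force
#' tone_frequency(0, 15, 1)    # 120 Hz: no force at unit gain
#' @export
tone_frequency <- function(f_p, f_t, audio_gain, cfg = feedback_config()) {
  if (any(f_t <= 0)) stop("target force must be positive")
  if (any(audio_gain < 0)) stop("audio_gain must be non-negative")
  slope <- (cfg$tone_target_hz - cfg$tone_min_hz) / f_t
  f <- cfg$tone_target_hz + slope * audio_gain * (f_p - f_t)
  pmin(pmax(f, cfg$tone_min_hz), cfg$tone_max_hz)
}

#' Build the 12-trial schedule
#'
#' Twelve trials in three fixed blocks of four: visual-only (vo) first, then
#' audio-visual (va), then auditory-only (ao). Within each block the gain
#' levels are a seeded random permutation of two low and two high trials.
#'
#' @param seed integer seed for the within-block gain randomisation.
#' @param rest_duration,task_duration epoch durations in seconds.
#' @return A data frame of class `trial_schedule` with columns `index`,
#'   `feedback_type` (factor vo/va/ao), `gain_level` (factor low/high),
#'   `rest_duration`, `task_duration`.
#' @export
build_schedule <- function(seed, rest_duration = 30, task_duration = 30) {
  rng <- local_rng(seed)
  types <- c("vo", "va", "ao")
  gains <- unlist(lapply(types, function(ft) sample(c("low", "low", "high", "high"))))
  out <- data.frame(
    index = 1:12,
    feedback_type = factor(rep(types, each = 4), levels = types),
    gain_level = factor(gains, levels = c("low", "high")),
    rest_duration = rest_duration,
    task_duration = task_duration
  )
  class(out) <- c("trial_schedule", "data.frame")
  out
}
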