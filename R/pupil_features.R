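# Pupillometry chain: blink detection (confidence + gaze acceleration),
# Gaussian-kernel FFT-convolution gap interpolation, per-epoch subtractive
# baseline correction, and the task-window mean.

#' Detect blinks from confidence and gaze acceleration
#'
#' A sample is blink-flagged when its eye-tracker confidence falls below
#' `conf_threshold` or the robust z-score (median/MAD) of the gaze
#' acceleration magnitude exceeds `accel_z_threshold`. Flagged runs closer
#' than `2 * pad_s` are merged and every run is padded by `pad_s` on each
#' side.
#'
#' @param pupil data frame with columns `time`, `diameter`, `confidence`,
#'   `gaze_x`, `gaze_y`, regularly sampled.
#' @param conf_threshold confidence cut-off in `[0, 1]`.
#' @param accel_z_threshold robust z cut-off for the gaze acceleration.
#' @param pad_s padding in seconds around each blink interval.
#' @return An object of class `blink_mask`: list with logical `mask` (TRUE =
#'   inside a padded blink) and matrix `intervals` (start, end seconds).
#' @export
detect_blinks <- function(pupil, conf_threshold = 0.6, accel_z_threshold = 5,
                          pad_s = 0.05) {
  need <- c("time", "confidence", "gaze_x", "gaze_y")
  missing_cols <- setdiff(need, names(pupil))
  if (length(missing_cols))
    stop("pupil stream lacks column(s): ", paste(missing_cols, collapse = ", "))
  n <- nrow(pupil)
  dt <- stats::median(diff(pupil$time))
  acc <- function(g) c(0, diff(diff(g)), 0) / dt^2
  amag <- sqrt(acc(pupil$gaze_x)^2 + acc(pupil$gaze_y)^2)
  med <- stats::median(amag)
  mad <- stats::mad(amag)
  z <- if (mad > 0) (amag - med) / mad else rep(0, n)
  flag <- pupil$confidence < conf_threshold | z > accel_z_threshold
  if (!any(flag)) {
    return(structure(list(mask = flag,
                          intervals = matrix(numeric(0), ncol = 2,
                                             dimnames = list(NULL, c("start", "end")))),
                     class = "blink_mask"))
  }
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  iv <- cbind(pupil$time[starts[r$values]], pupil$time[ends[r$values]])
  # merge runs separated by < 2 * pad_s, then pad
  o <- order(iv[, 1])
  iv <- iv[o, , drop = FALSE]
  merged <- iv[1, , drop = FALSE]
  if (nrow(iv) > 1) for (i in 2:nrow(iv)) {
    if (iv[i, 1] - merged[nrow(merged), 2] < 2 * pad_s)
      merged[nrow(merged), 2] <- max(merged[nrow(merged), 2], iv[i, 2])
    else merged <- rbind(merged, iv[i, ])
  }
  merged[, 1] <- pmax(merged[, 1] - pad_s, pupil$time[1])
  merged[, 2] <- pmin(merged[, 2] + pad_s, pupil$time[n])
  mask <- rep(FALSE, n)
  i1 <- findInterval(merged[, 1] - 1e-12, pupil$time) + 1L
  i2 <- findInterval(merged[, 2] + 1e-12, pupil$time)
  for (i in seq_len(nrow(merged)))
    if (i1[i] <= i2[i]) mask[i1[i]:i2[i]] <- TRUE
  dimnames(merged) <- list(NULL, c("start", "end"))
  structure(list(mask = mask, intervals = merged), class = "blink_mask")
}

#' @export
print.blink_mask <- function(x, ...) {
  cat(sprintf("Blink mask: %d interval(s), %.1f%% of samples masked\n",
              nrow(x$intervals), 100 * mean(x$mask)))
  invisible(x)
}

#' Interpolate masked gaps by normalised Gaussian FFT convolution
#'
#' Missing (NaN) samples are replaced by a Gaussian-weighted average of the
#' valid neighbours, computed as the ratio of two FFT convolutions (signal
#' with missing values zeroed, and the validity indicator), so missing
#' samples carry no weight. Valid samples are returned unchanged.
#'
#' Missing samples are first estimated by a single normalised convolution
#' over the valid neighbours and the estimate is then iterated to
#' self-consistency (each missing sample equals the Gaussian average of the
#' filled trace around it). The iteration removes the first-order bias a
#' one-pass weighted average carries at gap edges when the signal has a
#' local slope; it reproduces linear trends across gaps exactly.
#'
#' @param x numeric trace with `NA`/`NaN` at masked samples.
#' @param kernel_span_samples total kernel support in samples (default 120,
#'   about 0.5 s at 240 Hz); the Gaussian standard deviation is one eighth
#'   of the span.
#' @param max_iter iteration cap for the self-consistency refinement;
#'   `max_iter = 1` gives the plain one-pass normalised convolution.
#' @param tol convergence tolerance relative to the valid-sample spread.
#' @return gap-free trace.
#' @export
interpolate_gaps <- function(x, kernel_span_samples = 120, max_iter = 30,
                             tol = 1e-4) {
  bad <- !is.finite(x)
  if (!any(bad)) return(x)
  if (mean(bad) >= 0.5)
    stop("more than half of the trace is missing; epoch rejected")
  half <- floor(kernel_span_samples / 2)
  sigma <- kernel_span_samples / 8
  k <- exp(-0.5 * ((-half:half) / sigma)^2)
  xs <- ifelse(bad, 0, x)
  valid <- as.numeric(!bad)
  num <- fft_convolve_same(xs, k)
  den <- fft_convolve_same(valid, k)
  est <- num / pmax(den, .Machine$double.eps)
  if (any(!is.finite(est[bad])))
    stop("interpolation failed: gap wider than the kernel support")
  out <- x
  out[bad] <- est[bad]
  scale <- stats::sd(x[!bad])
  if (scale == 0 || !is.finite(scale)) scale <- 1
  den_full <- fft_convolve_same(rep(1, length(x)), k)
  for (it in seq_len(max(0L, max_iter - 1L))) {
    est <- fft_convolve_same(out, k) / den_full
    delta <- max(abs(est[bad] - out[bad]))
    out[bad] <- est[bad]
    if (delta < tol * scale) break
  }
  out
}

# Linear 'same' convolution via FFT (zero padding at the edges).
fft_convolve_same <- function(x, k) {
  n <- length(x); m <- length(k)
  nf <- stats::nextn(n + m - 1L, 2)
  X <- stats::fft(c(x, numeric(nf - n)))
  K <- stats::fft(c(k, numeric(nf - m)))
  full <- Re(stats::fft(X * K, inverse = TRUE)) / nf
  off <- (m - 1L) %/% 2L
  full[(off + 1L):(off + n)]
}

#' Subtractive baseline correction of one epoch
#'
#' Subtracts the mean of the samples in the baseline window (default
#' `[-10, -2)` seconds before task onset) from every sample of the epoch.
#'
#' @param epoch data frame with columns `t_rel` (seconds relative to task
#'   onset) and `diameter`.
#' @param baseline_window two-element numeric, half-open `[lo, hi)` in
#'   seconds relative to task onset.
#' @return epoch with corrected `diameter`; baseline mean stored in
#'   attribute `baseline_mm`.
#' @export
baseline_correct_epoch <- function(epoch, baseline_window = c(-10, -2)) {
  inb <- epoch$t_rel >= baseline_window[1] & epoch$t_rel < baseline_window[2]
  if (!any(inb))
    stop("epoch does not cover the baseline window")
  if (min(epoch$t_rel) > baseline_window[1] + 1e-9)
    stop("epoch does not cover the full baseline window")
  b <- epoch$diameter[inb]
  if (all(!is.finite(b))) stop("baseline window fully masked")
  base <- mean(b, na.rm = TRUE)
  epoch$diameter <- epoch$diameter - base
  attr(epoch, "baseline_mm") <- base
  epoch
}

#' Mean of a baseline-corrected task window
#'
#' @param epoch a baseline-corrected epoch (see [baseline_correct_epoch()]).
#' @param task_window two-element numeric, half-open `[lo, hi)` seconds.
#' @return mean corrected diameter (mm) over the task window.
#' @export
pupil_trial_mean <- function(epoch, task_window = c(0, 30)) {
  int <- epoch$t_rel >= task_window[1] & epoch$t_rel < task_window[2]
  if (!any(int)) stop("epoch has no samples in the task window")
  mean(epoch$diameter[int])
}

#' Pupil features for one session
#'
#' Runs the pupillometry chain of one recording: blink detection on the
#' continuous stream, NaN-marking and Gaussian FFT-convolution
#' interpolation, cutting into `[-10, +30)` s epochs around each task onset,
#' per-epoch subtractive baseline correction, and the task-window mean.
#' Epochs whose pre-interpolation mask covers half or more of their samples
#' are rejected (feature missing, reason recorded).
#'
#' @param session a `stream_set`.
#' @param config a [run_config()].
#' @return data frame, one row per trial: `pid`, `trial`, `pupil_mean`,
#'   `nan_fraction`, `n_blinks`, `rejected`, `reason`.
#' @export
pupil_features <- function(session, config = run_config()) {
  pupil <- session$pupil
  bm <- detect_blinks(pupil, config$conf_threshold, config$accel_z_threshold,
                      config$blink_pad_s)
  d <- pupil$diameter
  d[bm$mask] <- NaN
  whole_bad <- mean(bm$mask) >= 0.5
  if (!whole_bad) d <- interpolate_gaps(d, config$kernel_span_samples)
  onsets <- session$markers[session$markers$label == "task_onset", ]
  rows <- lapply(seq_len(nrow(onsets)), function(i) {
    on <- onsets$time[i]
    sel <- pupil$time >= on + config$epoch_window[1] - 1e-9 &
      pupil$time < on + config$epoch_window[2] - 1e-9
    nanfrac <- mean(bm$mask[sel])
    nblk <- if (nrow(bm$intervals)) sum(bm$intervals[, 1] < on + config$epoch_window[2] &
                                          bm$intervals[, 2] > on + config$epoch_window[1]) else 0L
    if (whole_bad || nanfrac >= 0.5) {
      return(data.frame(pid = session$pid, trial = onsets$trial[i],
                        pupil_mean = NA_real_, nan_fraction = nanfrac,
                        n_blinks = nblk, rejected = TRUE,
                        reason = "artifact fraction >= 50%"))
    }
    ep <- data.frame(t_rel = pupil$time[sel] - on, diameter = d[sel])
    ep <- baseline_correct_epoch(ep, config$baseline_window)
    data.frame(pid = session$pid, trial = onsets$trial[i],
               pupil_mean = pupil_trial_mean(ep, config$task_window),
               nan_fraction = nanfrac, n_blinks = nblk,
               rejected = FALSE, reason = "")
  })
  do.call(rbind, rows)
}
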