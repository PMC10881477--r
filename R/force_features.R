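#' Normalise a raw force trace
#'
#' Divides every sample by `0.15 * maxf`, so a perfectly matched target force
#' reads exactly 1.0 in normalised units.
#'
#' @param trace raw force samples.
#' @param maxf the participant's maximum voluntary force (positive).
#' @return normalised trace.
#' @export
normalize_force <- function(trace, maxf) {
  if (!is.numeric(maxf) || length(maxf) != 1L || maxf <= 0)
    stop("maxf must be a single positive number")
  trace / (maxf * 0.15)
}

#' Cut a continuous stream into trial epochs
#'
#' Uses matched `task_onset` / `task_offset` (and `rest_onset`) marker pairs
#' to cut a continuous sample stream into per-trial task and rest epochs.
#' Windows are half-open: a sample at `t` belongs to the epoch when
#' `onset <= t < offset`.
#'
#' @param x numeric samples (any stream).
#' @param time timestamps of `x`, seconds, strictly increasing.
#' @param markers marker data frame with columns `time`, `label`, `trial`,
#'   `feedback_type`, `gain_level`.
#' @return list of per-trial lists: `trial`, `feedback_type`, `gain_level`,
#'   `task` (samples), `rest` (samples), `task_onset` (seconds).
#' @export
epoch_stream <- function(x, time, markers) {
  if (nrow(markers) == 0L) return(list())
  need <- c("time", "label", "trial", "feedback_type", "gain_level")
  missing_cols <- setdiff(need, names(markers))
  if (length(missing_cols))
    stop("marker stream lacks column(s): ", paste(missing_cols, collapse = ", "))
  markers <- markers[order(markers$time), ]
  eps <- 1e-9
  trials <- sort(unique(markers$trial[markers$label == "task_onset"]))
  lapply(trials, function(tr) {
    m <- markers[markers$trial == tr, ]
    pick <- function(lab) {
      t <- m$time[m$label == lab]
      if (length(t) != 1L)
        stop("trial ", tr, ": expected exactly one ", lab, " marker")
      t
    }
    on <- pick("task_onset"); off <- pick("task_offset")
    ron <- pick("rest_onset")
    if (off <= on) stop("trial ", tr, ": task_offset precedes task_onset")
    list(trial = tr,
         feedback_type = m$feedback_type[1],
         gain_level = m$gain_level[1],
         task = x[time >= on - eps & time < off - eps],
         rest = x[time >= ron - eps & time < on - eps],
         task_onset = on)
  })
}

#' Mean force and RMSE of an unfiltered normalised task epoch
#'
#' The tracking-accuracy features are computed on the *unfiltered*
#' normalised trace: the mean force, and the root-mean-square deviation from
#' the normalised target (1.0).
#'
#' @param epoch unfiltered normalised task-window samples.
#' @return list with `mean_force` and `rmse`.
#' @export
trial_error_stats <- function(epoch) {
  if (length(epoch) == 0L) stop("empty epoch")
  list(mean_force = mean(epoch), rmse = sqrt(mean((epoch - 1)^2)))
}

#' Force features for one session
#'
#' Runs the force chain of one recording: normalise by `0.15 * maxf`, apply
#' the zero-phase Butterworth band-pass to the continuous stream, cut into
#' trials, and per task epoch compute the Welch PSD with its 4-12 Hz tremor
#' and 0-3 Hz voluntary band powers, plus mean force and RMSE from the
#' unfiltered trace.
#'
#' @param session a `stream_set` (see [simulate_session()] /
#'   [read_streams()]).
#' @param config a [run_config()].
#' @return data frame, one row per trial: `pid`, `trial`, `feedback_type`,
#'   `gain_level`, `tremor_power`, `voluntary_power`, `mean_force`, `rmse`.
#' @export
force_features <- function(session, config = run_config()) {
  norm <- normalize_force(session$force$force, session$maxf)
  filt <- bandpass_force(norm, fs = session$fs_force,
                         lo_hz = config$filter_lo_hz, hi_hz = config$filter_hi_hz,
                         order = config$filter_order)
  ep_f <- epoch_stream(filt, session$force$time, session$markers)
  ep_r <- epoch_stream(norm, session$force$time, session$markers)
  rows <- lapply(seq_along(ep_f), function(i) {
    spec <- welch_psd(ep_f[[i]]$task, fs = session$fs_force,
                      window_s = config$welch_window_s,
                      overlap = config$welch_overlap)
    err <- trial_error_stats(ep_r[[i]]$task)
    data.frame(pid = session$pid, trial = ep_f[[i]]$trial,
               feedback_type = ep_f[[i]]$feedback_type,
               gain_level = ep_f[[i]]$gain_level,
               tremor_power = band_power(spec, config$tremor_band[1],
                                         config$tremor_band[2]),
               voluntary_power = band_power(spec, config$voluntary_band[1],
                                            config$voluntary_band[2]),
               mean_force = err$mean_force, rmse = err$rmse)
  })
  do.call(rbind, rows)
}
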