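#' Run configuration
#'
#' All tunable parameters of a pipeline run, with defaults equal to the
#' study's printed values wherever one exists (sampling rates, epoch
#' durations, gains, tone anchors, filter, bands, kernel span, baseline
#' window) and documented package defaults elsewhere (Welch window, blink
#' thresholds, statistics options).
#'
#' @param ... named overrides of any default field.
#' @return An object of class `run_config` (named list).
#' @export
run_config <- function(...) {
  cfg <- list(
    fs_force = 80, fs_pupil = 240,
    rest_s = 30, task_s = 30,
    gain_low = 0.04, gain_high = 6.9,
    tone_target_hz = 440, tone_min_hz = 120, tone_max_hz = 880,
    audio_gain_low = 1, audio_gain_high = 6.9 / 0.04,
    filter_order = 5, filter_lo_hz = 0.1, filter_hi_hz = 12,
    welch_window_s = 4, welch_overlap = 0.5,
    tremor_band = c(4, 12), voluntary_band = c(0, 3),
    conf_threshold = 0.6, accel_z_threshold = 5, blink_pad_s = 0.05,
    kernel_span_samples = 120,
    baseline_window = c(-10, -2), epoch_window = c(-10, 30),
    task_window = c(0, 30),
    unit = "trial_pair", alpha = 0.05, holm = FALSE,
    n_per_group = 14, seed = 1, simulate = TRUE)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(cfg, over)
  structure(cfg, class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("Run configuration:\n")
  for (k in names(x))
    cat(sprintf("  %-22s %s\n", k, paste(format(x[[k]]), collapse = ", ")))
  invisible(x)
}

#' Write a configuration as flat key-value text
#'
#' @param config a [run_config()].
#' @param path output file path.
#' @export
write_config <- function(config, path) {
  lines <- vapply(names(config), function(k) {
    v <- config[[k]]
    sprintf("%s = %s", k, paste(format(v, digits = 15, scientific = FALSE),
                                collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a flat key-value configuration file
#'
#' Unknown keys are rejected; values are coerced to the type of the
#' corresponding default.
#'
#' @param path file of `key = value` lines (`#` comments allowed; vector
#'   values comma-separated).
#' @return A [run_config()].
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  defaults <- run_config()
  over <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE))
      stop("malformed configuration line: ", ln)
    k <- trimws(sub("=.*$", "", ln))
    v <- trimws(sub("^[^=]*=", "", ln))
    if (!k %in% names(defaults)) stop("unknown configuration key: ", k)
    parts <- trimws(strsplit(v, ",", fixed = TRUE)[[1]])
    over[[k]] <- if (is.character(defaults[[k]])) parts
    else if (is.logical(defaults[[k]])) as.logical(parts)
    else as.numeric(parts)
  }
  do.call(run_config, over)
}
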