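# On-disk session format: one directory per session holding force.tsv
# (time, force), pupil.tsv (time, diameter, confidence, gaze_x, gaze_y) and
# markers.tsv (time, label, trial, feedback_type, gain_level); timestamps
# are seconds written with six decimals. A cohort directory adds
# participants.tsv and manifest.tsv.

write_tsv <- function(df, path, digits = 6) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) formatC(x, digits = digits,
                                                 format = "f"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n")
  invisible(path)
}

read_tsv <- function(path) {
  if (!file.exists(path)) stop("missing file: ", basename(path))
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}

#' Write one session to a directory
#'
#' @param session a `stream_set`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(session$force, file.path(dir, "force.tsv"))
  write_tsv(session$pupil, file.path(dir, "pupil.tsv"))
  write_tsv(session$markers, file.path(dir, "markers.tsv"))
  meta <- data.frame(key = c("pid", "maxf", "fs_force", "fs_pupil"),
                     value = c(session$pid, format(session$maxf, digits = 10),
                               session$fs_force, session$fs_pupil))
  utils::write.table(meta, file.path(dir, "session.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, eol = "\n")
  invisible(dir)
}

#' Read one session directory into a stream set
#'
#' Validates required files and columns, sorts markers by time, checks
#' timestamp monotonicity, and warns when an empirical sampling rate
#' deviates more than 1 percent from the configured one.
#'
#' @param dir session directory written by [write_session()].
#' @param config a [run_config()] supplying the nominal sampling rates.
#' @return A `stream_set`.
#' @export
read_streams <- function(dir, config = run_config()) {
  force <- read_tsv(file.path(dir, "force.tsv"))
  pupil <- read_tsv(file.path(dir, "pupil.tsv"))
  markers <- read_tsv(file.path(dir, "markers.tsv"))
  meta <- read_tsv(file.path(dir, "session.tsv"))
  need <- list(force.tsv = c("time", "force"),
               pupil.tsv = c("time", "diameter", "confidence", "gaze_x", "gaze_y"),
               markers.tsv = c("time", "label", "trial", "feedback_type",
                               "gain_level"))
  for (f in names(need)) {
    df <- switch(f, force.tsv = force, pupil.tsv = pupil, markers.tsv = markers)
    miss <- setdiff(need[[f]], names(df))
    if (length(miss))
      stop(f, " lacks column(s): ", paste(miss, collapse = ", "))
  }
  for (nm in c("force", "pupil")) {
    t <- get(nm)$time
    if (any(diff(t) <= 0)) stop("non-monotone timestamps in ", nm, ".tsv")
  }
  getmeta <- function(k) meta$value[match(k, meta$key)]
  fs_force <- as.numeric(getmeta("fs_force"))
  fs_pupil <- as.numeric(getmeta("fs_pupil"))
  for (chk in list(c("force", fs_force, config$fs_force),
                   c("pupil", fs_pupil, config$fs_pupil))) {
    emp <- 1 / stats::median(diff(get(chk[1])$time))
    if (abs(emp - as.numeric(chk[3])) / as.numeric(chk[3]) > 0.01)
      warning(chk[1], " stream sampling rate ", signif(emp, 4),
              " Hz deviates > 1% from configured ", chk[3], " Hz")
  }
  markers <- markers[order(markers$time), ]
  out <- list(force = force, pupil = pupil, markers = markers,
              schedule = NULL, fs_force = fs_force, fs_pupil = fs_pupil,
              pid = getmeta("pid"), maxf = as.numeric(getmeta("maxf")))
  class(out) <- "stream_set"
  out
}

#' Write a simulated cohort to disk
#'
#' One sub-directory per session plus `participants.tsv` and `manifest.tsv`.
#'
#' @param cohort result of `simulate_cohort(..., level = "signal")`.
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dirs <- vapply(cohort$sessions, function(s) {
    d <- file.path(dir, s$pid)
    write_session(s, d)
    s$pid
  }, character(1))
  write_tsv(cohort$participants, file.path(dir, "participants.tsv"))
  utils::write.table(data.frame(session = dirs),
                     file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, eol = "\n")
  invisible(dir)
}

#' Extract the per-trial feature table of a cohort
#'
#' Applies [force_features()] and [pupil_features()] to every session and
#' joins the results with the participant table.
#'
#' @param cohort list with `sessions` and `participants` (from
#'   [simulate_cohort()] or assembled from [read_streams()]).
#' @param config a [run_config()].
#' @return tidy data frame, one row per participant x trial, with feature
#'   columns `tremor_power`, `voluntary_power`, `mean_force`, `rmse`,
#'   `pupil_mean` and the pupil quality columns.
#' @export
extract_features <- function(cohort, config = run_config()) {
  rows <- lapply(cohort$sessions, function(s) {
    ff <- force_features(s, config)
    pf <- pupil_features(s, config)
    merge(ff, pf, by = c("pid", "trial"), sort = FALSE)
  })
  feats <- do.call(rbind, rows)
  grp <- cohort$participants[, c("pid", "group")]
  out <- merge(grp, feats, by = "pid", sort = FALSE)
  out[order(match(out$pid, cohort$participants$pid), out$trial), ]
}
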