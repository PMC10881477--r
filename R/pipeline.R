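#' Run the complete analysis pipeline
#'
#' One reproducible run: simulate a cohort (or load sessions from disk),
#' extract per-trial force and pupil features, build gain contrasts, run the
#' statistical layer, and write `features.tsv`, `results.tsv`,
#' `quality.tsv`, a plain-text report, a log, and a verbatim copy of the
#' configuration into the output directory. Identical configuration and
#' seed give byte-identical outputs.
#'
#' @param config a [run_config()]; `config$simulate` selects simulation,
#'   `config$seed` drives every random draw.
#' @param out_dir output directory, or `NULL` to skip writing.
#' @param sessions_dir cohort directory (with `manifest.tsv` and
#'   `participants.tsv`) when `config$simulate` is `FALSE`.
#' @param effects a [cohort_effects()] used when simulating.
#' @return An object of class `tremor_study`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL,
                         sessions_dir = NULL, effects = cohort_effects()) {
  log <- character(0)
  note <- function(...) {
    log <<- c(log, sprintf(...))
    invisible(NULL)
  }
  note("pipeline start: seed=%d n_per_group=%d unit=%s alpha=%g",
       config$seed, config$n_per_group, config$unit, config$alpha)
  if (isTRUE(config$simulate)) {
    cohort <- simulate_cohort(config$n_per_group, effects, config$seed,
                              level = "signal")
    note("simulated cohort: %d sessions", length(cohort$sessions))
  } else {
    if (is.null(sessions_dir)) stop("sessions_dir required when simulate=FALSE")
    man <- read_tsv(file.path(sessions_dir, "manifest.tsv"))
    parts <- read_tsv(file.path(sessions_dir, "participants.tsv"))
    cohort <- list(participants = parts,
                   sessions = lapply(man$session, function(s)
                     read_streams(file.path(sessions_dir, s), config)))
    note("loaded cohort from %s: %d sessions", sessions_dir,
         length(cohort$sessions))
  }
  feats <- extract_features(cohort, config)
  note("features: %d rows (%d rejected pupil epochs)", nrow(feats),
       sum(feats$rejected))
  contrasts <- build_contrasts(feats, unit = config$unit)
  note("contrasts (%s): %d rows", config$unit, nrow(contrasts))

  tests <- list()
  for (oc in c("tremor_power", "pupil_mean"))
    for (ft in c("vo", "va", "ao"))
      tests[[sprintf("group_%s_%s", ft, oc)]] <-
        group_ttest(contrasts, ft, oc)
  for (oc in c("tremor_power", "pupil_mean"))
    for (g in c("pET", "HC"))
      for (ft in c("vo", "va", "ao"))
        tests[[sprintf("paired_%s_%s_%s", g, ft, oc)]] <-
          paired_gain_test(feats, g, ft, oc, alpha = config$alpha)
  for (oc in c("rmse", "mean_force", "voluntary_power")) {
    av <- anova_trials(feats, outcome = oc)
    tests[[sprintf("anova_group_%s", oc)]] <- av[[1]]
    tests[[sprintf("anova_feedback_type_%s", oc)]] <- av[[2]]
  }
  pt <- cohort$participants
  for (cv in c("age", "bdi"))
    tests[[sprintf("covariate_%s", cv)]] <-
      compare_covariates(pt[[cv]][pt$group == "pET"],
                         pt[[cv]][pt$group == "HC"], alpha = config$alpha)
  pet <- pt[pt$group == "pET", ]
  if (sum(is.finite(pet$tetras)) >= 4) {
    tests$corr_tetras_age <- correlate(pet$tetras, pet$age)
    tests$corr_tetras_bdi <- correlate(pet$tetras, pet$bdi)
    tests$corr_tetras_bdi_partial_age <-
      correlate(pet$tetras, pet$bdi, partial_covariate = pet$age)
  }
  if (isTRUE(config$holm)) {
    ps <- vapply(tests, `[[`, numeric(1), "p_value")
    adj <- stats::p.adjust(ps, method = "holm")
    for (i in seq_along(tests)) tests[[i]]$p_holm <- adj[[i]]
  }
  note("statistics: %d tests", length(tests))
  results <- do.call(rbind, lapply(names(tests), function(nm)
    as_result_row(tests[[nm]], list(id = nm))))
  pattern <- headline_pattern(feats, alpha = config$alpha)
  note("headline pattern %s", if (pattern$match) "reproduced" else
    "not reproduced")

  study <- structure(list(config = config, participants = pt,
                          features = feats, contrasts = contrasts,
                          tests = tests, results = results,
                          pattern = pattern, log = log),
                     class = "tremor_study")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(feats, file.path(out_dir, "features.tsv"), digits = 10)
    write_tsv(results, file.path(out_dir, "results.tsv"), digits = 10)
    qual <- feats[, c("pid", "trial", "nan_fraction", "n_blinks", "rejected",
                      "reason")]
    write_tsv(qual, file.path(out_dir, "quality.tsv"), digits = 10)
    write_config(config, file.path(out_dir, "config.txt"))
    writeLines(c(log, report_lines(study)), file.path(out_dir, "log.txt"))
    writeLines(report_lines(study), file.path(out_dir, "report.txt"))
  }
  study
}

report_lines <- function(study) {
  fmt <- function(x) {
    dfs <- if (all(is.na(x$df))) "" else
      sprintf("[%s]", paste(signif(x$df, 4), collapse = ", "))
    sprintf("  %-44s %s%s = %8.3f, p = %.4g   %s", x$comparison, x$statistic,
            dfs, x$value, x$p_value, x$branch %||% "")
  }
  sec <- function(title, ids) c(title, vapply(study$tests[ids], fmt,
                                              character(1)), "")
  ids <- names(study$tests)
  c("Synthetic-cohort analysis report",
    sprintf("seed %d, %d per group, unit = %s, alpha = %g",
            study$config$seed, study$config$n_per_group, study$config$unit,
            study$config$alpha), "",
    sec("Between-group contrast t-tests (high - low gain):",
        grep("^group_", ids, value = TRUE)),
    sec("Within-group high vs low gain:",
        grep("^paired_", ids, value = TRUE)),
    sec("Trial-level ANOVAs:", grep("^anova_", ids, value = TRUE)),
    sec("Covariates:", grep("^covariate_", ids, value = TRUE)),
    if (any(grepl("^corr_", ids)))
      sec("Correlations (pET):", grep("^corr_", ids, value = TRUE)),
    sprintf("Headline significance pattern reproduced: %s",
            study$pattern$match))
}

#' @export
print.tremor_study <- function(x, ...) {
  cat(sprintf("tremor_study: %d participants, %d feature rows, %d tests\n",
              nrow(x$participants), nrow(x$features), length(x$tests)))
  cat(sprintf("  headline pattern reproduced: %s\n", x$pattern$match))
  invisible(x)
}

#' @export
summary.tremor_study <- function(object, ...) {
  cat(paste(report_lines(object), collapse = "\n"), "\n")
  invisible(object)
}
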