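# Simulation utilities built on the feature-level cohort sampler: headline
# significance-pattern recovery, type-I-error calibration, and the
# sequential-design power analysis.

#' Evaluate the headline significance pattern on one feature table
#'
#' The qualitative finding the package's default cohort encodes: patients
#' show a significant tremor-band power increase under high gain in all
#' three feedback types; controls only under combined audio-visual feedback;
#' patients show a significant pupil-dilation contrast under the two
#' auditory-involved feedback types but not under visual-only feedback.
#'
#' @param features per-trial feature table.
#' @param alpha significance level.
#' @return list with logical `match` and a data frame `detail` (one row per
#'   component test: expectation, p-value, outcome).
#' @export
headline_pattern <- function(features, alpha = 0.05) {
  comp <- expand.grid(group = c("pET", "HC"), feedback_type = c("vo", "va", "ao"),
                      outcome = c("tremor_power", "pupil_mean"),
                      stringsAsFactors = FALSE)
  comp$expect_significant <- with(comp, ifelse(
    outcome == "tremor_power",
    group == "pET" | feedback_type == "va",
    group == "pET" & feedback_type %in% c("va", "ao")))
  # only the components the headline speaks to are scored: all six tremor
  # cells, and the three patient pupil cells
  comp <- comp[comp$outcome == "tremor_power" | comp$group == "pET", ]
  comp$p_value <- vapply(seq_len(nrow(comp)), function(i)
    paired_gain_test(features, comp$group[i], comp$feedback_type[i],
                     comp$outcome[i])$p_value, numeric(1))
  comp$significant <- comp$p_value < alpha
  comp$ok <- comp$significant == comp$expect_significant
  list(match = all(comp$ok), detail = comp)
}

#' Headline-pattern recovery rate over simulated studies
#'
#' Simulates `n_studies` independent cohorts at the given effect sizes and
#' reports the fraction whose feature table reproduces the full headline
#' significance pattern (see [headline_pattern()]).
#'
#' @param n_studies number of simulated studies.
#' @param n_per_group participants per group.
#' @param effects a [cohort_effects()].
#' @param seed master seed.
#' @param level `"signal"` runs the complete raw-stream pipeline per study;
#'   `"feature"` uses the fast feature-level sampler.
#' @param alpha significance level.
#' @param config a [run_config()] (signal level only).
#' @return list with `rate`, logical vector `matched`, and the per-study
#'   pattern details.
#' @export
pattern_recovery <- function(n_studies = 200, n_per_group = 14,
                             effects = cohort_effects(), seed = 1,
                             level = c("signal", "feature"), alpha = 0.05,
                             config = run_config()) {
  level <- match.arg(level)
  details <- vector("list", n_studies)
  matched <- logical(n_studies)
  for (s in seq_len(n_studies)) {
    feats <- simulate_study_features(n_per_group, effects,
                                     child_seed(seed, s, 100L), level, config)
    pat <- headline_pattern(feats, alpha)
    matched[s] <- pat$match
    details[[s]] <- pat$detail
  }
  list(rate = mean(matched), matched = matched, details = details)
}

#' Feature table of one simulated study
#'
#' @inheritParams pattern_recovery
#' @param seed integer seed.
#' @return per-trial feature table with `pid`, `group`, condition and
#'   feature columns.
#' @export
simulate_study_features <- function(n_per_group = 14,
                                    effects = cohort_effects(), seed = 1,
                                    level = c("signal", "feature"),
                                    config = run_config()) {
  level <- match.arg(level)
  co <- simulate_cohort(n_per_group, effects, seed, level)
  if (level == "feature") co$features else extract_features(co, config)
}

#' Type-I-error calibration of the group tests
#'
#' Simulates zero-effect cohorts (no group differences and no
#' between-participant heterogeneity: the exchangeable null) and reports the
#' rejection rate at level `alpha` of the between-group contrast t-test and
#' of the two trial-level one-way ANOVA factors.
#'
#' @param n_sims number of null cohorts.
#' @param n_per_group participants per group.
#' @param seed master seed.
#' @param alpha nominal level.
#' @param feedback_type feedback type for the contrast t-test.
#' @return list of empirical rejection rates: `group_ttest`, `anova_group`,
#'   `anova_feedback_type`, plus `n_sims`.
#' @export
calibrate_type1 <- function(n_sims = 1000, n_per_group = 14, seed = 1,
                            alpha = 0.05, feedback_type = "vo") {
  eff <- cohort_effects(null = TRUE)
  rej <- matrix(FALSE, n_sims, 3,
                dimnames = list(NULL, c("group_ttest", "anova_group",
                                        "anova_feedback_type")))
  for (s in seq_len(n_sims)) {
    co <- simulate_cohort(n_per_group, eff, child_seed(seed, s, 200L),
                          level = "feature")
    ct <- build_contrasts(co$features, unit = "trial_pair",
                          outcomes = "tremor_power")
    rej[s, 1] <- group_ttest(ct, feedback_type)$p_value < alpha
    av <- anova_trials(co$features, outcome = "rmse")
    rej[s, 2] <- av[[1]]$p_value < alpha
    rej[s, 3] <- av[[2]]$p_value < alpha
  }
  c(as.list(colMeans(rej)), list(n_sims = n_sims))
}

#' Sequential-design power simulation
#'
#' Emulates the sequential sampling plan: cohorts of increasing size are
#' simulated at the configured effect sizes and the primary between-group
#' contrast t-test is applied at each size; the smallest per-group n whose
#' simulated power reaches `power_target` is the stopping n, capped at
#' `n_max`.
#'
#' @param effects a [cohort_effects()].
#' @param alpha test level.
#' @param power_target target power (default 0.80).
#' @param n_max maximal per-group sample size (default 25).
#' @param n_min smallest per-group n examined.
#' @param n_sims simulated cohorts per sample size.
#' @param seed master seed.
#' @param feedback_type feedback type of the primary contrast.
#' @return An object of class `sequential_power`: list with `n` (grid),
#'   `power` (achieved power curve), `stopping_n` (NA when the cap is
#'   reached without attaining the target) and the design parameters.
#' @export
sequential_power <- function(effects = cohort_effects(), alpha = 0.05,
                             power_target = 0.80, n_max = 25, n_min = 4,
                             n_sims = 200, seed = 1, feedback_type = "vo") {
  ns <- n_min:n_max
  pow <- numeric(length(ns))
  for (i in seq_along(ns)) {
    hits <- vapply(seq_len(n_sims), function(s) {
      co <- simulate_cohort(ns[i], effects,
                            child_seed(seed, i * 1000L + s, 300L),
                            level = "feature")
      ct <- build_contrasts(co$features, unit = "trial_pair",
                            outcomes = "tremor_power")
      group_ttest(ct, feedback_type)$p_value < alpha
    }, logical(1))
    pow[i] <- mean(hits)
    if (pow[i] >= power_target && i >= 2L) {  # examine at least two sizes
      ns <- ns[seq_len(i)]; pow <- pow[seq_len(i)]
      break
    }
  }
  stopping <- if (any(pow >= power_target)) ns[which(pow >= power_target)[1]]
  else NA_integer_
  structure(list(n = ns, power = pow, stopping_n = stopping,
                 power_target = power_target, alpha = alpha, n_max = n_max,
                 n_sims = n_sims, feedback_type = feedback_type),
            class = "sequential_power")
}

#' @export
print.sequential_power <- function(x, ...) {
  cat(sprintf("Sequential design: target power %.2f at alpha %.2g, cap n = %d/group\n",
              x$power_target, x$alpha, x$n_max))
  if (is.na(x$stopping_n))
    cat(sprintf("  cap reached without attaining the target (power %.3f at n = %d)\n",
                x$power[length(x$power)], x$n[length(x$n)]))
  else
    cat(sprintf("  stopping n = %d/group (simulated power %.3f, %d sims per size)\n",
                x$stopping_n, x$power[match(x$stopping_n, x$n)], x$n_sims))
  invisible(x)
}

#' @export
plot.sequential_power <- function(x, xlab = "n per group", ylab = "Power",
                                  ...) {
  plot(x$n, x$power, type = "b", ylim = c(0, 1), xlab = xlab, ylab = ylab, ...)
  graphics::abline(h = x$power_target, lty = 2)
  if (!is.na(x$stopping_n)) graphics::abline(v = x$stopping_n, lty = 3)
  invisible(x)
}
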