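# Statistical layer over the tidy per-trial feature table: high-vs-low gain
# contrasts, between-group and within-group tests with normality gates,
# trial-level ANOVA, gated correlations, and covariate comparisons.

test_result <- function(statistic, value, df, p_value, test, comparison,
                        n, branch = NA_character_, estimate = NA_real_) {
  structure(list(statistic = statistic, value = unname(value), df = df,
                 p_value = unname(p_value), test = test,
                 comparison = comparison, n = n, branch = branch,
                 estimate = unname(estimate)),
            class = "tremor_test")
}

#' @export
print.tremor_test <- function(x, ...) {
  dfs <- if (all(is.na(x$df))) "" else
    sprintf("[%s]", paste(signif(x$df, 4), collapse = ", "))
  cat(sprintf("%s: %s%s = %.3f, p = %.4g  (%s%s)\n",
              x$comparison, x$statistic, dfs, x$value, x$p_value, x$test,
              if (!is.na(x$branch)) paste0("; branch: ", x$branch) else ""))
  invisible(x)
}

as_result_row <- function(x, extra = list()) {
  cbind(data.frame(comparison = x$comparison, test = x$test,
                   statistic = x$statistic, value = x$value,
                   df1 = x$df[1], df2 = if (length(x$df) > 1) x$df[2] else NA,
                   p_value = x$p_value, n = paste(x$n, collapse = "/"),
                   branch = x$branch, estimate = x$estimate),
        as.data.frame(extra))
}

#' High-minus-low gain contrasts
#'
#' For every participant and feedback type, computes the difference between
#' the high- and low-gain feedback conditions. With `unit = "trial_pair"`
#' the k-th low trial (in presentation order) is paired with the k-th high
#' trial, giving two contrast rows per participant and type (this is the
#' unit whose pooled count matches the df ~ 53 between-group t-tests of the
#' study the package models). With `unit = "participant"` the two trials per
#' gain level are averaged first, giving one row.
#'
#' @param features per-trial feature table (see [extract_features()]).
#' @param unit `"trial_pair"` or `"participant"`.
#' @param outcomes feature columns to difference.
#' @return An object of class `contrast_table`: data frame with `pid`,
#'   `group`, `feedback_type`, `pair_index` and one `delta_<outcome>` column
#'   per outcome. Incomplete cells are dropped with a message.
#' @export
build_contrasts <- function(features,
                            unit = c("trial_pair", "participant"),
                            outcomes = c("tremor_power", "pupil_mean")) {
  unit <- match.arg(unit)
  outcomes <- intersect(outcomes, names(features))
  sp <- split(features, list(features$pid, features$feedback_type),
              drop = TRUE)
  rows <- lapply(sp, function(d) {
    lo <- d[d$gain_level == "low", ][order(d$trial[d$gain_level == "low"]), ]
    hi <- d[d$gain_level == "high", ][order(d$trial[d$gain_level == "high"]), ]
    if (nrow(lo) == 0L || nrow(hi) == 0L) {
      message("dropping ", d$pid[1], "/", d$feedback_type[1],
              ": missing gain level")
      return(NULL)
    }
    if (unit == "participant") {
      deltas <- lapply(outcomes, function(oc)
        mean(hi[[oc]], na.rm = TRUE) - mean(lo[[oc]], na.rm = TRUE))
      k <- 1L
    } else {
      k <- seq_len(min(nrow(lo), nrow(hi)))
      deltas <- lapply(outcomes, function(oc) hi[[oc]][k] - lo[[oc]][k])
    }
    out <- data.frame(pid = d$pid[1], group = d$group[1],
                      feedback_type = d$feedback_type[1], pair_index = k)
    for (i in seq_along(outcomes))
      out[[paste0("delta_", outcomes[i])]] <- deltas[[i]]
    out
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  class(out) <- c("contrast_table", "data.frame")
  out
}

#' Between-group t-test on gain contrasts
#'
#' Two-sample pooled-variance t-test of the high-minus-low contrasts,
#' patients versus controls, within one feedback type.
#'
#' @param contrasts a [build_contrasts()] table.
#' @param feedback_type `"vo"`, `"va"` or `"ao"`.
#' @param outcome contrast column (without the `delta_` prefix).
#' @return A `tremor_test` with t, df = n1 + n2 - 2 and p.
#' @export
group_ttest <- function(contrasts, feedback_type,
                        outcome = "tremor_power") {
  col <- paste0("delta_", outcome)
  d <- contrasts[contrasts$feedback_type == feedback_type & is.finite(contrasts[[col]]), ]
  x <- d[[col]][d$group == "pET"]
  y <- d[[col]][d$group == "HC"]
  if (length(x) < 2L || length(y) < 2L)
    stop("need at least two contrasts per group")
  tt <- stats::t.test(x, y, var.equal = TRUE)
  test_result("t", tt$statistic, unname(tt$parameter), tt$p.value,
              "two-sample t (pooled variance)",
              sprintf("pET vs HC, %s, delta %s", feedback_type, outcome),
              c(length(x), length(y)),
              estimate = mean(x) - mean(y))
}

#' Within-group high-versus-low gain test
#'
#' Participant means per gain level within one group and feedback type,
#' compared by a paired t-test, falling back to a Wilcoxon signed-rank test
#' when a Shapiro-Wilk test rejects normality of the paired differences
#' (alpha = 0.05). The branch taken is recorded.
#'
#' @param features per-trial feature table.
#' @param group `"pET"` or `"HC"`.
#' @param feedback_type `"vo"`, `"va"` or `"ao"`.
#' @param outcome feature column.
#' @param alpha level of the normality gate.
#' @return A `tremor_test` (statistic `t` or `V`).
#' @export
paired_gain_test <- function(features, group, feedback_type,
                             outcome = "tremor_power", alpha = 0.05) {
  d <- features[features$group == group &
                  features$feedback_type == feedback_type, ]
  ag <- stats::aggregate(d[[outcome]],
                         list(pid = d$pid, gain = d$gain_level), mean,
                         na.rm = TRUE)
  w <- stats::reshape(ag, idvar = "pid", timevar = "gain", direction = "wide")
  hi <- w$x.high; lo <- w$x.low
  ok <- is.finite(hi) & is.finite(lo)
  hi <- hi[ok]; lo <- lo[ok]
  if (length(hi) < 3L) stop("need at least three complete pairs")
  diffs <- hi - lo
  if (all(diffs == 0)) {
    return(test_result("t", 0, length(diffs) - 1, 1, "paired t",
                       sprintf("%s %s: high vs low %s", group, feedback_type,
                               outcome),
                       length(diffs), branch = "degenerate: no difference",
                       estimate = 0))
  }
  sw_p <- tryCatch(stats::shapiro.test(diffs)$p.value, error = function(e) 0)
  if (sw_p >= alpha) {
    tt <- stats::t.test(hi, lo, paired = TRUE)
    test_result("t", tt$statistic, unname(tt$parameter), tt$p.value,
                "paired t",
                sprintf("%s %s: high vs low %s", group, feedback_type, outcome),
                length(diffs), branch = "parametric (Shapiro-Wilk passed)",
                estimate = mean(diffs))
  } else {
    wt <- stats::wilcox.test(hi, lo, paired = TRUE, exact = FALSE,
                             correct = TRUE)
    test_result("V", wt$statistic, NA_real_, wt$p.value,
                "Wilcoxon signed-rank",
                sprintf("%s %s: high vs low %s", group, feedback_type, outcome),
                length(diffs), branch = "nonparametric (Shapiro-Wilk rejected)",
                estimate = stats::median(diffs))
  }
}

#' Trial-level one-way ANOVAs
#'
#' Fixed-effects one-way ANOVA of a trial-level outcome on each factor in
#' turn (group; feedback type), reporting F, the effect and residual degrees
#' of freedom, and p. Separate one-way fits are used because the two factors
#' are reported with their own residual df. Trials are treated as
#' independent observations (the repeated-measures structure is ignored; see
#' the package vignette for the implied caveat).
#'
#' @param features per-trial feature table.
#' @param outcome feature column (e.g. `"rmse"`).
#' @param factors factor columns to test.
#' @return list of `tremor_test`, one per factor.
#' @export
anova_trials <- function(features, outcome = "rmse",
                         factors = c("group", "feedback_type")) {
  lapply(factors, function(fc) {
    f <- factor(features[[fc]])
    if (nlevels(droplevels(f)) < 2L)
      stop("factor ", fc, " has fewer than two levels")
    y <- features[[outcome]]
    ok <- is.finite(y)
    fit <- stats::aov(y[ok] ~ droplevels(f[ok]))
    sm <- summary(fit)[[1]]
    if (stats::var(y[ok]) <= (1e-10 * (abs(mean(y[ok])) + 1e-300))^2) {
      sm$`F value`[1] <- 0         # outcome constant across all cells
      sm$`Pr(>F)`[1] <- 1
    }
    test_result("F", sm$`F value`[1], c(sm$Df[1], sm$Df[2]), sm$`Pr(>F)`[1],
                "one-way ANOVA (trial level)",
                sprintf("%s effect on %s", fc, outcome), sum(ok))
  })
}

#' Compare a covariate between groups with a normality gate
#'
#' Shapiro-Wilk in each group; if either rejects (or a group is constant)
#' the comparison is a Mann-Whitney U test, otherwise a two-sample t-test.
#'
#' @param x,y covariate values in the two groups.
#' @param labels group labels for reporting.
#' @param alpha level of the normality gate.
#' @param test `"auto"` applies the Shapiro-Wilk gate; `"mann-whitney"` or
#'   `"t"` force a branch (clinical rating scales are conventionally
#'   compared by Mann-Whitney U regardless of the gate).
#' @return A `tremor_test` (statistic `U` or `t`) with the branch recorded.
#' @export
compare_covariates <- function(x, y, labels = c("pET", "HC"), alpha = 0.05,
                               test = c("auto", "mann-whitney", "t")) {
  test <- match.arg(test)
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 3L || length(y) < 3L)
    stop("need at least three observations per group")
  swp <- function(v) {
    if (length(unique(v)) < 3L) return(0)   # constant: force nonparametric
    tryCatch(stats::shapiro.test(v)$p.value, error = function(e) 0)
  }
  normal <- switch(test, auto = swp(x) >= alpha && swp(y) >= alpha,
                   `mann-whitney` = FALSE, t = TRUE)
  cmp <- sprintf("%s vs %s", labels[1], labels[2])
  if (normal) {
    tt <- stats::t.test(x, y, var.equal = TRUE)
    test_result("t", tt$statistic, unname(tt$parameter), tt$p.value,
                "two-sample t", cmp, c(length(x), length(y)),
                branch = "parametric (Shapiro-Wilk passed)",
                estimate = mean(x) - mean(y))
  } else {
    wt <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
    test_result("U", wt$statistic, NA_real_, wt$p.value, "Mann-Whitney U",
                cmp, c(length(x), length(y)),
                branch = "nonparametric (Shapiro-Wilk rejected)",
                estimate = stats::median(x) - stats::median(y))
  }
}

#' Gated (partial) correlation
#'
#' Pearson correlation when Shapiro-Wilk on both variables (and, when a
#' grouping is supplied, Levene's test on both) do not reject; Spearman rank
#' correlation otherwise. With `partial_covariate`, both variables are
#' residualised on the covariate (after rank transformation in the Spearman
#' branch) and the residuals are correlated with n - 3 degrees of freedom.
#'
#' @param x,y paired observations (n >= 4).
#' @param partial_covariate optional covariate to partial out.
#' @param group optional grouping for the variance-homogeneity gate.
#' @param alpha level of the gates.
#' @return A `tremor_test` (statistic `r` or `rho`).
#' @export
correlate <- function(x, y, partial_covariate = NULL, group = NULL,
                      alpha = 0.05) {
  ok <- is.finite(x) & is.finite(y) &
    (if (is.null(partial_covariate)) TRUE else is.finite(partial_covariate))
  x <- x[ok]; y <- y[ok]
  if (!is.null(partial_covariate)) partial_covariate <- partial_covariate[ok]
  if (!is.null(group)) group <- group[ok]
  n <- length(x)
  if (n < 4L) stop("need at least four paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for a constant variable")
  gate <- stats::shapiro.test(x)$p.value >= alpha &&
    stats::shapiro.test(y)$p.value >= alpha
  if (gate && !is.null(group) && nlevels(factor(group)) > 1L) {
    lv <- function(v) car::leveneTest(v ~ factor(group))[1, "Pr(>F)"]
    gate <- lv(x) >= alpha && lv(y) >= alpha
  }
  method <- if (gate) "pearson" else "spearman"
  if (!gate) { x <- rank(x); y <- rank(y)
    if (!is.null(partial_covariate)) partial_covariate <- rank(partial_covariate) }
  if (is.null(partial_covariate)) {
    ct <- stats::cor.test(x, y, method = "pearson")
    test_result(if (gate) "r" else "rho", ct$estimate, unname(ct$parameter),
                ct$p.value,
                if (gate) "Pearson correlation" else "Spearman rank correlation",
                "x ~ y", n,
                branch = if (gate) "parametric (gates passed)" else
                  "rank-based (gate rejected)",
                estimate = ct$estimate)
  } else {
    rx <- stats::resid(stats::lm(x ~ partial_covariate))
    ry <- stats::resid(stats::lm(y ~ partial_covariate))
    r <- stats::cor(rx, ry)
    df <- n - 3
    tstat <- r * sqrt(df / (1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), df)
    test_result(if (gate) "r" else "rho", r, df, p,
                paste0(if (gate) "Pearson" else "Spearman",
                       " partial correlation"),
                "x ~ y | covariate", n,
                branch = if (gate) "parametric (gates passed)" else
                  "rank-based (gate rejected)",
                estimate = r)
  }
}
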