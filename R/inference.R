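#' Cohen's d with pooled standard deviation
#'
#' `(mean(x) - mean(y)) / s_p` with
#' `s_p = sqrt(((n_x - 1) s_x^2 + (n_y - 1) s_y^2) / (n_x + n_y - 2))`.
#' The sign convention is first minus second group.
#'
#' @param x,y numeric samples (each n >= 2).
#' @return the standardized mean difference.
#' @export
cohens_d <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  nx <- length(x); ny <- length(y)
  if (nx < 2 || ny < 2) stop("each sample needs at least 2 observations")
  sp <- sqrt(((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2))
  if (sp == 0) stop("zero pooled standard deviation")
  (mean(x) - mean(y)) / sp
}

#' Two-group comparison with a normality gate
#'
#' Screens each group with a Shapiro-Wilk test at `gaussian_check_alpha`;
#' if both look Gaussian a Welch two-sample t-test is used, otherwise a
#' two-sample rank-sum (Mann-Whitney) test. Cohen's d is always reported
#' (sign: first minus second group, in the order of `sort(unique(labels))`
#' unless `labels` is a factor, in which case factor-level order).
#'
#' @param values numeric outcome.
#' @param labels two-group labels.
#' @param gaussian_check_alpha normality-screen alpha (default 0.05).
#' @return one-row data.frame: `variable`, `group1`, `group2`, `test`,
#'   `statistic`, `p_value`, `cohens_d`, `n1`, `n2`.
#' @export
compare_groups <- function(values, labels, gaussian_check_alpha = 0.05) {
  keep <- !is.na(values) & !is.na(labels)
  values <- values[keep]; labels <- labels[keep]
  lev <- if (is.factor(labels)) levels(factor(labels)) else sort(unique(labels))
  if (length(lev) != 2) stop("compare_groups requires exactly two groups")
  x <- values[labels == lev[1]]; y <- values[labels == lev[2]]
  if (length(x) < 3 || length(y) < 3) stop("each group needs at least 3 observations")
  normal <- function(v) length(unique(v)) > 2 &&
    shapiro.test(v)$p.value >= gaussian_check_alpha
  gaussian <- normal(x) && normal(y)
  if (gaussian) {
    ht <- t.test(x, y)               # Welch by default
    test <- "welch_t"
  } else {
    ht <- suppressWarnings(wilcox.test(x, y, exact = FALSE))
    test <- "rank_sum"
  }
  data.frame(variable = NA_character_, group1 = lev[1], group2 = lev[2],
             test = test, statistic = unname(ht$statistic),
             p_value = ht$p.value, cohens_d = cohens_d(x, y),
             n1 = length(x), n2 = length(y), stringsAsFactors = FALSE)
}

#' One-way ANOVA with post hoc Welch tests on motor noise
#'
#' Fits a one-way ANOVA of the score on group, then runs all pairwise Welch
#' two-sample t-tests with Cohen's d.
#'
#' @param values numeric outcome (e.g., motor-noise scores).
#' @param groups group labels (>= 3 groups, each n >= 3).
#' @return list with `anova` (data.frame: F, df1, df2, p_value) and
#'   `posthoc` (data.frame of pairwise Welch tests).
#' @export
anova_posthoc <- function(values, groups) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- factor(groups[keep])
  if (nlevels(groups) < 3) stop("need at least three groups")
  if (any(table(groups) < 3)) stop("every group needs at least 3 observations")
  fit <- aov(values ~ groups)
  an <- summary(fit)[[1]]
  anova_row <- data.frame(F = an$`F value`[1], df1 = an$Df[1], df2 = an$Df[2],
                          p_value = an$`Pr(>F)`[1])
  combs <- utils::combn(levels(groups), 2)
  posthoc <- do.call(rbind, lapply(seq_len(ncol(combs)), function(i) {
    g1 <- combs[1, i]; g2 <- combs[2, i]
    x <- values[groups == g1]; y <- values[groups == g2]
    ht <- t.test(x, y)
    data.frame(group1 = g1, group2 = g2, t = unname(ht$statistic),
               p_value = ht$p.value, cohens_d = cohens_d(x, y),
               n1 = length(x), n2 = length(y), stringsAsFactors = FALSE)
  }))
  list(anova = anova_row, posthoc = posthoc)
}

#' Compare two linear grouping models of an outcome by AIC
#'
#' Fits `outcome ~ grouping` by ordinary least squares for two alternative
#' grouping variables on the same rows and returns `AIC(model_a) -
#' AIC(model_b)`: positive values favor model B (the second grouping explains
#' the outcome better).
#'
#' @param outcome numeric outcome.
#' @param grouping_a,grouping_b two grouping vectors of the same length.
#' @return list with `delta_aic` (`AIC_a - AIC_b`), `aic_a`, `aic_b`.
#' @export
aic_compare <- function(outcome, grouping_a, grouping_b) {
  if (length(outcome) != length(grouping_a) ||
      length(outcome) != length(grouping_b))
    stop("outcome and groupings must align row-wise")
  keep <- !is.na(outcome) & !is.na(grouping_a) & !is.na(grouping_b)
  outcome <- outcome[keep]
  a <- lm(outcome ~ factor(grouping_a[keep]))
  b <- lm(outcome ~ factor(grouping_b[keep]))
  list(delta_aic = AIC(a) - AIC(b), aic_a = AIC(a), aic_b = AIC(b))
}

#' Group-by-phase linear mixed model of motor noise
#'
#' Fits `value ~ group * phase + (1 | subject_id)` by REML (each subject
#' contributes one value per phase; the random intercept absorbs stable
#' between-subject differences), tests the interaction with a Type III F
#' test (Satterthwaite denominator degrees of freedom), and runs follow-up
#' per-phase Welch contrasts between the two non-reference groups of
#' interest (all pairwise contrasts are returned).
#'
#' @param data long data.frame with `subject_id`, `group`, `phase`, `value`.
#' @return object of class `lmm_result`: `fixed_effects`, `interaction`
#'   (F, df, p), `random_intercept_var`, `residual_var`, `singular`,
#'   `per_phase` (pairwise Welch contrasts within each phase), `n_subjects`,
#'   `n_obs`, `model`.
#' @export
fit_group_phase_lmm <- function(data) {
  assert_columns(data, c("subject_id", "group", "phase", "value"), "long table")
  data <- data[complete.cases(data[, c("subject_id", "group", "phase", "value")]), ]
  data$group <- factor(data$group)
  data$phase <- factor(data$phase)
  m <- lmerTest::lmer(value ~ group * phase + (1 | subject_id), data = data,
                      REML = TRUE)
  singular <- lme4::isSingular(m)
  an <- stats::anova(m, type = 3)
  irow <- grep(":", rownames(an))
  vc <- as.data.frame(lme4::VarCorr(m))
  per_phase <- do.call(rbind, lapply(levels(data$phase), function(ph) {
    sub <- data[data$phase == ph, ]
    combs <- utils::combn(levels(droplevels(sub$group)), 2)
    do.call(rbind, lapply(seq_len(ncol(combs)), function(i) {
      x <- sub$value[sub$group == combs[1, i]]
      y <- sub$value[sub$group == combs[2, i]]
      ht <- t.test(x, y)
      data.frame(phase = ph, group1 = combs[1, i], group2 = combs[2, i],
                 t = unname(ht$statistic), p_value = ht$p.value,
                 cohens_d = cohens_d(x, y), stringsAsFactors = FALSE)
    }))
  }))
  structure(list(
    fixed_effects = lme4::fixef(m),
    interaction = data.frame(F = an$`F value`[irow],
                             df1 = an$NumDF[irow], df2 = an$DenDF[irow],
                             p_value = an$`Pr(>F)`[irow]),
    random_intercept_var = vc$vcov[vc$grp == "subject_id"],
    residual_var = vc$vcov[vc$grp == "Residual"],
    singular = singular,
    per_phase = per_phase,
    n_subjects = length(unique(data$subject_id)),
    n_obs = nrow(data),
    model = m), class = "lmm_result")
}

#' @export
print.lmm_result <- function(x, ...) {
  cat("Group x phase linear mixed model (random intercept per subject)\n")
  cat(sprintf("  %d subjects, %d observations%s\n", x$n_subjects, x$n_obs,
              if (x$singular) "  [singular fit: random-intercept variance at boundary]" else ""))
  cat(sprintf("  interaction: F(%g, %.1f) = %.2f, p = %.4g\n",
              x$interaction$df1, x$interaction$df2, x$interaction$F,
              x$interaction$p_value))
  cat("  per-phase contrasts:\n")
  print(x$per_phase, row.names = FALSE, digits = 3)
  invisible(x)
}
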