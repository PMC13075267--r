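#' Longitudinal cohort analysis of orientation-variability metrics
#'
#' Per-child repeated measures at 3, 6, 9 and 12 months are analysed with
#' linear mixed-effects models (random intercept per child), and the
#' composite variability metric is related to standardized gross-motor raw
#' scores by rank correlation across children.
#'
#' @name cohort_stats
NULL

check_cohort_table <- function(table) {
  needed <- c("child_id", "cohort", "age_months", "pitch_csd", "roll_csd",
              "yaw_csd", "gen_var", "msel_gm", "walking")
  missing <- setdiff(needed, names(table))
  if (length(missing))
    stop("cohort table missing column(s): ", paste(missing, collapse = ", "))
  invisible(table)
}

lmm_fixed_table <- function(fit, ddf) {
  if (ddf == "satterthwaite") {
    sm <- stats::coef(summary(fit))
    data.frame(term = rownames(sm), estimate = sm[, "Estimate"],
               se = sm[, "Std. Error"], df = sm[, "df"],
               p = sm[, "Pr(>|t|)"], row.names = NULL)
  } else {
    sm <- stats::coef(summary(fit))
    z <- sm[, "Estimate"] / sm[, "Std. Error"]
    data.frame(term = rownames(sm), estimate = sm[, "Estimate"],
               se = sm[, "Std. Error"], df = NA_real_,
               p = 2 * stats::pnorm(-abs(z)), row.names = NULL)
  }
}

new_lmm_result <- function(fit, ddf, singular, n_obs, n_children,
                           age_center = NA_real_) {
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(
    list(
      fixed = lmm_fixed_table(fit, ddf),
      ranef_var = vc$vcov[vc$grp == "child_id"][1],
      resid_var = vc$vcov[vc$grp == "Residual"][1],
      n_obs = n_obs, n_children = n_children,
      singular = singular, p_method = ddf, model = fit,
      age_center = age_center
    ),
    class = "lmm_result"
  )
}

#' @export
print.lmm_result <- function(x, ...) {
  cat(sprintf("<lmm_result> %d obs, %d children; p-values: %s%s\n",
              x$n_obs, x$n_children, x$p_method,
              if (x$singular) " [singular fit: interaction dropped]" else ""))
  fx <- x$fixed
  fx$estimate <- signif(fx$estimate, 4)
  fx$se <- signif(fx$se, 3)
  fx$p <- signif(fx$p, 3)
  print(fx, row.names = FALSE)
  invisible(x)
}

#' Age trend of a variability metric (linear mixed-effects model)
#'
#' Fits `metric ~ cohort * age_months + (1 | child_id)` by REML: a cohort
#' (ILA vs. LLA, reference LLA) fixed effect, a linear age effect, their
#' interaction, and a random intercept per child for the repeated visits.
#' Age enters centered at the sample mean (term `age_c`), so the `age_c`
#' fixed effect is the age-related slope of the metric per month and the
#' cohort main effect is the level difference at the average study age; the
#' interaction term tests the slope difference between cohorts.  If the fit
#' is singular the model is refit without the interaction and flagged.
#'
#' @param table A cohort table (see [simulate_cohort()]): one row per
#'   child-visit.  Rows with a missing metric value are dropped.
#' @param metric Column name of the response, e.g. `"roll_csd"`.
#' @param ddf How p-values for fixed effects are computed: `"wald"`
#'   (normal approximation, default) or `"satterthwaite"` (adjusted
#'   denominator degrees of freedom).  The method used is recorded in the
#'   result.
#' @param interaction Include the cohort-by-age interaction (default TRUE).
#' @return An `lmm_result`: fixed-effect table (`term`, `estimate`, `se`,
#'   `p`), random-intercept and residual variances, sample sizes, and the
#'   underlying `lmerMod` fit.
#' @export
#' @examples
#' tab <- simulate_cohort(synth_cohort_config(seed = 3))
#' fit_age_lmm(tab, "roll_csd")
fit_age_lmm <- function(table, metric, ddf = c("wald", "satterthwaite"),
                        interaction = TRUE) {
  check_cohort_table(table)
  ddf <- match.arg(ddf)
  if (!metric %in% names(table)) stop("unknown metric: ", metric)
  df <- as.data.frame(table)
  df$.y <- df[[metric]]
  df <- df[!is.na(df$.y), , drop = FALSE]
  df$child_id <- factor(df$child_id)
  df$cohort <- factor(df$cohort, levels = intersect(c("LLA", "ILA"),
                                                    unique(df$cohort)))
  visits <- table(df$child_id)
  if (sum(visits >= 2) < 2)
    stop("need at least 2 children with at least 2 visits")
  df$age_c <- df$age_months - mean(df$age_months)
  two_cohorts <- nlevels(df$cohort) > 1
  form <- if (!two_cohorts) {
    .y ~ age_c + (1 | child_id)
  } else if (interaction) {
    .y ~ cohort * age_c + (1 | child_id)
  } else {
    .y ~ cohort + age_c + (1 | child_id)
  }
  fit <- lmerTest::lmer(form, data = df, REML = TRUE)
  singular <- lme4::isSingular(fit)
  if (singular && interaction && two_cohorts) {
    fit <- lmerTest::lmer(.y ~ cohort + age_c + (1 | child_id),
                          data = df, REML = TRUE)
  }
  new_lmm_result(fit, ddf, singular, nrow(df), nlevels(df$child_id),
                 age_center = mean(df$age_months))
}

#' Level and slope contrasts between the three angles
#'
#' Stacks the pitch, roll and yaw circular SDs in long format and fits
#' `csd ~ angle * age_c + (1 | child_id)` with pitch as the reference level
#' and age centered at the sample mean.  The `angleroll` / `angleyaw` terms
#' are the level differences averaged over the study ages (roll vs. pitch,
#' yaw vs. pitch, degrees) and the `angle:age_c` interactions are the
#' corresponding per-month slope differences.
#'
#' @inheritParams fit_age_lmm
#' @return An `lmm_result`.
#' @export
fit_angle_contrast_lmm <- function(table, ddf = c("wald", "satterthwaite")) {
  check_cohort_table(table)
  ddf <- match.arg(ddf)
  df <- as.data.frame(table)
  long <- do.call(rbind, lapply(c("pitch", "roll", "yaw"), function(a) {
    data.frame(child_id = df$child_id, age_months = df$age_months,
               angle = a, .y = df[[paste0(a, "_csd")]])
  }))
  long <- long[!is.na(long$.y), , drop = FALSE]
  long$angle <- factor(long$angle, levels = c("pitch", "roll", "yaw"))
  long$child_id <- factor(long$child_id)
  long$age_c <- long$age_months - mean(long$age_months)
  if (sum(table(long$child_id) >= 2) < 2)
    stop("need at least 2 children with at least 2 visits")
  fit <- lmerTest::lmer(.y ~ angle * age_c + (1 | child_id),
                        data = long, REML = TRUE)
  singular <- lme4::isSingular(fit)
  if (singular) {
    fit <- lmerTest::lmer(.y ~ angle + age_c + (1 | child_id),
                          data = long, REML = TRUE)
  }
  new_lmm_result(fit, ddf, singular, nrow(long), nlevels(long$child_id),
                 age_center = mean(long$age_months))
}

#' Correlate a variability metric with gross-motor scores across children
#'
#' Pairs each child's metric at `metric_age` with their gross-motor raw
#' score at `msel_age` and computes the correlation across children.  Only
#' concurrent or future scores are allowed (`msel_age >= metric_age`): the
#' question is whether present orientation variability tracks or predicts
#' motor outcomes.  Walking infants are excluded to keep global body
#' posture comparable across time points.  Spearman correlation (average
#' ranks for ties) by default.
#'
#' @param table A cohort table (one row per child-visit).
#' @param metric_age,msel_age Ages in months at which the metric and the
#'   score are taken; `msel_age >= metric_age`.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param metric Metric column, default `"gen_var"`.
#' @return List with `r`, `p`, `n` (children contributing both
#'   measurements), `method`, `metric_age`, `msel_age`.
#' @export
correlate_msel <- function(table, metric_age, msel_age,
                           method = c("spearman", "pearson"),
                           metric = "gen_var") {
  check_cohort_table(table)
  method <- match.arg(method)
  if (msel_age < metric_age)
    stop("`msel_age` must be >= `metric_age`: only concurrent and future ",
         "scores are paired with a metric")
  df <- as.data.frame(table)
  df <- df[!df$walking, , drop = FALSE]
  x <- df[df$age_months == metric_age, c("child_id", metric)]
  y <- df[df$age_months == msel_age, c("child_id", "msel_gm")]
  m <- merge(x, y, by = "child_id")
  m <- m[stats::complete.cases(m), , drop = FALSE]
  if (nrow(m) < 3)
    stop("fewer than 3 children have both measurements")
  ct <- suppressWarnings(
    stats::cor.test(m[[metric]], m$msel_gm, method = method, exact = FALSE))
  list(r = unname(ct$estimate), p = ct$p.value, n = nrow(m),
       method = method, metric_age = metric_age, msel_age = msel_age)
}
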