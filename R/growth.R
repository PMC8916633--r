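# Mixed-effects growth analysis on log scale.
#
# The model for each measurement variable is
#   log(y) = b0 + b1 Sex + b2 Adult + b3 Sex*Adult
#            + b4 PediatricAge + b5 Sex*PediatricAge + alpha_i + eps,
# with Sex coded male = 1, Adult a dummy for adult subjects, PediatricAge
# the age in years for children (0 for adults) and alpha_i a per-subject
# random intercept. Fits use maximum likelihood (not REML) so the
# likelihood-ratio test between nested fixed-effect structures is valid.

.growth_beta_names <- c("(Intercept)", "sex", "adult", "sex:adult",
                        "pediatric_age", "sex:pediatric_age")

growth_subset <- function(data, variable) {
  req <- c("subject_id", "sex", "adult", "pediatric_age", "value")
  miss <- setdiff(req, names(data))
  if (length(miss)) stop("growth data lacks columns: ",
                         paste(miss, collapse = ", "))
  if (!is.null(variable) && "variable" %in% names(data))
    data <- data[data$variable == variable, , drop = FALSE]
  if (any(data$value <= 0)) stop("values must be positive (log scale)")
  if (any(data$adult == 1 & data$pediatric_age != 0))
    stop("adult rows must have pediatric_age 0")
  data
}

#' Fit the random-intercept growth model for one variable
#'
#' @param data long-format data.frame with columns `subject_id`, `sex`
#'   (male = 1), `adult` (0/1), `pediatric_age` (years; 0 for adults),
#'   `value` (> 0) and optionally `variable`.
#' @param variable variable name to subset on (if a `variable` column is
#'   present).
#' @return A `growth_model_fit`: list with `beta` (b0..b5), `vcov` (6 x 6),
#'   `sigma_subject`, `sigma_resid`, `loglik` (ML), `n_obs`, `n_subjects`,
#'   and the underlying `lme4` fit.
#' @export
fit_growth_model <- function(data, variable = NULL) {
  data <- growth_subset(data, variable)
  if (min(table(factor(data$sex, levels = 0:1))) == 0)
    stop("need observations from both sexes")
  if (length(unique(data$adult)) < 2)
    stop("need both pediatric and adult observations")
  data$log_value <- log(data$value)
  fit <- lme4::lmer(
    log_value ~ sex + adult + sex:adult + pediatric_age +
      sex:pediatric_age + (1 | subject_id),
    data = data, REML = FALSE,
    control = lme4::lmerControl(check.conv.singular = "ignore"))
  fe <- lme4::fixef(fit)
  ord <- match(.growth_beta_names, names(fe))
  if (any(is.na(ord))) stop("unexpected fixed-effect structure")
  beta <- fe[ord]
  names(beta) <- paste0("b", 0:5)
  V <- as.matrix(stats::vcov(fit))[ord, ord]
  dimnames(V) <- list(names(beta), names(beta))
  vc <- lme4::VarCorr(fit)
  structure(list(beta = beta, vcov = V,
                 sigma_subject = attr(vc$subject_id, "stddev")[[1]],
                 sigma_resid = stats::sigma(fit),
                 loglik = as.numeric(stats::logLik(fit)),
                 n_obs = nrow(data),
                 n_subjects = length(unique(data$subject_id)),
                 scale = "log", variable = variable, fit = fit),
            class = "growth_model_fit")
}

#' @export
print.growth_model_fit <- function(x, ...) {
  cat(sprintf("<growth_model_fit>%s %d obs / %d subjects (log scale, ML)\n",
              if (is.null(x$variable)) "" else paste0(" ", x$variable),
              x$n_obs, x$n_subjects))
  print(round(x$beta, 4))
  cat(sprintf("  sigma_subject %.4f, sigma_resid %.4f, logLik %.2f\n",
              x$sigma_subject, x$sigma_resid, x$loglik))
  invisible(x)
}

#' Single-pass outlier exclusion by standardized residuals
#'
#' Fits the growth model, removes observations whose conditional residuals
#' exceed `cutoff` residual standard deviations in absolute value (2.576,
#' the 0.995 standard-normal quantile, by default), and refits once on the
#' remainder.
#'
#' @inheritParams fit_growth_model
#' @param cutoff exclusion threshold in residual SDs.
#' @return list with `data` (filtered), `excluded` (row indices of the
#'   input), and `fit` (refit on the filtered data).
#' @export
exclude_outliers <- function(data, variable = NULL, cutoff = 2.576) {
  data <- growth_subset(data, variable)
  fit0 <- fit_growth_model(data)
  std <- stats::residuals(fit0$fit) / fit0$sigma_resid
  excl <- unname(which(abs(std) > cutoff))
  if (length(excl) == nrow(data))
    stop("all rows excluded; pathological fit")
  kept <- if (length(excl)) data[-excl, , drop = FALSE] else data
  list(data = kept, excluded = excl, fit = fit_growth_model(kept))
}

#' Likelihood-ratio test for the age effect
#'
#' Compares the full model against the nested model with both pediatric-age
#' terms removed (`b4 = b5 = 0`), both fitted by maximum likelihood. The
#' statistic is referred to chi-squared with 2 degrees of freedom.
#'
#' @inheritParams fit_growth_model
#' @return A `growth_test`: list with `statistic`, `df`, `p_value`,
#'   `label = "age_LRT"`.
#' @export
lrt_age_effect <- function(data, variable = NULL) {
  data <- growth_subset(data, variable)
  data$log_value <- log(data$value)
  full <- fit_growth_model(data)
  reduced <- lme4::lmer(
    log_value ~ sex + adult + sex:adult + (1 | subject_id),
    data = data, REML = FALSE,
    control = lme4::lmerControl(check.conv.singular = "ignore"))
  stat <- max(0, 2 * (full$loglik - as.numeric(stats::logLik(reduced))))
  structure(list(statistic = stat, df = 2,
                 p_value = stats::pchisq(stat, df = 2, lower.tail = FALSE),
                 estimate = NA_real_, std_error = NA_real_,
                 label = "age_LRT"),
            class = "growth_test")
}

#' Wald test of the sex contrast at a time point
#'
#' Tests the male-female difference of the fixed-effect linear predictor at
#' age <1 year (`b1`), age 5 years (`b1 + 5 b5`) or adulthood (`b1 + b3`),
#' using the normal reference for the Wald statistic.
#'
#' @param fit a `growth_model_fit`.
#' @param timepoint `"age0"`, `"age5"` or `"adult"`.
#' @param age evaluation age for the `"age5"` contrast (default 5 years).
#' @return A `growth_test` with `estimate`, `std_error`, `statistic`,
#'   `p_value`.
#' @export
wald_sex_contrast <- function(fit, timepoint = c("age0", "age5", "adult"),
                              age = 5) {
  stopifnot(inherits(fit, "growth_model_fit"))
  timepoint <- match.arg(timepoint)
  cvec <- switch(timepoint,
                 age0 = c(0, 1, 0, 0, 0, 0),
                 age5 = c(0, 1, 0, 0, 0, age),
                 adult = c(0, 1, 0, 1, 0, 0))
  est <- sum(cvec * fit$beta)
  se <- sqrt(drop(t(cvec) %*% fit$vcov %*% cvec))
  if (!is.finite(se) || se <= 0) stop("singular covariance for contrast")
  z <- est / se
  structure(list(statistic = z, df = 1,
                 p_value = 2 * stats::pnorm(-abs(z)),
                 estimate = est, std_error = se,
                 label = paste0("sex_", timepoint)),
            class = "growth_test")
}

#' @export
print.growth_test <- function(x, ...) {
  cat(sprintf("<growth_test> %s: statistic %.3f (df %s), p = %.4g\n",
              x$label, x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Percent of adult size attained at a pediatric age
#'
#' `100 * exp(eta_ped(age)) / exp(eta_adult)` from the fixed-effect point
#' estimates of a log-scale fit (no retransformation correction), i.e. the
#' pediatric modeled mean as a percentage of the adult modeled mean for the
#' same sex.
#'
#' @param fit a `growth_model_fit` (log scale).
#' @param sex 1 = male, 0 = female.
#' @param age pediatric age, years (default 5).
#' @return percent (100 = adult size).
#' @export
percent_growth <- function(fit, sex, age = 5) {
  stopifnot(inherits(fit, "growth_model_fit"), fit$scale == "log")
  b <- fit$beta
  eta_ped <- b[1] + b[2] * sex + b[5] * age + b[6] * sex * age
  eta_adult <- b[1] + b[2] * sex + b[3] + b[4] * sex
  unname(100 * exp(eta_ped - eta_adult))
}

#' Significance tier markers
#'
#' Asterisk convention: `*` p < .05, `**` p < .01, `***` p < .001, `****`
#' below the Bonferroni-corrected level (default .0004).
#'
#' @param p p-value(s).
#' @param bonferroni Bonferroni-corrected level.
#' @return character vector of markers.
#' @export
significance_marker <- function(p, bonferroni = 0.0004) {
  ifelse(p < bonferroni, "****",
         ifelse(p < 0.001, "***",
                ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))))
}

#' Per-sex, per-age-group summary table
#'
#' Mean (SD) per sex and age group. Pediatric ages map to groups `<1`, `1`,
#' `2`, `3`, `4` by completed year; adults form their own group.
#'
#' @param data growth data.frame (see [fit_growth_model()]); may contain
#'   several variables.
#' @return data.frame (variable, sex, group, n, mean, sd).
#' @export
age_group_summary <- function(data) {
  data <- growth_subset(data, NULL)
  grp <- character(nrow(data))
  adult <- data$adult == 1
  grp[adult] <- "adult"
  age <- data$pediatric_age[!adult]
  if (any(age >= 5))
    stop("unassignable age: pediatric age must be below 5 years ",
         "(adults are their own group)")
  grp[!adult] <- ifelse(age < 1, "<1", as.character(floor(age)))
  if (!"variable" %in% names(data)) data$variable <- "value"
  agg <- stats::aggregate(
    data$value,
    by = list(variable = data$variable, sex = data$sex, group = grp),
    FUN = function(v) c(n = length(v), mean = mean(v),
                        sd = stats::sd(v)))
  out <- data.frame(variable = agg$variable, sex = agg$sex,
                    group = agg$group, n = agg$x[, "n"],
                    mean = agg$x[, "mean"], sd = agg$x[, "sd"],
                    stringsAsFactors = FALSE)
  lev <- c("<1", "1", "2", "3", "4", "adult")
  out[order(out$variable, match(out$group, lev), -out$sex), ]
}

#' Full growth analysis for every variable in a dataset
#'
#' For each variable: single-pass outlier exclusion, refit, age-effect LRT,
#' Wald sex contrasts at age <1, age 5 and adulthood, and percent growth at
#' age 5 for each sex.
#'
#' @param data long-format growth data with a `variable` column.
#' @param cutoff outlier cutoff in residual SDs.
#' @param bonferroni Bonferroni-corrected significance level.
#' @return data.frame, one row per variable.
#' @export
growth_analysis <- function(data, cutoff = 2.576, bonferroni = 0.0004) {
  vars <- unique(data$variable)
  rows <- lapply(vars, function(v) {
    scr <- exclude_outliers(data, v, cutoff = cutoff)
    fit <- scr$fit
    lrt <- lrt_age_effect(scr$data)
    w0 <- wald_sex_contrast(fit, "age0")
    w5 <- wald_sex_contrast(fit, "age5")
    wa <- wald_sex_contrast(fit, "adult")
    data.frame(variable = v, n_excluded = length(scr$excluded),
               lrt_p = lrt$p_value,
               lrt_marker = significance_marker(lrt$p_value, bonferroni),
               wald_age0_p = w0$p_value, wald_age5_p = w5$p_value,
               wald_adult_p = wa$p_value,
               pct_growth_male = percent_growth(fit, sex = 1),
               pct_growth_female = percent_growth(fit, sex = 0),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
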