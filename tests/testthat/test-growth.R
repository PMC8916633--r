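sim200 <- function() fixture("growth200", function()
  simulate_growth_data(n_subjects = 200, scans_per_subject = c(1, 2),
                       seed = 42))

test_that("the mixed model recovers simulated coefficients", {
  d <- sim200()
  fit <- fit_growth_model(d)
  se <- sqrt(diag(fit$vcov))
  expect_true(all(abs(fit$beta - attr(d, "betas")) < 3 * se))
  expect_identical(fit$scale, "log")
  expect_true(isSymmetric(fit$vcov, tol = 1e-10))
  expect_true(all(eigen(fit$vcov, only.values = TRUE)$values > -1e-12))
})

test_that("a zero subject variance fits at the boundary", {
  d <- simulate_growth_data(n_subjects = 120, scans_per_subject = 2,
                            sigma_subject = 0, sigma_resid = 0.2,
                            seed = 13)
  fit <- fit_growth_model(d)
  expect_lt(fit$sigma_subject, 0.05)
})

test_that("noiseless data are interpolated exactly", {
  d <- simulate_growth_data(n_subjects = 50, scans_per_subject = 2,
                            sigma_subject = 0, sigma_resid = 0, seed = 7)
  fit <- suppressWarnings(suppressMessages(fit_growth_model(d)))
  expect_equal(unname(fit$beta), attr(d, "betas"), tolerance = 1e-8)
})

test_that("degenerate growth designs are refused", {
  d <- sim200()
  expect_error(fit_growth_model(d[d$sex == 1, ]), "both sexes")
  expect_error(fit_growth_model(d[d$adult == 0, ]), "adult")
  bad <- d; bad$pediatric_age[bad$adult == 1][1] <- 2
  expect_error(fit_growth_model(bad), "pediatric_age 0")
})

test_that("outlier exclusion removes exactly the planted observation", {
  d <- simulate_growth_data(n_subjects = 150, scans_per_subject = c(1, 2),
                            seed = 19)
  clean <- exclude_outliers(d)
  expect_identical(length(clean$excluded), 0L)
  expect_identical(nrow(clean$data), nrow(d))

  d2 <- d
  fit0 <- fit_growth_model(d)
  # perturb a scan from a single-scan subject by ten residual SDs
  singles <- names(which(table(d2$subject_id) == 1))
  idx <- which(d2$subject_id == singles[10])
  d2$value[idx] <- d2$value[idx] * exp(10 * fit0$sigma_resid)
  scr <- exclude_outliers(d2)
  expect_identical(scr$excluded, idx)
  expect_identical(nrow(scr$data), nrow(d) - 1L)
})

test_that("the exclusion constant is the rounded 0.995 normal quantile", {
  expect_identical(round(stats::qnorm(0.995), 3), 2.576)
  expect_identical(formals(exclude_outliers)$cutoff, 2.576)
})

test_that("the age-effect LRT is nonnegative and detects strong growth", {
  d <- sim200()
  lrt <- lrt_age_effect(d)
  expect_gte(lrt$statistic, 0)
  expect_identical(lrt$df, 2)
  expect_lt(lrt$p_value, 0.001)  # simulated with a strong age slope
  # power at a strong slope across replicates
  hits <- vapply(1:10, function(i) {
    di <- simulate_growth_data(n_subjects = 60,
                               scans_per_subject = c(1, 2),
                               seed = 100 + i)
    lrt_age_effect(di)$p_value < 0.001
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("Wald contrasts encode the sex difference at each time point", {
  d <- sim200()
  fit <- fit_growth_model(d)
  w0 <- wald_sex_contrast(fit, "age0")
  w5 <- wald_sex_contrast(fit, "age5")
  wa <- wald_sex_contrast(fit, "adult")
  expect_equal(w0$estimate, unname(fit$beta[2]))
  expect_equal(w5$estimate, unname(fit$beta[2] + 5 * fit$beta[6]))
  expect_equal(wa$estimate, unname(fit$beta[2] + fit$beta[4]))
  # standard errors against the brute-force quadratic form
  V <- fit$vcov
  c5 <- c(0, 1, 0, 0, 0, 5)
  se_brute <- sqrt(sum(outer(c5, c5) * V))
  expect_equal(w5$std_error, se_brute, tolerance = 1e-12)
  expect_true(all(c(w0$p_value, w5$p_value, wa$p_value) >= 0 &
                    c(w0$p_value, w5$p_value, wa$p_value) <= 1))

  # a fit with b3 = 0 exactly: adult contrast reduces to b1
  fit0 <- fit
  fit0$beta[4] <- 0
  expect_equal(wald_sex_contrast(fit0, "adult")$estimate,
               unname(fit0$beta[2]))
})

test_that("percent growth follows the modeled-means ratio", {
  d <- sim200()
  fit <- fit_growth_model(d)
  # no adult or age terms: pediatric equals adult predictor
  flat <- fit
  flat$beta <- c(b0 = 1, b1 = 0.3, b2 = 0, b3 = 0, b4 = 0, b5 = 0)
  expect_equal(percent_growth(flat, 1), 100)
  expect_equal(percent_growth(flat, 0), 100)
  # hand computation: exp(1.25) / exp(1.5) = exp(-0.25)
  hand <- fit
  hand$beta <- c(b0 = 1, b1 = 0, b2 = 0.5, b3 = 0, b4 = 0.05, b5 = 0)
  expect_equal(percent_growth(hand, 0), 100 * exp(-0.25),
               tolerance = 1e-12)
  expect_equal(round(percent_growth(hand, 0), 2), 77.88)
  # strictly increasing in the age slope
  pg <- vapply(seq(0, 0.2, by = 0.05), function(b4) {
    f <- hand; f$beta[5] <- b4
    percent_growth(f, 0)
  }, numeric(1))
  expect_true(all(diff(pg) > 0))
  # invariant under multiplicative rescaling of the raw variable
  d2 <- d; d2$value <- d2$value * 1000
  fit2 <- fit_growth_model(d2)
  expect_equal(percent_growth(fit2, 1), percent_growth(fit, 1),
               tolerance = 1e-6)
})

test_that("significance markers follow the four-tier convention", {
  expect_identical(significance_marker(c(0.2, 0.04, 0.009, 0.0009, 0.0003)),
                   c("", "*", "**", "***", "****"))
})

test_that("age-group summaries use the study's group edges", {
  d <- data.frame(subject_id = sprintf("S%d", 1:8),
                  sex = c(1, 1, 1, 1, 0, 0, 0, 0),
                  adult = c(0, 0, 0, 0, 0, 0, 1, 1),
                  pediatric_age = c(0.99, 1.0, 2.5, 3.2, 0.5, 4.9, 0, 0),
                  variable = "v",
                  value = c(4, 6, 5, 5, 2, 3, 9, 11))
  tab <- age_group_summary(d)
  g_m <- tab[tab$sex == 1, ]
  expect_setequal(g_m$group, c("<1", "1", "2", "3"))
  # 0.99 years is still group "<1"; 1.0 years starts group "1"
  expect_equal(tab$mean[tab$group == "<1" & tab$sex == 1], 4)
  expect_equal(tab$mean[tab$group == "1" & tab$sex == 1], 6)
  adult <- tab[tab$group == "adult", ]
  expect_equal(adult$mean, 10)
  expect_equal(adult$sd, sd(c(9, 11)), tolerance = 1e-12)

  toofar <- d; toofar$pediatric_age[1] <- 5.5
  expect_error(age_group_summary(toofar), "unassignable age")

  const <- d; const$value <- 7
  tc <- age_group_summary(const)
  expect_true(all(tc$mean == 7))
  expect_true(all(tc$sd == 0 | is.na(tc$sd)))
})

test_that("two values 4 and 6 summarize as mean 5, sd 1.414", {
  d <- data.frame(subject_id = c("a", "b"), sex = c(1, 1), adult = c(0, 0),
                  pediatric_age = c(2.1, 2.9), variable = "v",
                  value = c(4, 6))
  tab <- age_group_summary(d)
  expect_equal(tab$mean, 5)
  expect_equal(round(tab$sd, 3), 1.414)
})

test_that("the per-variable analysis table mirrors the reporting layout", {
  d1 <- sim200()
  d2 <- simulate_growth_data(n_subjects = 80, scans_per_subject = c(1, 2),
                             seed = 77, variable = "GlottisArea")
  tab <- growth_analysis(rbind(d1, d2))
  expect_identical(nrow(tab), 2L)
  expect_setequal(tab$variable, c("PharynxVolume", "GlottisArea"))
  expect_true(all(c("lrt_p", "wald_age0_p", "wald_age5_p", "wald_adult_p",
                    "pct_growth_male", "pct_growth_female")
                  %in% names(tab)))
  expect_true(all(tab$lrt_p >= 0 & tab$lrt_p <= 1))
})
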