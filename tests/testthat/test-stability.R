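test_that("snapshot counts complete the grid with zeros", {
  snaps <- data.frame(day = c(1, 1, 2), tick_minute = c(0, 0, 55),
                      id = c("a", "b", "a"))
  counts <- snapshot_counts(snaps, n_days = 2, tick = 5)
  expect_identical(nrow(counts), 2L * 288L)
  expect_identical(counts$count[counts$day == 1 & counts$tick_minute == 0], 2L)
  expect_identical(counts$count[counts$day == 2 & counts$tick_minute == 55], 1L)
  expect_identical(sum(counts$count), 3L)
})

test_that("hourly proportions: constant counts give c/n; >1 is retained", {
  counts <- expand.grid(day = 1:3, tick_minute = seq(0, 1435, 5))
  counts$count <- 9
  hp <- hourly_proportions(counts, c(`1` = 12, `2` = 12, `3` = 6))
  expect_identical(nrow(hp), 3L * 24L)
  expect_true(all(hp$proportion[hp$day %in% 1:2] == 9 / 12))
  expect_true(all(hp$proportion[hp$day == 3] == 1.5))  # overdetection kept
  expect_true(all(hp$complete))
})

test_that("zero AMS counts are excluded with a warning; missing ticks flagged", {
  counts <- expand.grid(day = 1:2, tick_minute = seq(0, 1435, 5))
  counts$count <- 5
  expect_warning(hp <- hourly_proportions(counts, c(`1` = 10, `2` = 0)),
                 "zero AMS")
  expect_identical(sort(unique(hp$day)), 1L)

  holey <- counts[!(counts$day == 1 & counts$tick_minute == 30), ]
  expect_warning(hp2 <- hourly_proportions(holey, c(`1` = 10, `2` = 10)),
                 "missing ticks")
  expect_false(hp2$complete[hp2$day == 1 & hp2$hour == 0])
  expect_error(hourly_proportions(counts, c(`1` = 10)), "missing AMS")
})

test_that("ams_daily_counts counts distinct visiting cows per day", {
  visits <- data.frame(day = c(1, 1, 1, 2), visit_minute = c(5, 10, 700, 60),
                       cow_id = c("a", "a", "b", "a"))
  expect_identical(ams_daily_counts(visits, 2), c(`1` = 2L, `2` = 1L))
})

test_that("identical proportions give equal means and zero variance components", {
  rows <- expand.grid(day = 1:4, hour = 0:23)
  rows$proportion <- 0.8
  fit <- fit_hour_day_model(rows)
  expect_true(all(fit$hour_means == 0.8))
  expect_identical(fit$var_day, 0)
  expect_identical(fit$var_resid, 0)
  expect_identical(fit$df_resid, 23L * 3L)
})

test_that("unbalanced layouts are an explicit error", {
  rows <- expand.grid(day = 1:3, hour = 0:5)
  rows$proportion <- runif(nrow(rows))
  expect_error(fit_hour_day_model(rows[-1, ]), "unbalanced")
  expect_error(fit_hour_day_model(rbind(rows, rows[1, ])), "unbalanced")
  expect_error(fit_hour_day_model(rows[rows$day == 1, ]), ">= 2 days")
})

test_that("closed-form estimates match the REML optimization oracle", {
  skip_if_not_installed("lme4")
  skip_if_not_installed("emmeans")
  set.seed(314)
  for (rep in 1:3) {
    rows <- balanced_rows(n_days = 3, hours = 0:3,
                          hour_effects = c(0, 0.05, -0.04, 0.08),
                          sd_day = 0.08, sd_resid = 0.02)
    fit <- fit_hour_day_model(rows)

    d <- transform(rows, day = factor(day), hour = factor(hour))
    lm4 <- lme4::lmer(proportion ~ 0 + hour + (1 | day), data = d,
                      REML = TRUE,
                      control = lme4::lmerControl(
                        optCtrl = list(xtol_abs = 1e-12, ftol_abs = 1e-12)))
    vc <- as.data.frame(lme4::VarCorr(lm4))
    expect_equal(fit$var_day, vc$vcov[vc$grp == "day"], tolerance = 1e-6)
    expect_equal(fit$var_resid, vc$vcov[vc$grp == "Residual"],
                 tolerance = 1e-6)
    emm <- summary(emmeans::emmeans(lm4, "hour"))
    expect_equal(unname(fit$hour_means), emm$emmean, tolerance = 1e-6)
    expect_equal(rep(fit$se_mean, 4), emm$SE, tolerance = 1e-6)
  }
})

test_that("Tukey p-values agree with the emmeans oracle and dominate the t-test", {
  skip_if_not_installed("lme4")
  skip_if_not_installed("emmeans")
  set.seed(271)
  rows <- balanced_rows(n_days = 6, hours = 0:5,
                        hour_effects = c(0, 0.02, 0, -0.03, 0.05, 0),
                        sd_day = 0.05, sd_resid = 0.03)
  fit <- fit_hour_day_model(rows)
  pw <- tukey_pairwise(fit, alpha = 0.01)
  expect_identical(nrow(pw), 15L)

  d <- transform(rows, day = factor(day), hour = factor(hour))
  lm4 <- lme4::lmer(proportion ~ 0 + hour + (1 | day), data = d)
  emm_pw <- summary(emmeans::emmeans(lm4, pairwise ~ hour,
                                     adjust = "tukey")$contrasts)
  # emmeans orders contrasts hour_a - hour_b over the same upper triangle
  expect_equal(pw$adjusted_p, emm_pw$p.value, tolerance = 1e-5)
  expect_equal(abs(pw$difference), abs(emm_pw$estimate), tolerance = 1e-8)

  # adjusted p never below the unadjusted two-sided t-test p
  p_t <- 2 * stats::pt(-abs(pw$difference) / fit$se_contrast, fit$df_resid)
  expect_true(all(pw$adjusted_p >= p_t - 1e-12))
})

test_that("a 10-residual-SE separation is significant; equal means are not", {
  rows <- expand.grid(day = 1:5, hour = 0:7)
  rows$proportion <- 0.85
  set.seed(99)
  rows$proportion <- rows$proportion + rnorm(nrow(rows), 0, 0.01)
  fit0 <- fit_hour_day_model(rows)
  sep <- 10 * sqrt(2 * fit0$var_resid / fit0$n_days)
  rows$proportion[rows$hour == 7] <- rows$proportion[rows$hour == 7] + sep
  fit <- fit_hour_day_model(rows)
  pw <- tukey_pairwise(fit, alpha = 0.01)
  big <- pw[pw$hour_a == 7 | pw$hour_b == 7, ]
  expect_true(all(big$significant))

  flat <- expand.grid(day = 1:5, hour = 0:7)
  flat$proportion <- 0.85
  pw_flat <- tukey_pairwise(fit_hour_day_model(flat))
  expect_true(all(pw_flat$adjusted_p == 1))
  expect_false(any(pw_flat$significant))
})

test_that("variance components are recovered over repeated simulations", {
  set.seed(515)
  sd_day <- 0.03
  sd_resid <- 0.015
  n_rep <- 200
  est <- replicate(n_rep, {
    rows <- balanced_rows(31, 0:23, hour_effects = seq(0, 0.23, by = 0.01),
                          sd_day = sd_day, sd_resid = sd_resid)
    fit <- fit_hour_day_model(rows)
    c(fit$var_day, fit$var_resid)
  })
  mc_se <- apply(est, 1, stats::sd) / sqrt(n_rep)
  expect_lt(abs(mean(est[1, ]) - sd_day^2), 3 * mc_se[1])
  expect_lt(abs(mean(est[2, ]) - sd_resid^2), 3 * mc_se[2])
})

test_that("the mean of hour means equals the grand mean (balanced design)", {
  set.seed(12)
  rows <- balanced_rows(5, 0:23, hour_effects = rnorm(24, 0, 0.05),
                        sd_day = 0.04, sd_resid = 0.02)
  fit <- fit_hour_day_model(rows)
  expect_equal(mean(fit$hour_means), mean(rows$proportion))
  expect_equal(mean(fit$hour_means), fit$grand_mean)
})
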