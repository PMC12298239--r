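test_that("toy cohort sums of squares match the frozen independent decomposition", {
  # Expected values frozen from an independent Error-strata decomposition
  # (aov with subject/(condition*limb) strata) of the same integer table;
  # exact rational values.
  fit <- rm_anova(toy_cohort(), dv = "L", band = "2_5")
  tab <- tidy(fit)

  expect_equal(tab$ss_effect, c(508 / 9, 2 / 9, 4 / 9), tolerance = 1e-10)
  expect_equal(tab$ss_error, c(8 / 9, 1 / 9, 38 / 9), tolerance = 1e-10)
  expect_identical(tab$df1, c(2L, 1L, 2L))
  expect_identical(tab$df2, c(4L, 2L, 4L))
  expect_equal(tab$statistic, c(127, 4, 4 / 19), tolerance = 1e-10)
  expect_equal(tab$partial_eta_sq, c(508 / 516, 2 / 3, 4 / 42), tolerance = 1e-10)
  expect_equal(fit$ss_subjects, 97 / 9, tolerance = 1e-10)

  # full within+between decomposition accounts for the total sum of squares
  vals <- toy_cohort()$L
  expect_equal(fit$ss_total, sum((vals - mean(vals))^2), tolerance = 1e-9)
})

test_that("rm_anova agrees with the aov Error-strata oracle on random cohorts", {
  withr::local_seed(41)
  for (i in 1:3) {
    tab <- simulate_cohort(cohort_design(n_subjects = 8L, seed = 100 + i))
    fit <- tidy(rm_anova(tab, dv = "L", band = "9_14"))
    d <- dplyr::filter(tab, band == "9_14")
    d$subject_id <- factor(d$subject_id)
    d$condition <- factor(d$condition)
    d$limb <- factor(d$limb)
    o <- summary(stats::aov(L ~ condition * limb + Error(subject_id / (condition * limb)),
                            data = d))
    expect_equal(fit$statistic[1], o[["Error: subject_id:condition"]][[1]]["condition", "F value"],
                 tolerance = 1e-8)
    expect_equal(fit$statistic[2], o[["Error: subject_id:limb"]][[1]]["limb", "F value"],
                 tolerance = 1e-8)
    expect_equal(fit$statistic[3],
                 o[["Error: subject_id:condition:limb"]][[1]]["condition:limb", "F value"],
                 tolerance = 1e-8)
  }
})

test_that("a dv constant across conditions yields zero condition F and eta squared", {
  tab <- toy_cohort()
  # make every subject's six cells equal within subject (varies between subjects)
  tab$L <- rep(c(1, 2, 3), each = 6)
  fit <- tidy(rm_anova(tab, dv = "L", band = "2_5"))
  expect_equal(fit$ss_effect, rep(0, 3), tolerance = 1e-12)
  expect_equal(fit$partial_eta_sq, rep(0, 3), tolerance = 1e-12)
})

test_that("incomplete or duplicated designs are rejected with cell listings", {
  tab <- toy_cohort()
  expect_error(rm_anova(tab[-1, ], dv = "L", band = "2_5"),
               "missing cell.*A/rest/left")
  expect_error(rm_anova(dplyr::bind_rows(tab, tab[1, ]), dv = "L", band = "2_5"),
               "Duplicate cell")
  expect_error(rm_anova(tab, dv = "L", band = "9_14"), "No rows")
})

test_that("Greenhouse-Geisser correction rescales the reference dfs, not the table dfs", {
  withr::local_seed(42)
  tab <- simulate_cohort(cohort_design(seed = 77))
  plain <- tidy(rm_anova(tab, dv = "F", band = "2_5"))
  gg <- tidy(rm_anova(tab, dv = "F", band = "2_5", correction = "greenhouse-geisser"))
  expect_identical(gg$df1, plain$df1)
  expect_identical(gg$statistic, plain$statistic)
  expect_true(all(gg$gg_epsilon > 0 & gg$gg_epsilon <= 1 + 1e-9))
  # the two-level side factor has a single contrast: epsilon is exactly 1
  expect_equal(gg$gg_epsilon[gg$effect == "side"], 1, tolerance = 1e-9)
  expect_equal(gg$p_value,
               pf(gg$statistic, gg$gg_epsilon * gg$df1, gg$gg_epsilon * gg$df2,
                  lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("Tukey contrasts flag a hugely shifted condition and stay monotone", {
  tab <- toy_cohort()
  # per-subject/limb baseline, identical for rest and endurance; sprint
  # shifted by ~10 with a subject-varying wobble feeding the error term
  jit <- as.numeric(factor(paste(tab$subject_id, tab$limb))) / 10
  wob <- c(A = -0.1, B = 0, C = 0.1)[tab$subject_id]
  tab$L <- jit + ifelse(tab$condition == "sprint", 10 + wob, 0)
  ph <- tukey_posthoc(tab, dv = "L", band = "2_5")
  expect_lt(ph$p_adj[ph$contrast == "sprint - rest"], 0.001)
  expect_lt(ph$p_adj[ph$contrast == "sprint - endurance"], 0.001)
  expect_gt(ph$p_adj[ph$contrast == "endurance - rest"], 0.9)
  expect_true(all(ph$p_adj >= ph$p_unadj - 1e-12))

  # equal condition means (Latin-square subject wobble) -> all adjusted p = 1
  square <- matrix(c(0.1, -0.1, 0, -0.1, 0, 0.1, 0, 0.1, -0.1), nrow = 3,
                   dimnames = list(c("A", "B", "C"), c("rest", "endurance", "sprint")))
  tab$L <- square[cbind(tab$subject_id, tab$condition)]
  ph0 <- tukey_posthoc(tab, dv = "L", band = "2_5")
  expect_true(all(ph0$p_adj > 0.95))
})

test_that("summary t-test reproduces printed cohort demographics to 2 dp", {
  res <- demographic_tests(speed_skater_demographics())
  by_var <- split(res, res$variable)
  expect_equal(round(by_var$age$statistic, 2), -1.13)
  expect_equal(round(by_var$age$cohen_d, 2), 0.37)
  expect_equal(round(by_var$height$statistic, 2), -0.92)
  expect_equal(round(by_var$height$cohen_d, 2), 0.30)
  expect_equal(round(by_var$body_mass$statistic, 2), -2.07)
  expect_equal(round(by_var$body_mass$p_value, 3), 0.045)
  expect_equal(round(by_var$body_mass$cohen_d, 2), 0.67)
})

test_that("summary t-test is antisymmetric under group swap; identical groups give t = 0", {
  g1 <- summary_group(10, 2, 12)
  g2 <- summary_group(11.5, 3, 15)
  a <- t_from_summary(g1, g2)
  b <- t_from_summary(g2, g1)
  expect_equal(a$statistic, -b$statistic)
  expect_equal(a$p_value, b$p_value)
  expect_identical(a$df, b$df)

  same <- t_from_summary(g1, g1)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_equal(cohen_d_from_summary(g1, g1), 0)
  expect_error(t_from_summary(summary_group(1, 0, 5), summary_group(2, 0, 5)),
               "Degenerate")
  expect_error(cohen_d_from_summary(summary_group(1, 0, 5), summary_group(2, 0, 5)),
               "Degenerate")
})

test_that("normality check behaves at boundary sizes and on skewed data", {
  withr::local_seed(43)
  expect_error(check_normality(c(1, 2)), "3 <= n")
  expect_error(check_normality(rep(1, 10)), "Degenerate")

  res <- check_normality(rnorm(19))
  expect_true(res$statistic > 0 && res$statistic <= 1)

  # strongly lognormal data at n = 50 should essentially always fail
  fails <- replicate(40, !check_normality(exp(rnorm(50)))$pass)
  expect_gt(mean(fails), 0.95)
})

test_that("Levene check: identical groups give F = 0, unequal spread is detected", {
  g <- list(c(1, 2, 3, 4), c(1, 2, 3, 4))
  res <- check_homogeneity(g)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  expect_error(check_homogeneity(list(c(1, 2, 3))), "at least two")
  expect_error(check_homogeneity(list(rep(2, 5), rep(2, 6))), "Degenerate")

  withr::local_seed(44)
  hits <- replicate(50, {
    check_homogeneity(list(rnorm(19, sd = 1), rnorm(19, sd = sqrt(10))))$p_value < 0.05
  })
  expect_gt(mean(hits), 0.9)
})

test_that("effect-size labels switch exactly at the conventional thresholds", {
  expect_identical(interpret_eta_squared(c(0.009, 0.01, 0.059, 0.06, 0.139, 0.14)),
                   c("negligible", "small", "small", "medium", "medium", "large"))
  expect_identical(interpret_cohen_d(c(0.19, 0.2, 0.49, 0.5, 0.79, 0.8)),
                   c("negligible", "small", "small", "medium", "medium", "large"))
})
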