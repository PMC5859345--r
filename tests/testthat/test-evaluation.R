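test_that("dose classification applies the open 20% band with boundary to over/under", {
  expect_equal(classify_dose(44.5, 40), "ideal") # 11.3% deviation
  expect_equal(classify_dose(48.1, 40), "overestimation") # 20.25%
  expect_equal(classify_dose(48, 40), "overestimation") # exactly 20%
  expect_equal(classify_dose(32, 40), "underestimation") # exactly -20%
  expect_equal(classify_dose(42, 42), "ideal")
  expect_error(classify_dose(40, 0), class = "warfpgx_record_error")
})

test_that("MAE and its standard error follow the absolute-error sample", {
  m1 <- mean_absolute_error(c(40, 50), c(45, 45))
  expect_equal(m1$mae, 5)
  expect_equal(m1$mae_se, 0)
  m2 <- mean_absolute_error(c(40, 55), c(45, 45))
  expect_equal(m2$mae, 7.5)
  expect_equal(m2$mae_se, 2.5) # sd({5,10})/sqrt(2) = sqrt(12.5)/sqrt(2)
  expect_equal(mean_absolute_error(c(40, 50), c(40, 50))$mae, 0)
})

test_that("regression of stable dose on prediction matches hand OLS", {
  exact <- suppressWarnings( # perfect fit makes summary.lm warn
    regress_wsd_on_prediction(c(1, 2, 3, 4), 2 * c(1, 2, 3, 4))
  )
  expect_equal(exact$r_squared, 1)

  fit <- regress_wsd_on_prediction(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(fit$r, 0.8)
  expect_equal(fit$r_squared, 0.64)
  expect_equal(fit$r_squared, fit$r^2, tolerance = 1e-9)
  expect_equal(fit$slope, 0.8)
  expect_equal(fit$intercept, 0.5)
  expect_equal(fit$f_statistic, 0.64 / 0.36 * 2, tolerance = 1e-9)

  set.seed(1234)
  x <- rnorm(4000)
  y <- rnorm(4000)
  expect_lt(regress_wsd_on_prediction(x, y)$r_squared, 0.01)

  expect_error(regress_wsd_on_prediction(rep(35, 5), rnorm(5)),
    class = "warfpgx_degenerate"
  )
})

test_that("classification tables are exhaustive and reproduce printed fractions", {
  # the study's pharmacogenetic row: 32 ideal of 47 is 68.1%
  tab <- study_classification("pgx")
  expect_equal(100 * tab$ideal / tab$total, 68.1, tolerance = 0.05)

  perfect <- classification_table(c(30, 40, 50), c(30, 40, 50))
  expect_equal(perfect$ideal, 3L)
  expect_equal(perfect$underestimation + perfect$overestimation, 0L)

  inflated <- classification_table(1.5 * c(30, 40, 50), c(30, 40, 50))
  expect_equal(inflated$overestimation, 3L)

  set.seed(7)
  pred <- runif(200, 20, 60)
  act <- runif(200, 20, 60)
  t200 <- classification_table(pred, act)
  expect_equal(
    t200$ideal + t200$underestimation + t200$overestimation, t200$total
  )
  expect_equal(t200$total, 200L)
})

test_that("event rates and NNG chain through ARR as defined", {
  er_pgx <- event_rate(study_classification("pgx"))
  er_clin <- event_rate(study_classification("clinical"))
  er_fix <- event_rate(study_classification("fixed"))
  expect_equal(er_pgx, 15 / 47)
  expect_equal(er_clin, 22 / 47)
  expect_equal(er_fix, 26 / 47)
  expect_equal(event_rate(list(
    underestimation = 0, overestimation = 0, total = 10
  )), 0)

  nng_c <- number_needed_to_genotype(er_pgx, er_clin)
  expect_equal(nng_c$arr, 7 / 47)
  expect_equal(nng_c$nng, 47 / 7)
  nng_f <- number_needed_to_genotype(er_pgx, er_fix)
  expect_equal(nng_f$nng, 47 / 11)
  expect_gt(nng_c$nng, 1) # nng >= 1 whenever arr <= 1

  tie <- number_needed_to_genotype(0.5, 0.5)
  expect_true(tie$undefined)
  expect_equal(tie$nng, Inf)
  expect_error(number_needed_to_genotype(-0.1, 0.5), class = "warfpgx_schema_error")
})

test_that("Pearson chi-square matches hand computations and degenerate cases", {
  res <- pearson_chi_square(study_bleeding_table())
  expect_lt(abs(res$statistic - 6.285), 5e-4)
  expect_equal(res$df, 2L)
  expect_lt(abs(res$p_value - 0.043), 5e-4)

  prop <- rbind(c(10, 20, 30), c(5, 10, 15))
  expect_equal(pearson_chi_square(prop)$statistic, 0)

  diag <- pearson_chi_square(rbind(c(10, 0), c(0, 10)))
  expect_equal(diag$statistic, 20)
  expect_equal(diag$df, 1L)

  expect_error(pearson_chi_square(rbind(c(1, 0), c(2, 0))),
    class = "warfpgx_degenerate"
  )
})

test_that("Pearson chi-square agrees with the stats oracle on random tables", {
  set.seed(42)
  for (i in 1:25) {
    m <- matrix(rpois(6, 8) + 1, 2, 3)
    ours <- pearson_chi_square(m)
    ref <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ours$p_value, unname(ref$p.value), tolerance = 1e-12)
  }
})

test_that("group comparisons work from raw values and from summary triplets", {
  # identical groups: no effect
  same <- group_dose_comparison(values = list(c(40, 42, 44), c(40, 42, 44)))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  # summary-statistic ANOVA on the three VKORC1 genotype groups
  vko <- group_dose_comparison(summaries = data.frame(
    n = c(15, 23, 9), mean = c(51.2, 39.1, 32.5), sd = c(15.9, 13.0, 8.8)
  ))
  expect_equal(vko$method, "anova")
  expect_equal(vko$statistic, 6.34, tolerance = 1e-2)
  expect_equal(vko$df, c(2, 44))
  expect_lt(abs(vko$p_value - 0.004), 5e-4)

  # pooled t on the two CYP2C9 groups
  cyp <- group_dose_comparison(summaries = data.frame(
    n = c(34, 13), mean = c(42.6, 39.4), sd = c(13.8, 17.5)
  ))
  expect_equal(cyp$method, "t")
  expect_equal(cyp$df, 45)
  expect_true(cyp$p_value > 0.50 && cyp$p_value < 0.52)

  expect_error(group_dose_comparison(values = list(c(1, 2))),
    class = "warfpgx_schema_error"
  )
})

test_that("raw-value group comparisons agree with t.test and aov oracles", {
  set.seed(11)
  g2 <- list(rnorm(12, 40, 8), rnorm(15, 36, 8))
  ours <- group_dose_comparison(values = g2)
  ref <- t.test(g2[[1]], g2[[2]], var.equal = TRUE)
  expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)

  g3 <- list(rnorm(10, 50, 10), rnorm(14, 40, 10), rnorm(8, 35, 10))
  ours3 <- group_dose_comparison(values = g3)
  df <- data.frame(
    y = unlist(g3),
    g = factor(rep(seq_along(g3), lengths(g3)))
  )
  ref3 <- summary(aov(y ~ g, data = df))[[1]]
  expect_equal(ours3$statistic, ref3[["F value"]][1], tolerance = 1e-10)
  expect_equal(ours3$p_value, ref3[["Pr(>F)"]][1], tolerance = 1e-10)
})

test_that("evaluate_models reconciles totals with the stable-dose subset", {
  cohort <- simulate_cohort(sim_params(n = 60, seed = 13))
  preds <- predict_weekly_doses(cohort)
  ev <- evaluate_models(cohort, preds)
  expect_gt(ev$n_stable, 0)
  for (mod in c("pgx", "clinical", "fixed")) {
    expect_equal(ev$models[[mod]]$classification$total, ev$n_stable)
    expect_gte(ev$models[[mod]]$performance$mae, 0)
    er <- ev$models[[mod]]$event_rate
    expect_true(er >= 0 && er <= 1)
  }
  expect_null(ev$models$fixed$regression) # constant predictor
  expect_equal(ev$nng$pgx_vs_clinical$arr,
    abs(ev$models$pgx$event_rate - ev$models$clinical$event_rate)
  )
})
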