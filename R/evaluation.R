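#' Classify a predicted dose against the empirical stable dose
#'
#' A prediction is *ideal* when it falls within 20% (by default) of the
#' empirically reached stable dose; *overestimation* when it is at least 20%
#' higher; *underestimation* when it is at least 20% lower. The relative
#' difference is taken against the actual stable dose. The exact-20% boundary
#' belongs to over/underestimation ("at least 20%"), so the ideal band is an
#' open interval.
#'
#' @param predicted Predicted weekly dose(s), mg/week.
#' @param actual_wsd Empirical stable dose(s), mg/week (> 0).
#' @param tolerance Relative threshold (default 0.20).
#' @return Character vector in
#'   `c("ideal", "underestimation", "overestimation")`.
#' @export
#' @examples
#' classify_dose(44.5, 40) # ideal
#' classify_dose(48.1, 40) # overestimation (20.25% above)
classify_dose <- function(predicted, actual_wsd, tolerance = 0.20) {
  if (any(actual_wsd <= 0, na.rm = TRUE)) {
    abort("actual stable dose must be positive", class = "warfpgx_record_error")
  }
  rel <- (predicted - actual_wsd) / actual_wsd
  dplyr::case_when(
    abs(rel) < tolerance ~ "ideal",
    rel >= tolerance ~ "overestimation",
    TRUE ~ "underestimation"
  )
}

#' Mean absolute error of a dose-prediction model
#'
#' MAE is the average of the absolute differences between the predicted dose
#' and the empirical stable dose; its uncertainty is reported as the standard
#' error of the absolute-error sample (sample SD divided by sqrt(n)).
#'
#' @param predictions,actuals Equal-length numeric vectors (mg/week).
#' @param model Optional model label carried into the result.
#' @return A `warf_performance` list: `model`, `mae`, `mae_se`, `n`.
#' @export
mean_absolute_error <- function(predictions, actuals, model = "") {
  if (length(predictions) != length(actuals) || length(predictions) < 1) {
    abort("predictions and actuals must be equal-length and nonempty",
      class = "warfpgx_schema_error"
    )
  }
  err <- abs(predictions - actuals)
  n <- length(err)
  structure(
    list(
      model = model, mae = mean(err),
      mae_se = if (n > 1) sd(err) / sqrt(n) else NA_real_, n = n
    ),
    class = "warf_performance"
  )
}

#' Regress the empirical stable dose on a model's predictions
#'
#' Ordinary least squares of the actual stable dose on the predicted dose
#' (the orientation of the standard stable-dose-versus-predicted scatter),
#' with the F-test of the slope on (1, n - 2) degrees of freedom.
#'
#' @param predictions,actuals Equal-length numeric vectors, `n >= 3`;
#'   predictions must not be constant.
#' @return A `warf_regression` list: `r`, `r_squared`, `f_statistic`,
#'   `p_value`, `slope`, `intercept`, `n`.
#' @export
regress_wsd_on_prediction <- function(predictions, actuals) {
  n <- length(predictions)
  if (n != length(actuals) || n < 3) {
    abort("need at least 3 paired observations", class = "warfpgx_schema_error")
  }
  if (sd(predictions) == 0) {
    abort("predictions are constant; regression is degenerate",
      class = "warfpgx_degenerate"
    )
  }
  fit <- lm(actuals ~ predictions)
  sm <- summary(fit)
  r <- cor(predictions, actuals)
  structure(
    list(
      r = r, r_squared = sm$r.squared,
      f_statistic = unname(sm$fstatistic[1]),
      p_value = pf(sm$fstatistic[1], 1, n - 2, lower.tail = FALSE),
      slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]), n = n
    ),
    class = "warf_regression"
  )
}

#' Ideal / under / overestimation classification table
#'
#' @param predictions,actuals Equal-length numeric dose vectors (mg/week).
#' @param tolerance Relative threshold (default 0.20).
#' @param model Optional model label.
#' @return A `warf_classification` list: `model`, `ideal`, `underestimation`,
#'   `overestimation`, `total`.
#' @export
classification_table <- function(predictions, actuals, tolerance = 0.20,
                                 model = "") {
  cls <- factor(classify_dose(predictions, actuals, tolerance),
    levels = dose_class_levels
  )
  counts <- table(cls)
  structure(
    list(
      model = model,
      ideal = as.integer(counts[["ideal"]]),
      underestimation = as.integer(counts[["underestimation"]]),
      overestimation = as.integer(counts[["overestimation"]]),
      total = length(cls)
    ),
    class = "warf_classification"
  )
}

#' @export
print.warf_classification <- function(x, ...) {
  cat(sprintf(
    "%s: ideal %d (%.1f%%), under %d (%.1f%%), over %d (%.1f%%) of %d\n",
    if (nzchar(x$model)) x$model else "classification",
    x$ideal, 100 * x$ideal / x$total,
    x$underestimation, 100 * x$underestimation / x$total,
    x$overestimation, 100 * x$overestimation / x$total, x$total
  ))
  invisible(x)
}

#' Event rate of a classification table
#'
#' The probability of a "bad" prediction:
#' `(underestimation + overestimation) / total`.
#'
#' @param table A `warf_classification` (or a list with the same fields).
#' @return A probability in `[0, 1]`.
#' @export
event_rate <- function(table) {
  if (table$total == 0) {
    abort("empty classification table", class = "warfpgx_degenerate")
  }
  (table$underestimation + table$overestimation) / table$total
}

#' Number needed to genotype
#'
#' The average number of patients who must be genotyped for one to benefit
#' from pharmacogenetic dosing relative to a comparator model: the reciprocal
#' of the absolute risk reduction, `ARR = |ER_a - ER_b|`. When the two event
#' rates are equal the ARR is zero and the NNG is undefined (reported as
#' infinite with an explicit flag).
#'
#' @param er_a,er_b Event rates in `[0, 1]` (conventionally the
#'   pharmacogenetic model and the comparator).
#' @return A `warf_nng` list: `er_a`, `er_b`, `arr`, `nng`, `undefined`.
#' @export
#' @examples
#' number_needed_to_genotype(15 / 47, 22 / 47) # NNG about 6.7
number_needed_to_genotype <- function(er_a, er_b) {
  if (any(c(er_a, er_b) < 0) || any(c(er_a, er_b) > 1)) {
    abort("event rates must lie in [0, 1]", class = "warfpgx_schema_error")
  }
  arr <- abs(er_a - er_b)
  structure(
    list(
      er_a = er_a, er_b = er_b, arr = arr,
      nng = if (arr > 0) 1 / arr else Inf,
      undefined = arr == 0
    ),
    class = "warf_nng"
  )
}

#' Pearson chi-square test of independence
#'
#' `sum((O - E)^2 / E)` with expected counts from the row/column margins,
#' `(rows - 1) * (cols - 1)` degrees of freedom and no continuity correction.
#'
#' @param table A counts matrix (e.g. the 2 x 3 bleeding-by-dose-group table).
#' @return A list: `statistic`, `df`, `p_value`, `expected`.
#' @export
#' @examples
#' pearson_chi_square(rbind(c(19, 25, 11), c(23, 19, 2)))
pearson_chi_square <- function(table) {
  m <- as.matrix(table)
  if (any(m < 0)) {
    abort("counts must be non-negative", class = "warfpgx_schema_error")
  }
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(expected <= 0)) {
    abort("all expected counts must be positive", class = "warfpgx_degenerate")
  }
  stat <- sum((m - expected)^2 / expected)
  df <- (nrow(m) - 1L) * (ncol(m) - 1L)
  list(
    statistic = stat, df = df,
    p_value = pchisq(stat, df = df, lower.tail = FALSE),
    expected = expected
  )
}

#' Compare stable doses across genotype groups
#'
#' Two groups are compared with the pooled-variance two-sample t-test; three
#' or more with one-way ANOVA. Both accept either raw per-patient dose
#' vectors or published summary triplets (n, mean, sd), so group comparisons
#' can be reproduced from a summary table alone: the pooled t statistic and
#' the one-way ANOVA between/within decomposition are functions of the
#' summaries only.
#'
#' @param values A list of numeric vectors, one per group (each n >= 2); or
#'   `NULL` when `summaries` is given.
#' @param summaries A data frame with columns `n`, `mean`, `sd`, one row per
#'   group; or `NULL` when `values` is given.
#' @return A list: `method` (`"t"` or `"anova"`), `statistic`, `df`
#'   (length 1 for t, length 2 for ANOVA), `p_value`.
#' @export
#' @examples
#' group_dose_comparison(summaries = data.frame(
#'   n = c(15, 23, 9), mean = c(51.2, 39.1, 32.5), sd = c(15.9, 13.0, 8.8)
#' ))
group_dose_comparison <- function(values = NULL, summaries = NULL) {
  if (is.null(summaries)) {
    if (is.null(values) || length(values) < 2) {
      abort("need at least two groups", class = "warfpgx_schema_error")
    }
    summaries <- data.frame(
      n = vapply(values, length, integer(1)),
      mean = vapply(values, mean, double(1)),
      sd = vapply(values, sd, double(1))
    )
  }
  k <- nrow(summaries)
  if (k < 2 || any(summaries$n < 2)) {
    abort("need >= 2 groups with n >= 2 each", class = "warfpgx_schema_error")
  }
  n <- summaries$n
  m <- summaries$mean
  s <- summaries$sd
  big_n <- sum(n)
  if (k == 2) {
    sp2 <- ((n[1] - 1) * s[1]^2 + (n[2] - 1) * s[2]^2) / (big_n - 2)
    tstat <- (m[1] - m[2]) / sqrt(sp2 * (1 / n[1] + 1 / n[2]))
    df <- big_n - 2
    list(
      method = "t", statistic = tstat, df = df,
      p_value = 2 * pt(abs(tstat), df, lower.tail = FALSE)
    )
  } else {
    grand <- sum(n * m) / big_n
    ss_between <- sum(n * (m - grand)^2)
    ss_within <- sum((n - 1) * s^2)
    df1 <- k - 1
    df2 <- big_n - k
    fstat <- (ss_between / df1) / (ss_within / df2)
    list(
      method = "anova", statistic = fstat, df = c(df1, df2),
      p_value = pf(fstat, df1, df2, lower.tail = FALSE)
    )
  }
}

#' Full model-performance evaluation on the stable-dose subset
#'
#' Restricts the cohort to patients with an empirically reached stable dose,
#' then computes, for each of the three prediction models, the MAE with its
#' standard error, the stable-dose-on-prediction regression (skipped for the
#' constant fixed-dose model), the 20% classification table and its event
#' rate; plus the pairwise absolute risk reduction and number needed to
#' genotype of the pharmacogenetic model against the clinical and fixed-dose
#' comparators.
#'
#' @param cohort A `warf_cohort`.
#' @param predictions Output of [predict_weekly_doses()] (or same shape).
#' @param tolerance Relative classification threshold (default 0.20).
#' @return A list: `n_stable`, `stable` (per-patient tibble with wsd and
#'   per-model classifications), `models` (per-model `performance`,
#'   `regression`, `classification`, `event_rate`), `nng`
#'   (`pgx_vs_clinical`, `pgx_vs_fixed`).
#' @export
evaluate_models <- function(cohort, predictions, tolerance = 0.20) {
  stab <- stable_doses(cohort)
  stab <- stab[stab$is_stable, ]
  if (nrow(stab) == 0) {
    return(list(
      n_stable = 0L, stable = stab, models = NULL, nng = NULL
    ))
  }
  per_model <- list()
  per_patient <- stab[, c("id", "wsd")]
  for (mod in c("pgx", "clinical", "fixed")) {
    pred <- predictions[predictions$model == mod, c("id", "weekly_dose")]
    merged <- dplyr::inner_join(per_patient, pred, by = "id")
    reg <- if (mod == "fixed" || sd(merged$weekly_dose) == 0) {
      NULL
    } else if (nrow(merged) >= 3) {
      regress_wsd_on_prediction(merged$weekly_dose, merged$wsd)
    } else {
      NULL
    }
    cls <- classification_table(merged$weekly_dose, merged$wsd, tolerance, model = mod)
    per_model[[mod]] <- list(
      performance = mean_absolute_error(merged$weekly_dose, merged$wsd, model = mod),
      regression = reg,
      classification = cls,
      event_rate = event_rate(cls)
    )
    per_patient[[paste0("pred_", mod)]] <- merged$weekly_dose[match(per_patient$id, merged$id)]
    per_patient[[paste0("class_", mod)]] <-
      classify_dose(per_patient[[paste0("pred_", mod)]], per_patient$wsd, tolerance)
  }
  list(
    n_stable = nrow(stab),
    stable = per_patient,
    models = per_model,
    nng = list(
      pgx_vs_clinical = number_needed_to_genotype(
        per_model$pgx$event_rate, per_model$clinical$event_rate
      ),
      pgx_vs_fixed = number_needed_to_genotype(
        per_model$pgx$event_rate, per_model$fixed$event_rate
      )
    )
  )
}
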