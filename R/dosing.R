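#' IWPC dosing-equation coefficients
#'
#' Loads the coefficient set for the IWPC pharmacogenetic (`"pgx"`) or
#' clinical (`"clinical"`) dosing equation. Both equations are linear on the
#' square-root-of-weekly-dose scale; the predicted weekly dose is the squared
#' linear predictor. The defaults shipped with the package are the published
#' IWPC estimates; a user-supplied CSV with columns `term, estimate` overrides
#' them, so recalibrated or population-specific coefficient sets can be
#' plugged in without code changes.
#'
#' Terms: `intercept`, `age_decade` (age in decades, age/10 continuous),
#' `height_cm`, `weight_kg`, genotype indicators (`vkorc1_GA`, `vkorc1_AA`,
#' `vkorc1_unknown`, `cyp2c9_1_2` ... `cyp2c9_unknown`; pharmacogenetic
#' equation only), race indicators (reference: white) and the
#' `enzyme_inducer` / `amiodarone` flags.
#'
#' @param model `"pgx"` or `"clinical"`.
#' @param file Optional path to a CSV coefficient file overriding the default.
#' @return Named numeric vector of coefficients.
#' @export
iwpc_coefficients <- function(model = c("pgx", "clinical"), file = NULL) {
  model <- match.arg(model)
  if (is.null(file)) {
    file <- system.file(
      "extdata",
      sprintf("iwpc_%s_coefficients.csv", model),
      package = "warfpgx"
    )
  }
  if (!file.exists(file)) {
    abort(paste0("coefficient file not found: ", file),
      class = "warfpgx_schema_error"
    )
  }
  tab <- readr::read_csv(file,
    col_types = readr::cols(
      term = readr::col_character(),
      estimate = readr::col_double()
    ),
    progress = FALSE
  )
  if (!"intercept" %in% tab$term) {
    abort("coefficient file must contain an 'intercept' term",
      class = "warfpgx_schema_error"
    )
  }
  stats::setNames(tab$estimate, tab$term)
}

cyp2c9_term <- c(
  "*1/*2" = "cyp2c9_1_2", "*1/*3" = "cyp2c9_1_3", "*2/*2" = "cyp2c9_2_2",
  "*2/*3" = "cyp2c9_2_3", "*3/*3" = "cyp2c9_3_3", "unknown" = "cyp2c9_unknown"
)
vkorc1_term <- c(
  "GA" = "vkorc1_GA", "AA" = "vkorc1_AA", "unknown" = "vkorc1_unknown"
)
race_term <- c(
  "asian" = "race_asian",
  "black_or_african_american" = "race_black_or_african_american",
  "missing_or_mixed" = "race_missing_or_mixed"
)

coef_or_zero <- function(coeffs, term) {
  ifelse(is.na(term) | !(term %in% names(coeffs)), 0, coeffs[term])
}

# Shared linear predictor on the sqrt(mg/week) scale; genotype terms
# contribute only when present in the coefficient set.
iwpc_linear_predictor <- function(cohort, coeffs, genetic) {
  if (any(is.na(cohort$age) | is.na(cohort$height) | is.na(cohort$weight))) {
    abort("age, height and weight are required for IWPC dose prediction",
      class = "warfpgx_record_error"
    )
  }
  lp <- coeffs[["intercept"]] +
    coeffs[["age_decade"]] * cohort$age / 10 +
    coeffs[["height_cm"]] * cohort$height +
    coeffs[["weight_kg"]] * cohort$weight +
    coef_or_zero(coeffs, race_term[cohort$race]) +
    coeffs[["enzyme_inducer"]] * as.numeric(cohort$enzyme_inducer) +
    coeffs[["amiodarone"]] * as.numeric(cohort$amiodarone)
  if (genetic) {
    lp <- lp +
      coef_or_zero(coeffs, vkorc1_term[cohort$vkorc1]) +
      coef_or_zero(coeffs, cyp2c9_term[cohort$cyp2c9])
  }
  unname(lp)
}

square_lp <- function(lp) {
  if (any(lp < 0)) {
    warn("negative linear predictor clamped to dose 0")
    lp <- pmax(lp, 0)
  }
  lp^2
}

#' IWPC pharmacogenetic weekly dose
#'
#' Evaluates the IWPC pharmacogenetic equation for each patient: the linear
#' predictor (intercept, age in decades, height, weight, VKORC1 and CYP2C9
#' genotype indicators, race indicators, enzyme-inducer and amiodarone flags)
#' on the square-root scale, squared to mg/week. `"unknown"` genotypes use
#' their own published coefficients. A negative linear predictor (possible
#' only with pathological coefficient sets) is clamped to dose 0 with a
#' warning.
#'
#' @param cohort A `warf_cohort` (any number of rows).
#' @param coeffs Coefficients from [iwpc_coefficients()].
#' @return Numeric vector of predicted weekly doses (mg/week).
#' @export
#' @examples
#' p <- patient_record(age = 50, height = 170, weight = 70)
#' iwpc_pgx_weekly_dose(p) # about 44.5 mg/week
iwpc_pgx_weekly_dose <- function(cohort, coeffs = iwpc_coefficients("pgx")) {
  square_lp(iwpc_linear_predictor(cohort, coeffs, genetic = TRUE))
}

#' IWPC clinical weekly dose
#'
#' The genotype-free companion equation: same covariates as
#' [iwpc_pgx_weekly_dose()] minus the CYP2C9/VKORC1 terms, with its own
#' published coefficient values.
#'
#' @inheritParams iwpc_pgx_weekly_dose
#' @return Numeric vector of predicted weekly doses (mg/week).
#' @export
iwpc_clinical_weekly_dose <- function(cohort, coeffs = iwpc_coefficients("clinical")) {
  square_lp(iwpc_linear_predictor(cohort, coeffs, genetic = FALSE))
}

#' Fixed-dose comparator
#'
#' The empirical practice of starting every patient on 5 mg/day regardless of
#' covariates, i.e. a constant 35 mg/week.
#'
#' @return 35 (mg/week).
#' @export
fixed_weekly_dose <- function() {
  35
}

#' INR measurement parameters
#'
#' @param pt_normal Mean normal prothrombin time in seconds (study value 15.0).
#' @param isi International Sensitivity Index of the thromboplastin reagent
#'   (manufacturer value 1.03).
#' @return An `inr_params` list.
#' @export
inr_params <- function(pt_normal = 15.0, isi = 1.03) {
  if (!isTRUE(pt_normal > 0) || !isTRUE(isi > 0)) {
    abort("pt_normal and isi must both be positive", class = "warfpgx_schema_error")
  }
  structure(list(pt_normal = pt_normal, isi = isi), class = "inr_params")
}

#' International normalized ratio from prothrombin time
#'
#' `INR = (PT_patient / PT_normal) ^ ISI`.
#'
#' @param pt_seconds Patient prothrombin time(s) in seconds (> 0).
#' @param params An [inr_params()] object.
#' @return Numeric INR value(s).
#' @export
#' @examples
#' inr_from_pt(30) # about 2.04
inr_from_pt <- function(pt_seconds, params = inr_params()) {
  if (any(pt_seconds <= 0, na.rm = TRUE)) {
    abort("prothrombin time must be positive", class = "warfpgx_record_error")
  }
  (pt_seconds / params$pt_normal)^params$isi
}

#' Predicted weekly doses for all three models
#'
#' @param cohort A `warf_cohort`.
#' @param pgx_coeffs,clinical_coeffs Coefficient sets (defaults: shipped IWPC
#'   values).
#' @return A tibble `id, model, weekly_dose` with models `pgx`, `clinical`,
#'   `fixed`.
#' @export
predict_weekly_doses <- function(cohort,
                                 pgx_coeffs = iwpc_coefficients("pgx"),
                                 clinical_coeffs = iwpc_coefficients("clinical")) {
  tibble::tibble(
    id = rep(cohort$id, 3),
    model = rep(c("pgx", "clinical", "fixed"), each = nrow(cohort)),
    weekly_dose = c(
      iwpc_pgx_weekly_dose(cohort, pgx_coeffs),
      iwpc_clinical_weekly_dose(cohort, clinical_coeffs),
      rep(fixed_weekly_dose(), nrow(cohort))
    )
  )
}
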