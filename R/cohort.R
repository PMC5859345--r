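#' Construct a single patient record
#'
#' Builds a one-row cohort tibble holding the static covariates the dosing
#' models need (demographics, anthropometrics, genotypes, interacting
#' medication flags, target INR range) together with the patient's visit
#' history as a nested tibble. Mostly a convenience for scripts and tests;
#' whole cohorts are usually read from CSV with [read_cohort()] or simulated
#' with [simulate_cohort()].
#'
#' @param id Patient identifier (opaque string).
#' @param sex `"male"` or `"female"`.
#' @param age Age in years (> 0).
#' @param height Height in cm (> 0).
#' @param weight Weight in kg (> 0).
#' @param race One of `"white"`, `"asian"`, `"black_or_african_american"`,
#'   `"missing_or_mixed"`. The study population is mapped to the reference
#'   category (`"white"`, all race indicators zero).
#' @param enzyme_inducer Logical; carbamazepine, phenytoin or rifampin use.
#' @param amiodarone Logical; amiodarone use.
#' @param cyp2c9 CYP2C9 diplotype, one of `"*1/*1"`, `"*1/*2"`, `"*1/*3"`,
#'   `"*2/*2"`, `"*2/*3"`, `"*3/*3"`, `"unknown"`.
#' @param vkorc1 VKORC1 -1639G>A genotype: `"GG"`, `"GA"`, `"AA"` or
#'   `"unknown"`.
#' @param target_inr_low,target_inr_high Therapeutic INR window,
#'   `0 < low < high`. Defaults to the usual 2.0--3.0 range.
#' @param indication `"thromboembolic"`, `"cardiovascular"` or `"both"`.
#' @param bleeding Worst-ever bleeding event class: `"none"`, `"minor"`,
#'   `"major"`, or `NA` if unrecorded.
#' @param visits A tibble with columns `visit` (ordinal index), `weekly_dose`
#'   (mg/week), `pt_seconds`, `inr`. `pt_seconds` and `inr` may each be `NA`
#'   but not both in the same visit.
#' @return A one-row `warf_cohort` tibble.
#' @export
#' @examples
#' p <- patient_record(age = 50, height = 170, weight = 70)
#' iwpc_pgx_weekly_dose(p)
patient_record <- function(id = "P001",
                           sex = "female",
                           age = 50,
                           height = 170,
                           weight = 70,
                           race = "white",
                           enzyme_inducer = FALSE,
                           amiodarone = FALSE,
                           cyp2c9 = "*1/*1",
                           vkorc1 = "GG",
                           target_inr_low = 2,
                           target_inr_high = 3,
                           indication = "thromboembolic",
                           bleeding = "none",
                           visits = NULL) {
  if (is.null(visits)) {
    visits <- tibble::tibble(
      visit = integer(), weekly_dose = double(),
      pt_seconds = double(), inr = double()
    )
  }
  rec <- tibble::tibble(
    id = as.character(id), sex = sex, age = as.numeric(age),
    height = as.numeric(height), weight = as.numeric(weight), race = race,
    enzyme_inducer = as.logical(enzyme_inducer),
    amiodarone = as.logical(amiodarone),
    cyp2c9 = cyp2c9, vkorc1 = vkorc1,
    target_inr_low = as.numeric(target_inr_low),
    target_inr_high = as.numeric(target_inr_high),
    indication = indication, bleeding = bleeding,
    visits = list(tibble::as_tibble(visits))
  )
  as_cohort(rec)
}

patient_columns <- c(
  "id", "sex", "age", "height", "weight", "race", "enzyme_inducer",
  "amiodarone", "cyp2c9", "vkorc1", "target_inr_low", "target_inr_high",
  "indication", "bleeding"
)
visit_columns <- c("id", "visit", "weekly_dose", "pt_seconds", "inr")

#' Coerce and validate a cohort tibble
#'
#' @param x A data frame with the `patient_record()` columns and a `visits`
#'   list-column.
#' @param inr_params Optional [inr_params()]; when supplied, stored INR values
#'   are checked against `inr_from_pt()` of the stored prothrombin time.
#' @return `x` as a validated `warf_cohort` tibble.
#' @export
as_cohort <- function(x, inr_params = NULL) {
  x <- tibble::as_tibble(x)
  missing_cols <- setdiff(c(patient_columns, "visits"), names(x))
  if (length(missing_cols) > 0) {
    abort(
      paste0("cohort is missing column(s): ", paste(missing_cols, collapse = ", ")),
      class = "warfpgx_schema_error"
    )
  }
  validate_cohort(x, inr_params = inr_params)
  class(x) <- c("warf_cohort", class(x))
  x
}

validate_cohort <- function(cohort, inr_params = NULL) {
  bad_row <- function(id, msg) {
    abort(
      sprintf("patient '%s': %s", id, msg),
      class = "warfpgx_record_error"
    )
  }
  for (i in seq_len(nrow(cohort))) {
    p <- cohort[i, ]
    id <- p$id
    if (is.na(id) || !nzchar(id)) bad_row(sprintf("<row %d>", i), "empty id")
    if (!p$sex %in% sex_levels) bad_row(id, sprintf("invalid sex '%s'", p$sex))
    if (!isTRUE(p$age > 0)) bad_row(id, "age must be > 0")
    if (!isTRUE(p$height > 0)) bad_row(id, "height must be > 0")
    if (!isTRUE(p$weight > 0)) bad_row(id, "weight must be > 0")
    if (!p$race %in% race_levels) bad_row(id, sprintf("invalid race '%s'", p$race))
    if (!p$cyp2c9 %in% cyp2c9_levels) {
      bad_row(id, sprintf("unparseable CYP2C9 genotype '%s'", p$cyp2c9))
    }
    if (!p$vkorc1 %in% vkorc1_levels) {
      bad_row(id, sprintf("unparseable VKORC1 genotype '%s'", p$vkorc1))
    }
    if (!isTRUE(p$target_inr_low > 0) || !isTRUE(p$target_inr_high > p$target_inr_low)) {
      bad_row(id, "target INR range must satisfy 0 < low < high")
    }
    if (!p$indication %in% indication_levels) {
      bad_row(id, sprintf("invalid indication '%s'", p$indication))
    }
    if (!is.na(p$bleeding) && !p$bleeding %in% bleeding_levels) {
      bad_row(id, sprintf("invalid bleeding class '%s'", p$bleeding))
    }
    v <- p$visits[[1]]
    if (nrow(v) > 0) {
      if (is.unsorted(v$visit, strictly = TRUE)) {
        bad_row(id, "visits must be strictly ordered by visit index")
      }
      if (any(v$weekly_dose < 0, na.rm = TRUE)) bad_row(id, "weekly_dose must be >= 0")
      if (any(is.na(v$pt_seconds) & is.na(v$inr))) {
        bad_row(id, "each visit needs at least one of pt_seconds or inr")
      }
      if (!is.null(inr_params)) {
        both <- !is.na(v$pt_seconds) & !is.na(v$inr)
        if (any(both)) {
          expected <- inr_from_pt(v$pt_seconds[both], inr_params)
          if (any(abs(expected - v$inr[both]) > 1e-9)) {
            bad_row(id, "stored INR inconsistent with prothrombin time")
          }
        }
      }
    }
  }
  invisible(cohort)
}

#' Read a patient cohort from CSV files
#'
#' Patients are stored one row per patient; visit histories live in a separate
#' long-format CSV keyed by patient id, which keeps both files human-auditable.
#'
#' @param patients_path CSV with the static patient columns (see
#'   [patient_record()] for the schema).
#' @param visits_path CSV with columns `id, visit, weekly_dose, pt_seconds,
#'   inr`. `pt_seconds`/`inr` may be empty, but not both for one visit.
#' @param inr_params Optional [inr_params()] used to cross-check stored INR
#'   values against prothrombin times.
#' @return A validated `warf_cohort` tibble with nested `visits`.
#' @export
read_cohort <- function(patients_path, visits_path, inr_params = NULL) {
  if (!file.exists(patients_path)) {
    abort(paste0("patients file not found: ", patients_path),
      class = "warfpgx_schema_error"
    )
  }
  patients <- readr::read_csv(
    patients_path,
    col_types = readr::cols(
      id = readr::col_character(), sex = readr::col_character(),
      age = readr::col_double(), height = readr::col_double(),
      weight = readr::col_double(), race = readr::col_character(),
      enzyme_inducer = readr::col_logical(), amiodarone = readr::col_logical(),
      cyp2c9 = readr::col_character(), vkorc1 = readr::col_character(),
      target_inr_low = readr::col_double(), target_inr_high = readr::col_double(),
      indication = readr::col_character(), bleeding = readr::col_character()
    ),
    progress = FALSE
  )
  missing_cols <- setdiff(patient_columns, names(patients))
  if (length(missing_cols) > 0) {
    abort(
      paste0(
        "patients file is missing mandatory column(s): ",
        paste(missing_cols, collapse = ", ")
      ),
      class = "warfpgx_schema_error"
    )
  }
  visits <- readr::read_csv(
    visits_path,
    col_types = readr::cols(
      id = readr::col_character(), visit = readr::col_integer(),
      weekly_dose = readr::col_double(), pt_seconds = readr::col_double(),
      inr = readr::col_double()
    ),
    progress = FALSE
  )
  missing_cols <- setdiff(visit_columns, names(visits))
  if (length(missing_cols) > 0) {
    abort(
      paste0(
        "visits file is missing mandatory column(s): ",
        paste(missing_cols, collapse = ", ")
      ),
      class = "warfpgx_schema_error"
    )
  }
  nested <- tidyr::nest(dplyr::arrange(visits, .data$id, .data$visit),
    visits = !"id"
  )
  cohort <- dplyr::left_join(patients, nested, by = "id")
  empty_visits <- tibble::tibble(
    visit = integer(), weekly_dose = double(),
    pt_seconds = double(), inr = double()
  )
  cohort$visits <- purrr::map(cohort$visits, function(v) {
    if (is.null(v)) empty_visits else v
  })
  as_cohort(cohort, inr_params = inr_params)
}

#' Write a cohort back to the two-file CSV layout
#'
#' Inverse of [read_cohort()]: `read_cohort()` after `write_cohort()` returns
#' an equal cohort.
#'
#' @param cohort A `warf_cohort`.
#' @param patients_path,visits_path Output CSV paths.
#' @return Invisibly, the two paths.
#' @export
write_cohort <- function(cohort, patients_path, visits_path) {
  readr::write_csv(dplyr::select(cohort, dplyr::all_of(patient_columns)),
    patients_path,
    progress = FALSE
  )
  long <- tidyr::unnest(
    dplyr::select(cohort, "id", "visits"), "visits"
  )
  readr::write_csv(long, visits_path, progress = FALSE)
  invisible(c(patients = patients_path, visits = visits_path))
}

#' Classify body-mass index into WHO categories
#'
#' Cut-offs: underweight < 18.5, normal 18.5--24.9, overweight 25--29.9,
#' obese >= 30 kg/m^2.
#'
#' @param bmi Numeric vector of BMI values (kg/m^2).
#' @return Character vector of categories.
#' @export
bmi_class <- function(bmi) {
  as.character(cut(bmi,
    breaks = c(-Inf, 18.5, 25, 30, Inf),
    labels = c("underweight", "normal", "overweight", "obese"),
    right = FALSE
  ))
}

#' Cohort descriptive summary
#'
#' Computes the descriptive table for a cohort: sample size, percentage
#' breakdowns by sex, indication, bleeding class and WHO BMI class, and
#' mean +/- SD of age, BMI and INR. BMI is weight / (height in m)^2; the INR
#' summary averages each patient's visit INRs first, then summarises across
#' patients.
#'
#' @param cohort A nonempty `warf_cohort`.
#' @return A `warf_cohort_summary` list with elements `n`, `percent`
#'   (named list of percentage tables), and `mean_sd` (rows age, bmi, inr).
#' @export
summarize_cohort <- function(cohort) {
  if (nrow(cohort) == 0) {
    abort("cannot summarize an empty cohort", class = "warfpgx_degenerate")
  }
  pct <- function(x, levels) {
    x <- x[!is.na(x)]
    tab <- table(factor(x, levels = levels))
    stats::setNames(100 * as.vector(tab) / sum(tab), levels)
  }
  bmi <- cohort$weight / (cohort$height / 100)^2
  inr_by_patient <- purrr::map_dbl(cohort$visits, function(v) {
    vals <- v$inr[!is.na(v$inr)]
    if (length(vals) == 0) NA_real_ else mean(vals)
  })
  mean_sd <- function(x) {
    x <- x[!is.na(x)]
    c(mean = mean(x), sd = if (length(x) > 1) sd(x) else NA_real_)
  }
  out <- list(
    n = nrow(cohort),
    percent = list(
      sex = pct(cohort$sex, sex_levels),
      indication = pct(cohort$indication, indication_levels),
      bleeding = pct(cohort$bleeding, bleeding_levels),
      bmi_class = pct(bmi_class(bmi),
        c("underweight", "normal", "overweight", "obese"))
    ),
    mean_sd = rbind(
      age = mean_sd(cohort$age),
      bmi = mean_sd(bmi),
      inr = mean_sd(inr_by_patient)
    )
  )
  structure(out, class = "warf_cohort_summary")
}

#' @export
print.warf_cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort summary (n = %d)\n", x$n))
  for (nm in names(x$percent)) {
    p <- x$percent[[nm]]
    cat(sprintf(
      "  %s: %s\n", nm,
      paste(sprintf("%s %.1f%%", names(p), p), collapse = ", ")
    ))
  }
  for (nm in rownames(x$mean_sd)) {
    cat(sprintf(
      "  %s: %.1f +/- %.1f\n", nm,
      x$mean_sd[nm, "mean"], x$mean_sd[nm, "sd"]
    ))
  }
  invisible(x)
}
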