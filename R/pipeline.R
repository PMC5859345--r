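#' Configuration for a pipeline run
#'
#' Bundles the inputs of the two pipeline commands: either simulation
#' parameters (for [cmd_simulate()]) or the cohort file paths (for
#' [cmd_evaluate()]), plus the knobs shared by both.
#'
#' @param patients,visits,fragments Input CSV paths (`fragments` optional;
#'   when given, genotypes are called from the fragment patterns and override
#'   the genotype columns of the patient file).
#' @param pgx_coeffs_file,clinical_coeffs_file Optional coefficient CSV paths
#'   overriding the shipped IWPC values.
#' @param tolerance Relative dose-classification threshold, in (0, 1);
#'   default 0.20.
#' @param out Output directory.
#' @param sim A [sim_params()] object (simulation only).
#' @param seed Integer seed (simulation only; mandatory there).
#' @return A `warf_run_config` list.
#' @export
run_config <- function(patients = NULL, visits = NULL, fragments = NULL,
                       pgx_coeffs_file = NULL, clinical_coeffs_file = NULL,
                       tolerance = 0.20, out = ".", sim = NULL, seed = NULL) {
  if (!is.numeric(tolerance) || tolerance <= 0 || tolerance >= 1) {
    abort("tolerance must lie in (0, 1)", class = "warfpgx_schema_error")
  }
  structure(
    list(
      patients = patients, visits = visits, fragments = fragments,
      pgx_coeffs_file = pgx_coeffs_file,
      clinical_coeffs_file = clinical_coeffs_file,
      tolerance = tolerance, out = out, sim = sim, seed = seed
    ),
    class = "warf_run_config"
  )
}

#' Simulate a cohort and write its fixture files
#'
#' @param config A [run_config()] with `sim` (optional; defaults to
#'   [sim_params()]) and a mandatory `seed`.
#' @return Invisibly, the written file paths.
#' @export
cmd_simulate <- function(config) {
  if (is.null(config$seed) && is.null(config$sim$seed)) {
    abort("a seed is required for simulation", class = "warfpgx_schema_error")
  }
  sim <- config$sim %||% sim_params()
  if (!is.null(config$seed)) sim$seed <- config$seed
  message(sprintf(
    "simulating cohort: n = %d, dose noise sd = %.3f, seed = %d",
    sim$n, sim$dose_noise_sd, sim$seed
  ))
  paths <- generate_fixture_files(sim, config$out)
  message(sprintf("wrote %s", paste(paths, collapse = ", ")))
  invisible(paths)
}

#' Run the full retrospective evaluation pipeline
#'
#' Reads the cohort, optionally re-calls genotypes from RFLP fragment
#' patterns, computes genotype/allele frequencies and Hardy-Weinberg tests
#' for both loci, predicts weekly doses under the pharmacogenetic, clinical
#' and fixed-dose models, determines each patient's empirical stable dose,
#' and evaluates the three models (MAE, regression, 20% classification,
#' event rates, ARR/NNG) on the stable-dose subset, plus the
#' bleeding-by-dose-group contingency analysis on the full cohort. Writes
#' `report.json` and a per-patient `classifications.csv` to the output
#' directory.
#'
#' @param config A [run_config()] with `patients` and `visits` paths.
#' @return The report list, invisibly. `report$status` is `"ok"`, or
#'   `"no_stable_patients"` when no patient reached a stable dose (the
#'   evaluation section is then empty).
#' @export
cmd_evaluate <- function(config) {
  cohort <- read_cohort(config$patients, config$visits)
  if (!is.null(config$fragments)) {
    frag <- readr::read_csv(config$fragments,
      col_types = readr::cols(.default = readr::col_character()),
      progress = FALSE
    )
    calls <- call_genotypes_from_fragments(frag)
    idx <- match(cohort$id, calls$id)
    hit <- !is.na(idx)
    cohort$cyp2c9[hit] <- calls$cyp2c9[idx[hit]]
    cohort$vkorc1[hit] <- calls$vkorc1[idx[hit]]
  }
  pgx_coeffs <- iwpc_coefficients("pgx", config$pgx_coeffs_file)
  clinical_coeffs <- iwpc_coefficients("clinical", config$clinical_coeffs_file)

  counts_cyp <- genotype_counts_from_cohort(cohort, "cyp2c9")
  counts_vko <- genotype_counts_from_cohort(cohort, "vkorc1")
  genetics <- list(
    cyp2c9 = list(
      counts = as.list(counts_cyp$counts),
      genotype_frequencies = as.list(genotype_frequencies(counts_cyp)),
      allele_frequencies = as.list(allele_frequencies(counts_cyp)),
      hwe = unclass(hwe_chi_square(counts_cyp))
    ),
    vkorc1 = list(
      counts = as.list(counts_vko$counts),
      genotype_frequencies = as.list(genotype_frequencies(counts_vko)),
      allele_frequencies = as.list(allele_frequencies(counts_vko)),
      hwe = unclass(hwe_chi_square(counts_vko))
    )
  )

  predictions <- predict_weekly_doses(cohort, pgx_coeffs, clinical_coeffs)
  evaluation <- evaluate_models(cohort, predictions, config$tolerance)

  bleed_tab <- bleeding_contingency(
    cohort, predictions[predictions$model == "pgx", ], config$tolerance
  )
  bleeding <- list(
    table = unname(apply(bleed_tab, 1, as.list)),
    chi_square = if (all(rowSums(bleed_tab) > 0) && all(colSums(bleed_tab) > 0)) {
      pearson_chi_square(bleed_tab)[c("statistic", "df", "p_value")]
    } else {
      NULL
    }
  )

  report <- list(
    status = if (evaluation$n_stable > 0) "ok" else "no_stable_patients",
    n_patients = nrow(cohort),
    n_stable = evaluation$n_stable,
    genetics = genetics,
    evaluation = serialize_evaluation(evaluation),
    bleeding = bleeding
  )

  if (!dir.exists(config$out)) dir.create(config$out, recursive = TRUE)
  jsonlite::write_json(report, file.path(config$out, "report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null"
  )
  if (evaluation$n_stable > 0) {
    readr::write_csv(evaluation$stable,
      file.path(config$out, "classifications.csv"),
      progress = FALSE
    )
  }
  invisible(report)
}

serialize_evaluation <- function(evaluation) {
  if (evaluation$n_stable == 0) {
    return(list())
  }
  models <- purrr::map(evaluation$models, function(m) {
    list(
      performance = unclass(m$performance),
      regression = if (is.null(m$regression)) NULL else unclass(m$regression),
      classification = unclass(m$classification),
      event_rate = m$event_rate
    )
  })
  list(
    models = models,
    nng = purrr::map(evaluation$nng, unclass)
  )
}
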