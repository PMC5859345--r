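#' Simulation parameters for a synthetic anticoagulation cohort
#'
#' Defaults emulate the statistical structure of the study cohort: n = 101;
#' genotype class probabilities equal to the observed genotype counts over
#' 101 (CYP2C9 75/25/1, VKORC1 30/49/22; the two loci are drawn
#' independently); age Normal(48.8, 14.4) truncated to 16--76 years; 42.4%
#' male; BMI Normal(27.8, 5.2) with sex-specific height distributions, weight
#' derived from BMI and height; mostly 2.0--3.0 INR targets with a small
#' mechanical-valve fraction at 2.5--3.5.
#'
#' The dose-generating process is the pharmacogenetic linear predictor plus
#' Gaussian noise on the square-root-of-dose scale (so at `dose_noise_sd = 0`
#' the pharmacogenetic model recovers every stable dose exactly), squared and
#' floored at a 7 mg/week minimum. Each patient ends with at least three
#' visits at the true stable dose with in-range INR, preceded by 0--3
#' titration visits at other doses with sub-therapeutic INR. Bleeding is
#' drawn from a logistic model in the relative dose excess
#' `(actual - predicted) / predicted`, so overdosing relative to the
#' pharmacogenetic prediction raises bleeding probability.
#'
#' @param n Number of patients.
#' @param cyp2c9_probs,vkorc1_probs Named genotype-class probabilities
#'   (must sum to 1).
#' @param age_mean,age_sd,age_range Truncated-normal age distribution (years).
#' @param male_prob Probability of male sex.
#' @param bmi_mean,bmi_sd,bmi_range Truncated-normal BMI (kg/m^2).
#' @param height_mean Named vector (male, female) of mean heights (cm).
#' @param height_sd Height SD (cm).
#' @param inducer_prob,amiodarone_prob Medication-flag probabilities.
#' @param indication_probs Named probabilities for the treatment indication.
#' @param high_target_prob Fraction with a 2.5--3.5 INR target
#'   (mechanical valve).
#' @param dose_noise_sd SD of dose noise on the sqrt(mg/week) scale (>= 0).
#' @param wsd_floor Minimum stable dose (mg/week).
#' @param titration_visits,stable_visits Candidate counts of titration and
#'   stable terminal visits (sampled per patient).
#' @param inr_noise_sd SD of in-range INR around the target midpoint.
#' @param bleeding_intercept,bleeding_slope Logistic bleeding-model
#'   coefficients on the relative-dose-excess scale.
#' @param minor_fraction Fraction of bleeding events that are minor.
#' @param inr [inr_params()] used to back-compute prothrombin times.
#' @param pgx_coeffs Pharmacogenetic coefficients driving the true doses.
#' @param seed Integer seed; the same seed reproduces the identical cohort.
#' @return A `warf_sim_params` list.
#' @export
sim_params <- function(n = 101,
                       cyp2c9_probs = c("*1/*1" = 75, "*1/*2" = 25, "*2/*2" = 1) / 101,
                       vkorc1_probs = c(GG = 30, GA = 49, AA = 22) / 101,
                       age_mean = 48.8, age_sd = 14.4, age_range = c(16, 76),
                       male_prob = 0.424,
                       bmi_mean = 27.8, bmi_sd = 5.2, bmi_range = c(15, 45),
                       height_mean = c(male = 172, female = 159),
                       height_sd = 6.5,
                       inducer_prob = 0.02, amiodarone_prob = 0.05,
                       indication_probs = c(
                         thromboembolic = 0.505,
                         cardiovascular = 0.414, both = 0.081
                       ),
                       high_target_prob = 3 / 101,
                       dose_noise_sd = 0.9,
                       wsd_floor = 7,
                       titration_visits = 0:3,
                       stable_visits = 3:5,
                       inr_noise_sd = 0.25,
                       bleeding_intercept = -0.35,
                       bleeding_slope = 2.5,
                       minor_fraction = 0.85,
                       inr = inr_params(),
                       pgx_coeffs = NULL,
                       seed = NULL) {
  p <- list(
    n = n, cyp2c9_probs = cyp2c9_probs, vkorc1_probs = vkorc1_probs,
    age_mean = age_mean, age_sd = age_sd, age_range = age_range,
    male_prob = male_prob, bmi_mean = bmi_mean, bmi_sd = bmi_sd,
    bmi_range = bmi_range, height_mean = height_mean, height_sd = height_sd,
    inducer_prob = inducer_prob, amiodarone_prob = amiodarone_prob,
    indication_probs = indication_probs, high_target_prob = high_target_prob,
    dose_noise_sd = dose_noise_sd, wsd_floor = wsd_floor,
    titration_visits = titration_visits, stable_visits = stable_visits,
    inr_noise_sd = inr_noise_sd, bleeding_intercept = bleeding_intercept,
    bleeding_slope = bleeding_slope, minor_fraction = minor_fraction,
    inr = inr, pgx_coeffs = pgx_coeffs, seed = seed
  )
  for (nm in c("cyp2c9_probs", "vkorc1_probs", "indication_probs")) {
    if (abs(sum(p[[nm]]) - 1) > 1e-8 || any(p[[nm]] < 0)) {
      abort(sprintf("%s must be non-negative and sum to 1", nm),
        class = "warfpgx_schema_error"
      )
    }
  }
  if (p$dose_noise_sd < 0 || p$inr_noise_sd < 0) {
    abort("noise SDs must be >= 0", class = "warfpgx_schema_error")
  }
  if (p$n < 1) abort("n must be >= 1", class = "warfpgx_schema_error")
  structure(p, class = "warf_sim_params")
}

rnorm_trunc <- function(n, mean, sd, range) {
  x <- rnorm(n, mean, sd)
  bad <- which(x < range[1] | x > range[2])
  while (length(bad) > 0) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(x < range[1] | x > range[2])
  }
  x
}

round_half_mg <- function(dose) {
  pmax(2.5, round(dose / 2.5) * 2.5)
}

#' Simulate a synthetic patient cohort
#'
#' Draws a full cohort (covariates, genotypes, dose-titration visit histories
#' ending in a recoverable stable-dose run, bleeding outcomes) from the
#' generative model described in [sim_params()]. With the same seed the
#' returned cohort is identical.
#'
#' @param params A [sim_params()] object.
#' @return A `warf_cohort` with an attached `sim_params` attribute.
#' @export
#' @examples
#' cohort <- simulate_cohort(sim_params(n = 20, seed = 42))
#' summarize_cohort(cohort)
simulate_cohort <- function(params = sim_params()) {
  if (!is.null(params$seed)) {
    return(withr::with_seed(params$seed, simulate_cohort_impl(params)))
  }
  simulate_cohort_impl(params)
}

simulate_cohort_impl <- function(params) {
  n <- params$n
  coeffs <- params$pgx_coeffs %||% iwpc_coefficients("pgx")
  sex <- sample(sex_levels, n, replace = TRUE,
    prob = c(params$male_prob, 1 - params$male_prob)
  )
  age <- round(rnorm_trunc(n, params$age_mean, params$age_sd, params$age_range), 1)
  height <- round(rnorm(n, params$height_mean[sex], params$height_sd), 1)
  bmi <- rnorm_trunc(n, params$bmi_mean, params$bmi_sd, params$bmi_range)
  weight <- round(bmi * (height / 100)^2, 1)
  cyp2c9 <- sample(names(params$cyp2c9_probs), n,
    replace = TRUE, prob = params$cyp2c9_probs
  )
  vkorc1 <- sample(names(params$vkorc1_probs), n,
    replace = TRUE, prob = params$vkorc1_probs
  )
  high_target <- runif(n) < params$high_target_prob
  base <- tibble::tibble(
    id = sprintf("P%03d", seq_len(n)),
    sex = sex, age = age, height = height, weight = weight,
    race = "white",
    enzyme_inducer = runif(n) < params$inducer_prob,
    amiodarone = runif(n) < params$amiodarone_prob,
    cyp2c9 = cyp2c9, vkorc1 = vkorc1,
    target_inr_low = ifelse(high_target, 2.5, 2.0),
    target_inr_high = ifelse(high_target, 3.5, 3.0),
    indication = sample(names(params$indication_probs), n,
      replace = TRUE, prob = params$indication_probs
    )
  )

  lp <- iwpc_linear_predictor(base, coeffs, genetic = TRUE)
  sqrt_wsd <- lp + rnorm(n, 0, params$dose_noise_sd)
  wsd <- pmax(pmax(sqrt_wsd, 0)^2, params$wsd_floor)
  predicted <- pmax(lp, 0)^2

  # Bleeding risk rises with the relative excess of the empirical dose over
  # the pharmacogenetically predicted dose.
  rde <- (wsd - predicted) / predicted
  p_bleed <- plogis(params$bleeding_intercept + params$bleeding_slope * rde)
  bled <- runif(n) < p_bleed
  severity <- ifelse(runif(n) < params$minor_fraction, "minor", "major")
  bleeding <- ifelse(bled, severity, "none")

  inr_to_pt <- function(i) params$inr$pt_normal * i^(1 / params$inr$isi)
  visits <- purrr::pmap(
    list(wsd, base$target_inr_low, base$target_inr_high),
    function(w, lo, hi) {
      k <- sample_one(params$titration_visits)
      m <- sample_one(params$stable_visits)
      tit_doses <- head(c(
        35,
        round_half_mg((35 + w) / 2),
        round_half_mg(w * runif(1, 0.7, 1.3))
      ), k)
      tit_inr <- runif(k, 1.0, lo - 0.1)
      mid <- (lo + hi) / 2
      st_inr <- pmin(pmax(mid + rnorm(m, 0, params$inr_noise_sd), lo), hi)
      inr_raw <- c(tit_inr, st_inr)
      pt <- inr_to_pt(inr_raw)
      tibble::tibble(
        visit = seq_len(k + m),
        weekly_dose = c(tit_doses, rep(w, m)),
        pt_seconds = pt,
        inr = inr_from_pt(pt, params$inr)
      )
    }
  )
  base$bleeding <- bleeding
  base$visits <- visits
  cohort <- as_cohort(base, inr_params = params$inr)
  attr(cohort, "sim_params") <- params
  cohort
}

# sample() treats a length-1 numeric x as 1:x; always sample from the set.
sample_one <- function(x) {
  if (length(x) == 1) x else sample(x, 1)
}

fragment_patterns <- function(cyp2c9, vkorc1) {
  star2 <- c("*1/*1" = 0, "*1/*2" = 1, "*1/*3" = 0, "*2/*2" = 2,
    "*2/*3" = 1, "*3/*3" = 0)[cyp2c9]
  star3 <- c("*1/*1" = 0, "*1/*2" = 0, "*1/*3" = 1, "*2/*2" = 0,
    "*2/*3" = 1, "*3/*3" = 2)[cyp2c9]
  avaii <- c("397,57", "454,397,57", "454")[star2 + 1]
  kpni <- c("105", "105,85,20", "85,20")[star3 + 1]
  mspi <- c(GG = "167,123", GA = "290,167,123", AA = "290")[vkorc1]
  list(CYP2C9_star2_AvaII = avaii, CYP2C9_star3_KpnI = kpni,
    VKORC1_1639_MspI = mspi)
}

#' Generate a complete fixture file set from the simulator
#'
#' Simulates a cohort and writes the three pipeline input files: the patient
#' CSV, the long-format visits CSV, and an RFLP fragment CSV whose band
#' patterns are consistent with each patient's genotypes (so genotype calling
#' on the fragment file reproduces the generating genotypes exactly).
#' Regenerating with the same seed produces byte-identical files.
#'
#' @param params A [sim_params()] object.
#' @param dir Output directory (created if absent).
#' @return Invisibly, a named vector of the three file paths.
#' @export
generate_fixture_files <- function(params, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cohort <- simulate_cohort(params)
  paths <- c(
    patients = file.path(dir, "patients.csv"),
    visits = file.path(dir, "visits.csv"),
    fragments = file.path(dir, "fragments.csv")
  )
  write_cohort(cohort, paths[["patients"]], paths[["visits"]])
  pat <- fragment_patterns(cohort$cyp2c9, cohort$vkorc1)
  fragments <- tibble::tibble(
    id = rep(cohort$id, times = 3),
    assay = rep(names(pat), each = nrow(cohort)),
    fragments_bp = c(pat[[1]], pat[[2]], pat[[3]])
  )
  fragments <- dplyr::arrange(fragments, .data$id, .data$assay)
  readr::write_csv(fragments, paths[["fragments"]], progress = FALSE)
  invisible(paths)
}
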