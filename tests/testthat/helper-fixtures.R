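# In-code fixtures shared across test files.

# A visit tibble from parallel dose/INR vectors.
make_visits <- function(doses, inrs, pt = NA_real_) {
  tibble::tibble(
    visit = seq_along(doses),
    weekly_dose = doses,
    pt_seconds = rep_len(pt, length(doses)),
    inr = inrs
  )
}

# A small hand-built three-patient cohort with stable and unstable histories.
make_small_cohort <- function() {
  dplyr::bind_rows(
    patient_record(
      id = "A", sex = "male", age = 50, height = 170, weight = 70,
      cyp2c9 = "*1/*1", vkorc1 = "GG", bleeding = "none",
      visits = make_visits(c(35, 35, 35), c(2.2, 2.5, 2.4))
    ),
    patient_record(
      id = "B", sex = "female", age = 62.5, height = 158, weight = 82,
      cyp2c9 = "*1/*2", vkorc1 = "GA", bleeding = "minor",
      indication = "cardiovascular",
      visits = make_visits(c(35, 40, 45), c(1.5, 1.8, 2.1))
    ),
    patient_record(
      id = "C", sex = "female", age = 41, height = 164, weight = 60,
      cyp2c9 = "*1/*1", vkorc1 = "AA", bleeding = "major",
      indication = "both",
      visits = make_visits(c(30, 25, 25, 25, 25), c(3.4, 2.1, 2.4, 2.6, 2.5))
    )
  )
}

# The printed bleeding-by-dose-group contingency counts of the study.
study_bleeding_table <- function() {
  rbind(none = c(19, 25, 11), yes = c(23, 19, 2))
}

# The printed 20%-classification counts for the three models (stable n = 47).
study_classification <- function(model) {
  counts <- list(
    pgx = c(ideal = 32, underestimation = 12, overestimation = 3),
    clinical = c(ideal = 25, underestimation = 12, overestimation = 10),
    fixed = c(ideal = 21, underestimation = 15, overestimation = 11)
  )[[model]]
  structure(
    list(
      model = model, ideal = counts[["ideal"]],
      underestimation = counts[["underestimation"]],
      overestimation = counts[["overestimation"]],
      total = sum(counts)
    ),
    class = "warf_classification"
  )
}
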