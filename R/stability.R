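#' Determine the empirical warfarin stable dose from a visit history
#'
#' A patient has reached a warfarin stable dose (WSD) when they remained on
#' the same weekly dose for at least three consecutive visits with the INR in
#' the therapeutic target range at every visit of that run (inclusive bounds).
#' A visit with missing INR inside a candidate window disqualifies that window
#' but not the patient. When several windows qualify, the earliest one defines
#' the WSD, mirroring a prospective reading of the record.
#'
#' @param visits A visit tibble (`visit`, `weekly_dose`, `inr`, ...), ordered.
#' @param target Length-2 numeric `c(low, high)` or a list with `low`/`high`.
#' @param min_run Minimum run length (default 3 visits).
#' @return A list: `is_stable`, `wsd` (mg/week, `NA` if unstable),
#'   `window` (visit indices of the earliest qualifying run of `min_run`).
#' @export
#' @examples
#' v <- tibble::tibble(
#'   visit = 1:3, weekly_dose = c(35, 35, 35),
#'   pt_seconds = NA_real_, inr = c(2.2, 2.5, 2.4)
#' )
#' find_stable_dose(v, c(2, 3))
find_stable_dose <- function(visits, target, min_run = 3L) {
  if (is.list(target) && !is.null(target$low)) target <- c(target$low, target$high)
  low <- target[[1]]
  high <- target[[2]]
  n <- nrow(visits)
  if (n == 0) {
    abort("at least one visit is required", class = "warfpgx_degenerate")
  }
  ok <- !is.na(visits$inr) & visits$inr >= low & visits$inr <= high
  for (start in seq_len(max(0L, n - min_run + 1L))) {
    idx <- start:(start + min_run - 1L)
    doses <- visits$weekly_dose[idx]
    if (length(unique(doses)) == 1L && all(ok[idx])) {
      return(list(
        is_stable = TRUE,
        wsd = doses[1],
        window = visits$visit[idx]
      ))
    }
  }
  list(is_stable = FALSE, wsd = NA_real_, window = integer())
}

#' Stable-dose determination for a whole cohort
#'
#' Applies [find_stable_dose()] to every patient using their own target INR
#' range.
#'
#' @param cohort A `warf_cohort`.
#' @param min_run Minimum run length (default 3 visits).
#' @return A tibble `id, is_stable, wsd, window_start`.
#' @export
stable_doses <- function(cohort, min_run = 3L) {
  res <- purrr::pmap(
    list(cohort$visits, cohort$target_inr_low, cohort$target_inr_high),
    function(v, lo, hi) {
      if (nrow(v) == 0) {
        return(list(is_stable = FALSE, wsd = NA_real_, window = integer()))
      }
      find_stable_dose(v, c(lo, hi), min_run = min_run)
    }
  )
  tibble::tibble(
    id = cohort$id,
    is_stable = purrr::map_lgl(res, "is_stable"),
    wsd = purrr::map_dbl(res, "wsd"),
    window_start = purrr::map_int(res, function(r) {
      if (length(r$window) > 0) as.integer(r$window[1]) else NA_integer_
    })
  )
}

#' Group an actual dose relative to a model-calculated dose
#'
#' Classifies the given therapeutic dose as higher than, the same as, or
#' lower than the calculated dose. "Same" means the relative difference to
#' the predicted dose is below `tolerance`; the 20% band mirrors the
#' clinically-relevant threshold used for the dose classification (about
#' 1 mg/day against a 5 mg/day starting dose).
#'
#' @param actual Given weekly dose(s), mg/week (> 0).
#' @param predicted Calculated weekly dose(s), mg/week (> 0).
#' @param tolerance Relative half-width of the "same" band (default 0.20).
#' @return Character vector in `c("higher", "same", "lower")`.
#' @export
dose_group_vs_predicted <- function(actual, predicted, tolerance = 0.20) {
  if (any(actual <= 0 | predicted <= 0, na.rm = TRUE)) {
    abort("doses must be positive", class = "warfpgx_record_error")
  }
  rel <- (actual - predicted) / predicted
  dplyr::case_when(
    abs(rel) < tolerance ~ "same",
    rel >= tolerance ~ "higher",
    TRUE ~ "lower"
  )
}

#' Bleeding-by-dose-group contingency table
#'
#' Cross-tabulates ever-bleeding (minor or major at least once) against the
#' patient's given therapeutic dose grouped as higher/same/lower than the
#' model-calculated dose. The given dose is the weekly dose at the last
#' recorded visit; patients without a bleeding record or without visits are
#' omitted (as in registry data with incomplete records).
#'
#' @param cohort A `warf_cohort`.
#' @param predictions A tibble `id, weekly_dose` of calculated doses for one
#'   model (e.g. the `pgx` rows of [predict_weekly_doses()]).
#' @param tolerance Relative band for "same" (default 0.20).
#' @return A 2 x 3 integer matrix, rows `none`/`yes`, columns
#'   `higher`/`same`/`lower`.
#' @export
bleeding_contingency <- function(cohort, predictions, tolerance = 0.20) {
  given <- purrr::map_dbl(cohort$visits, function(v) {
    if (nrow(v) == 0) NA_real_ else v$weekly_dose[nrow(v)]
  })
  df <- tibble::tibble(id = cohort$id, bleeding = cohort$bleeding, given = given)
  df <- dplyr::inner_join(df, predictions[, c("id", "weekly_dose")], by = "id")
  df <- df[!is.na(df$bleeding) & !is.na(df$given) & df$given > 0, ]
  out <- matrix(0L, 2, 3, dimnames = list(
    bleeding = c("none", "yes"), dose_group = dose_group_levels
  ))
  if (nrow(df) == 0) {
    return(out)
  }
  grp <- factor(dose_group_vs_predicted(df$given, df$weekly_dose, tolerance),
    levels = dose_group_levels
  )
  bled <- factor(ifelse(df$bleeding == "none", "none", "yes"),
    levels = c("none", "yes")
  )
  tab <- table(bled, grp)
  out[] <- as.integer(tab)
  out
}
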