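# Per-birthday residence flags: regional police records only cover crimes
# committed in the force area, so analyses need to know who was living
# there at each age to define an appropriate denominator.

#' Per-birthday residence flags
#'
#' For each participant and each age in `ages`, the flag is TRUE when an
#' address interval covering that birthday has an in-area postcode. A
#' birthday on an interval boundary counts as covered by the interval
#' ending that day. A birthday covered by no interval gives FALSE plus a
#' coverage-gap marker — absence of address data is not evidence of
#' absence from the area.
#'
#' @param cohort Cohort tibble with `study_id`, `dob` and the `addresses`
#'   list-column (`postcode`, `from_date`, `to_date`).
#' @param area_predicate Function mapping full postcodes to logical
#'   in-area. Defaults to the synthetic gazetteer's predicate.
#' @param ages Integer vector of birthdays to flag.
#' @return A tibble with `study_id` and, per age k, `age<k>` (logical) and
#'   `gap<k>` (TRUE when no interval covered that birthday).
#' @export
residence_flags <- function(cohort,
                            area_predicate = synthetic_area_predicate(),
                            ages = 10:28) {
  if (anyNA(cohort$dob)) {
    abort("missing dob", class = "crimelink_validation_error")
  }
  flag_cols <- paste0("age", ages)
  gap_cols <- paste0("gap", ages)
  out <- tibble::tibble(study_id = cohort$study_id)
  flags <- matrix(FALSE, nrow(cohort), length(ages))
  gaps <- matrix(FALSE, nrow(cohort), length(ages))
  for (i in seq_len(nrow(cohort))) {
    addr <- cohort$addresses[[i]]
    stopifnot(all(addr$from_date <= addr$to_date))
    in_area <- area_predicate(addr$postcode)
    for (j in seq_along(ages)) {
      bday <- add_years(cohort$dob[i], ages[j])
      covering <- addr$from_date <= bday & bday <= addr$to_date
      if (!any(covering)) {
        gaps[i, j] <- TRUE
      } else {
        flags[i, j] <- any(in_area[covering])
      }
    }
  }
  for (j in seq_along(ages)) {
    out[[flag_cols[j]]] <- flags[, j]
    out[[gap_cols[j]]] <- gaps[, j]
  }
  out
}

# k-th birthday; a 29 Feb birth observed on 28 Feb in non-leap years.
add_years <- function(dob, k) {
  y <- lubridate::year(dob) + k
  m <- lubridate::month(dob)
  d <- lubridate::day(dob)
  out <- as.Date(sprintf("%04d-%02d-%02d", y, m, d), format = "%Y-%m-%d")
  feb29 <- is.na(out) & m == 2L & d == 29L
  if (any(feb29)) out[feb29] <- as.Date(sprintf("%04d-02-28", y[feb29]))
  out
}

#' Denominator summary from residence flags
#'
#' @param flags Output of [residence_flags()].
#' @return A list with `by_age` (tibble: age, proportion in-area) and
#'   `all_ages` (proportion in-area on every birthday in the flag range).
#' @export
denominator_summary <- function(flags) {
  age_cols <- grep("^age[0-9]+$", names(flags), value = TRUE)
  by_age <- tibble::tibble(
    age = as.integer(sub("^age", "", age_cols)),
    proportion = vapply(age_cols, function(cl) mean(flags[[cl]]),
                        numeric(1))
  ) |> arrange(.data$age)
  all_flag <- rowSums(!as.matrix(flags[age_cols])) == 0L
  list(by_age = by_age, all_ages = mean(all_flag))
}
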