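# Stage 1, step one: deterministic matching. Forename, surname and date of
# birth must be identical (after normalisation); postcodes are then used
# only to grade how strong each exact match is.

#' Match-strength tier from the two address sets
#'
#' For a pair already matched exactly on names and date of birth, the
#' postcode tiers are: 1 when any full postcode is shared between the
#' cohort's (current and historical) addresses and the subject's, 2 when
#' only an outward (post-town) code is shared, 3 when the address sets are
#' disjoint. The best tier across all address pairs wins.
#'
#' @param cohort_postcodes,subject_postcodes Character vectors of full
#'   postcodes, or lists of such vectors (one element per pair).
#' @return Integer vector of strengths in \{1, 2, 3\}.
#' @examples
#' assign_match_strength("ZA1 2CD", c("ZA1 2CD", "ZX9 1AA"))  # 1
#' assign_match_strength("ZA1 2CD", "ZA1 9ZZ")                # 2
#' @export
assign_match_strength <- function(cohort_postcodes, subject_postcodes) {
  if (!is.list(cohort_postcodes)) cohort_postcodes <- list(cohort_postcodes)
  if (!is.list(subject_postcodes)) subject_postcodes <- list(subject_postcodes)
  n <- max(length(cohort_postcodes), length(subject_postcodes))
  cohort_postcodes <- rep_len(cohort_postcodes, n)
  subject_postcodes <- rep_len(subject_postcodes, n)
  vapply(seq_len(n), function(i) {
    tier <- postcode_tier_similarity(cohort_postcodes[[i]],
                                     subject_postcodes[[i]])
    if (is.na(tier)) 3L else if (tier == 1) 1L else if (tier == 0.5) 2L else 3L
  }, integer(1))
}

# Flatten a cohort's address list-column to one postcode vector per person.
cohort_postcode_sets <- function(cohort) {
  purrr::map(cohort$addresses, function(a) unique(a$postcode))
}

#' Deterministic linkage on forename, surname and date of birth
#'
#' Emits one candidate per (study_id, offender_id) pair whose normalised
#' forename, surname and date of birth are all identical, graded by
#' [assign_match_strength()]. Current and historical postcodes on both
#' sides participate in the strength tier.
#'
#' @param cohort Cohort tibble ([generate_cohort()] layout).
#' @param subjects Subject register tibble.
#' @return A candidate tibble: `study_id`, `offender_id`, `method`
#'   (`"deterministic"`), `strength`, `score` (NA), exact-agreement columns
#'   (`forename_exact`, `surname_exact`, `dob_exact`, all TRUE by
#'   construction), `postcode_full`, `postcode_outward`, and `status`
#'   (`"accepted"`). Empty inputs give an empty tibble.
#' @export
deterministic_link <- function(cohort, subjects) {
  empty <- tibble::tibble(
    study_id = character(), offender_id = character(),
    method = character(), strength = integer(), score = numeric(),
    forename_exact = logical(), surname_exact = logical(),
    dob_exact = logical(), postcode_full = logical(),
    postcode_outward = logical(), status = character()
  )
  if (nrow(cohort) == 0L || nrow(subjects) == 0L) return(empty)

  ckey <- cohort |>
    mutate(key = paste(normalise_name(.data$forename),
                       normalise_name(.data$surname),
                       .data$dob, sep = "|"),
           cpc = cohort_postcode_sets(cohort)) |>
    select("study_id", "key", "cpc")
  skey <- subjects |>
    mutate(key = paste(normalise_name(.data$forename),
                       normalise_name(.data$surname),
                       .data$dob, sep = "|")) |>
    select("offender_id", "key", spc = "postcodes")

  pairs <- inner_join(ckey, skey, by = "key", relationship = "many-to-many")
  if (nrow(pairs) == 0L) return(empty)

  pairs |>
    mutate(
      method = "deterministic",
      strength = assign_match_strength(.data$cpc, .data$spc),
      score = NA_real_,
      forename_exact = TRUE, surname_exact = TRUE, dob_exact = TRUE,
      postcode_full = .data$strength == 1L,
      postcode_outward = .data$strength <= 2L,
      status = "accepted"
    ) |>
    select(-"key", -"cpc", -"spc") |>
    arrange(.data$study_id, .data$offender_id)
}
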