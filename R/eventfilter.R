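# Stage 2: select event records with an eligible disposal. Outcome codes
# are offence-level, so they identify the disposal only for single-offender
# crimes; group crimes are judged on each offender's own concatenated
# classification terms.

.valid_oc <- paste0("OC", 1:22)
.eligible_oc <- c("OC1", "OC2", "OC3", "OC4", "OC6", "OC7", "OC8")
.eligible_terms <- c(
  "charged", "tic", "cautioned", "adult conditional caution",
  "postal requisition", "reported for summons", "cannabis warning",
  "penalty notice for disorder", "community resolution", "prosecuted"
)

#' Disposal eligibility for single-offender crimes
#'
#' Eligible outcome codes are OC1 (charged), OC2-3 (cautioned), OC4 (taken
#' into consideration), OC6 (penalty notice for disorder), OC7 (cannabis
#' warning) and OC8 (community resolution).
#'
#' @param outcome_code Character vector of Home Office outcome codes
#'   (`"OC1"`..`"OC22"`).
#' @return Logical vector.
#' @examples
#' is_eligible_single(c("OC1", "OC5", "OC8"))
#' @export
is_eligible_single <- function(outcome_code) {
  bad <- !outcome_code %in% .valid_oc
  if (any(bad)) {
    abort(sprintf("unknown outcome code(s): %s",
                  paste(unique(outcome_code[bad]), collapse = ", ")),
          class = "crimelink_validation_error")
  }
  outcome_code %in% .eligible_oc
}

#' Disposal eligibility for group crimes
#'
#' A group-crime record is eligible when the offender's own concatenated
#' classification contains at least one eligible term: charged, TIC,
#' cautioned, adult conditional caution, postal requisition, reported for
#' summons, cannabis warning, penalty notice for disorder, community
#' resolution, or the legacy term "prosecuted" (used before the
#' recording-platform change for TICs and out-of-court disposals, and
#' honoured whenever present). Matching is whole-term after splitting on
#' ";", never substring — "discharged" must not satisfy "charged".
#'
#' @param classification_terms Character vector of "; "-concatenated term
#'   strings, or a list of term character vectors.
#' @param event_date,era_boundary Unused in the decision (the legacy term
#'   is honoured whenever present) but accepted so callers can assert
#'   era-consistency.
#' @return Logical vector.
#' @examples
#' is_eligible_group("suspect; arrested; charged")
#' is_eligible_group("suspect; eliminated")
#' @export
is_eligible_group <- function(classification_terms, event_date = NULL,
                              era_boundary = as.Date("2015-09-01")) {
  terms <- if (is.list(classification_terms)) {
    purrr::map(classification_terms, function(t) trimws(tolower(t)))
  } else {
    split_terms(classification_terms)
  }
  vapply(terms, function(t) any(t %in% .eligible_terms), logical(1))
}

#' Filter events to eligible records of linked individuals
#'
#' Joins the event table to the link table (events of unlinked offender
#' ids are dropped), then applies [is_eligible_single()] to single-offender
#' crimes and [is_eligible_group()] to group crimes. Output rows are keyed
#' by (study_id, occurrence_id): one record per linked individual per
#' crime.
#'
#' @param events Event tibble ([generate_events()] layout).
#' @param link_table A `link_table` or a tibble of `study_id`,
#'   `offender_id`.
#' @return The eligible events with `study_id` attached.
#' @export
filter_events <- function(events, link_table) {
  links <- if (inherits(link_table, "link_table")) {
    link_table$links
  } else {
    link_table
  }
  if (any(events$offender_count < 1L)) {
    abort("offender_count must be a positive integer",
          class = "crimelink_validation_error")
  }
  # accept already-joined input (filtering is idempotent)
  events <- select(events, -dplyr::any_of("study_id"))
  linked <- events |>
    inner_join(distinct(select(links, "study_id", "offender_id")),
               by = "offender_id")
  if (nrow(linked) == 0L) {
    return(mutate(linked, eligible = logical(0)) |> select(-"eligible"))
  }
  single <- linked$offender_count == 1L
  keep <- logical(nrow(linked))
  keep[single] <- is_eligible_single(linked$outcome_code[single])
  keep[!single] <- is_eligible_group(linked$classification_terms[!single])
  linked |>
    filter(keep) |>
    select("study_id", dplyr::everything()) |>
    arrange(.data$study_id, .data$occurrence_id)
}

#' Records, offences and individuals in a filtered event table
#'
#' A record is one row (one individual's involvement in one crime); an
#' offence is a distinct occurrence; group crimes with several linked
#' participants therefore yield more records than offences.
#'
#' @param filtered Output of [filter_events()].
#' @return One-row tibble: `n_records`, `n_offences`, `n_individuals`.
#' @export
count_records_and_offences <- function(filtered) {
  tibble::tibble(
    n_records = nrow(filtered),
    n_offences = dplyr::n_distinct(filtered$occurrence_id),
    n_individuals = dplyr::n_distinct(filtered$study_id)
  )
}
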