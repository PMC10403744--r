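# Worked arithmetic on linkage flow counts and offence-group tabulations.
# These helpers operate on plain published-style counts (tier totals,
# distinct-id totals, group tabulations), so a flow chart or summary table
# can be checked or reproduced without the underlying records.

#' Linkage flow arithmetic from summary counts
#'
#' From deterministic tier counts, the probabilistic match total, the
#' number of individuals fragmented across two offender ids and the
#' linkage-permitted denominator, derives the quantities a linkage flow
#' chart reports: the deterministic total, the probabilistic additions,
#' the distinct linked individuals (offender ids minus the fragmented
#' surplus) and the percentage of the permitted sample linked to at least
#' one eligible record.
#'
#' @param tier_counts Numeric vector of deterministic match counts at
#'   strengths 1, 2, 3.
#' @param probabilistic_total Total offender ids matched after the
#'   probabilistic stage (superset of the deterministic matches).
#' @param fragmented_individuals Individuals holding two offender ids.
#' @param n_permitted Participants with permission to link.
#' @param n_linked_with_records Individuals linked to at least one
#'   eligible event record (may be fewer than linked individuals).
#' @return One-row tibble: `deterministic_total`,
#'   `probabilistic_additions`, `distinct_individuals`, `pct_linked`.
#' @examples
#' linkage_flow_arithmetic(c(956, 403, 517), 2292, 19, 12662, 1757)
#' @export
linkage_flow_arithmetic <- function(tier_counts, probabilistic_total,
                                    fragmented_individuals, n_permitted,
                                    n_linked_with_records) {
  stopifnot(length(tier_counts) == 3L, all(tier_counts >= 0))
  det <- sum(tier_counts)
  if (probabilistic_total < det) {
    abort("probabilistic total cannot be below the deterministic total",
          class = "crimelink_validation_error")
  }
  tibble::tibble(
    deterministic_total = det,
    probabilistic_additions = probabilistic_total - det,
    distinct_individuals = probabilistic_total - fragmented_individuals,
    pct_linked = 100 * n_linked_with_records / n_permitted
  )
}

#' Offence-group shares from counts
#'
#' @param counts Named numeric vector (or tibble with `offence_group` and
#'   `n`) of record counts by offence group.
#' @param total Denominator; defaults to `sum(counts)`.
#' @param digits Decimal places for the printed share (default 1).
#' @return A tibble: `offence_group`, `n`, `share` (percent, rounded to
#'   `digits`).
#' @examples
#' offence_group_shares(c(`Drug offences` = 1237, Theft = 1077), 6413)
#' @export
offence_group_shares <- function(counts, total = NULL, digits = 1) {
  if (is.data.frame(counts)) {
    tbl <- tibble::tibble(offence_group = counts$offence_group,
                          n = counts$n)
  } else {
    tbl <- tibble::tibble(offence_group = names(counts),
                          n = as.numeric(counts))
  }
  total <- total %||% sum(tbl$n)
  tbl |>
    mutate(share = round(100 * .data$n / total, digits)) |>
    arrange(dplyr::desc(.data$n))
}
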