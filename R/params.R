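#' Synthetic-generator parameters
#'
#' Builds and validates the parameter set controlling the synthetic cohort,
#' police register and event table. The defaults describe the study
#' conditions the generator emulates: a birth cohort of 12,662 participants
#' with linkage permission born 1991-01-01 to 1993-01-31, a police register
#' covering everyone born in that window in the force area, roughly 18% of
#' the cohort appearing in the register, about 1% of offending members
#' fragmented across two offender identities, and identifier corruption at
#' the rates the review-stage evaluation assumes (2% typos, 5% name
#' variants, 20% stale addresses).
#'
#' @param n_cohort Number of cohort members.
#' @param n_background Number of non-cohort decoy subjects in the register.
#' @param offending_rate Fraction of cohort members holding at least one
#'   offender identity.
#' @param fragmentation_rate Fraction of offending members split across two
#'   offender identities.
#' @param twin_rate Fraction of cohort members who are part of a twin pair
#'   (co-twins share surname and date of birth).
#' @param name_variant_rate Probability that a register forename is the
#'   short/formal counterpart of the cohort form (nickname table).
#' @param typo_rate Probability of a single-character edit in a register
#'   name field.
#' @param stale_address_rate Probability that the register postcode is a new
#'   address absent from the cohort-held address history.
#' @param group_crime_rate Fraction of offences involving multiple offenders.
#' @param events_per_offender Mean of the (zero-truncated, overdispersed)
#'   count of crime records per offender identity.
#' @param in_area_rate Probability a cohort family's first address lies in
#'   the policing area.
#' @param move_out_hazard Annual probability, from age 18, of moving out of
#'   the policing area.
#' @param era_boundary Date the police recording platform changed; group
#'   crime records before it use the legacy term "prosecuted" for TICs and
#'   out-of-court disposals.
#' @param electronic_start First date with electronic records; earlier
#'   events are paper-era and dropped at `pre_electronic_drop`.
#' @param court_data_start First date with Magistrates' Court case fields.
#' @param extraction_date Date of the police extract; retention review is a
#'   single sweep at this date and no events occur after it.
#' @param pre_electronic_drop Probability a paper-era (pre
#'   `electronic_start`) record was never transferred to the electronic
#'   system. The true survival rate of paper records is unknowable, so this
#'   is a free parameter; the default drops them all.
#' @param dob_window Two dates bounding cohort dates of birth.
#' @param seed Integer seed; fully determines all generated output.
#' @return A validated list of class `synth_params`.
#' @examples
#' p <- synth_params(n_cohort = 500, n_background = 200, seed = 1)
#' p$offending_rate
#' @export
synth_params <- function(n_cohort = 12662,
                         n_background = 10000,
                         offending_rate = 0.18,
                         fragmentation_rate = 0.01,
                         twin_rate = 0.02,
                         name_variant_rate = 0.05,
                         typo_rate = 0.02,
                         stale_address_rate = 0.20,
                         group_crime_rate = 0.22,
                         events_per_offender = 3,
                         in_area_rate = 0.90,
                         move_out_hazard = 0.03,
                         era_boundary = as.Date("2015-09-01"),
                         electronic_start = as.Date("2007-01-01"),
                         court_data_start = as.Date("2015-11-01"),
                         extraction_date = as.Date("2021-07-01"),
                         pre_electronic_drop = 1.0,
                         dob_window = as.Date(c("1991-01-01", "1993-01-31")),
                         seed = 1L) {
  p <- list(
    n_cohort = as.integer(n_cohort), n_background = as.integer(n_background),
    offending_rate = offending_rate, fragmentation_rate = fragmentation_rate,
    twin_rate = twin_rate, name_variant_rate = name_variant_rate,
    typo_rate = typo_rate, stale_address_rate = stale_address_rate,
    group_crime_rate = group_crime_rate,
    events_per_offender = events_per_offender,
    in_area_rate = in_area_rate, move_out_hazard = move_out_hazard,
    era_boundary = as.Date(era_boundary),
    electronic_start = as.Date(electronic_start),
    court_data_start = as.Date(court_data_start),
    extraction_date = as.Date(extraction_date),
    pre_electronic_drop = pre_electronic_drop,
    dob_window = as.Date(dob_window), seed = as.integer(seed)
  )
  rates <- c(
    "offending_rate", "fragmentation_rate", "twin_rate", "name_variant_rate",
    "typo_rate", "stale_address_rate", "group_crime_rate", "in_area_rate",
    "move_out_hazard", "pre_electronic_drop"
  )
  for (r in rates) {
    v <- p[[r]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      abort(sprintf("`%s` must be a single number in [0, 1], got %s",
                    r, format(v)), class = "crimelink_param_error")
    }
  }
  if (p$n_cohort < 1L) {
    abort("`n_cohort` must be at least 1", class = "crimelink_param_error")
  }
  if (p$n_background < 0L) {
    abort("`n_background` must be non-negative",
          class = "crimelink_param_error")
  }
  if (p$events_per_offender <= 0) {
    abort("`events_per_offender` must be positive",
          class = "crimelink_param_error")
  }
  if (length(p$dob_window) != 2L || any(is.na(p$dob_window)) ||
      p$dob_window[1] > p$dob_window[2]) {
    abort("`dob_window` must be two ordered dates",
          class = "crimelink_param_error")
  }
  if (is.na(p$seed)) {
    abort("`seed` must be an integer", class = "crimelink_param_error")
  }
  structure(p, class = "synth_params")
}

#' @export
print.synth_params <- function(x, ...) {
  cat("<synth_params>\n")
  cat(sprintf("  cohort %d + %d background; offending %.2f, fragmentation %.2f\n",
              x$n_cohort, x$n_background, x$offending_rate,
              x$fragmentation_rate))
  cat(sprintf("  corruption: typo %.2f, variant %.2f, stale address %.2f\n",
              x$typo_rate, x$name_variant_rate, x$stale_address_rate))
  cat(sprintf("  dates: dob %s..%s, electronic from %s, extract %s\n",
              x$dob_window[1], x$dob_window[2], x$electronic_start,
              x$extraction_date))
  cat(sprintf("  seed %d\n", x$seed))
  invisible(x)
}

# Derive a stream-specific RNG seed from the master seed so that stages are
# reproducible independently of each other. Kept below 2^31.
stream_seed <- function(seed, stream) {
  offsets <- c(cohort = 11L, register = 223L, events = 3301L,
               pipeline = 44011L)
  (as.integer(seed) * 7919L + offsets[[stream]]) %% 2147483647L
}
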