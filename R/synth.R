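# Synthetic cohort / police-register / event-table generator with ground
# truth. Every corruption process the linkage stages must absorb (nickname
# variants, typos, stale postcodes, shared twin identifiers, offender-id
# fragmentation, group crimes, era-dependent disposal terminology, paper-era
# left-censoring, retention deletion) is generated here at configurable
# rates, so downstream precision/recall can be measured exactly.

new_id <- function(prefix, n, width = 6) {
  sprintf(paste0(prefix, "%0", width, "d"), seq_len(n))
}

# One random single-character substitution (never a no-op).
typo_edit <- function(x) {
  vapply(x, function(s) {
    if (nchar(s) == 0L) return(s)
    i <- sample.int(nchar(s), 1L)
    old <- substr(s, i, i)
    repl <- sample(setdiff(LETTERS, old), 1L)
    paste0(substr(s, 1L, i - 1L), repl, substr(s, i + 1L, nchar(s)))
  }, character(1), USE.NAMES = FALSE)
}

# Swap a forename with its nickname-table counterpart where one exists.
nickname_swap <- function(x) {
  fi <- match(x, .nickname_pairs[, "formal"])
  si <- match(x, .nickname_pairs[, "short"])
  out <- x
  out[!is.na(fi)] <- .nickname_pairs[fi[!is.na(fi)], "short"]
  out[!is.na(si)] <- .nickname_pairs[si[!is.na(si)], "formal"]
  unname(out)
}

# Residential history from birth to extraction: contiguous spells, the first
# in the policing area with probability `in_area_rate`; childhood moves stay
# within the current stratum, moves from age 18 leave the area with a fixed
# probability, reproducing the gradual loss of in-area residency through the
# twenties. Twins inherit their co-twin's childhood history (shared
# household), which is what makes twin false links plausible downstream.
address_history <- function(dob, extraction_date, in_area_rate) {
  n_moves <- min(stats::rpois(1L, 1.2), 4L)
  move_ages <- sort(stats::runif(n_moves, 2, 28))
  starts <- c(dob, dob + round(move_ages * 365.25))
  starts <- unique(starts[starts < extraction_date])
  in_area <- stats::runif(1) < in_area_rate
  strata <- logical(length(starts))
  strata[1] <- in_area
  if (length(starts) > 1L) {
    for (k in 2:length(starts)) {
      age_at_move <- as.numeric(starts[k] - dob) / 365.25
      strata[k] <- if (age_at_move >= 18 && strata[k - 1]) {
        stats::runif(1) >= 0.35
      } else {
        strata[k - 1]
      }
    }
  }
  ends <- c(starts[-1] - 1, extraction_date)
  tibble::tibble(
    postcode = vapply(strata, function(s) sample_postcodes(1L, s),
                      character(1)),
    from_date = starts,
    to_date = ends
  )
}

#' Generate a synthetic cohort roster
#'
#' Builds `n_cohort` participants with forename, surname, date of birth
#' (uniform over `dob_window`), sex, a residential address history of
#' non-overlapping chronological spells, a twin-group label shared by
#' co-twins (who also share surname and date of birth, and childhood
#' addresses), and a linkage-permission flag. Output is fully determined by
#' `params$seed`.
#'
#' @param params A [synth_params()] object.
#' @return A tibble with one row per participant: `study_id`, `forename`,
#'   `surname`, `dob`, `sex`, `twin_group` (NA for singletons),
#'   `linkage_permitted`, and list-column `addresses` (tibbles with
#'   `postcode`, `from_date`, `to_date`).
#' @examples
#' cohort <- generate_cohort(synth_params(n_cohort = 50, seed = 7))
#' cohort$addresses[[1]]
#' @export
generate_cohort <- function(params) {
  stopifnot(inherits(params, "synth_params"))
  set.seed(stream_seed(params$seed, "cohort"))
  n <- params$n_cohort

  sex <- sample(c("F", "M"), n, replace = TRUE)
  forename <- ifelse(
    sex == "F",
    sample(.forenames_f, n, replace = TRUE, prob = .zipf(length(.forenames_f))),
    sample(.forenames_m, n, replace = TRUE, prob = .zipf(length(.forenames_m)))
  )
  surname <- sample(.surnames, n, replace = TRUE,
                    prob = .zipf(length(.surnames)))
  dob <- params$dob_window[1] +
    sample.int(as.integer(diff(params$dob_window)) + 1L, n, replace = TRUE) - 1L

  twin_group <- rep(NA_character_, n)
  n_pairs <- floor(n * params$twin_rate / 2)
  if (n_pairs > 0L) {
    members <- sample.int(n, 2L * n_pairs)
    a <- members[seq_len(n_pairs)]
    b <- members[n_pairs + seq_len(n_pairs)]
    twin_group[a] <- twin_group[b] <- new_id("T", n_pairs, 4)
    surname[b] <- surname[a]
    dob[b] <- dob[a]
    # co-twins never share a forename (parents name them apart), though
    # the names may still be similar enough to trouble the linkage
    clash <- forename[b] == forename[a]
    for (k in which(clash)) {
      pool <- if (sex[b[k]] == "F") .forenames_f else .forenames_m
      pool <- setdiff(pool, forename[a[k]])
      forename[b[k]] <- sample(pool, 1L, prob = .zipf(length(pool)))
    }
  }

  addresses <- purrr::map(seq_len(n), function(i) {
    address_history(dob[i], params$extraction_date, params$in_area_rate)
  })
  if (n_pairs > 0L) {
    a <- which(!is.na(twin_group))
    for (g in unique(twin_group[a])) {
      idx <- which(twin_group == g)
      # co-twins share the childhood household: copy spells starting before 18
      child <- addresses[[idx[1]]] |>
        filter(as.numeric(.data$from_date - dob[idx[1]]) / 365.25 < 18)
      adult <- addresses[[idx[2]]] |>
        filter(as.numeric(.data$from_date - dob[idx[2]]) / 365.25 >= 18)
      if (nrow(adult) > 0L) {
        # childhood (shared household) ends when the co-twin first moves
        # out; drop copied spells that start after that
        child <- filter(child, .data$from_date < adult$from_date[1])
        child$to_date[nrow(child)] <- adult$from_date[1] - 1
      }
      merged <- bind_rows(child, adult)
      merged$to_date[nrow(merged)] <- params$extraction_date
      if (nrow(merged) > 1L) {
        merged$to_date[-nrow(merged)] <- merged$from_date[-1] - 1
      }
      addresses[[idx[2]]] <- merged
    }
  }

  tibble::tibble(
    study_id = new_id("S", n),
    forename = forename,
    surname = surname,
    dob = dob,
    sex = sex,
    twin_group = twin_group,
    linkage_permitted = TRUE,
    addresses = addresses
  )
}

# Corrupt one register copy of a cohort member's identifiers.
corrupt_identifiers <- function(rec, params) {
  forename <- rec$forename
  surname <- rec$surname
  if (stats::runif(1) < params$name_variant_rate) {
    forename <- nickname_swap(forename)
  }
  if (stats::runif(1) < params$typo_rate) {
    if (stats::runif(1) < 0.5) forename <- typo_edit(forename)
    else surname <- typo_edit(surname)
  }
  current <- rec$addresses[[1]]$postcode[nrow(rec$addresses[[1]])]
  postcodes <- current
  if (stats::runif(1) < params$stale_address_rate) {
    # the person moved and the cohort-held history is out of date; half of
    # such moves are local (same post town, new inward code)
    if (stats::runif(1) < 0.5) {
      ow <- postcode_parts(current)$outward
      postcodes <- paste(ow, sub("^\\S+\\s", "", sample_postcodes(1L, TRUE)))
    } else {
      postcodes <- sample_postcodes(1L, in_area = TRUE)
    }
  } else if (nrow(rec$addresses[[1]]) > 1L && stats::runif(1) < 0.3) {
    postcodes <- c(current, rec$addresses[[1]]$postcode[1])
  }
  list(forename = forename, surname = surname, postcodes = list(postcodes))
}

#' Generate a synthetic police subject register with ground truth
#'
#' Each cohort member offends (appears in the register) independently with
#' probability `offending_rate`; a fraction `fragmentation_rate` of
#' offenders is split across two offender identities, emulating the police
#' marking one person as two. Register identifiers are corrupted copies of
#' the cohort identifiers (nickname variants, single-character typos, stale
#' postcodes at the configured rates). `n_background` decoy subjects drawn
#' from the same name and postcode pools, with dates of birth in the same
#' window, are added; they never appear in the ground truth.
#'
#' @param cohort A cohort tibble from [generate_cohort()].
#' @param params The same [synth_params()] object.
#' @return A list with `subjects` (tibble: `offender_id`, `forename`,
#'   `surname`, `dob`, `sex`, list-column `postcodes`) and `truth` (tibble:
#'   `study_id`, `offender_id`, one row per true link).
#' @export
generate_police_register <- function(cohort, params) {
  stopifnot(inherits(params, "synth_params"), nrow(cohort) > 0L)
  set.seed(stream_seed(params$seed, "register"))

  offends <- stats::runif(nrow(cohort)) < params$offending_rate
  offenders <- cohort[offends, , drop = FALSE]
  n_ids <- ifelse(stats::runif(nrow(offenders)) < params$fragmentation_rate,
                  2L, 1L)

  rows <- purrr::map(seq_len(nrow(offenders)), function(i) {
    rec <- offenders[i, ]
    purrr::map(seq_len(n_ids[i]), function(j) {
      corr <- corrupt_identifiers(rec, params)
      tibble::tibble(
        truth_study_id = rec$study_id,
        forename = corr$forename,
        surname = corr$surname,
        dob = rec$dob,
        sex = rec$sex,
        postcodes = corr$postcodes
      )
    }) |> bind_rows()
  }) |> bind_rows()

  nb <- params$n_background
  if (nb > 0L) {
    bsex <- sample(c("F", "M"), nb, replace = TRUE)
    bg <- tibble::tibble(
      truth_study_id = NA_character_,
      forename = ifelse(
        bsex == "F",
        sample(.forenames_f, nb, replace = TRUE,
               prob = .zipf(length(.forenames_f))),
        sample(.forenames_m, nb, replace = TRUE,
               prob = .zipf(length(.forenames_m)))),
      surname = sample(.surnames, nb, replace = TRUE,
                       prob = .zipf(length(.surnames))),
      dob = params$dob_window[1] +
        sample.int(as.integer(diff(params$dob_window)) + 1L, nb,
                   replace = TRUE) - 1L,
      sex = bsex,
      postcodes = purrr::map(stats::runif(nb) < 0.7, function(s) {
        sample_postcodes(1L, in_area = s)
      })
    )
    rows <- bind_rows(rows, bg)
  }

  rows <- rows[sample.int(nrow(rows)), , drop = FALSE]
  rows$offender_id <- new_id("O", nrow(rows))
  subjects <- rows |>
    select("offender_id", "forename", "surname", "dob", "sex", "postcodes")
  truth <- rows |>
    filter(!is.na(.data$truth_study_id)) |>
    select(study_id = "truth_study_id", "offender_id") |>
    arrange(.data$study_id, .data$offender_id)
  list(subjects = subjects, truth = truth)
}

# --- events ------------------------------------------------------------------

.offence_groups <- c(
  "Arson and criminal damage", "Burglary", "Drug offences", "Fraud",
  "Miscellaneous crimes against society", "Possession of weapons",
  "Public order offences", "Robbery", "Sexual offences", "Theft",
  "Vehicle offences", "Violence against the person"
)
.offence_group_weights <- c(
  0.127, 0.073, 0.193, 0.007, 0.025, 0.013, 0.107, 0.016, 0.007, 0.168,
  0.043, 0.224
)

# Disposal term for each eligible outcome code, and the ineligible pool.
.oc_terms <- c(
  OC1 = "charged", OC2 = "cautioned", OC3 = "adult conditional caution",
  OC4 = "tic", OC6 = "penalty notice for disorder", OC7 = "cannabis warning",
  OC8 = "community resolution"
)
.ineligible_oc <- paste0("OC", c(5, 9:22))
.ineligible_terms <- c(
  "eliminated", "insufficient evidence", "released without charge",
  "no further action", "victim declined"
)
# terms replaced by the legacy "prosecuted" before the recording-platform
# change: TICs and all out-of-court disposals (charges keep "charged")
.legacy_replaced <- setdiff(unname(.oc_terms), "charged")

sample_disposal <- function(n) {
  eligible <- stats::runif(n) < 0.55
  oc <- character(n)
  oc[eligible] <- sample(names(.oc_terms), sum(eligible), replace = TRUE,
                         prob = c(0.45, 0.12, 0.05, 0.08, 0.10, 0.08, 0.12))
  oc[!eligible] <- sample(.ineligible_oc, sum(!eligible), replace = TRUE)
  oc
}

oc_rank <- function(oc) as.integer(sub("^OC", "", oc))

#' Generate a synthetic crime event table
#'
#' One row per (occurrence, offender). A fraction `group_crime_rate` of
#' offences involves 2-4 offenders sharing one `occurrence_id`; those rows
#' share dates, offence code and the offence-level outcome code (the most
#' serious disposal in the group), while each offender's own disposal
#' appears in their concatenated classification terms. Events before
#' `era_boundary` use the legacy term "prosecuted" in place of TIC and
#' out-of-court disposal terms. Magistrates' Court case fields are populated
#' only for charged events reported after `court_data_start`. Ages at
#' offence peak in the late teens; the alcohol flag and court verdict carry
#' realistic (very high) missingness.
#'
#' @param subjects Subject register from [generate_police_register()].
#' @param params The same [synth_params()] object.
#' @return A tibble with columns `occurrence_id`, `offender_id`,
#'   `created_date`, `reported_date`, `from_date`, `ho_code`,
#'   `offence_group`, `offender_count`, `outcome_code`,
#'   `classification_terms` ("; "-concatenated), `da_flag`, `knife_flag`,
#'   `drugs_flag`, `alcohol_flag`, `substance_use`, `scorexmultiplier`,
#'   `mopi_group`, `casefile_id`, `casefile_date`, `verdict`.
#' @export
generate_events <- function(subjects, params) {
  stopifnot(inherits(params, "synth_params"), nrow(subjects) > 0L)
  set.seed(stream_seed(params$seed, "events"))

  mu <- max(params$events_per_offender - 1, 0.01)
  n_ev <- 1L + stats::rnbinom(nrow(subjects), size = 0.8, mu = mu)
  slot <- tibble::tibble(
    offender_id = rep(subjects$offender_id, n_ev),
    dob = rep(subjects$dob, n_ev)
  )
  n <- nrow(slot)

  # ages at offence: late-teens peak, truncated to [10, age at extraction]
  max_age <- as.numeric(params$extraction_date - slot$dob) / 365.25
  age <- pmin(pmax(stats::rnorm(n, mean = 19, sd = 4.5), 10), max_age - 0.05)
  slot$from_date <- slot$dob + round(age * 365.25)

  # group crimes: cluster a fraction of slots, across distinct offenders
  slot <- slot[sample.int(n), , drop = FALSE]
  occ <- integer(n)
  is_group <- stats::runif(n) < params$group_crime_rate
  next_occ <- 1L
  i <- 1L
  while (i <= n) {
    if (is_group[i]) {
      size <- sample(2:4, 1L)
      take <- i
      j <- i + 1L
      while (length(take) < size && j <= n) {
        if (occ[j] == 0L &&
            !slot$offender_id[j] %in% slot$offender_id[take]) {
          take <- c(take, j)
        }
        j <- j + 1L
      }
      occ[take] <- next_occ
    } else {
      occ[i] <- next_occ
    }
    next_occ <- next_occ + 1L
    i <- i + 1L
    while (i <= n && occ[i] != 0L) i <- i + 1L
  }
  slot$occ <- occ

  # offence-level fields are shared within an occurrence: take them from the
  # first row of each occurrence
  harm <- default_harm_table()
  code_weights <- c(0.74, 0.12, 0.08, 0.03, 0.012, 0.008, 0.005, 0.003, 0.002)
  occ_tbl <- slot |>
    group_by(.data$occ) |>
    summarise(from_date = min(.data$from_date), n_off = n(), .groups = "drop")
  m <- nrow(occ_tbl)
  delay_pool <- c(0L, 1L, sample(2:9, 20, TRUE), sample(10:400, 8, TRUE))
  occ_tbl <- occ_tbl |>
    mutate(
      reported_date = .data$from_date +
        sample(delay_pool, m, replace = TRUE,
               prob = c(rep(0.53, 1), rep(0.21, 1), rep(0.22 / 20, 20),
                        rep(0.04 / 8, 8))),
      created_date = .data$reported_date,
      ho_code = sample(harm$ho_code[order(harm$harm_score)], m,
                       replace = TRUE, prob = code_weights),
      offence_group = sample(.offence_groups, m, replace = TRUE,
                             prob = .offence_group_weights),
      da_flag = stats::runif(m) < 0.12,
      knife_flag = stats::runif(m) < 0.03,
      drugs_flag = .data$offence_group == "Drug offences" |
        stats::runif(m) < 0.05,
      hate_flag = stats::runif(m) < 0.01,
      firearm_flag = stats::runif(m) < 0.01,
      safeguarding_flag = stats::runif(m) < 0.02,
      alcohol_flag = ifelse(stats::runif(m) < 0.982, NA,
                            stats::runif(m) < 0.5),
      substance_use = ifelse(
        stats::runif(m) < 0.952, NA_character_,
        sample(c("alcohol", "alcohol and drugs", "drugs", "not affected",
                 "not known"), m, replace = TRUE))
    )
  occ_tbl$reported_date <- pmin(occ_tbl$reported_date, params$extraction_date)

  # per-offender disposals; the occurrence-level outcome code is the most
  # serious (lowest-numbered) disposal among the group's members
  slot$own_oc <- sample_disposal(n)
  occ_oc <- slot |>
    group_by(.data$occ) |>
    summarise(outcome_code = .data$own_oc[which.min(oc_rank(.data$own_oc))],
              .groups = "drop")

  ev <- slot |>
    select(-"from_date") |>
    left_join(occ_tbl, by = "occ") |>
    left_join(occ_oc, by = "occ")

  own_term <- ifelse(ev$own_oc %in% names(.oc_terms),
                     .oc_terms[ev$own_oc],
                     sample(.ineligible_terms, n, replace = TRUE))
  legacy <- ev$from_date < params$era_boundary & own_term %in% .legacy_replaced
  own_term[legacy] <- "prosecuted"
  ev$classification_terms <- paste("suspect", "arrested", own_term, sep = "; ")

  ev$scorexmultiplier <- score_severity(
    ev$ho_code,
    severity_flags(
      domestic_abuse = ev$da_flag, hate = ev$hate_flag, drug = ev$drugs_flag,
      firearm = ev$firearm_flag, safeguarding_children = ev$safeguarding_flag
    ),
    table = harm
  )
  ev$mopi_group <- harm$mopi_group[match(ev$ho_code, harm$ho_code)]

  # Magistrates' Court fields: charged occurrences reported after the court
  # data start; verdict itself is often missing (poor CPS-to-police flow)
  has_case <- ev$outcome_code == "OC1" &
    ev$reported_date >= params$court_data_start & stats::runif(n) < 0.8
  ev$casefile_id <- ifelse(has_case, paste0("CF", ev$occ), NA_character_)
  ev$casefile_date <- dplyr::if_else(
    has_case, ev$reported_date + sample(60:300, n, replace = TRUE),
    as.Date(NA)
  )
  ev$verdict <- ifelse(
    has_case & stats::runif(n) < 0.62,
    sample(c("guilty", "not guilty"), n, replace = TRUE, prob = c(0.8, 0.2)),
    NA_character_
  )

  ev |>
    mutate(occurrence_id = sprintf("E%06d", .data$occ),
           offender_count = .data$n_off) |>
    select("occurrence_id", "offender_id", "created_date", "reported_date",
           "from_date", "ho_code", "offence_group", "offender_count",
           "outcome_code", "classification_terms", "da_flag", "knife_flag",
           "drugs_flag", "alcohol_flag", "substance_use",
           "scorexmultiplier", "mopi_group", "casefile_id", "casefile_date",
           "verdict") |>
    arrange(.data$occurrence_id, .data$offender_id)
}

#' Apply retention (review-and-deletion) rules to an event table
#'
#' Emulates the record-retention sweep at extraction. Offences fall into
#' three review groups (1 = most serious, 2 = sexual/violent/serious,
#' 3 = all other); where one offender holds several offences, the most
#' serious offence (lowest group number) sets the review category for all of
#' them. Group-3-categorised offenders' records are deleted when a clear
#' period of at least `clear_years` (no later offence) precedes
#' `extraction_date`; Group 1/2 records are retained (deletion for those
#' requires a manual review this simulator never triggers). Separately,
#' events before `electronic_start` are paper-era and are dropped with
#' probability `pre_electronic_drop`.
#'
#' @param events Event tibble from [generate_events()] (must carry
#'   `mopi_group`).
#' @param extraction_date Date of the retention sweep.
#' @param clear_years Clear-period threshold in years for Group 3 deletion.
#' @param electronic_start First date with electronic records.
#' @param pre_electronic_drop Drop probability for paper-era events.
#' @return The retained subset of `events`.
#' @export
apply_retention <- function(events, extraction_date,
                            clear_years = 6,
                            electronic_start = as.Date("2007-01-01"),
                            pre_electronic_drop = 1.0) {
  if (!"mopi_group" %in% names(events) || anyNA(events$mopi_group) ||
      !all(events$mopi_group %in% 1:3)) {
    abort("every event must carry a `mopi_group` in 1..3",
          class = "crimelink_validation_error")
  }
  extraction_date <- as.Date(extraction_date)
  if (nrow(events) == 0L) return(events)

  per_off <- events |>
    group_by(.data$offender_id) |>
    summarise(review_group = min(.data$mopi_group),
              last_notice = max(.data$reported_date), .groups = "drop") |>
    mutate(deleted = .data$review_group == 3L &
             as.numeric(extraction_date - .data$last_notice) / 365.25 >=
               clear_years)

  kept <- events |>
    left_join(select(per_off, "offender_id", "deleted"), by = "offender_id") |>
    filter(!.data$deleted) |>
    select(-"deleted")

  paper_era <- kept$from_date < as.Date(electronic_start)
  if (any(paper_era) && pre_electronic_drop > 0) {
    drop <- paper_era & stats::runif(nrow(kept)) < pre_electronic_drop
    kept <- kept[!drop, , drop = FALSE]
  }
  kept
}

#' Split concatenated classification terms
#'
#' @param x Character vector of "; "-concatenated classification strings.
#' @return A list of character vectors, lower-cased and trimmed.
#' @export
split_terms <- function(x) {
  purrr::map(strsplit(tolower(x), ";", fixed = TRUE),
             function(t) trimws(t))
}
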