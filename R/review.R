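# Manual-review rules and duplicate resolution. Candidates flow through a
# twin check, a low-confidence (bottom-decile) review of probabilistic
# links, and duplicate resolution; removals are recorded in a ledger so the
# final table plus the ledger always accounts for every candidate.

#' Twin check
#'
#' Twins share surname, date of birth and (usually) childhood address, so a
#' co-twin is at high risk of creating a false link. Candidates whose
#' study_id belongs to a twin group are retained only if the register
#' record matches on both sex and the first two characters of forename;
#' failures are marked `removed_twin`. Non-twin candidates are untouched.
#'
#' @param candidates Candidate tibble ([combine_candidates()]).
#' @param cohort Cohort tibble carrying `twin_group`, `sex`, `forename`.
#' @param subjects Subject register (for the register-side sex/forename).
#' @return `candidates` with `status` updated.
#' @export
twin_check <- function(candidates, cohort, subjects) {
  if (nrow(candidates) == 0L) return(candidates)
  cd <- cohort |>
    mutate(c_fn2 = substr(normalise_name(.data$forename), 1, 2)) |>
    select("study_id", "twin_group", c_sex = "sex", "c_fn2")
  sd <- subjects |>
    mutate(s_fn2 = substr(normalise_name(.data$forename), 1, 2)) |>
    select("offender_id", s_sex = "sex", "s_fn2")
  candidates |>
    left_join(cd, by = "study_id") |>
    left_join(sd, by = "offender_id") |>
    mutate(status = if_else(
      .data$status == "accepted" & !is.na(.data$twin_group) &
        !(.data$c_sex == .data$s_sex & .data$c_fn2 == .data$s_fn2),
      "removed_twin", .data$status)) |>
    select(-"twin_group", -"c_sex", -"s_sex", -"c_fn2", -"s_fn2")
}

#' Low-confidence review of probabilistic links
#'
#' Among accepted probabilistic candidates, the bottom decile by score is
#' selected for review and retained only when it has a match on forename
#' AND full date of birth, OR surname AND full date of birth, OR a full
#' postcode match; failures are marked `removed_low_confidence`. Agreement
#' here means exact equality after normalisation (hard checks, not
#' similarity thresholds). Deterministic matches are exempt.
#'
#' @param candidates Candidate tibble with scores and exact-agreement
#'   columns.
#' @param decile Fraction of lowest-scoring probabilistic links reviewed.
#' @return `candidates` with `status` updated.
#' @export
low_confidence_review <- function(candidates, decile = 0.10) {
  probs <- candidates$status == "accepted" &
    candidates$method == "probabilistic"
  if (!any(probs)) return(candidates)
  cutoff <- stats::quantile(candidates$score[probs], decile, names = FALSE)
  reviewed <- probs & candidates$score <= cutoff
  passes <- (candidates$forename_exact & candidates$dob_exact) |
    (candidates$surname_exact & candidates$dob_exact) |
    candidates$postcode_full
  candidates$status[reviewed & !passes] <- "removed_low_confidence"
  candidates
}

#' Resolve duplicate claims into the final link table
#'
#' Applies three rules to accepted candidates: (a) when several study_ids
#' claim one offender_id, only a claim with a strong, full-postcode match
#' is retained — a deterministic claim outranks a probabilistic one, and if
#' the claim is still ambiguous all are removed; (b) when one study_id
#' holds several offender_ids none of which has date-of-birth or postcode
#' support, names alone lack distinguishing power and all are removed;
#' (c) one study_id with several well-supported offender_ids keeps them all
#' (identity fragmentation on the police side).
#'
#' @param candidates Candidate tibble after the review steps.
#' @return A `link_table` object: list with `links` (tibble of `study_id`,
#'   `offender_id`, `method`, `strength`, `score`) and `ledger` (named
#'   integer vector of removal counts, including the review stages').
#' @export
resolve_duplicates <- function(candidates) {
  ledger <- c(
    removed_twin = sum(candidates$status == "removed_twin"),
    removed_low_confidence =
      sum(candidates$status == "removed_low_confidence"),
    removed_duplicate = 0L
  )
  acc <- filter(candidates, .data$status == "accepted")

  # (a) offender_id claimed by several study_ids
  if (nrow(acc) > 0L) {
    acc <- acc |>
      group_by(.data$offender_id) |>
      mutate(.n_claims = dplyr::n_distinct(.data$study_id)) |>
      ungroup()
    contested <- filter(acc, .data$.n_claims > 1L)
    if (nrow(contested) > 0L) {
      keep <- contested |>
        filter(.data$postcode_full) |>
        group_by(.data$offender_id) |>
        filter(if (any(.data$method == "deterministic")) {
          .data$method == "deterministic"
        } else TRUE) |>
        filter(dplyr::n_distinct(.data$study_id) == 1L) |>
        ungroup()
      removed <- anti_join(contested, keep,
                           by = c("study_id", "offender_id"))
      ledger[["removed_duplicate"]] <-
        ledger[["removed_duplicate"]] + nrow(removed)
      acc <- bind_rows(filter(acc, .data$.n_claims == 1L), keep)
    }
    acc <- select(acc, -".n_claims")
  }

  # (b) one study_id with several offender_ids, none dob- or
  # postcode-supported
  if (nrow(acc) > 0L) {
    acc <- acc |>
      group_by(.data$study_id) |>
      mutate(.n_ids = dplyr::n_distinct(.data$offender_id),
             .any_support = any(.data$dob_exact | .data$postcode_full)) |>
      ungroup()
    weak <- acc$.n_ids > 1L & !acc$.any_support
    ledger[["removed_duplicate"]] <-
      ledger[["removed_duplicate"]] + sum(weak)
    acc <- acc |>
      filter(!weak) |>
      select(-".n_ids", -".any_support")
  }

  links <- acc |>
    select("study_id", "offender_id", "method", "strength", "score") |>
    arrange(.data$study_id, .data$offender_id)
  structure(
    list(links = links, ledger = ledger, n_candidates = nrow(candidates)),
    class = "link_table"
  )
}

#' @export
print.link_table <- function(x, ...) {
  cat("<link_table>\n")
  cat(sprintf("  %d links: %d individuals, %d offender ids\n",
              nrow(x$links), dplyr::n_distinct(x$links$study_id),
              dplyr::n_distinct(x$links$offender_id)))
  cat(sprintf("  removals: %s\n",
              paste(names(x$ledger), x$ledger, sep = "=", collapse = ", ")))
  invisible(x)
}

#' Tidy a link table
#'
#' @param x A `link_table`.
#' @param ... Unused.
#' @return The per-link tibble.
#' @export
tidy.link_table <- function(x, ...) x$links

#' One-row summary of a link table
#'
#' @param x A `link_table`.
#' @param ... Unused.
#' @return A one-row tibble: link, individual, offender-id and removal
#'   counts.
#' @export
glance.link_table <- function(x, ...) {
  tibble::tibble(
    n_links = nrow(x$links),
    n_individuals = dplyr::n_distinct(x$links$study_id),
    n_offender_ids = dplyr::n_distinct(x$links$offender_id),
    n_deterministic = sum(x$links$method == "deterministic"),
    n_probabilistic = sum(x$links$method == "probabilistic"),
    removed_twin = x$ledger[["removed_twin"]],
    removed_low_confidence = x$ledger[["removed_low_confidence"]],
    removed_duplicate = x$ledger[["removed_duplicate"]]
  )
}

#' Generic tidy/glance (broom-style)
#'
#' @param x Object to tidy or summarise.
#' @param ... Passed to methods.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidy
#' @export
glance <- function(x, ...) UseMethod("glance")

#' Linkage flow report
#'
#' Stage-by-stage accounting of the linkage: deterministic matches by
#' strength tier, probabilistic additions, removals by reason, and the
#' final distinct individuals and offender ids. The conservation identity
#' candidates = final links + removals holds by construction.
#'
#' @param candidates Candidate tibble after review (pre-dedup statuses are
#'   read from it).
#' @param link_table The [resolve_duplicates()] result.
#' @return A tibble with `stage` and `count`.
#' @export
flow_report <- function(candidates, link_table) {
  det <- filter(candidates, .data$method == "deterministic")
  lt <- link_table$links
  frag_surplus <- nrow(lt) - dplyr::n_distinct(lt$study_id)
  tibble::tibble(
    stage = c(
      "deterministic_strength_1", "deterministic_strength_2",
      "deterministic_strength_3", "deterministic_total",
      "probabilistic_additions", "candidates_total",
      "removed_twin", "removed_low_confidence", "removed_duplicate",
      "final_links", "distinct_individuals", "distinct_offender_ids",
      "fragmented_surplus"
    ),
    count = c(
      sum(det$strength == 1L), sum(det$strength == 2L),
      sum(det$strength == 3L), nrow(det),
      sum(candidates$method == "probabilistic"), nrow(candidates),
      unname(link_table$ledger[["removed_twin"]]),
      unname(link_table$ledger[["removed_low_confidence"]]),
      unname(link_table$ledger[["removed_duplicate"]]),
      nrow(lt), dplyr::n_distinct(lt$study_id),
      dplyr::n_distinct(lt$offender_id), frag_surplus
    )
  )
}

#' Precision and recall against ground truth
#'
#' @param link_table A `link_table` (or a tibble of `study_id`,
#'   `offender_id`).
#' @param truth Ground-truth tibble of true `study_id`, `offender_id`
#'   pairs.
#' @return One-row tibble: `n_links`, `n_truth`, `true_positive`,
#'   `precision`, `recall`, `f1`.
#' @export
evaluate_links <- function(link_table, truth) {
  links <- if (inherits(link_table, "link_table")) {
    link_table$links
  } else {
    link_table
  }
  links <- distinct(select(links, "study_id", "offender_id"))
  truth <- distinct(select(truth, "study_id", "offender_id"))
  tp <- nrow(inner_join(links, truth, by = c("study_id", "offender_id")))
  precision <- if (nrow(links) == 0L) NA_real_ else tp / nrow(links)
  recall <- if (nrow(truth) == 0L) NA_real_ else tp / nrow(truth)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0) {
    NA_real_
  } else {
    2 * precision * recall / (precision + recall)
  }
  tibble::tibble(
    n_links = nrow(links), n_truth = nrow(truth), true_positive = tp,
    precision = precision, recall = recall, f1 = f1
  )
}
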