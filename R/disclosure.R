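# Disclosure control: transform linked events into research-ready release
# records. Raw identifiers and dates never appear in the release; ids are
# keyed-hash pseudonyms that retain equivalent functionality, dates become
# ages in completed months (month and year of offence are kept), heavy
# tails are top-coded, and any frequency table released is protected by
# small-cell suppression with complementary suppression.

#' Pseudonymise identifiers with a keyed hash
#'
#' Deterministic within a release (same raw id, same salt, same token) so
#' joins across rows keep working; different salts give unrelated tokens;
#' the token carries no information about the raw id without the salt.
#'
#' @param raw_id Character vector of raw identifiers (non-empty).
#' @param salt Single string, fixed per release.
#' @return Character vector of 16-hex-digit tokens (NA maps to NA).
#' @export
pseudonymise_id <- function(raw_id, salt) {
  if (!is.character(salt) || length(salt) != 1L || !nzchar(salt)) {
    abort("`salt` must be a single non-empty string",
          class = "crimelink_validation_error")
  }
  if (any(!is.na(raw_id) & !nzchar(raw_id))) {
    abort("empty raw_id", class = "crimelink_validation_error")
  }
  vapply(raw_id, function(id) {
    if (is.na(id)) return(NA_character_)
    substr(rlang::hash(paste0(salt, "\x1f", id)), 1, 16)
  }, character(1), USE.NAMES = FALSE)
}

#' Age in completed calendar months
#'
#' Number of whole calendar months elapsed between birth and an event: a
#' month counts only once its day-of-month has been reached (the usual
#' "age in months" convention).
#'
#' @param dob,event_date Date vectors (recycled); every `event_date` must
#'   be on or after its `dob`.
#' @return Integer vector of month counts.
#' @examples
#' date_to_age_months(as.Date("1992-04-15"), as.Date("2010-04-14"))  # 215
#' date_to_age_months(as.Date("1992-04-15"), as.Date("2010-04-15"))  # 216
#' @export
date_to_age_months <- function(dob, event_date) {
  dob <- as.Date(dob); event_date <- as.Date(event_date)
  n <- max(length(dob), length(event_date))
  dob <- rep_len(dob, n); event_date <- rep_len(event_date, n)
  ok <- is.na(dob) | is.na(event_date) | event_date >= dob
  if (!all(ok)) {
    abort("event_date before dob", class = "crimelink_validation_error")
  }
  months <- 12L * (lubridate::year(event_date) - lubridate::year(dob)) +
    (lubridate::month(event_date) - lubridate::month(dob)) -
    as.integer(lubridate::day(event_date) < lubridate::day(dob))
  as.integer(months)
}

#' Top-code a numeric variable
#'
#' Values at or above the cutoff are replaced by a capped category label;
#' values below are kept. With an infinite cutoff the input is returned
#' unchanged (numeric), otherwise the result is character.
#'
#' @param value Numeric vector.
#' @param cutoff Cap; `Inf` for identity.
#' @param label Capped-category label; default `"<cutoff>+"`.
#' @return `value` unchanged if `cutoff` is infinite, else a character
#'   vector.
#' @examples
#' top_code(c(2, 12), cutoff = 5)  # "2", "5+"
#' @export
top_code <- function(value, cutoff, label = paste0(format(cutoff), "+")) {
  if (is.infinite(cutoff)) return(value)
  ifelse(is.na(value), NA_character_,
         ifelse(value >= cutoff, label, as.character(value)))
}

# --- small-cell suppression --------------------------------------------------

# Feasible values each suppressed cell can take given released cells and
# the published row/column margins: exhaustive non-negative integer
# enumeration (small tables only). Returns a list of per-cell value sets,
# or NULL if the pattern is too large to enumerate.
feasible_values <- function(counts, suppressed, max_states = 2e6) {
  cells <- which(suppressed, arr.ind = TRUE)
  k <- nrow(cells)
  if (k == 0L) return(list())
  row_rem <- rowSums(counts) - rowSums(counts * !suppressed)
  col_rem <- colSums(counts) - colSums(counts * !suppressed)
  # order cells row-major for pruning
  ord <- order(cells[, 1], cells[, 2])
  cells <- cells[ord, , drop = FALSE]
  sets <- vector("list", k)
  for (i in seq_len(k)) sets[[i]] <- integer(0)
  states <- 0L
  recurse <- function(i, rrem, crem) {
    if (states > max_states) return(FALSE)
    if (i > k) {
      if (all(rrem == 0) && all(crem == 0)) {
        for (j in seq_len(k)) {
          sets[[j]] <<- union(sets[[j]], vals[[j]])
        }
      }
      return(TRUE)
    }
    r <- cells[i, 1]; cc <- cells[i, 2]
    # if this is the last suppressed cell in its row, value is forced
    later_in_row <- i < k && any(cells[seq(i + 1L, k), 1] == r)
    upper <- min(rrem[r], crem[cc])
    cand <- if (!later_in_row) {
      if (rrem[r] <= crem[cc]) rrem[r] else integer(0)
    } else {
      0:upper
    }
    for (v in cand) {
      states <<- states + 1L
      vals[[i]] <<- v
      rrem[r] <- rrem[r] - v; crem[cc] <- crem[cc] - v
      if (!recurse(i + 1L, rrem, crem)) return(FALSE)
      rrem[r] <- rrem[r] + v; crem[cc] <- crem[cc] + v
    }
    TRUE
  }
  vals <- vector("list", k)
  ok <- recurse(1L, row_rem, col_rem)
  if (!ok) return(NULL)
  attr(sets, "cells") <- cells
  sets
}

# Which suppressed cells are exactly recoverable from released cells plus
# margins? Returns list(rec = logical, cells = matrix of (row, col)), or
# NULL when the pattern is too large to enumerate exactly.
recoverable_cells <- function(counts, suppressed, max_states = 2e6) {
  sets <- feasible_values(counts, suppressed, max_states)
  if (is.null(sets)) return(NULL)
  list(rec = vapply(sets, function(s) length(s) == 1L, logical(1)),
       cells = attr(sets, "cells"))
}

#' Small-cell suppression with complementary protection
#'
#' Primary suppression hides every cell with `0 < count < threshold`.
#' Complementary suppression then hides additional cells until no
#' suppressed count can be exactly recovered from the released cells plus
#' the (published) row and column margins; recoverability is decided by
#' exhaustive enumeration of feasible non-negative integer fills, falling
#' back to a row/column singleton rule on tables too large to enumerate.
#' A cell that is a row's (or the table's) only non-zero entry cannot be
#' protected while its margin is published; such cells are reported in
#' `unprotectable`.
#'
#' @param freq_table Numeric matrix (or data.frame) of non-negative counts;
#'   dimnames are preserved.
#' @param threshold Counts strictly below this (and above zero) are
#'   suppressed. Default 5.
#' @return A `suppressed_table`: list with `counts` (original), `released`
#'   (counts with suppressed cells NA), `suppressed` (logical matrix),
#'   `row_margins`, `col_margins`, `threshold`, `unprotectable`.
#' @export
suppress_small_cells <- function(freq_table, threshold = 5) {
  counts <- as.matrix(freq_table)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("freq_table must contain non-negative integer counts",
          class = "crimelink_validation_error")
  }
  storage.mode(counts) <- "integer"
  suppressed <- counts > 0L & counts < threshold

  unprotectable <- matrix(FALSE, nrow(counts), ncol(counts),
                          dimnames = dimnames(counts))

  # Protect (r, c) by completing a 2x2 rectangle of suppressed cells:
  # pick a partner column and row (smallest positive released counts
  # first) so the fill can shift by +/-1 around the cycle. Returns the
  # updated pattern, or NULL when no rectangle adds a new cell.
  protect_rectangle <- function(suppressed, r, c) {
    cand_cols <- setdiff(order(counts[r, ] == 0L, counts[r, ]), c)
    cand_rows <- setdiff(order(counts[, c] == 0L, counts[, c]), r)
    for (c2 in cand_cols) {
      for (r2 in cand_rows) {
        cells <- rbind(c(r, c2), c(r2, c), c(r2, c2))
        new <- cells[!suppressed[cells], , drop = FALSE]
        if (nrow(new) > 0L) {
          suppressed[cells] <- TRUE
          return(suppressed)
        }
      }
    }
    NULL
  }

  if (any(suppressed)) {
    primaries <- which(suppressed, arr.ind = TRUE)
    repeat {
      chk <- recoverable_cells(counts, suppressed)
      if (is.null(chk)) {
        # table too large for exact checking: protect every primary cell
        # with a rectangle once, then stop
        for (i in seq_len(nrow(primaries))) {
          upd <- protect_rectangle(suppressed, primaries[i, 1],
                                   primaries[i, 2])
          if (!is.null(upd)) suppressed <- upd
        }
        break
      }
      if (!any(chk$rec)) break
      progress <- FALSE
      for (i in which(chk$rec)) {
        upd <- protect_rectangle(suppressed, chk$cells[i, 1],
                                 chk$cells[i, 2])
        if (!is.null(upd)) {
          suppressed <- upd
          progress <- TRUE
          break
        }
      }
      if (!progress) {
        # no rectangle can add ambiguity (degenerate shapes, e.g. a
        # single row with its margin published)
        unprotectable[chk$cells[chk$rec, , drop = FALSE]] <- TRUE
        break
      }
    }
  }

  released <- counts
  released[suppressed] <- NA_integer_
  structure(
    list(counts = counts, released = released, suppressed = suppressed,
         row_margins = rowSums(counts), col_margins = colSums(counts),
         threshold = threshold, unprotectable = unprotectable),
    class = "suppressed_table"
  )
}

#' @export
print.suppressed_table <- function(x, ...) {
  cat(sprintf("<suppressed_table> threshold %d, %d cell(s) suppressed\n",
              x$threshold, sum(x$suppressed)))
  disp <- matrix(as.character(x$released), nrow(x$released),
                 dimnames = dimnames(x$released))
  disp[is.na(disp)] <- "-"
  print(disp, quote = FALSE)
  invisible(x)
}

#' @export
tidy.suppressed_table <- function(x, ...) {
  dn <- dimnames(x$counts) %||%
    list(as.character(seq_len(nrow(x$counts))),
         as.character(seq_len(ncol(x$counts))))
  tibble::tibble(
    row = rep(dn[[1]], times = ncol(x$counts)),
    col = rep(dn[[2]], each = nrow(x$counts)),
    count = as.vector(x$counts),
    released = as.vector(x$released),
    suppressed = as.vector(x$suppressed)
  )
}

#' Cross-tabulate a release with suppression applied
#'
#' @param release Release tibble ([build_release()]).
#' @param row_var,col_var Column names to tabulate.
#' @param threshold Suppression threshold.
#' @return A `suppressed_table`.
#' @export
tabulate_release <- function(release, row_var, col_var, threshold = 5) {
  tab <- table(release[[row_var]], release[[col_var]])
  suppress_small_cells(unclass(as.matrix(tab)), threshold = threshold)
}

# --- release building --------------------------------------------------------

#' Default disclosure-control configuration
#'
#' @param salt Pseudonymisation key, fixed per release.
#' @param severity_cutoff Top-coding cutoff for the severity score.
#' @param offender_count_cutoff Top-coding cutoff for offender count.
#' @param missingness_threshold Fields missing above this fraction are
#'   withheld from the release.
#' @param high_missing_fields Candidate fields subject to the missingness
#'   rule.
#' @return A named list.
#' @export
release_config <- function(salt = "release-1",
                           severity_cutoff = 10,
                           offender_count_cutoff = 5,
                           missingness_threshold = 0.90,
                           high_missing_fields = c("alcohol_flag",
                                                   "substance_use",
                                                   "verdict")) {
  list(salt = salt, severity_cutoff = severity_cutoff,
       offender_count_cutoff = offender_count_cutoff,
       missingness_threshold = missingness_threshold,
       high_missing_fields = high_missing_fields)
}

#' Build disclosure-controlled release records
#'
#' Converts linked, filtered events into research-ready rows: pseudonymised
#' occurrence and casefile ids, every date replaced by the participant's
#' age in completed months (month and year of offence are retained),
#' severity and offender count top-coded, and any candidate field whose
#' missingness exceeds the configured threshold withheld entirely. One
#' `has_record = FALSE` row is emitted for every linkage-permitted
#' participant with no eligible record, so denominators survive the
#' transformation.
#'
#' @param linked_events Output of [filter_events()].
#' @param cohort Cohort tibble (for dates of birth and the
#'   linkage-permission flag).
#' @param config A [release_config()] list.
#' @return A list with `release` (tibble of release records) and
#'   `drop_report` (tibble: field, missingness, dropped).
#' @export
build_release <- function(linked_events, cohort, config = release_config()) {
  dobs <- select(cohort, "study_id", "dob")
  ev <- left_join(linked_events, dobs, by = "study_id")
  if (anyNA(ev$dob)) {
    abort("missing dob for linked participant(s)",
          class = "crimelink_validation_error")
  }

  drop_report <- tibble::tibble(
    field = config$high_missing_fields,
    missingness = vapply(config$high_missing_fields, function(f) {
      if (!f %in% names(ev) || nrow(ev) == 0L) return(NA_real_)
      mean(is.na(ev[[f]]))
    }, numeric(1)),
    dropped = NA
  )
  drop_report$dropped <- !is.na(drop_report$missingness) &
    drop_report$missingness > config$missingness_threshold

  rel <- tibble::tibble(
    study_id = ev$study_id,
    pseudo_occurrence_id = pseudonymise_id(ev$occurrence_id, config$salt),
    pseudo_casefile_id = pseudonymise_id(ev$casefile_id, config$salt),
    age_at_offence_months = date_to_age_months(ev$dob, ev$from_date),
    age_created_months = date_to_age_months(ev$dob, ev$created_date),
    age_reported_months = date_to_age_months(ev$dob, ev$reported_date),
    age_casefile_months = date_to_age_months(ev$dob, ev$casefile_date),
    offence_month = lubridate::month(ev$from_date),
    offence_year = lubridate::year(ev$from_date),
    offence_group = ev$offence_group,
    severity_topcoded = top_code(ev$scorexmultiplier,
                                 config$severity_cutoff),
    offender_count_topcoded = top_code(ev$offender_count,
                                       config$offender_count_cutoff),
    da_flag = ev$da_flag,
    knife_flag = ev$knife_flag,
    drugs_flag = ev$drugs_flag,
    has_record = TRUE
  )
  for (f in drop_report$field[!drop_report$dropped]) {
    if (f %in% names(ev)) rel[[f]] <- ev[[f]]
  }

  eligible <- cohort |>
    filter(.data$linkage_permitted) |>
    anti_join(distinct(select(linked_events, "study_id")), by = "study_id")
  if (nrow(eligible) > 0L) {
    blank <- rel[0, ]
    norec <- blank[seq_len(nrow(eligible)), , drop = FALSE]
    norec$study_id <- eligible$study_id
    norec$has_record <- FALSE
    rel <- bind_rows(rel, norec)
  }

  list(release = arrange(rel, .data$study_id), drop_report = drop_report)
}

#' Scan a release for raw-identifier leaks
#'
#' Searches every character cell of the release for any forename, surname,
#' full postcode, raw occurrence/offender/casefile id, or full ISO date
#' (dates of birth and event dates) present in the pipeline inputs.
#'
#' @param release Release tibble.
#' @param cohort,subjects,events The raw pipeline inputs.
#' @return A tibble of leaked values (zero rows when the release is clean).
#' @export
scan_release_leaks <- function(release, cohort, subjects, events) {
  needles <- unique(c(
    cohort$forename, cohort$surname, unlist(cohort_postcode_sets(cohort)),
    format(cohort$dob),
    subjects$forename, subjects$surname, unlist(subjects$postcodes),
    subjects$offender_id,
    events$occurrence_id, stats::na.omit(events$casefile_id),
    format(events$from_date), format(events$reported_date)
  ))
  needles <- needles[!is.na(needles) & nzchar(needles)]
  cells <- unlist(lapply(release, function(col) {
    if (is.character(col) || is.factor(col)) unique(as.character(col))
    else character(0)
  }), use.names = FALSE)
  cells <- unique(cells[!is.na(cells)])
  # exclude the cohort's own research ids: they are the release key
  cells <- setdiff(cells, release$study_id)
  if (length(cells) == 0L) {
    return(tibble::tibble(value = character(), kind = "leak"))
  }
  haystack <- paste(cells, collapse = "\n")
  hit <- vapply(needles, function(nd) {
    grepl(nd, haystack, fixed = TRUE)
  }, logical(1))
  tibble::tibble(value = needles[hit], kind = "leak")
}
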