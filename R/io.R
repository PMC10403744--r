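# CSV round-tripping for the pipeline's intermediate files. Address
# histories and postcode sets are list-columns in memory; on disk they are
# packed into single delimited fields so every intermediate stays one flat,
# documented CSV.

pack_addresses <- function(addresses) {
  vapply(addresses, function(a) {
    paste(sprintf("%s:%s:%s", a$postcode, a$from_date, a$to_date),
          collapse = "|")
  }, character(1))
}

unpack_addresses <- function(packed) {
  purrr::map(strsplit(packed, "|", fixed = TRUE), function(spells) {
    parts <- strsplit(spells, ":", fixed = TRUE)
    tibble::tibble(
      postcode = vapply(parts, `[`, character(1), 1),
      from_date = as.Date(vapply(parts, `[`, character(1), 2)),
      to_date = as.Date(vapply(parts, `[`, character(1), 3))
    )
  })
}

#' Write synthetic pipeline inputs to a directory
#'
#' Writes `cohort.csv`, `subjects.csv`, `events.csv` and `truth.csv`.
#' Address histories are packed as `postcode:from:to` spells joined by
#' `|`; subject postcode sets are `|`-joined; all dates ISO 8601.
#'
#' @param cohort,subjects,events,truth Tibbles from the generator.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synth_dir <- function(cohort, subjects, events, truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(
    mutate(cohort, addresses = pack_addresses(.data$addresses)),
    file.path(dir, "cohort.csv"))
  readr::write_csv(
    mutate(subjects, postcodes = vapply(.data$postcodes, paste,
                                        character(1), collapse = "|")),
    file.path(dir, "subjects.csv"))
  readr::write_csv(events, file.path(dir, "events.csv"))
  readr::write_csv(truth, file.path(dir, "truth.csv"))
  invisible(dir)
}

#' Read synthetic pipeline inputs from a directory
#'
#' @param dir Directory written by [write_synth_dir()].
#' @return A list with `cohort`, `subjects`, `events`, `truth`.
#' @export
read_synth_dir <- function(dir) {
  cohort <- readr::read_csv(file.path(dir, "cohort.csv"),
                            show_col_types = FALSE) |>
    mutate(addresses = unpack_addresses(.data$addresses))
  subjects <- readr::read_csv(file.path(dir, "subjects.csv"),
                              show_col_types = FALSE) |>
    mutate(postcodes = strsplit(.data$postcodes, "|", fixed = TRUE))
  events <- readr::read_csv(file.path(dir, "events.csv"),
                            show_col_types = FALSE)
  truth <- readr::read_csv(file.path(dir, "truth.csv"),
                           show_col_types = FALSE)
  list(cohort = cohort, subjects = subjects, events = events, truth = truth)
}
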