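# Disclosure control: pseudonymisation, age conversion, top-coding,
# small-cell suppression, release building and the leak scan.

test_that("pseudonymisation is deterministic, salted and functional", {
  a <- pseudonymise_id("E000123", "salt-A")
  expect_identical(a, pseudonymise_id("E000123", "salt-A"))
  expect_false(a == pseudonymise_id("E000123", "salt-B"))
  expect_false(grepl("E000123", a, fixed = TRUE))
  # group-crime rows sharing an occurrence share the pseudo id
  ids <- pseudonymise_id(c("E1", "E2", "E1"), "s")
  expect_identical(ids[1], ids[3])
  expect_false(ids[1] == ids[2])
  # injective on observed inputs at scale
  many <- pseudonymise_id(sprintf("E%06d", 1:5000), "s")
  expect_equal(anyDuplicated(many), 0L)
  expect_identical(pseudonymise_id(NA_character_, "s"), NA_character_)
  expect_error(pseudonymise_id("", "s"),
               class = "crimelink_validation_error")
  expect_error(pseudonymise_id("X", ""),
               class = "crimelink_validation_error")
})

test_that("age in completed months matches a calendar-walk oracle", {
  expect_equal(date_to_age_months(as.Date("1992-04-15"),
                                  as.Date("1992-04-15")), 0L)
  expect_equal(date_to_age_months(as.Date("1992-04-15"),
                                  as.Date("2010-04-14")), 215L)
  expect_equal(date_to_age_months(as.Date("1992-04-15"),
                                  as.Date("2010-04-15")), 216L)
  expect_error(date_to_age_months(as.Date("1992-04-15"),
                                  as.Date("1992-04-14")),
               class = "crimelink_validation_error")

  # oracle: walk the calendar day by day, counting a month each time the
  # birth day-of-month is reached (dob days 1..28 so every month has one)
  walk_months <- function(dob, event) {
    if (event == dob) return(0L)
    d <- seq(dob + 1, event, by = "day")
    sum(lubridate::day(d) == lubridate::day(dob))
  }
  set.seed(14)
  dobs <- as.Date("1991-01-01") +
    sample(0:700, 1000, replace = TRUE)
  dobs <- lubridate::`day<-`(dobs, sample(1:28, 1000, replace = TRUE))
  events <- dobs + sample(0:8000, 1000, replace = TRUE)
  got <- date_to_age_months(dobs, events)
  want <- vapply(seq_len(1000),
                 function(i) walk_months(dobs[i], events[i]), integer(1))
  expect_equal(got, want)
})

test_that("top-coding caps at the cutoff and is identity at infinity", {
  expect_equal(top_code(c(0.2, 9.9, 10, 40), 10),
               c("0.2", "9.9", "10+", "10+"))
  expect_equal(top_code(c(1L, 12L), 5, "5+"), c("1", "5+"))
  expect_identical(top_code(c(0.2, 1e6), Inf), c(0.2, 1e6))
})

test_that("small cells are suppressed with complementary protection", {
  counts <- matrix(c(50, 3, 40, 22,
                     60, 80, 45, 30,
                     70, 55, 65, 90),
                   nrow = 4, dimnames = list(
                     c("r1", "r2", "r3", "r4"), c("male", "female", "all")))
  st <- suppress_small_cells(counts, threshold = 5)
  expect_true(st$suppressed["r2", "male"])      # primary
  expect_gte(sum(st$suppressed), 2)             # complementary happened
  # brute-force recoverability check: no suppressed cell is determined
  chk <- crimelink:::recoverable_cells(st$counts, st$suppressed)
  expect_false(any(chk$rec))

  clean <- matrix(c(10, 20, 30, 40), nrow = 2)
  st2 <- suppress_small_cells(clean)
  expect_equal(sum(st2$suppressed), 0L)
  expect_equal(st2$released, st2$counts)

  expect_error(suppress_small_cells(matrix(c(-1, 2, 3, 4), 2)),
               class = "crimelink_validation_error")
})

test_that("a single small cell with published margins triggers complementary suppression", {
  counts <- matrix(c(2, 30, 25,
                     40, 35, 28,
                     33, 44, 50,
                     20, 25, 30), nrow = 4, byrow = TRUE)
  st <- suppress_small_cells(counts, threshold = 5)
  expect_gte(sum(st$suppressed), 2)
  chk <- crimelink:::recoverable_cells(st$counts, st$suppressed)
  expect_false(any(chk$rec))
  # zero cells are never primary-suppressed
  z <- matrix(c(0, 10, 20, 30), 2)
  expect_equal(sum(suppress_small_cells(z)$suppressed), 0L)
})

test_that("release records carry ages, pseudo ids and no raw identifiers", {
  w <- test_world()
  linked <- filter_events(w$events, w$truth)
  rel <- build_release(linked, w$cohort)
  release <- rel$release

  has <- release[release$has_record, ]
  expect_equal(nrow(has), nrow(linked))
  expect_true(all(has$age_at_offence_months >= 0))
  # month and year of offence survive the date-to-age conversion
  expect_equal(sort(unique(has$offence_year)),
               sort(unique(lubridate::year(linked$from_date))))
  expect_true(all(has$offence_month %in% 1:12))

  # every linkage-permitted unlinked participant gets one no-record row
  unlinked <- setdiff(w$cohort$study_id[w$cohort$linkage_permitted],
                      linked$study_id)
  norec <- release[!release$has_record, ]
  expect_setequal(norec$study_id, unlinked)
  expect_equal(anyDuplicated(norec$study_id), 0L)

  # dropped fields: generated missingness for alcohol/substance/verdict is
  # far above the 90% threshold
  expect_true(all(rel$drop_report$dropped))
  expect_false(any(rel$drop_report$field %in% names(release)))

  # automated leak scan
  leaks <- scan_release_leaks(release, w$cohort, w$subjects, w$events)
  expect_equal(nrow(leaks), 0L)

  # missing dob is a hard error
  bad <- dplyr::mutate(linked, study_id = "S_UNKNOWN")
  expect_error(build_release(bad, w$cohort),
               class = "crimelink_validation_error")
})

test_that("severity and offender count are top-coded in the release", {
  w <- test_world()
  linked <- filter_events(w$events, w$truth)
  rel <- build_release(linked, w$cohort,
                       release_config(severity_cutoff = 1,
                                      offender_count_cutoff = 2))
  has <- rel$release[rel$release$has_record, ]
  expect_true(any(has$severity_topcoded == "1+"))
  expect_true(all(has$offender_count_topcoded %in% c("1", "2+")))
})

test_that("tabulate_release applies suppression to frequency tables", {
  w <- test_world()
  linked <- filter_events(w$events, w$truth)
  rel <- build_release(linked, w$cohort)
  has <- dplyr::mutate(rel$release[rel$release$has_record, ],
                       sex = dplyr::left_join(
                         rel$release[rel$release$has_record, ],
                         dplyr::select(w$cohort, study_id, sex),
                         by = "study_id")$sex)
  st <- tabulate_release(has, "offence_group", "sex")
  expect_s3_class(st, "suppressed_table")
  expect_true(all(is.na(st$released[st$suppressed])))
  if (any(st$suppressed)) {
    chk <- crimelink:::recoverable_cells(st$counts, st$suppressed)
    if (!is.null(chk)) expect_false(any(chk$rec))
  }
  td <- tidy(st)
  expect_equal(nrow(td), length(st$counts))
})
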