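# Generator contracts: determinism, rates, structural invariants, era
# terminology and retention rules.

test_that("identical parameters give byte-identical output", {
  p <- synth_params(n_cohort = 120, n_background = 60, seed = 7)
  c1 <- generate_cohort(p)
  c2 <- generate_cohort(p)
  expect_identical(c1, c2)
  r1 <- generate_police_register(c1, p)
  r2 <- generate_police_register(c2, p)
  expect_identical(r1, r2)
  e1 <- generate_events(r1$subjects, p)
  e2 <- generate_events(r2$subjects, p)
  expect_identical(e1, e2)
})

test_that("cohort structure follows the configured rates and window", {
  p <- synth_params(n_cohort = 10000, n_background = 0, twin_rate = 0.02,
                    seed = 11)
  cohort <- generate_cohort(p)
  expect_equal(nrow(cohort), 10000L)
  expect_true(all(cohort$dob >= p$dob_window[1] &
                    cohort$dob <= p$dob_window[2]))
  # twin-group membership within binomial 99% bounds of the 2% rate
  n_twin <- sum(!is.na(cohort$twin_group))
  bounds <- qbinom(c(0.005, 0.995), 10000, 0.02)
  expect_gte(n_twin, bounds[1])
  expect_lte(n_twin, bounds[2])
  # co-twins share surname and dob, never forename
  twins <- cohort[!is.na(cohort$twin_group), ]
  by_group <- split(twins, twins$twin_group)
  expect_true(all(vapply(by_group, function(g) {
    nrow(g) == 2L && g$surname[1] == g$surname[2] &&
      g$dob[1] == g$dob[2] && g$forename[1] != g$forename[2]
  }, logical(1))))
  # address histories: chronological, non-overlapping, contiguous cover
  ok <- vapply(cohort$addresses[1:200], function(a) {
    all(a$from_date <= a$to_date) &&
      (nrow(a) == 1L || all(a$from_date[-1] == a$to_date[-nrow(a)] + 1))
  }, logical(1))
  expect_true(all(ok))
})

test_that("twin_rate = 0 produces no twin groups", {
  p <- synth_params(n_cohort = 300, n_background = 0, twin_rate = 0,
                    seed = 3)
  expect_true(all(is.na(generate_cohort(p)$twin_group)))
})

test_that("register offending rate is binomial and truth is consistent", {
  p <- synth_params(n_cohort = 5000, n_background = 200,
                    offending_rate = 0.15, seed = 13)
  cohort <- generate_cohort(p)
  reg <- generate_police_register(cohort, p)
  n_offenders <- dplyr::n_distinct(reg$truth$study_id)
  bounds <- qbinom(c(0.005, 0.995), 5000, 0.15)
  expect_gte(n_offenders, bounds[1])
  expect_lte(n_offenders, bounds[2])
  # every truth offender_id exists in the register; truth study_ids are
  # cohort members; background subjects never appear in truth
  expect_true(all(reg$truth$offender_id %in% reg$subjects$offender_id))
  expect_true(all(reg$truth$study_id %in% cohort$study_id))
  expect_equal(nrow(reg$subjects),
               nrow(reg$truth) + p$n_background)
})

test_that("fragmentation and corruption switches behave", {
  p0 <- synth_params(n_cohort = 800, n_background = 0,
                     fragmentation_rate = 0, typo_rate = 0,
                     name_variant_rate = 0, stale_address_rate = 0,
                     seed = 5)
  cohort <- generate_cohort(p0)
  reg <- generate_police_register(cohort, p0)
  # one-to-at-most-one and identifier-exact true pairs
  expect_equal(anyDuplicated(reg$truth$study_id), 0L)
  joined <- dplyr::inner_join(
    reg$truth,
    dplyr::select(cohort, study_id, forename, surname, dob),
    by = "study_id") |>
    dplyr::inner_join(
      dplyr::select(reg$subjects, offender_id, s_fn = forename,
                    s_sn = surname, s_dob = dob),
      by = "offender_id")
  expect_true(all(joined$forename == joined$s_fn))
  expect_true(all(joined$surname == joined$s_sn))
  expect_true(all(joined$dob == joined$s_dob))

  pf <- synth_params(n_cohort = 3000, n_background = 0,
                     offending_rate = 0.5, fragmentation_rate = 0.2,
                     seed = 5)
  regf <- generate_police_register(generate_cohort(pf), pf)
  per_person <- table(regf$truth$study_id)
  expect_true(any(per_person == 2L))
  expect_true(all(per_person <= 2L))
})

test_that("group crimes share occurrence ids and dates are ordered", {
  w <- test_world()
  ev <- w$events
  expect_true(all(ev$from_date <= ev$reported_date))
  by_occ <- dplyr::count(ev, occurrence_id, offender_count)
  expect_equal(by_occ$n, by_occ$offender_count)
  grp <- ev[ev$offender_count > 1, ]
  expect_gt(nrow(grp), 0)
  # no offender appears twice in one occurrence
  expect_equal(anyDuplicated(ev[, c("occurrence_id", "offender_id")]), 0L)
})

test_that("legacy 'prosecuted' term replaces disposal terms before the era boundary", {
  w <- test_world()
  terms <- split_terms(w$events$classification_terms)
  pre <- w$events$from_date < w$params$era_boundary
  legacy_terms <- c("cautioned", "adult conditional caution", "tic",
                    "penalty notice for disorder", "cannabis warning",
                    "community resolution")
  pre_has_modern <- vapply(terms[pre], function(t) any(t %in% legacy_terms),
                           logical(1))
  expect_false(any(pre_has_modern))
  expect_true(any(vapply(terms[pre], function(t) "prosecuted" %in% t,
                         logical(1))))
  # and after the boundary the legacy term is never generated
  post_has_legacy <- vapply(terms[!pre], function(t) "prosecuted" %in% t,
                            logical(1))
  expect_false(any(post_has_legacy))
})

test_that("court case fields only appear after the court-data start", {
  w <- test_world()
  with_case <- !is.na(w$events$casefile_id)
  expect_true(all(w$events$reported_date[with_case] >=
                    w$params$court_data_start))
  expect_true(all(w$events$outcome_code[with_case] == "OC1"))
})

test_that("retention implements the review-group and clear-period rules", {
  ev <- dplyr::bind_rows(
    mini_event("X1", "OFF_A", "2010-05-01", mopi_group = 3L),
    mini_event("X2", "OFF_B", "2010-05-01", mopi_group = 1L),
    mini_event("X3", "OFF_C", "2010-05-01", mopi_group = 3L),
    mini_event("X4", "OFF_C", "2012-05-01", mopi_group = 1L)
  )
  kept <- apply_retention(ev, as.Date("2021-07-01"))
  # Group 3 offender with an 11-year clear period: deleted
  expect_false("OFF_A" %in% kept$offender_id)
  # Group 1 records retained regardless
  expect_true("OFF_B" %in% kept$offender_id)
  # most serious offence sets the review category for all offences
  expect_equal(sum(kept$offender_id == "OFF_C"), 2L)

  # recent Group 3 offender (clear period < 6 years): retained
  ev2 <- mini_event("Y1", "OFF_D", "2018-05-01", mopi_group = 3L)
  expect_equal(nrow(apply_retention(ev2, as.Date("2021-07-01"))), 1L)

  expect_error(apply_retention(dplyr::select(ev, -mopi_group),
                               as.Date("2021-07-01")),
               class = "crimelink_validation_error")
})

test_that("retention is monotone in the clear-period threshold", {
  w <- test_world()
  k6 <- apply_retention(w$events, w$params$extraction_date, clear_years = 6,
                        pre_electronic_drop = 0)
  k10 <- apply_retention(w$events, w$params$extraction_date,
                         clear_years = 10, pre_electronic_drop = 0)
  # a longer clear period deletes no more records
  expect_true(nrow(k10) >= nrow(k6))
  expect_equal(nrow(dplyr::anti_join(
    k6, k10, by = c("occurrence_id", "offender_id"))), 0L)
})

test_that("paper-era events are dropped at the configured rate", {
  w <- test_world()
  kept <- apply_retention(w$events, w$params$extraction_date,
                          pre_electronic_drop = 1)
  expect_true(all(kept$from_date >= w$params$electronic_start))
  kept0 <- apply_retention(w$events, w$params$extraction_date,
                           pre_electronic_drop = 0)
  expect_true(any(kept0$from_date < w$params$electronic_start))
})

test_that("csv round-trip preserves the generated tables", {
  w <- test_world(seed = 55, n_cohort = 60, n_background = 30)
  dir <- withr::local_tempdir()
  write_synth_dir(w$cohort, w$subjects, w$events, w$truth, dir)
  back <- read_synth_dir(dir)
  expect_equal(back$cohort$addresses, w$cohort$addresses)
  expect_equal(back$subjects$postcodes, w$subjects$postcodes)
  expect_equal(nrow(back$events), nrow(w$events))
  expect_equal(back$truth, w$truth, ignore_attr = TRUE)
})
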