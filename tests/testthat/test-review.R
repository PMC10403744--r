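# Review rules (twin check, low-confidence review), duplicate resolution,
# ledger conservation, flow report and ground-truth evaluation.

cand_row <- function(study_id, offender_id, method = "probabilistic",
                     strength = NA_integer_, score = 20,
                     forename_exact = TRUE, surname_exact = TRUE,
                     dob_exact = TRUE, postcode_full = FALSE,
                     postcode_outward = FALSE, status = "accepted") {
  tibble::tibble(
    study_id = study_id, offender_id = offender_id, method = method,
    strength = strength, score = score, forename_exact = forename_exact,
    surname_exact = surname_exact, dob_exact = dob_exact,
    postcode_full = postcode_full, postcode_outward = postcode_outward,
    status = status
  )
}

test_that("twin candidates need sex plus forename-prefix agreement", {
  cohort <- dplyr::bind_rows(
    mini_cohort("S1", "JAMIE", "SMITH", "1992-01-10", "M", "ZA1 2CD", "T1"),
    mini_cohort("S2", "CLARA", "SMITH", "1992-01-10", "F", "ZA1 2CD", "T1"),
    mini_cohort("S3", "BOB", "JONES", "1991-06-01", "M", "ZA2 3EF")
  )
  subjects <- dplyr::bind_rows(
    mini_subject("O1", "JAMES", "SMITH", "1992-01-10", "M", "ZA1 2CD"),
    mini_subject("O2", "BOBBY", "JONES", "1991-06-01", "F", "ZA2 3EF")
  )
  cand <- dplyr::bind_rows(
    cand_row("S1", "O1"),                      # twin, sex + "JA" agree
    cand_row("S2", "O1"),                      # twin, sex mismatch
    cand_row("S3", "O2", forename_exact = FALSE)  # not a twin: untouched
  )
  out <- twin_check(cand, cohort, subjects)
  expect_equal(out$status, c("accepted", "removed_twin", "accepted"))
})

test_that("bottom-decile probabilistic links must pass a hard agreement rule", {
  # 10 probabilistic acceptances; scores 1..10 so the bottom decile is the
  # score-1 row; craft several low rows by using 20 rows
  cand <- dplyr::bind_rows(purrr::map(1:20, function(i) {
    cand_row(sprintf("S%02d", i), sprintf("O%02d", i), score = i,
             forename_exact = FALSE, surname_exact = FALSE,
             dob_exact = FALSE, postcode_full = FALSE)
  }))
  # rows 1 and 2 are at/below the 10% quantile of 1..20
  # row 1: forename + full dob -> retained
  cand$forename_exact[1] <- TRUE; cand$dob_exact[1] <- TRUE
  # row 2: surname only -> removed
  cand$surname_exact[2] <- TRUE
  out <- low_confidence_review(cand)
  expect_equal(out$status[1], "accepted")
  expect_equal(out$status[2], "removed_low_confidence")
  # rows above the decile stay accepted whatever their agreements
  expect_true(all(out$status[5:20] == "accepted"))

  # full postcode alone is sufficient
  cand2 <- cand
  cand2$surname_exact[2] <- FALSE; cand2$postcode_full[2] <- TRUE
  expect_equal(low_confidence_review(cand2)$status[2], "accepted")
  # surname + full dob is sufficient
  cand3 <- cand
  cand3$dob_exact[2] <- TRUE
  expect_equal(low_confidence_review(cand3)$status[2], "accepted")
  # deterministic matches are exempt
  cand4 <- cand
  cand4$method[2] <- "deterministic"
  expect_equal(low_confidence_review(cand4)$status[2], "accepted")
})

test_that("duplicate resolution follows the postcode-strength rules", {
  # (a) two study_ids claim one offender: the full-postcode claim wins
  cand <- dplyr::bind_rows(
    cand_row("S1", "OX", postcode_full = TRUE),
    cand_row("S2", "OX", postcode_full = FALSE)
  )
  lt <- resolve_duplicates(cand)
  expect_equal(lt$links$study_id, "S1")
  expect_equal(unname(lt$ledger[["removed_duplicate"]]), 1L)

  # (a) no strong claim at all: remove every claim
  cand2 <- dplyr::bind_rows(
    cand_row("S1", "OX", postcode_full = FALSE),
    cand_row("S2", "OX", postcode_full = FALSE)
  )
  expect_equal(nrow(resolve_duplicates(cand2)$links), 0L)

  # (b) one study with several offender ids, none dob/postcode supported
  cand3 <- dplyr::bind_rows(
    cand_row("S1", "O1", dob_exact = FALSE, postcode_full = FALSE),
    cand_row("S1", "O2", dob_exact = FALSE, postcode_full = FALSE),
    cand_row("S1", "O3", dob_exact = FALSE, postcode_full = FALSE)
  )
  expect_equal(nrow(resolve_duplicates(cand3)$links), 0L)

  # (c) fragmentation: both well-supported offender ids retained
  cand4 <- dplyr::bind_rows(
    cand_row("S1", "O1", dob_exact = TRUE),
    cand_row("S1", "O2", dob_exact = TRUE)
  )
  lt4 <- resolve_duplicates(cand4)
  expect_equal(nrow(lt4$links), 2L)
  expect_equal(dplyr::n_distinct(lt4$links$study_id), 1L)
})

test_that("a deterministic claim outranks a probabilistic one on ties", {
  cand <- dplyr::bind_rows(
    cand_row("S1", "OX", method = "deterministic", strength = 1L,
             score = NA_real_, postcode_full = TRUE),
    cand_row("S2", "OX", postcode_full = TRUE)
  )
  lt <- resolve_duplicates(cand)
  expect_equal(lt$links$study_id, "S1")
  # two equally strong probabilistic claims cannot be adjudicated
  cand2 <- dplyr::bind_rows(
    cand_row("S1", "OX", postcode_full = TRUE),
    cand_row("S2", "OX", postcode_full = TRUE)
  )
  expect_equal(nrow(resolve_duplicates(cand2)$links), 0L)
})

test_that("the link table is one-to-at-most-one on offender ids", {
  w <- test_world()
  lt <- test_linkage(w)$link_table
  expect_equal(anyDuplicated(lt$links$offender_id), 0L)
})

test_that("candidates are conserved: final links plus ledger removals", {
  w <- test_world()
  lk <- test_linkage(w)
  lt <- lk$link_table
  expect_equal(nrow(lk$candidates), nrow(lt$links) + sum(lt$ledger))
})

test_that("twin check and low-confidence review commute on disjoint subsets", {
  cohort <- dplyr::bind_rows(
    mini_cohort("S1", "JAMIE", "SMITH", "1992-01-10", "M", "ZA1 2CD", "T1"),
    mini_cohort("S2", "GRETA", "SMITH", "1992-01-10", "F", "ZA1 2CD", "T1"),
    mini_cohort("S3", "BOB", "JONES", "1991-06-01", "M", "ZA2 3EF"),
    mini_cohort("S4", "DAN", "HILL", "1991-07-01", "M", "ZA3 4GH")
  )
  subjects <- dplyr::bind_rows(
    mini_subject("O1", "JAMES", "SMITH", "1992-01-10", "F", "ZA1 2CD"),
    mini_subject("O2", "ROB", "JONES", "1991-06-01", "M", "ZA2 3EF"),
    mini_subject("O3", "DAN", "HILL", "1991-07-01", "M", "ZA3 4GH")
  )
  # S1/O1 fails the twin rule (sex mismatch); S3/O2 sits in the bottom
  # decile with no qualifying agreement; S4/O3 is clean
  cand <- dplyr::bind_rows(
    cand_row("S1", "O1", score = 30),
    cand_row("S3", "O2", score = 1, forename_exact = FALSE,
             dob_exact = FALSE),
    cand_row("S4", "O3", score = 25)
  )
  ab <- low_confidence_review(twin_check(cand, cohort, subjects))
  ba <- twin_check(low_confidence_review(cand), cohort, subjects)
  expect_equal(ab$status, ba$status)
  expect_equal(ab$status, c("removed_twin", "removed_low_confidence",
                            "accepted"))
})

test_that("flow report counts are internally consistent", {
  w <- test_world()
  lk <- test_linkage(w)
  flow <- flow_report(lk$candidates, lk$link_table)
  g <- function(s) flow$count[flow$stage == s]
  expect_equal(g("deterministic_strength_1") + g("deterministic_strength_2") +
                 g("deterministic_strength_3"), g("deterministic_total"))
  expect_equal(g("deterministic_total") + g("probabilistic_additions"),
               g("candidates_total"))
  expect_equal(g("candidates_total") - g("removed_twin") -
                 g("removed_low_confidence") - g("removed_duplicate"),
               g("final_links"))
  expect_equal(g("distinct_individuals"),
               g("distinct_offender_ids") - g("fragmented_surplus"))
})

test_that("evaluation counts true positives against ground truth", {
  links <- tibble::tibble(study_id = c("S1", "S2", "S3"),
                          offender_id = c("O1", "O2", "O9"))
  truth <- tibble::tibble(study_id = c("S1", "S2", "S4"),
                          offender_id = c("O1", "O2", "O4"))
  ev <- evaluate_links(links, truth)
  expect_equal(ev$true_positive, 2L)
  expect_equal(ev$precision, 2 / 3)
  expect_equal(ev$recall, 2 / 3)
})
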