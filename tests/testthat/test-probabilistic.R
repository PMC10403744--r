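# Fellegi-Sunter scoring, blocking and threshold classification.

# Custom five-field model with m = 0.9, u = 0.1 everywhere: every field
# contributes log2(9) on agreement.
flat_models <- function() {
  tibble::tibble(
    field = c("forename", "surname", "dob", "sex", "postcode"),
    m_prob = 0.9, u_prob = 0.1,
    comparator = c("string_similarity", "string_similarity",
                   "date_components", "exact", "postcode_tiered"),
    similarity_threshold = 1
  )
}

test_that("score is the closed-form sum of field weights", {
  cohort <- mini_cohort("S1", "ALICE", "SMITH", "1992-01-10", "F", "ZA1 2CD")
  subjects <- mini_subject("O1", "ALICE", "SMITH", "1992-01-10", "F",
                           "ZA1 2CD")
  pairs <- tibble::tibble(study_id = "S1", offender_id = "O1")
  sc <- score_pairs(pairs, cohort, subjects, flat_models())
  expect_equal(sc$score, 5 * log2(9), tolerance = 1e-12)

  # flipping one field from agree to disagree strictly decreases the score
  subjects2 <- mini_subject("O1", "ALICE", "SMITH", "1992-01-10", "M",
                            "ZA1 2CD")
  sc2 <- score_pairs(pairs, cohort, subjects2, flat_models())
  expect_equal(sc2$score, 4 * log2(9) + log2(0.1 / 0.9), tolerance = 1e-12)
  expect_lt(sc2$score, sc$score)
})

test_that("missing fields contribute zero weight", {
  cohort <- mini_cohort("S1", "ALICE", "SMITH", "1992-01-10", "F", "ZA1 2CD")
  cohort$forename <- NA_character_
  cohort$surname <- NA_character_
  cohort$dob <- as.Date(NA)
  cohort$sex <- NA_character_
  cohort$addresses <- list(tibble::tibble(postcode = character(),
                                          from_date = as.Date(character()),
                                          to_date = as.Date(character())))
  subjects <- mini_subject("O1", "ALICE", "SMITH", "1992-01-10", "F",
                           "ZA1 2CD")
  sc <- score_pairs(tibble::tibble(study_id = "S1", offender_id = "O1"),
                    cohort, subjects, flat_models())
  expect_equal(sc$score, 0)
})

test_that("m/u validation rejects degenerate models", {
  bad <- flat_models()
  bad$u_prob[1] <- 0.95
  expect_error(fs_weights(bad), class = "crimelink_validation_error")
  w <- fs_weights(fs_field_models())
  expect_true(all(w$agree_weight > 0))
  expect_true(all(w$disagree_weight < 0))
})

test_that("blocking validates its scheme and honours key membership", {
  w <- test_world(seed = 55, n_cohort = 60, n_background = 30)
  expect_error(block_candidates(w$cohort, w$subjects, character(0)),
               class = "crimelink_param_error")
  expect_error(block_candidates(w$cohort, w$subjects, "nope"),
               class = "crimelink_param_error")
  # a pair agreeing only on dob is still blocked together
  cohort <- mini_cohort("S1", "ALICE", "SMITH", "1992-01-10", "F", "ZA1 2CD")
  subjects <- mini_subject("O1", "ZOE", "WOOD", "1992-01-10", "F", "ZB2 9XY")
  b <- block_candidates(cohort, subjects)
  expect_equal(nrow(b), 1L)
})

test_that("a single dob key equals the brute-force dob-equality join", {
  w <- test_world(seed = 55, n_cohort = 60, n_background = 30)
  blocked <- block_candidates(w$cohort, w$subjects, scheme = "dob")
  brute <- expand.grid(ci = seq_len(nrow(w$cohort)),
                       si = seq_len(nrow(w$subjects)))
  brute <- tibble::tibble(
    study_id = w$cohort$study_id[brute$ci],
    offender_id = w$subjects$offender_id[brute$si],
    same = w$cohort$dob[brute$ci] == w$subjects$dob[brute$si]
  ) |> dplyr::filter(same) |> dplyr::select(-same)
  expect_setequal(paste(blocked$study_id, blocked$offender_id),
                  paste(brute$study_id, brute$offender_id))
})

test_that("default blocking retains true pairs", {
  w <- test_world()
  blocked <- block_candidates(w$cohort, w$subjects)
  retained <- dplyr::semi_join(w$truth, blocked,
                               by = c("study_id", "offender_id"))
  expect_gte(nrow(retained) / nrow(w$truth), 0.99)
})

test_that("blocking + scoring equals exhaustive all-pairs scoring", {
  w <- test_world(seed = 77, n_cohort = 200, n_background = 120,
                  offending_rate = 0.4)
  subjects <- w$subjects[seq_len(min(200, nrow(w$subjects))), ]
  models <- fs_field_models()  # fixed models so both routes share weights
  all_pairs <- tidyr::expand_grid(study_id = w$cohort$study_id,
                                  offender_id = subjects$offender_id)
  exhaustive <- classify_pairs(
    score_pairs(all_pairs, w$cohort, subjects, models))
  routed <- classify_pairs(
    score_pairs(block_candidates(w$cohort, subjects), w$cohort, subjects,
                models))
  key <- function(d) sort(paste(d$study_id, d$offender_id, d$score))
  expect_equal(key(routed), key(exhaustive))
})

test_that("classification respects the threshold and is monotone", {
  w <- test_world(seed = 55, n_cohort = 60, n_background = 30)
  scored <- score_pairs(block_candidates(w$cohort, w$subjects), w$cohort,
                        w$subjects, fs_field_models())
  expect_equal(nrow(classify_pairs(scored, max(scored$score) + 1)), 0L)
  expect_equal(nrow(classify_pairs(scored, -Inf)), nrow(scored))
  thresholds <- seq(-5, 30, by = 5)
  counts <- vapply(thresholds,
                   function(t) nrow(classify_pairs(scored, t)), integer(1))
  expect_true(all(diff(counts) <= 0))
  expect_true(all(classify_pairs(scored, 10)$score >= 10))
})

test_that("EM refinement recovers agreement structure from the pairs", {
  w <- test_world()
  lk <- test_linkage(w)
  refined <- fs_em_refine(lk$scored, lk$models)
  # agreement on true matches is near-certain for names and dob; the
  # refined u are conditional on blocked (key-sharing) pairs, so they sit
  # above population chance rates but stay well below m
  expect_gt(refined$m_prob[refined$field == "dob"], 0.9)
  expect_gt(refined$m_prob[refined$field == "forename"], 0.9)
  expect_true(all(refined$m_prob > refined$u_prob))
  # refined weights still separate true from false pairs
  rescored <- score_pairs(lk$blocked, w$cohort, w$subjects, refined)
  truth_scores <- dplyr::semi_join(rescored, w$truth,
                                   by = c("study_id", "offender_id"))$score
  other_scores <- dplyr::anti_join(rescored, w$truth,
                                   by = c("study_id", "offender_id"))$score
  expect_gt(stats::median(truth_scores), stats::quantile(other_scores, 0.99))
})

test_that("deterministic matches are a subset of probabilistic acceptances", {
  w <- test_world()
  lk <- test_linkage(w)
  missing <- dplyr::anti_join(lk$det, lk$prob,
                              by = c("study_id", "offender_id"))
  expect_equal(nrow(missing), 0L)
})
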