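# Shared synthetic worlds, generated once per test run and memoised by
# parameter signature so several tests can reuse the same fixture.

.world_cache <- new.env(parent = emptyenv())

test_world <- function(seed = 101, n_cohort = 1000, n_background = 700, ...) {
  key <- paste(deparse(list(seed, n_cohort, n_background, ...)),
               collapse = "")
  key <- rlang::hash(key)
  if (!is.null(.world_cache[[key]])) return(.world_cache[[key]])
  p <- synth_params(n_cohort = n_cohort, n_background = n_background,
                    seed = seed, ...)
  cohort <- generate_cohort(p)
  reg <- generate_police_register(cohort, p)
  events <- generate_events(reg$subjects, p)
  w <- list(params = p, cohort = cohort, subjects = reg$subjects,
            truth = reg$truth, events = events)
  .world_cache[[key]] <- w
  w
}

# Stage 1 run on a world, memoised alongside it.
test_linkage <- function(world, threshold = fs_default_threshold()) {
  key <- rlang::hash(list(world$params, threshold))
  if (!is.null(.world_cache[[key]])) return(.world_cache[[key]])
  det <- deterministic_link(world$cohort, world$subjects)
  models <- fs_field_models(world$subjects)
  blocked <- block_candidates(world$cohort, world$subjects)
  scored <- score_pairs(blocked, world$cohort, world$subjects, models)
  prob <- classify_pairs(scored, threshold)
  cand <- combine_candidates(det, prob)
  cand <- twin_check(cand, world$cohort, world$subjects)
  cand <- low_confidence_review(cand)
  lt <- resolve_duplicates(cand)
  out <- list(det = det, models = models, blocked = blocked,
              scored = scored, prob = prob, candidates = cand,
              link_table = lt)
  .world_cache[[key]] <- out
  out
}

# Minimal hand-built cohort row with a given address history.
mini_cohort <- function(study_id, forename, surname, dob, sex,
                        postcodes, twin_group = NA_character_) {
  from <- as.Date(dob) + seq(0, by = 3000, length.out = length(postcodes))
  to <- c(from[-1] - 1, as.Date("2021-07-01"))
  tibble::tibble(
    study_id = study_id, forename = forename, surname = surname,
    dob = as.Date(dob), sex = sex, twin_group = twin_group,
    linkage_permitted = TRUE,
    addresses = list(tibble::tibble(postcode = postcodes,
                                    from_date = from, to_date = to))
  )
}

mini_subject <- function(offender_id, forename, surname, dob, sex,
                         postcodes) {
  tibble::tibble(
    offender_id = offender_id, forename = forename, surname = surname,
    dob = as.Date(dob), sex = sex, postcodes = list(postcodes)
  )
}

# Minimal event row for filter/severity/disclosure tests.
mini_event <- function(occurrence_id, offender_id, from_date,
                       outcome_code = "OC1", offender_count = 1L,
                       terms = "suspect; arrested; charged",
                       ho_code = "HO105.1", mopi_group = 3L,
                       offence_group = "Theft",
                       reported_date = from_date) {
  tibble::tibble(
    occurrence_id = occurrence_id, offender_id = offender_id,
    created_date = as.Date(reported_date),
    reported_date = as.Date(reported_date),
    from_date = as.Date(from_date), ho_code = ho_code,
    offence_group = offence_group, offender_count = offender_count,
    outcome_code = outcome_code, classification_terms = terms,
    da_flag = FALSE, knife_flag = FALSE, drugs_flag = FALSE,
    alcohol_flag = NA, substance_use = NA_character_,
    scorexmultiplier = 0.01, mopi_group = mopi_group,
    casefile_id = NA_character_, casefile_date = as.Date(NA),
    verdict = NA_character_
  )
}
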