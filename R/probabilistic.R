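# Stage 1, step two: Fellegi-Sunter probabilistic scoring. Each field
# comparison contributes log2(m/u) when it agrees (similarity at or above
# the field's threshold) and log2((1-m)/(1-u)) when it disagrees; missing
# values contribute nothing. Pair scores are the sum over fields, and pairs
# at or above a score threshold are designated matches. This stands in for
# the commercial linkage engine the original study ran with default
# settings; comparators, m/u values, blocking scheme and threshold are all
# configuration here.

#' Default field models for probabilistic scoring
#'
#' One row per identifier field with its m-probability (chance the field
#' agrees on a true match), u-probability (chance it agrees on a random
#' non-match), comparator and agreement threshold. When a subject register
#' is supplied, u-probabilities for names and date of birth are estimated
#' from its value frequencies (the probability two randomly chosen records
#' agree, `sum(p^2)`); otherwise pool-based defaults are used.
#'
#' @param subjects Optional subject register used to estimate
#'   u-probabilities. Frequency estimates are used only when the register
#'   has at least `min_freq_n` rows; sparser registers make `sum(p^2)`
#'   collapse towards `1/n` (every value looks unique), which would
#'   misprice chance agreement, so pool-based defaults are kept instead.
#' @param min_freq_n Minimum register size for frequency-based estimation.
#' @return A tibble with columns `field`, `m_prob`, `u_prob`, `comparator`,
#'   `similarity_threshold`, and the partial-agreement probabilities
#'   `m_partial`, `u_partial` (postcode only: the chance of outward-level
#'   agreement given no full-postcode match).
#' @export
fs_field_models <- function(subjects = NULL, min_freq_n = 500L) {
  u <- c(forename = 0.016, surname = 0.007, dob = 1 / 760,
         sex = 0.5, postcode = 5e-4)
  u_outward <- 0.01
  if (!is.null(subjects) && nrow(subjects) >= min_freq_n) {
    agree_prob <- function(x) {
      p <- table(x) / length(x)
      max(sum(p^2), 1e-6)
    }
    u[["forename"]] <- agree_prob(normalise_name(subjects$forename))
    u[["surname"]] <- agree_prob(normalise_name(subjects$surname))
    u[["dob"]] <- agree_prob(as.character(subjects$dob))
    u[["sex"]] <- agree_prob(subjects$sex)
    u_outward <- agree_prob(
      postcode_parts(vapply(subjects$postcodes, `[`, character(1), 1))$outward)
  }
  models <- tibble::tibble(
    field = c("forename", "surname", "dob", "sex", "postcode"),
    m_prob = c(0.95, 0.95, 0.95, 0.98, 0.70),
    u_prob = unname(u[c("forename", "surname", "dob", "sex", "postcode")]),
    comparator = c("string_similarity", "string_similarity",
                   "date_components", "exact", "postcode_tiered"),
    similarity_threshold = c(0.85, 0.85, 0.85, 1, 1),
    m_partial = c(NA, NA, NA, NA, 0.75),
    u_partial = c(NA, NA, NA, NA, u_outward)
  )
  validate_field_models(models)
  models
}

validate_field_models <- function(models) {
  req <- c("field", "m_prob", "u_prob", "comparator", "similarity_threshold")
  if (!all(req %in% names(models))) {
    abort("field models need columns field, m_prob, u_prob, comparator, similarity_threshold",
          class = "crimelink_validation_error")
  }
  bad <- models$m_prob <= models$u_prob |
    models$m_prob <= 0 | models$m_prob >= 1 |
    models$u_prob <= 0 | models$u_prob >= 1
  if (any(bad)) {
    abort(sprintf(
      "m/u probabilities invalid for field(s): %s (need 0 < u < m < 1)",
      paste(models$field[bad], collapse = ", ")),
      class = "crimelink_validation_error")
  }
  invisible(models)
}

#' Agreement and disagreement weights of field models
#'
#' @param models A field-model tibble ([fs_field_models()]).
#' @return The models with `agree_weight = log2(m/u)` (positive),
#'   `disagree_weight = log2((1-m)/(1-u))` (negative) and, where partial
#'   probabilities are defined, `partial_weight = log2(m_partial/u_partial)`
#'   columns added.
#' @export
fs_weights <- function(models) {
  validate_field_models(models)
  out <- models |>
    mutate(agree_weight = log2(.data$m_prob / .data$u_prob),
           disagree_weight = log2((1 - .data$m_prob) / (1 - .data$u_prob)))
  if (all(c("m_partial", "u_partial") %in% names(models))) {
    out <- mutate(out, partial_weight =
                    log2(.data$m_partial / .data$u_partial))
  } else {
    out$partial_weight <- NA_real_
  }
  out
}

# --- blocking ----------------------------------------------------------------

.blocking_keys <- list(
  # full date of birth
  dob = function(df) as.character(df$dob),
  # birth year + surname initial
  yob_sur1 = function(df) {
    paste(lubridate::year(df$dob),
          substr(normalise_name(df$surname), 1, 1))
  },
  # full surname + forename initial
  sur_fn1 = function(df) {
    paste(normalise_name(df$surname),
          substr(normalise_name(df$forename), 1, 1))
  }
)

#' Candidate pairs sharing any blocking key
#'
#' Restricts comparison to pairs agreeing on at least one key of the
#' scheme, avoiding the full cross-product. The default scheme (full date
#' of birth; birth year + surname initial; surname + forename initial) is
#' redundant by design so that a single corrupted field cannot exclude a
#' true pair.
#'
#' @param cohort,subjects Roster and register tibbles.
#' @param scheme Character vector naming keys among `"dob"`, `"yob_sur1"`,
#'   `"sur_fn1"`. Must be non-empty.
#' @return A distinct tibble of `study_id`, `offender_id` pairs.
#' @export
block_candidates <- function(cohort, subjects,
                             scheme = c("dob", "yob_sur1", "sur_fn1")) {
  if (length(scheme) == 0L) {
    abort("blocking scheme must name at least one key",
          class = "crimelink_param_error")
  }
  unknown <- setdiff(scheme, names(.blocking_keys))
  if (length(unknown) > 0L) {
    abort(sprintf("unknown blocking key(s): %s",
                  paste(unknown, collapse = ", ")),
          class = "crimelink_param_error")
  }
  if (nrow(cohort) == 0L || nrow(subjects) == 0L) {
    return(tibble::tibble(study_id = character(), offender_id = character()))
  }
  purrr::map(scheme, function(k) {
    fn <- .blocking_keys[[k]]
    ck <- tibble::tibble(study_id = cohort$study_id, key = fn(cohort))
    sk <- tibble::tibble(offender_id = subjects$offender_id,
                         key = fn(subjects))
    inner_join(ck, sk, by = "key", relationship = "many-to-many") |>
      select("study_id", "offender_id")
  }) |>
    bind_rows() |>
    distinct()
}

# --- scoring -----------------------------------------------------------------

#' Score candidate pairs with the Fellegi-Sunter model
#'
#' For each pair, every non-missing field contributes its agreement weight
#' when the comparator similarity reaches the field's threshold and its
#' disagreement weight otherwise; the score is the sum. Per-field exact
#' agreement indicators are carried along for the downstream review rules,
#' which are hard equality checks, not similarity checks.
#'
#' @param pairs Tibble of `study_id`, `offender_id` pairs (e.g. from
#'   [block_candidates()]).
#' @param cohort,subjects Roster and register tibbles.
#' @param models Field models ([fs_field_models()]).
#' @details Per field the contribution is: the agreement weight when the
#'   similarity reaches the field's threshold; the partial weight when the
#'   model defines one and the similarity reaches 0.5 (postcode
#'   outward-level agreement); otherwise the disagreement weight. Missing
#'   values contribute 0.
#' @return `pairs` with `score`, per-field similarity columns (`sim_*`) and
#'   exact-agreement columns (`forename_exact`, `surname_exact`,
#'   `dob_exact`, `sex_exact`, `postcode_full`, `postcode_outward`).
#' @export
score_pairs <- function(pairs, cohort, subjects,
                        models = fs_field_models(subjects)) {
  w <- fs_weights(models)
  if (nrow(pairs) == 0L) {
    return(mutate(pairs, score = numeric(0)))
  }
  cdat <- cohort |>
    mutate(c_forename = normalise_name(.data$forename),
           c_surname = normalise_name(.data$surname),
           c_pc = cohort_postcode_sets(cohort)) |>
    select("study_id", "c_forename", "c_surname", c_dob = "dob",
           c_sex = "sex", "c_pc")
  sdat <- subjects |>
    mutate(s_forename = normalise_name(.data$forename),
           s_surname = normalise_name(.data$surname)) |>
    select("offender_id", "s_forename", "s_surname", s_dob = "dob",
           s_sex = "sex", s_pc = "postcodes")
  d <- pairs |>
    left_join(cdat, by = "study_id") |>
    left_join(sdat, by = "offender_id")

  # postcode tiers via set joins (vectorised over all pairs)
  cpc <- tibble::tibble(
    study_id = rep(cdat$study_id, lengths(cdat$c_pc)),
    pc = unlist(cdat$c_pc)
  ) |> semi_join(pairs, by = "study_id")
  spc <- tibble::tibble(
    offender_id = rep(sdat$offender_id, lengths(sdat$s_pc)),
    pc = unlist(sdat$s_pc)
  ) |> semi_join(pairs, by = "offender_id")
  full_pairs <- inner_join(cpc, spc, by = "pc",
                           relationship = "many-to-many") |>
    distinct(.data$study_id, .data$offender_id) |>
    mutate(.full = TRUE)
  out_pairs <- inner_join(
    mutate(cpc, ow = postcode_parts(.data$pc)$outward) |>
      distinct(.data$study_id, .data$ow),
    mutate(spc, ow = postcode_parts(.data$pc)$outward) |>
      distinct(.data$offender_id, .data$ow),
    by = "ow", relationship = "many-to-many") |>
    distinct(.data$study_id, .data$offender_id) |>
    mutate(.outward = TRUE)
  d <- d |>
    left_join(full_pairs, by = c("study_id", "offender_id")) |>
    left_join(out_pairs, by = c("study_id", "offender_id"))
  pc_missing <- lengths(d$c_pc) == 0L | lengths(d$s_pc) == 0L
  sim_pc <- ifelse(pc_missing, NA_real_,
                   ifelse(!is.na(d$.full), 1,
                          ifelse(!is.na(d$.outward), 0.5, 0)))

  sims <- list(
    forename = field_similarity(d$c_forename, d$s_forename,
                                "string_similarity"),
    surname = field_similarity(d$c_surname, d$s_surname,
                               "string_similarity"),
    dob = field_similarity(d$c_dob, d$s_dob, "date_components"),
    sex = field_similarity(d$c_sex, d$s_sex, "exact"),
    postcode = sim_pc
  )

  score <- numeric(nrow(d))
  for (f in w$field) {
    wf <- w[w$field == f, ]
    s <- sims[[f]]
    contrib <- ifelse(
      is.na(s), 0,
      ifelse(s >= wf$similarity_threshold, wf$agree_weight,
             ifelse(!is.na(wf$partial_weight) & s >= 0.5,
                    wf$partial_weight, wf$disagree_weight)))
    score <- score + contrib
  }

  pairs |>
    mutate(
      score = score,
      sim_forename = sims$forename, sim_surname = sims$surname,
      sim_dob = sims$dob, sim_sex = sims$sex, sim_postcode = sims$postcode,
      forename_exact = !is.na(sims$forename) &
        d$c_forename == d$s_forename,
      surname_exact = !is.na(sims$surname) & d$c_surname == d$s_surname,
      dob_exact = !is.na(sims$dob) & d$c_dob == d$s_dob,
      sex_exact = !is.na(sims$sex) & sims$sex == 1,
      postcode_full = !is.na(sims$postcode) & sims$postcode == 1,
      postcode_outward = !is.na(sims$postcode) & sims$postcode >= 0.5
    )
}

#' EM refinement of m/u probabilities
#'
#' Classic two-class mixture EM on the per-field binary agreement patterns
#' of scored pairs: pairs are latently matches or non-matches; the E-step
#' computes each pair's match posterior from the current m/u and match
#' proportion, the M-step re-estimates them from posterior-weighted
#' agreement rates. Missing fields are ignored per pair. Off by default —
#' the shipped m/u values are deliberate configuration — but available for
#' registers whose agreement structure differs from the defaults.
#'
#' @param scored Output of [score_pairs()] (its `sim_*` columns are used).
#' @param models Field models to refine.
#' @param max_iter,tol Iteration cap and convergence tolerance on
#'   parameter change.
#' @return The models with refined `m_prob`/`u_prob` (probabilities are
#'   clamped to keep m > u and both inside (0, 1)).
#' @export
fs_em_refine <- function(scored, models, max_iter = 50, tol = 1e-6) {
  w <- fs_weights(models)
  gam <- vapply(w$field, function(f) {
    s <- scored[[paste0("sim_", f)]]
    thr <- w$similarity_threshold[w$field == f]
    ifelse(is.na(s), NA_real_, as.numeric(s >= thr))
  }, numeric(nrow(scored)))
  m <- w$m_prob
  u <- w$u_prob
  p <- 0.01
  clamp <- function(x) pmin(pmax(x, 1e-4), 1 - 1e-4)
  for (it in seq_len(max_iter)) {
    # E-step: per-pair match posterior over non-missing fields
    lm_ <- rep(log(p), nrow(gam))
    lu_ <- rep(log(1 - p), nrow(gam))
    for (j in seq_along(m)) {
      g <- gam[, j]
      ok <- !is.na(g)
      lm_[ok] <- lm_[ok] + ifelse(g[ok] == 1, log(m[j]), log(1 - m[j]))
      lu_[ok] <- lu_[ok] + ifelse(g[ok] == 1, log(u[j]), log(1 - u[j]))
    }
    post <- 1 / (1 + exp(lu_ - lm_))
    # M-step
    m_new <- vapply(seq_along(m), function(j) {
      ok <- !is.na(gam[, j])
      clamp(sum(post[ok] * gam[ok, j]) / sum(post[ok]))
    }, numeric(1))
    u_new <- vapply(seq_along(u), function(j) {
      ok <- !is.na(gam[, j])
      clamp(sum((1 - post[ok]) * gam[ok, j]) / sum(1 - post[ok]))
    }, numeric(1))
    p_new <- clamp(mean(post))
    delta <- max(abs(c(m_new - m, u_new - u, p_new - p)))
    m <- m_new; u <- u_new; p <- p_new
    if (delta < tol) break
  }
  # keep weights well-defined
  bad <- m <= u
  if (any(bad)) {
    m[bad] <- pmin(u[bad] + 0.05, 1 - 1e-4)
  }
  out <- models
  out$m_prob <- m
  out$u_prob <- u
  validate_field_models(out)
  out
}

#' Default probabilistic acceptance threshold
#'
#' Sits above the score of chance pairs agreeing on a single name plus
#' date of birth and sex (~16-17.5 under the default field models) and
#' below the weakest true-match configuration — both names and date of
#' birth agreeing with a stale postcode (~20-22) — so deterministic
#' matches always clear it. See the methods vignette for the calibration
#' reasoning.
#'
#' @return A single number (score threshold, log2 scale).
#' @export
fs_default_threshold <- function() 18

#' Designate scored pairs as probabilistic matches
#'
#' Keeps every pair whose score reaches the threshold. One-to-one
#' resolution is deliberately deferred to the review stage
#' ([resolve_duplicates()]).
#'
#' @param scored Output of [score_pairs()].
#' @param threshold Finite score threshold.
#' @return Accepted pairs with `method = "probabilistic"` and
#'   `status = "accepted"`.
#' @export
classify_pairs <- function(scored, threshold = fs_default_threshold()) {
  if (!is.finite(threshold) && !identical(threshold, -Inf)) {
    abort("threshold must be finite (or -Inf to accept all)",
          class = "crimelink_param_error")
  }
  scored |>
    filter(.data$score >= threshold) |>
    mutate(method = "probabilistic", status = "accepted")
}

#' Combine deterministic and probabilistic candidates
#'
#' Deterministic matches take precedence: a pair found by both routes is
#' kept once, labelled deterministic (its exact-identifier evidence is the
#' stronger claim), with its probabilistic score attached for reference.
#'
#' @param det Deterministic candidates ([deterministic_link()]).
#' @param prob Accepted probabilistic candidates ([classify_pairs()]).
#' @return A single candidate tibble.
#' @export
combine_candidates <- function(det, prob) {
  prob_only <- anti_join(prob, det, by = c("study_id", "offender_id"))
  det_scored <- det |>
    left_join(select(prob, "study_id", "offender_id", prob_score = "score"),
              by = c("study_id", "offender_id")) |>
    mutate(score = .data$prob_score) |>
    select(-"prob_score")
  bind_rows(det_scored, mutate(prob_only, strength = NA_integer_)) |>
    arrange(.data$study_id, .data$offender_id)
}
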