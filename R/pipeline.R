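# End-to-end orchestration: generate -> link -> review -> filter -> score
# -> release -> tabulate, with a run manifest, removal ledger, flow report
# and (when ground truth is present) precision/recall evaluation.

#' Run the full linkage pipeline
#'
#' Generates (or loads) the inputs, runs Stage 1 (deterministic +
#' probabilistic matching, twin check, low-confidence review, duplicate
#' resolution), Stage 2 (retention sweep, disposal-eligibility filtering),
#' severity checks, disclosure control and residence flags. Every stage
#' output is written as CSV under `out_dir` together with `ledger.json`,
#' `flow_report.csv`, `evaluation.csv` and a `manifest.json` recording the
#' configuration hash, seed and per-stage row counts. The run is
#' deterministic given the seed.
#'
#' @param params A [synth_params()] object (its seed drives all
#'   randomness).
#' @param out_dir Output directory, or `NULL` to skip writing files.
#' @param threshold Probabilistic acceptance threshold.
#' @param em Refine m/u probabilities by EM ([fs_em_refine()]) on the
#'   blocked pairs before classification. Off by default.
#' @param config A [release_config()] list.
#' @return A list with `cohort`, `subjects`, `truth`, `events`,
#'   `events_retained`, `candidates`, `link_table`, `flow`, `evaluation`,
#'   `linked_events`, `counts`, `release`, `drop_report`, `flags`,
#'   `denominator`, `manifest`.
#' @export
run_pipeline <- function(params = synth_params(), out_dir = NULL,
                         threshold = fs_default_threshold(), em = FALSE,
                         config = release_config()) {
  stopifnot(inherits(params, "synth_params"))

  cohort <- generate_cohort(params)
  reg <- generate_police_register(cohort, params)
  events <- generate_events(reg$subjects, params)
  set.seed(stream_seed(params$seed, "pipeline"))
  events_retained <- apply_retention(
    events, params$extraction_date,
    electronic_start = params$electronic_start,
    pre_electronic_drop = params$pre_electronic_drop
  )

  linkable <- filter(cohort, .data$linkage_permitted)
  det <- deterministic_link(linkable, reg$subjects)
  models <- fs_field_models(reg$subjects)
  blocked <- block_candidates(linkable, reg$subjects)
  scored <- score_pairs(blocked, linkable, reg$subjects, models)
  if (em) {
    models <- fs_em_refine(scored, models)
    scored <- score_pairs(blocked, linkable, reg$subjects, models)
  }
  prob <- classify_pairs(scored, threshold)
  candidates <- combine_candidates(det, prob)
  candidates <- twin_check(candidates, linkable, reg$subjects)
  candidates <- low_confidence_review(candidates)
  link_table <- resolve_duplicates(candidates)
  flow <- flow_report(candidates, link_table)
  evaluation <- evaluate_links(link_table, reg$truth)

  linked_events <- filter_events(events_retained, link_table)
  counts <- count_records_and_offences(linked_events)
  rel <- build_release(linked_events, cohort, config)
  flags <- residence_flags(cohort)
  denom <- denominator_summary(flags)

  manifest <- list(
    seed = params$seed,
    config_hash = rlang::hash(list(params = unclass(params),
                                   threshold = threshold, em = em,
                                   config = config)),
    stage_counts = list(
      cohort = nrow(cohort), subjects = nrow(reg$subjects),
      truth = nrow(reg$truth), events = nrow(events),
      events_retained = nrow(events_retained),
      candidates = nrow(candidates), links = nrow(link_table$links),
      removed = sum(link_table$ledger),
      linked_events = nrow(linked_events),
      release_rows = nrow(rel$release)
    )
  )

  result <- list(
    cohort = cohort, subjects = reg$subjects, truth = reg$truth,
    events = events, events_retained = events_retained,
    candidates = candidates, link_table = link_table, flow = flow,
    evaluation = evaluation, linked_events = linked_events,
    counts = counts, release = rel$release, drop_report = rel$drop_report,
    flags = flags, denominator = denom, manifest = manifest
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_synth_dir(cohort, reg$subjects, events, reg$truth, out_dir)
    readr::write_csv(select(candidates, -dplyr::any_of("cpc")),
                     file.path(out_dir, "candidates.csv"))
    readr::write_csv(link_table$links, file.path(out_dir, "link_table.csv"))
    jsonlite::write_json(as.list(link_table$ledger),
                         file.path(out_dir, "ledger.json"),
                         auto_unbox = TRUE)
    readr::write_csv(flow, file.path(out_dir, "flow_report.csv"))
    readr::write_csv(evaluation, file.path(out_dir, "evaluation.csv"))
    readr::write_csv(linked_events, file.path(out_dir, "linked_events.csv"))
    readr::write_csv(rel$release, file.path(out_dir, "release.csv"))
    jsonlite::write_json(rel$drop_report,
                         file.path(out_dir, "drop_report.json"),
                         auto_unbox = TRUE)
    readr::write_csv(flags, file.path(out_dir, "flags.csv"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE)
  }
  result
}
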