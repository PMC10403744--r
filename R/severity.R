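# Crime-harm severity: a base harm score per Home Office offence code,
# inflated by cumulative percentage multipliers for aggravating factors.
# The police use these scores to monitor harm rather than crime volume.

#' Default harm-score table
#'
#' The bundled table carries the nine published exemplar harm scores —
#' offences spanning the full 0.01..100 range — under synthetic Home Office
#' style codes, plus the review (retention) group each offence falls into.
#' The force's complete internal table is not public; analyses with a fuller
#' table supply their own via the `table` argument of [base_harm()] /
#' [score_severity()] or a YAML config (see [read_harm_table()]).
#'
#' @return A tibble with columns `ho_code`, `description`, `harm_score`,
#'   `mopi_group`.
#' @examples
#' default_harm_table()
#' @export
default_harm_table <- function() {
  tibble::tribble(
    ~ho_code,  ~description,                                     ~harm_score, ~mopi_group,
    "HO105.1", "minor public order offence",                     0.01,        3L,
    "HO092.1", "possession with intent to supply class A drugs", 0.8,         3L,
    "HO005.1", "wounding with intent to do serious bodily harm", 1.45,        2L,
    "HO019.1", "rape",                                           2.9,         2L,
    "HO106.1", "conspiring to traffic a person into the UK for exploitation", 8, 2L,
    "HO086.1", "causing or inciting child pornography",          10,          2L,
    "HO004.1", "manslaughter",                                   30,          1L,
    "HO114.1", "use of noxious substance in terrorism offence",  50,          1L,
    "HO001.1", "murder",                                         100,         1L
  )
}

validate_harm_table <- function(table) {
  req <- c("ho_code", "harm_score")
  if (!all(req %in% names(table))) {
    abort("harm table needs columns `ho_code` and `harm_score`",
          class = "crimelink_validation_error")
  }
  if (any(table$harm_score <= 0)) {
    abort("harm scores must be positive",
          class = "crimelink_validation_error")
  }
  if (anyDuplicated(table$ho_code)) {
    abort("duplicated ho_code in harm table",
          class = "crimelink_validation_error")
  }
  # published tables have no score strictly between 3 and 8; user tables
  # violating the gap are suspicious but not invalid
  gap <- table$harm_score > 3 & table$harm_score < 8
  if (any(gap)) {
    warn(sprintf(
      "%d harm score(s) fall in the (3, 8) gap no published offence occupies",
      sum(gap)))
  }
  invisible(table)
}

#' Read a harm table from a YAML config
#'
#' The file maps offence codes to entries with `harm_score` and optionally
#' `description` and `mopi_group`.
#'
#' @param path Path to a YAML file.
#' @return A harm-table tibble (see [default_harm_table()]).
#' @export
read_harm_table <- function(path) {
  raw <- yaml::read_yaml(path)
  tbl <- purrr::imap(raw, function(entry, code) {
    tibble::tibble(
      ho_code = code,
      description = entry$description %||% NA_character_,
      harm_score = as.numeric(entry$harm_score),
      mopi_group = as.integer(entry$mopi_group %||% 3L)
    )
  }) |> bind_rows()
  validate_harm_table(tbl)
  tbl
}

#' Base harm score for an offence code
#'
#' @param ho_code Character vector of offence codes.
#' @param table Harm table; defaults to [default_harm_table()].
#' @return Numeric vector of base harm scores. Unknown codes are an error —
#'   a silent default would corrupt severity aggregates.
#' @examples
#' base_harm("HO001.1")  # murder, 100
#' @export
base_harm <- function(ho_code, table = default_harm_table()) {
  validate_harm_table(table)
  idx <- match(ho_code, table$ho_code)
  if (anyNA(idx)) {
    abort(sprintf("unknown ho_code(s): %s",
                  paste(unique(ho_code[is.na(idx)]), collapse = ", ")),
          class = "crimelink_lookup_error")
  }
  table$harm_score[idx]
}

#' Aggravating-factor flags for severity multipliers
#'
#' @param domestic_abuse,hate,drug,firearm,safeguarding_children Logical
#'   vectors (recycled to a common length). `NA` is treated as absent.
#' @return A tibble of five logical columns.
#' @export
severity_flags <- function(domestic_abuse = FALSE, hate = FALSE,
                           drug = FALSE, firearm = FALSE,
                           safeguarding_children = FALSE) {
  tbl <- tibble::tibble(
    domestic_abuse = domestic_abuse %|NA|% FALSE,
    hate = hate %|NA|% FALSE,
    drug = drug %|NA|% FALSE,
    firearm = firearm %|NA|% FALSE,
    safeguarding_children = safeguarding_children %|NA|% FALSE
  )
  tbl
}

`%|NA|%` <- function(x, y) ifelse(is.na(x), y, x)

.multipliers <- c(
  domestic_abuse = 1.30,     # +30%
  hate = 1.50,               # +50%
  drug = 1.05,               # +5%
  firearm = 1.10,            # +10%
  safeguarding_children = 1.30 # +30%
)

#' Apply cumulative severity multipliers to a base harm score
#'
#' Each present factor inflates the score: +30% domestic abuse, +50% hate,
#' +5% drug, +10% firearm, +30% safeguarding children. Multipliers are
#' cumulative and applied in that order; with no intermediate rounding the
#' product is the same under any order, which is the reading adopted here
#' (and tested).
#'
#' @param base Positive numeric vector of base harm scores.
#' @param flags A [severity_flags()] tibble (rows recycled against `base`).
#' @return Numeric vector of severity scores.
#' @examples
#' apply_multipliers(1.45, severity_flags(domestic_abuse = TRUE))  # 1.885
#' @export
apply_multipliers <- function(base, flags) {
  if (any(base <= 0)) {
    abort("base harm scores must be positive",
          class = "crimelink_validation_error")
  }
  n <- max(length(base), nrow(flags))
  base <- rep_len(base, n)
  out <- base
  for (f in names(.multipliers)) {
    on <- rep_len(flags[[f]], n)
    out <- out * ifelse(on, .multipliers[[f]], 1)
  }
  out
}

#' Severity score for events
#'
#' Convenience wrapper: look up the base harm score for each offence code
#' and apply the multiplier flags.
#'
#' @inheritParams base_harm
#' @param flags A [severity_flags()] tibble, one row per code.
#' @return Numeric vector of `scorexmultiplier` values.
#' @export
score_severity <- function(ho_code, flags, table = default_harm_table()) {
  apply_multipliers(base_harm(ho_code, table), flags)
}
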