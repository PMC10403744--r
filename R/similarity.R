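# Field comparators for probabilistic matching. Values are similarities in
# [0, 1]: 1 for identical values, symmetric in their arguments.

#' Normalise a name for comparison
#'
#' Case-folds, transliterates accents to ASCII, strips punctuation and
#' collapses whitespace. Used before both deterministic and probabilistic
#' comparison; nickname expansion is deliberately not part of
#' normalisation (exact matching stays exact).
#'
#' @param x Character vector.
#' @return Character vector of normalised names.
#' @export
normalise_name <- function(x) {
  x <- toupper(trimws(x))
  x <- iconv(x, from = "", to = "ASCII//TRANSLIT")
  x <- gsub("[^A-Z ]", "", x)
  gsub(" +", " ", x)
}

# Pure-R Jaro similarity (scalar): reference implementation used to
# cross-check the compiled kernel in the test suite.
jaro_r <- function(a, b) {
  la <- nchar(a); lb <- nchar(b)
  if (la == 0L && lb == 0L) return(1)
  if (la == 0L || lb == 0L) return(0)
  window <- max(floor(max(la, lb) / 2) - 1L, 0L)
  sa <- strsplit(a, "", fixed = TRUE)[[1]]
  sb <- strsplit(b, "", fixed = TRUE)[[1]]
  matched_b <- logical(lb)
  ma <- integer(0)
  mb_pos <- integer(0)
  for (i in seq_len(la)) {
    lo <- max(1L, i - window); hi <- min(lb, i + window)
    if (lo > hi) next
    for (j in lo:hi) {
      if (!matched_b[j] && sa[i] == sb[j]) {
        matched_b[j] <- TRUE
        ma <- c(ma, i)
        mb_pos <- c(mb_pos, j)
        break
      }
    }
  }
  m <- length(ma)
  if (m == 0L) return(0)
  # transpositions: matched characters of b in the order they were matched
  b_in_order <- sb[sort(mb_pos)]
  a_in_order <- sa[ma]
  t <- sum(a_in_order != b_in_order) / 2
  (m / la + m / lb + (m - t) / m) / 3
}

#' Jaro-Winkler similarity
#'
#' Jaro similarity boosted for a shared prefix (up to 4 characters, scaling
#' factor 0.1), the standard comparator for short personal names: tolerant
#' of single typos and transposed characters.
#'
#' @param a,b Character vectors (recycled to a common length).
#' @return Numeric vector of similarities in \[0, 1\].
#' @examples
#' jaro_winkler("CATHERINE", "KATHERINE")
#' @export
jaro_winkler <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  jw_sim_cpp(a, b)
}

# Pure-R Jaro-Winkler, kept as an independent reference for the compiled
# kernel.
jaro_winkler_r <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  vapply(seq_len(n), function(i) {
    j <- jaro_r(a[i], b[i])
    prefix <- 0L
    for (k in seq_len(min(4L, nchar(a[i]), nchar(b[i])))) {
      if (substr(a[i], k, k) == substr(b[i], k, k)) prefix <- k else break
    }
    j + prefix * 0.1 * (1 - j)
  }, numeric(1))
}

# Component-wise date similarity: mean of day/month/year agreement, with a
# high partial credit for a day/month transposition (a common keying error).
date_similarity <- function(a, b) {
  a <- as.Date(a); b <- as.Date(b)
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  da <- lubridate::day(a); ma <- lubridate::month(a); ya <- lubridate::year(a)
  db <- lubridate::day(b); mb <- lubridate::month(b); yb <- lubridate::year(b)
  comp <- ((da == db) + (ma == mb) + (ya == yb)) / 3
  transposed <- ya == yb & da == mb & ma == db & da != ma
  ifelse(transposed, pmax(comp, 0.9), comp)
}

# Tiered postcode similarity across two address sets: 1 if any full
# postcode is shared, 0.5 if only an outward (post-town) code is shared,
# else 0. Accepts single postcodes or character vectors.
postcode_tier_similarity <- function(a, b) {
  a <- unlist(a); b <- unlist(b)
  if (length(a) == 0L || length(b) == 0L) return(NA_real_)
  if (any(a %in% b)) return(1)
  if (any(postcode_parts(a)$outward %in% postcode_parts(b)$outward)) {
    return(0.5)
  }
  0
}

#' Field similarity under a named comparator
#'
#' @param a,b The values to compare. For `postcode_tiered` these may be
#'   character vectors (address sets); for other comparators scalars or
#'   equal-length vectors.
#' @param comparator One of `"exact"`, `"string_similarity"`,
#'   `"date_components"`, `"postcode_tiered"`. `string_similarity` is
#'   nickname-aware Jaro-Winkler: two names that are formal/short forms of
#'   the same entry in [nickname_table()] compare as 1.
#' @return Similarity in \[0, 1\]; `NA` when either value is missing
#'   (missing fields contribute no weight to a match score).
#' @examples
#' field_similarity("CATHERINE", "KATHERINE", "string_similarity")
#' field_similarity("ZA1 2CD", "ZA1 9ZZ", "postcode_tiered")
#' @export
field_similarity <- function(a, b, comparator = c("exact",
                                                  "string_similarity",
                                                  "date_components",
                                                  "postcode_tiered")) {
  comparator <- match.arg(comparator)
  if (comparator == "postcode_tiered") {
    return(postcode_tier_similarity(a, b))
  }
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  missing <- is.na(a) | is.na(b)
  out <- switch(
    comparator,
    exact = as.numeric(a == b),
    string_similarity = {
      s <- jaro_winkler(a, b)
      ifelse(canonical_name(a) == canonical_name(b), pmax(s, 1), s)
    },
    date_components = date_similarity(a, b)
  )
  out[missing] <- NA_real_
  out
}
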