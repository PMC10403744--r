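# Identifier pools used by the synthetic generator. All values are invented;
# postcodes use reserved-looking outward codes so no real UK postcode can be
# reproduced by accident.
#
# Pool sizes matter: name-frequency concentration (sum of squared value
# probabilities) sets the chance-agreement rate between unrelated people,
# which drives false-positive risk exactly as in real registers. The pools
# therefore combine a curated head (which carries the nickname table) with
# a synthetic long tail, giving a few hundred forenames per sex and ~1500
# surnames under Zipf-like weights — concentration comparable to a real
# birth-year register.

# Formal forename pools by sex, early-1990s UK flavour.
.forenames_f_head <- c(
  "CATHERINE", "ELIZABETH", "VICTORIA", "REBECCA", "CHARLOTTE", "STEPHANIE",
  "SAMANTHA", "JESSICA", "LAUREN", "HANNAH", "SOPHIE", "EMILY", "AMY",
  "RACHEL", "GEMMA", "NATALIE", "KIRSTY", "LEANNE", "STACEY", "DANIELLE",
  "NICOLA", "CLAIRE", "JOANNE", "MICHELLE", "KERRY", "LINDSEY", "ABIGAIL",
  "ALEXANDRA", "FRANCESCA", "GABRIELLA", "HARRIET", "IMOGEN", "JOSEPHINE",
  "KATHERINE", "LILLIAN", "MADELEINE", "NATASHA", "OLIVIA", "PENELOPE",
  "ROSALIND", "SUSANNAH", "TABITHA", "VERITY", "WINIFRED", "YASMIN",
  "ZOE", "ELEANOR", "FELICITY", "GEORGINA", "HENRIETTA"
)
.forenames_m_head <- c(
  "JAMES", "WILLIAM", "THOMAS", "DANIEL", "MATTHEW", "CHRISTOPHER",
  "JONATHAN", "BENJAMIN", "NICHOLAS", "ALEXANDER", "SAMUEL", "JOSHUA",
  "MICHAEL", "ANDREW", "RICHARD", "ROBERT", "EDWARD", "CHARLES", "GEORGE",
  "HENRY", "OLIVER", "JACOB", "LUKE", "ADAM", "AARON", "CALLUM", "CONNOR",
  "DOMINIC", "ELLIOT", "FREDERICK", "GARETH", "HARRISON", "ISAAC", "JOSEPH",
  "KIERAN", "LAWRENCE", "MAXWELL", "NATHANIEL", "OSCAR", "PATRICK",
  "QUENTIN", "RUSSELL", "SEBASTIAN", "TIMOTHY", "VINCENT", "WESLEY",
  "ZACHARY", "DUNCAN", "FERGUS", "GREGORY"
)
.surnames_head <- c(
  "SMITH", "JONES", "WILLIAMS", "TAYLOR", "BROWN", "DAVIES", "EVANS",
  "WILSON", "THOMAS", "JOHNSON", "ROBERTS", "ROBINSON", "THOMPSON", "WRIGHT",
  "WALKER", "WHITE", "EDWARDS", "HUGHES", "GREEN", "HALL", "LEWIS", "HARRIS",
  "CLARKE", "PATEL", "JACKSON", "WOOD", "TURNER", "MARTIN", "COOPER", "HILL",
  "WARD", "MORRIS", "MOORE", "CLARK", "LEE", "KING", "BAKER", "HARRISON",
  "MORGAN", "ALLEN", "JAMES", "SCOTT", "PHILLIPS", "WATSON", "DAVIS",
  "PARKER", "PRICE", "BENNETT", "YOUNG", "GRIFFITHS", "MITCHELL", "KELLY",
  "COOK", "CARTER", "RICHARDSON", "BAILEY", "COLLINS", "BELL", "SHAW",
  "MURPHY", "MILLER", "COX", "RICHARDS", "KHAN", "MARSHALL", "ANDERSON",
  "SIMPSON", "ELLIS", "ADAMS", "SINGH", "BEGUM", "WILKINSON", "FOSTER",
  "CHAPMAN", "POWELL", "WEBB", "ROGERS", "GRAY", "MASON", "ALI", "HUNT",
  "HUSSAIN", "CAMPBELL", "MATTHEWS", "OWEN", "PALMER", "HOLMES", "MILLS",
  "BARNES", "KNIGHT", "LLOYD", "BUTLER", "RUSSELL", "BARKER", "FISHER",
  "STEVENS", "JENKINS", "MURRAY", "DIXON", "HARVEY"
)

# Synthetic long tails: deterministic syllable products, deduplicated
# against the curated heads.
.name_tail <- function(prefixes, suffixes, head) {
  setdiff(unique(as.vector(outer(prefixes, suffixes, paste0))), head)
}
.forenames_f <- c(.forenames_f_head, .name_tail(
  c("AN", "BEL", "CAR", "DEL", "ELI", "FLO", "GRA", "ISA", "JUL", "KAR",
    "LIL", "MAR", "NOR", "OPA", "PRI", "ROS", "SEL", "TAM", "URS", "VAL"),
  c("INA", "ETTA", "ELLE", "ISSA", "ORA", "ENA", "ITH", "ANNE", "EEN",
    "YSSA", "IELA", "ETH", "ONIA"),
  .forenames_f_head))
.forenames_m <- c(.forenames_m_head, .name_tail(
  c("AL", "BER", "CAL", "DOR", "ED", "FER", "GIL", "HAR", "IV", "JOR",
    "KEL", "LOR", "MER", "NOR", "OS", "PER", "ROD", "STAN", "TOR", "WIL"),
  c("TON", "RIC", "WIN", "MUND", "BERT", "FORD", "LEY", "DEN", "WYN",
    "SON", "ARD", "VIN", "MOND"),
  .forenames_m_head))
.surnames <- c(.surnames_head, .name_tail(
  c("ASH", "BARK", "COMB", "DUN", "ELM", "FEN", "GOR", "HAL", "ING",
    "KIRK", "LANG", "MARSH", "NOR", "OAK", "PEN", "QUAR", "RAD", "SEL",
    "THORN", "UP", "VEN", "WHIT", "YAR", "BRAD", "CRES", "DOV", "EAST",
    "FAIR", "GRAN", "HOLM", "IV", "KEL", "LIN", "MOR", "NEW", "OS", "PIT",
    "ROCK"),
  c("LEY", "WOOD", "FIELD", "BROOK", "DALE", "FORD", "HAM", "HURST",
    "COMBE", "WORTH", "SHAW", "THORPE", "WICK", "STONE", "MERE", "DON",
    "WELL", "GATE", "CROFT", "BURY", "COTE", "RIDGE", "MOOR", "LAND",
    "BECK", "HOLT", "CLIFF", "POOL", "STEAD", "TON", "VALE", "WAY",
    "BOURNE", "DEAN", "FELL", "GRAVE", "HILL"),
  .surnames_head))

# Zipf-like sampling weights: curated head names are the common ones.
.zipf <- function(k, s = 0.8) (1 / seq_len(k)^s) / sum(1 / seq_len(k)^s)

# Bundled nickname table: formal form <-> short form, one pair per row.
# Used by the generator (name-variant corruption) and, in canonicalised
# form, by the string comparator so short forms score as equivalent.
.nickname_pairs <- matrix(c(
  "CATHERINE",   "CATH",
  "KATHERINE",   "KATIE",
  "ELIZABETH",   "LIZZIE",
  "VICTORIA",    "VICKY",
  "REBECCA",     "BECKY",
  "CHARLOTTE",   "LOTTIE",
  "STEPHANIE",   "STEPH",
  "SAMANTHA",    "SAM",
  "JESSICA",     "JESS",
  "ABIGAIL",     "ABBIE",
  "ALEXANDRA",   "SANDRA",
  "FRANCESCA",   "FRAN",
  "GABRIELLA",   "GABBY",
  "HARRIET",     "HATTIE",
  "JOSEPHINE",   "JOSIE",
  "MADELEINE",   "MADDIE",
  "NATASHA",     "TASHA",
  "PENELOPE",    "PENNY",
  "SUSANNAH",    "SUSIE",
  "GEORGINA",    "GEORGIE",
  "HENRIETTA",   "HETTY",
  "MICHELLE",    "SHELLEY",
  "DANIELLE",    "DANI",
  "JAMES",       "JAMIE",
  "WILLIAM",     "BILLY",
  "THOMAS",      "TOMMY",
  "DANIEL",      "DANNY",
  "MATTHEW",     "MATT",
  "CHRISTOPHER", "CHRIS",
  "JONATHAN",    "JONNY",
  "BENJAMIN",    "BEN",
  "NICHOLAS",    "NICK",
  "ALEXANDER",   "ALEX",
  "SAMUEL",      "SAMMY",
  "JOSHUA",      "JOSH",
  "MICHAEL",     "MICKY",
  "ANDREW",      "ANDY",
  "RICHARD",     "RICKY",
  "ROBERT",      "BOBBY",
  "EDWARD",      "TEDDY",
  "CHARLES",     "CHARLIE",
  "GEORGE",      "GEORDIE",
  "HENRY",       "HARRY",
  "JACOB",       "JAKE",
  "FREDERICK",   "FREDDIE",
  "HARRISON",    "HARRIS",
  "JOSEPH",      "JOE",
  "LAWRENCE",    "LARRY",
  "MAXWELL",     "MAX",
  "NATHANIEL",   "NAT",
  "PATRICK",     "PADDY",
  "SEBASTIAN",   "SEB",
  "TIMOTHY",     "TIM",
  "VINCENT",     "VINNIE",
  "ZACHARY",     "ZACK",
  "GREGORY",     "GREG"
), ncol = 2, byrow = TRUE, dimnames = list(NULL, c("formal", "short")))

#' Bundled nickname table
#'
#' Formal/short forename pairs used by the synthetic generator's
#' name-variant corruption process and by the name comparator, which treats
#' the two forms of a pair as equivalent.
#'
#' @return A tibble with columns `formal` and `short`.
#' @export
nickname_table <- function() {
  tibble::as_tibble(as.data.frame(.nickname_pairs, stringsAsFactors = FALSE))
}

# Map a name to its canonical (formal) form if it appears in the nickname
# table as a short form; otherwise return it unchanged. Vectorised.
canonical_name <- function(x) {
  idx <- match(x, .nickname_pairs[, "short"])
  out <- ifelse(is.na(idx), x, .nickname_pairs[idx, "formal"])
  unname(out)
}

# --- synthetic postcode gazetteer -------------------------------------------
# UK-shaped postcodes "<outward> <inward>"; outwards start with ZA/ZB (the
# policing area) or ZX/ZY (elsewhere). Z* outward codes avoid collision with
# real post towns.

.gazetteer_outwards <- function() {
  # ~100 in-area post towns (a plausible count for a 1.7M-person force
  # area) and 40 elsewhere
  in_area  <- paste0(rep(c("ZA", "ZB"), each = 50), 1:50)
  out_area <- paste0(rep(c("ZX", "ZY"), each = 20), 1:20)
  list(in_area = in_area, out_area = out_area)
}

# Sample n full postcodes. `in_area` selects the post-town stratum.
sample_postcodes <- function(n, in_area = TRUE) {
  ow <- .gazetteer_outwards()
  pool <- if (in_area) ow$in_area else ow$out_area
  outward <- sample(pool, n, replace = TRUE)
  inward <- paste0(
    sample(1:9, n, replace = TRUE),
    replicate(n, paste(sample(LETTERS[1:20], 2, replace = TRUE), collapse = ""))
  )
  paste(outward, inward)
}

#' Postcode parts
#'
#' Split full postcodes into outward (post-town) and inward (local) parts.
#' The outward part is everything before the space.
#'
#' @param postcode Character vector of full postcodes, `"OUTWARD INWARD"`.
#' @return A tibble with columns `outward` and `inward`.
#' @export
postcode_parts <- function(postcode) {
  outward <- sub("\\s.*$", "", postcode)
  inward <- sub("^\\S+\\s*", "", postcode)
  tibble::tibble(outward = outward, inward = inward)
}

#' Default in-area predicate for the synthetic gazetteer
#'
#' Returns a function mapping full postcodes to TRUE when the outward code
#' belongs to the synthetic policing-area stratum (outwards starting ZA/ZB).
#' Analyses of real data would inject a predicate backed by a force-boundary
#' lookup instead.
#'
#' @return A function `character -> logical`.
#' @export
synthetic_area_predicate <- function() {
  in_area <- .gazetteer_outwards()$in_area
  function(postcode) postcode_parts(postcode)$outward %in% in_area
}
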