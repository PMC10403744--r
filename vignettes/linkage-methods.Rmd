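---
title: "Linking a birth cohort to regional police records: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking a birth cohort to regional police records: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crimelink)
library(dplyr)
```

## The problem

Regional police forces and longitudinal cohort studies share no strong
persistent identifier, so linking a cohort roster to a police register has
to work from personal identifiers — forename, surname, date of birth, sex
and address history — all of which drift, get mistyped, or go stale.
`crimelink` implements the two-stage procedure used for such linkages:

* **Stage 1** establishes *identity* links between study participants and
  register identities (`offender_id`s), by deterministic exact matching
  graded with postcode tiers, then Fellegi–Sunter probabilistic scoring,
  then a set of hard review rules (twin check, low-confidence review,
  duplicate resolution).
* **Stage 2** selects the *event* records of the linked identities that
  carry an eligible disposal (charge, offence taken into consideration,
  caution, or another out-of-court disposal), attaches a crime-harm
  severity score, and converts everything into disclosure-controlled
  release records.

Because real identifiers are access-controlled, the package ships a
synthetic generator that reproduces the error processes the method has to
absorb, together with a ground-truth link table, so precision and recall
are measurable exactly.

## Stage 1: the matching model

### Deterministic tier

A pair matches deterministically when normalised forename, surname and
date of birth are all identical. Postcodes then grade the match: strength
1 when any full postcode is shared between the cohort's current-and-
historical addresses and the register's, strength 2 when only the outward
(post-town) code is shared, strength 3 otherwise. Postcode is deliberately
*not* a matching field: participants who acquire police records are also
the participants whose study-held addresses are most likely out of date,
so requiring address agreement would bias the linkage. Both sides'
historical postcodes participate in the tier and the best tier wins; the
alternative (latest address only) discards exactly the information that
distinguishes a stale address from a wrong one.

### Probabilistic scoring

Each field `f` has an m-probability (agreement chance on true matches) and
u-probability (agreement chance on random pairs). A pair's score is

$$ S = \sum_{f} w_f, \qquad
   w_f = \begin{cases}
     \log_2 (m_f / u_f) & \text{similarity} \ge \text{threshold}_f\\
     \log_2 \big((1-m_f)/(1-u_f)\big) & \text{otherwise,}
   \end{cases} $$

with missing fields contributing nothing. Comparators: nickname-aware
Jaro–Winkler for names (agreement threshold 0.85, so single-character
typos on realistic names agree and formal/short forms — `CATHERINE`/`CATH`
— agree exactly via the bundled nickname table); component-wise
day/month/year comparison for dates of birth with high partial credit for
a day/month transposition; exact comparison for sex; and a tiered
comparator for postcode sets.

Three numerical choices matter and are worth recording:

* **u-probabilities are estimated from register value frequencies**
  (`sum(p^2)`, the chance two random records agree), but only when the
  register has at least 500 rows; on sparser registers every value looks
  unique and the estimate collapses to `1/n`, which would misprice chance
  agreement badly (a date of birth would get weight `log2(0.95 n)` instead
  of `log2(0.95 \cdot 760)`). Below the gate, pool-based defaults are used.
* **Outward-only postcode agreement gets its own weight**,
  `log2(m_{out}/u_{out})` with `m_out = 0.75` and `u_out` estimated from
  the register (~0.01). Granting the full-postcode weight
  (`u ≈ 5·10⁻⁴`) to an event with chance probability ~10⁻² would
  systematically inflate weak pairs; this was the single largest
  false-positive channel before the level-specific weight was introduced.
* **The default acceptance threshold is 18** (log₂ scale). Under the
  default models, a chance pair agreeing on one name plus date of birth
  plus sex scores ≈ 16–17.5, while the weakest true-match configuration —
  both names and date of birth agreeing, postcode stale — scores ≈ 20–22.
  The threshold sits in that gap, which also makes the deterministic
  matches a strict subset of probabilistic acceptances by construction.
  A pair agreeing on a single name and date of birth is *not* accepted;
  engines that accepted such pairs would flood the review stage.

Blocking restricts scoring to pairs sharing at least one key: full date of
birth; birth year + surname initial; surname + forename initial. The
scheme is redundant so no single corrupted field can exclude a true pair;
on registers small enough to score exhaustively, blocked-and-scored
acceptances equal exhaustive acceptances (tested).

### Review rules

All three review rules are *hard* equality checks after normalisation, not
similarity checks — they exist precisely to catch pairs that similarity
scoring was too generous to:

* **Twin check** — twins share surname, date of birth and childhood
  address, so a co-twin looks like an excellent match everywhere except
  forename. Candidates whose participant is a twin survive only if sex
  and the first two forename characters agree.
* **Low-confidence review** — among accepted probabilistic links, the
  bottom decile by score is retained only with (forename AND full date of
  birth) OR (surname AND full date of birth) OR a full-postcode match.
  The decile is computed over probabilistic acceptances only:
  deterministic matches carry exact-identifier evidence and are exempt.
* **Duplicate resolution** — (a) several participants claiming one
  offender identity: only a full-postcode-supported claim survives; a
  deterministic claim outranks a probabilistic one; if the claim is still
  ambiguous, every claim is removed (this tie-break is our design — twins
  who still share a household can both hold full-postcode support, and an
  exact-identifier claim is the stronger evidence). (b) One participant
  holding several offender identities none of which has date-of-birth or
  postcode support: names alone lack distinguishing power and all are
  removed. (c) Several *well-supported* identities for one participant
  are all retained — that is genuine fragmentation on the police side,
  not an error.

Every removal is ledgered, so candidates in = final links + removals is an
identity, not an aspiration.

## Stage 2: events, severity, release

Disposal eligibility is decided differently by crime arity because the
main outcome code is an offence-level field: for single-offender crimes
the Home Office outcome code must be in {OC1, OC2, OC3, OC4, OC6, OC7,
OC8}; for group crimes each offender's own concatenated classification
terms are consulted instead, against the term list {charged, tic,
cautioned, adult conditional caution, postal requisition, reported for
summons, cannabis warning, penalty notice for disorder, community
resolution, prosecuted}. Term matching is whole-term after splitting on
";" — never substring, so "discharged" cannot satisfy "charged". The
legacy term "prosecuted" (used before the September 2015 recording-platform
change to cover TICs and all out-of-court disposals) is honoured whenever
present, not only before the boundary: a term that appears is evidence
regardless of an era mislabel.

Severity is a base harm score per offence code (0.01–100; the bundled
table carries the nine published exemplar scores, and user tables load
from YAML) inflated by cumulative multipliers: +30% domestic abuse, +50%
hate, +5% drug, +10% firearm, +30% safeguarding children. The multipliers
have a stated application order, but multiplication without intermediate
rounding is commutative, so we adopt the order-invariant reading, apply no
rounding, and test invariance explicitly — rounding is the only mechanism
by which order could matter. User tables with scores inside the (3, 8)
gap — which no published offence occupies — draw a warning, not an error,
because the gap's rationale is not documented.

Disclosure control replaces every identifier and date: keyed-hash
pseudonyms for occurrence and casefile ids (deterministic within a
release, so group-crime structure survives; unrecoverable without the
salt), ages in *completed calendar months* (a month counts once the
day-of-month is reached; the convention is pinned against an independent
calendar-walk oracle), month and year of offence retained, severity and
offender count top-coded, and any field whose missingness exceeds 90%
withheld entirely (the drop threshold mirrors the magnitude of the fields
the source system cannot populate: the alcohol flag, substance-use field
and court verdict all exceed 92% missing). Released frequency tables pass
through small-cell suppression: cells with 0 < n < 5 are hidden, and
complementary cells are suppressed in 2×2 rectangles until exhaustive
enumeration of margin-consistent integer fills finds no suppressed cell
with a unique value. A cell that is structurally determined (for example a
row whose margin is published and whose other entries are all released
zeros) is reported as unprotectable rather than silently left exposed.

Per-birthday residence flags supply the denominator: the flag at age *k*
is true when an in-area address interval covers the k-th birthday; a
birthday on an interval boundary counts as covered by the interval ending
that day; a birthday covered by no interval is false *with a gap marker*,
because absent address data is not evidence of absence from the area.

## What the generator emulates — and what it does not

The generator reproduces, at configurable rates: nickname variants (5% by
default), single-character typos (2%), stale addresses (20%, half of them
local moves within the post town), offender-identity fragmentation (1% of
offenders), twins (2% of the cohort, sharing surname, date of birth and
childhood address but never forename — parents do not give twins the same
name), group crimes (22% of offences, sharing an occurrence id and
offence-level outcome), era-dependent disposal terminology, court-case
fields only from late 2015, heavy missingness in the alcohol / substance /
verdict fields, retention review (most-serious-offence category; Group 3
deleted after a 6-year clear period in a single sweep at extraction —
review periods are documented but review *scheduling* is not, so a single
sweep is the assumption), and paper-era left-censoring before 2007 (the
true survival rate of paper records is unknowable; the default drops them
all and the rate is an explicit free parameter).

Name and postcode pools are sized so that chance-agreement probabilities
(`sum(p^2)` ≈ 0.016 for forenames, 0.007 for surnames, ~100 in-area post
towns) are comparable to a real birth-year register — collision realism is
what makes the measured false-positive rates meaningful. The pools
themselves are invented; no real postcode can be generated.

Not emulated: realistic offence-mix correlation with demographics,
geographic structure beyond post-town strata, return-migration into the
area, date-of-birth corruption (the comparator tolerates transpositions
but the generator does not produce them), and fully fake identifiers.
Passing tests therefore demonstrate that the *machinery* is correct under
the modelled error processes, not that real-data linkage would achieve the
same precision.

One evaluation configuration deserves its own note: the noiseless-recovery
check (all corruption rates zero, precision = recall = 1 demanded) is run
with a register containing only true offenders. With background decoys
present, exact namesakes — same forename, surname and date of birth by
chance — occur at a small but non-zero rate, and no method can distinguish
them with the fields available; identity is formally underdetermined, so
demanding precision 1.0 there would test the dice, not the code. Decoy
discrimination is measured instead under default corruption, where the
precision requirement is ≥ 0.99 with decoys present.

## Problem sizes

The test suite and the acceptance script run cohorts of 200–10,000 with
registers up to ~4,000 subjects and event tables of ~10⁴ rows — the sizes
at which every brute-force oracle (all-pairs scoring, row-wise predicate
filtering, exhaustive suppression enumeration) is still exact. The
pipeline itself scales to the full cohort size (the scoring kernel is
compiled; blocking keeps the pair count near-linear in register size);
those sizes were chosen because the oracles, not the pipeline, are the
binding constraint.

## A short tour

```{r tour, eval = FALSE}
params <- synth_params(n_cohort = 1200, n_background = 800, seed = 4)
res <- run_pipeline(params)

res$flow                 # stage-by-stage linkage accounting
res$evaluation           # precision / recall against ground truth
glance(res$link_table)   # one-row linkage summary
res$counts               # records vs offences vs individuals
res$denominator$by_age   # in-area residence by birthday

plot_match_scores(res$candidates, truth = res$truth)
plot_offence_mix(res$linked_events)
plot_denominator(res$denominator)
```

## Known limitations

* m-probabilities are fixed defaults, not EM-estimated; the u-estimation
  gate (n ≥ 500) is a blunt instrument. Both are configuration, and the
  scoring layer accepts any model table.
* The review rules reproduce documented decision rules; a real linkage
  unit would adjudicate borderline pairs by hand, which no rule set
  replicates.
* The retention simulator deletes whole offender histories in one sweep;
  rolling annual reviews would retain slightly more.
* Small-cell suppression guarantees non-recoverability only against the
  released table's own margins, not against external knowledge or
  repeated overlapping tabulations.
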