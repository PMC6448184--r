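---
title: "The provlink linkage model: match types, temporal scoring, and the synthetic test world"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The provlink linkage model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(provlink)
```

## The problem and the model

A state licensure roster lists every professional licensed to practice in
the state — name, address, state license number — but carries no national
identifier, contains duplicates, and retains providers who have died,
retired, or left. The national registry (NPPES-style public use files)
carries the NPI, legal name, taxonomy codes and two addresses, refreshed
yearly, but covers the whole country and cannot be joined to a roster by
any shared key. `provlink` links the two by constrained comparison of the
textual fields, under three modelling commitments:

1. **The roster defines the population.** Every licensed provider of the
   chosen type is assumed to appear there; the registry is the
   enrichment source. Linkage is therefore evaluated per roster record.
2. **Specialty taxonomy and geography are hard filters.** A registry
   record whose primary *and* secondary NUCC codes both fall outside the
   provider type's set, or whose addresses both fall outside the study
   region, is removed before matching. This buys large candidate-space
   reductions at a known cost: a provider mis-taxonomized in the registry
   is unlinkable by construction, and the stage report makes that loss
   visible rather than silent.
3. **Agreement is per entity, and evidence decays with age.** Four
   entities — last name, first name, city, street — are compared per
   yearly snapshot. An entity whose most recent agreeing year is the
   window's final year contributes 5 points; each year it recedes costs
   one point; an entity that never agrees contributes 0. Totals live in
   [0, 20] and a threshold decides acceptance. The additive integer model
   is deliberate: it is auditable row by row, unlike probabilistic
   (Fellegi–Sunter-style) weights, which are an explicit non-goal.

## The seven match types

Candidate pairs are classified by which entities agree:
{first+last} × {city+street, city, street, neither}, then {last-only} ×
{city+street, city, street}. The 2×4 grid has eight cells; the excluded
cell is bare surname agreement with no corroborating address, which has no
discriminating power in a state-sized cohort. That exclusion — and the
rank order `FL_CS > FL_C > FL_S > FL > L_CS > L_C > L_S`, where full-name
families dominate and city outranks street within a family because town
names suffer fewer transcription errors — is this package's design choice;
both are configurable in principle through `enumerate_match_types()`s
table, and classification is monotone: adding an agreeing entity never
weakens the type.

A candidate's per-year classification feeds the temporal model: a year
contributes to an entity's year set only when the pair matched at all that
year (last names agreed with some corroboration). A consequence worth
stating: when a surname changes in year *c*, all four entities stop
accruing from *c* onward, so the achievable total for a replacement-style
change staged at *c* in a 2013–2017 window is `4 × (5 − (2017 − (c−1)))` —
recoverable at the default threshold only for changes in the last two
window years. Token-insertion-style changes ("Brown Smith" → "Brown
Jackson Smith") are instead bridged in every year by the compound-surname
rule below.

## Equality rules and their tolerances

All comparison happens on normalized keys: uppercase, punctuation
stripped (apostrophes deleted, hyphens become token separators),
generational suffixes (JR, SR, II–V) removed, USPS street suffixes
canonicalized from a shipped editable table, unit/suite designators
dropped, and the city key reduced to the town name.

* **Exact mode** (`fuzzy = FALSE`): keys must be equal and non-empty.
* **Fuzzy mode** (default): Levenshtein distance at most 2 when the
  longer key has ≥ 5 characters, at most 1 otherwise, and never fuzzy for
  keys shorter than 3 characters. The tier is keyed on the *longer* side
  so that a deletion typo of a long name does not downgrade its own
  tolerance; the sub-3 floor stops a lone initial from absorbing a
  different initial. These tiers accept doubled-letter misspellings
  ("Helen"/"Hellan", distance 2) while rejecting genuine surname
  replacements ("Black"/"Gold", distance 5).
* **First names** additionally agree initial-vs-full ("H" vs "HELEN"),
  reflecting rosters that abbreviate. This deliberately does *not* bridge
  a middle name used as a first name — a failure mode that remains out of
  scope (see Limitations).
* **Compound surnames** agree when one token set is a subset of the
  other ("BROWN SMITH" ⊂ "BROWN JACKSON SMITH").
* **Addresses**: the roster's single address is compared against both
  registry addresses with OR semantics, and the location filter likewise
  keeps a record if either address is in-region — the stated goal is not
  losing in-state providers, and OR maximizes it.

Both comparison modes are first-class because real matchers of this kind
have shipped as exact-only; the package exposes `matching.fuzzy` as
config so the cost of exactness is measurable (the test suite measures it
on the misspelling channel).

## Blocking and its completeness argument

All-pairs comparison is quadratic; blocking compares only pairs sharing a
key. A first-letter or phonetic key is *not* complete under the fuzzy
tiers — a single edit can change the first letter — so the blocking key is
instead: every surname token (serving the subset rule, which requires a
shared exact token) plus the deletion neighbourhood of the space-free
surname key at depth 2 (depth 0 in exact mode). Two strings within
Levenshtein distance *k* always share a member of their depth-*k*
deletion neighbourhoods (the FastSS property), so no pair the classifier
would accept is ever excluded. This is verified empirically as an oracle
property: on 100 random adversarial instances, blocked matching is
`identical()` to exhaustive matching.

## Resolution, merging, and determinism

Accepted candidates are resolved one-to-one: globally best first (total,
then match-type rank, then most recent snapshot), an NPI once assigned
leaves contention and the losing license falls back to its next
candidate. A license whose best candidates are exactly tied across
different NPIs is excluded and logged as ambiguous — directories are
precision-critical, so the package never guesses. The merged record takes
the legal name and all national fields from the registry (rosters often
retain a pre-marriage surname) and the license number from the roster,
with match type and total score carried as provenance columns. The whole
pipeline is deterministic for fixed inputs and config; every stage logs
`in == out + dropped`.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `window` | 2013–2017 | calendar years | five consecutive yearly snapshots, the study design this package models |
| `threshold` | 12 | points | **package default, not an externally fixed constant**: accepts a recent full-name match with ≥ 1 corroborating address entity; rejects any single-entity coincidence (max 5) and stale name-only matches |
| `fuzzy` | TRUE | — | tolerate 1–2-edit transcription typos |
| `block` | TRUE | — | complete blocking (above); `FALSE` forces all-pairs |
| `states` | CT, MA, NY, RI, FL | — | study region: home state, neighbours, part-year residents |
| taxonomy table | shipped TSV | NUCC codes | editable because NUCC revises codes; nurse-practitioner (363L family) and dentist (1223 family) sets are the defensible family defaults, since only four individual codes are documented with certainty |

Run configuration files are JSON (not YAML) because the deployment
environment guarantees a JSON parser but no YAML parser; the contract —
an editable external table, and the effective config serialized beside
every run's outputs — is unchanged.

## The synthetic world

`generate_cohort()` emits a roster CSV, five registry snapshot CSVs with
official public-use-file headers and check-digit-valid NPIs, a truth
table, and a manifest. Its stated world:

* *n* identities with unique (first, last) pairs from bundled lexicons;
  5% compound surnames; 5% suffixes; addresses 80% CT, 20% spread over
  MA/NY/RI/FL; the roster spells street suffixes out while the registry
  abbreviates, so suffix canonicalization is always exercised.
* Registry-only distractors (default 20% of *n*, half out-of-region to
  exercise the location filter, half in-region with out-of-cohort
  surnames and towns to exercise precision).
* Error channels, mutually exclusive per identity, 2% each by default —
  an arbitrary default, documented as such, since no field estimate of
  per-channel rates exists: misspelling (1–2 edits, verified by
  Levenshtein), name change (replacement at distance > 2, or token
  insertion; staged at a uniform window year), move (new street and town
  from a uniform window year onward), inaccurate taxonomy (out-of-set
  primary, secondary emptied), middle-as-first, and roster rows with no
  registry record at all (deceased/retired).
* One master seed; per-identity substream seeds, so earlier identities
  are stable as *n* grows, and output files are byte-identical across
  runs with the same seed.

What it does **not** emulate: demographic name/address frequencies,
within-file roster duplicates (the readers handle and count them; tests
exercise that path with handcrafted fixtures), registry records with more
than one "other identifier", and multi-line addresses. A green test on
this world therefore establishes structural correctness of the pipeline
and its error-channel behaviour — not performance on any real roster.

## Numerical and edge-case choices

* Entity scores floor at 0 so the formula totals over windows longer
  than six years, where the decrement would otherwise go negative.
* Empty keys never agree (an empty street leaves a record matchable on
  name + city only); empty gender maps to `unknown`.
* `score_entity` rejects match years outside the window as a
  precondition error rather than clamping.
* Duplicate roster licenses: first occurrence wins, counted, never
  silent. Registry rows failing NPI validation are quarantined to a
  reject table, never dropped.
* All tie-breaks in resolution end in a deterministic ordering (license
  number, then NPI) so re-runs are byte-identical.

## Known limitations

* A provider using a middle name as a first name links only as `L_CS`
  (15 points when address history is stable) — found, but classified as
  a last-name-only family match; with a threshold above 15 they are
  lost. No first-name/middle-name swap rule is attempted.
* Surname replacements that predate the snapshot window are unbridgeable
  by design; so are registry records whose taxonomies are wrong in both
  positions.
* Taxonomy filtering is not expected to transfer to physician rosters,
  where taxonomy families are too broad to discriminate; physician
  linkage is a non-goal.
* Recall and precision are the only reported metrics; no single
  "accuracy" scalar is defined or computed.
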