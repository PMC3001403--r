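---
title: "screenkit: models and methods for HTS facility data management"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{screenkit: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screenkit)
```

## The problem

Shared high-throughput screening (HTS) facilities run many interleaved
small-molecule and RNAi screens for independent research groups. The
informatics burden is less about statistics than about careful
book-keeping under physical constraints: screening libraries are plated
in 96-, 384- or 1536-well microplates and aliquoted into working copies
whose per-well reagent volumes are consumed over time; screeners deposit
per-well result data and call "positives"; follow-up work cherry-picks
positive reagents from stock plates onto custom plates via liquid-handling
robots; and every consequential lab or administrative event needs an
audit trail. screenkit implements this core as an R library with a thin
command-line layer, not a web application: the entities are S4 classes,
the operations are ordinary functions, and all state is explicit.

## Domain model

The entity vocabulary mirrors the standard facility domain model:

* `ScreenUser` — screeners and administrators, with role-based
  capabilities (`login`, `volume_admin`, `read_everything`) and a
  checklist of administrative tasks.
* `ScreenLibrary` — a versioned, plated set of reagents over a
  contiguous plate range. Each well has a type (`experimental`, `empty`,
  `dmso_control`, `library_control`, `buffer`); only experimental wells
  carry reagents, and control/empty wells are never cherry-pickable.
  Small-molecule reagents store vendor identifiers, SMILES/InChI
  structures and molecular mass; silencing reagents store the targeted
  gene (Entrez id, symbol, GenBank accessions), sequences, and — for
  pooled siRNA reagents — the duplex wells they deconvolute to.
* `LibraryCopy` — a physical aliquot of a library's plates with a
  per-well remaining-volume ledger and per-plate freeze/thaw counts.
* `Screen` / `ScreenResult` — screening-project metadata plus imported
  per-well values organised into raw and derived data columns, with
  positives indicators.
* `CherryPickRequest` — the follow-up workflow state machine from
  screener picks to plated cherry-pick plates.
* `ActivityLog` — an append-only audit trail of typed activities.

Well coordinates are held 0-based internally; every user-facing string
uses the letter + 1-based zero-padded column convention ("A01"), with
rows beyond Z labelled AA..AF for 1536-well plates. Parsers accept both
the padded and unpadded dialects because real SD files and robot files
disagree; writers always emit the padded form. The conversion boundary
lives in exactly one place (`parseWellName()` / `formatWellName()`).

## File formats

Library contents arrive as SD files (small molecule) or spreadsheet-style
workbooks (RNAi); screen results arrive as workbooks with a `Data
Headers` sheet describing each data column and one or more data sheets of
per-well values. The SDF reader interprets only the associated-data
blocks and tolerates (ignores) V2000 molblocks — structures travel as
SMILES/InChI data fields, stored verbatim without chemistry validation.
Field names are configurable via a mapping for foreign dialects.

Because the environment provides no XLSX *writer*, the package's native
workbook format is plain text: tab-separated sheets introduced by
`#%sheet <name>` markers under a `#%workbook` header. This keeps fixtures
diffable and round-trips byte-identically; `.xlsx` files are still
accepted on import when readxl is available. Import/export round-trip
identity is asserted in the test suite for both reagent classes.

## The volume ledger

Volumes are stored as integer nanoliters and rendered as microliters.
This is a deliberate numerical choice: ledgers see long sequences of
debits, credits and corrections, and exact integer arithmetic makes
conservation (`remaining = initial − Σdebits + Σcredits`) testable with
`identical()` rather than a tolerance. Library screenings debit every
well of the screened plates uniformly by `volume × replicates` (per-well
debits arise only from cherry picks and manual corrections) and increment
the plate's freeze/thaw count; a debit that would drive any well negative
rejects the whole operation atomically. Corrections set a well to an
observed value and require the `volume_admin` role. Retired plates accept
no debits and are excluded from cherry-pick availability.

## Screen results and positives

Data columns carry replicate ordinal, time point, readout technology and
a derivation flag. Derived values are imported, not computed — analysis
happens in external statistical software — so the package validates only
the derivation graph: a derived column must reference earlier columns,
which makes cycles impossible by construction. Positives columns use one
of three indicators: boolean (the value itself), partitioned (any of
strong/medium/weak counts as positive; only `none` does not), or a
numeric threshold. "Exceeds the cutoff" is read as a *strict* inequality,
and the direction (`above`/`below`) is an explicit column attribute
because inhibition assays cut downward. Positive percentages are
`100 × count / n_experimental`, over experimental wells that carry a
value in the column; control wells never enter positives calculations.

Cross-screen comparison builds an outer join keyed by well or by reagent
(vendor id): every key present in any source appears, missing cells stay
empty (`NA`, never zero), and column names carry source provenance.
Study annotations are keyed by reagent and join by reagent regardless of
the table's key mode. Filtering is conjunctive with typed operators;
`NA` cells never satisfy a criterion. Heat maps are returned as plain
row × column matrices; rendering is left to the caller.

## The cherry-pick workflow

1. **Validation.** Screener picks are accepted or rejected per pick with
   a reason: `unknown_well`, `non_experimental`, `deprecated`,
   `duplicate`, or `over_limit` beyond the facility's cap, in submission
   order.
2. **Deconvolution.** Pool siRNA picks expand to one lab pick per duplex
   well; small-molecule and duplex picks map 1:1.
3. **Reservation.** For each pick in order, among cherry-pick-source
   copies holding at least the effective volume (the approved volume
   when set, else the requested one; the boundary is inclusive), the copy
   with the *smallest sufficient remaining volume* is chosen, ties
   breaking on the lexicographically smallest copy name. This depletes
   nearly-empty copies first and is deterministic and auditable — the
   tie-break is this package's choice where facility practice varies.
   Insufficiency leaves a pick unfulfilled, never fails the operation;
   unfulfilled picks can be rolled over (once) into a new request.
4. **Mapping.** Reserved picks are sorted by (source plate, source well
   row-major, copy name) and assigned to consecutive available
   destination wells — the destination format minus the required-empty
   set (controls, edge-effect avoidance) — overflowing to new plates, so
   the plate count is `ceiling(n / n_available)`. With randomized layout,
   destination wells are permuted *within* each plate by a generator
   seeded with the request's persisted seed; plate membership stays
   source-plate-batched so liquid-handler efficiency is preserved. The
   exported mapping CSV orders rows by destination plate then source
   plate, and reruns are byte-identical.
5. **Plating status.** `plated` confirms the transfer (and logs the lab
   activity); `canceled` credits every reservation back exactly;
   `failed` keeps the debit — the reagent was physically consumed — and
   respawns the plate's picks as fresh unfulfilled picks whose remapped
   successor plate reuses the ordinal with attempt + 1. The
   failed-keeps/canceled-refunds distinction is a design reading of
   "confirm (or cancel) the reservation"; it is what makes the ledger
   conservation property hold with consumption accounted.

## Data sharing policy

Screens carry a sharing level 0–3 (0 shares everything … 3 private).
Members (lab head, lead screener, collaborators) and administrators with
the `read_everything` role always see everything. Otherwise, with user
level `u` (the minimum level over the screens they belong to, computed
within the same reagent-class domain, defaulting to private) and screen
level `s`: access is `none` if either is 3, `full` if `u ≤ s`, else
`metadata_only`. Under this concrete matrix the intermediate
`positives_and_protocol` tier is not produced; it remains in the access
vocabulary and is reachable through the pluggable `policy` hook, which
replaces the level rule (but never the membership/admin overrides) so a
facility can substitute its own sharing semantics. Column-level
enforcement maps `full` to all data columns, `positives_and_protocol` to
positives columns only, and lower tiers to none.

## Activities

Five facility activity kinds are built in — library screening and cherry
pick liquid transfer (lab); well deprecation, well volume correction and
checklist item event (administrative) — and the registry is open:
workflow steps that must leave an audit record (request submission,
reservation, cancellation refunds, plate failures, contents imports)
register additional kinds at load. A kind's category is fixed at first
registration. The log is append-only with sequential ids; activity dates
are event dates and may precede the record date.

## Synthetic data: the stated world

The generator emulates a plausible facility fixture, not any particular
data set:

* 384-well plates by default; column 1 is DMSO controls and the last
  column library controls — a conventional edge-control layout.
* Small-molecule reagents draw SMILES from a fixed set of valid template
  structures (no chemistry dependency); RNAi pools carry 4 duplexes each
  (the common SMARTpool-style configuration), with 19–21-nt sequences.
* Screen results have two unit-scale Gaussian replicate columns, a
  derived replicate-mean score and a threshold positives column
  (cutoff 2.5, direction above). True positives are Bernoulli draws at
  the spec's positives rate (default 0.5% for small molecule, 2% for
  RNAi, matching the typical cherry-pick fractions of 0.3–0.5% and
  1–3%) with a +5 activity shift, so the realized positive fraction
  stays within binomial error of the rate.
* Everything is deterministic under the spec seed, down to the bytes of
  the generated files.

What a green test on this world does **not** establish: robustness to
plate-position artefacts (edge effects, drift), non-Gaussian readouts,
vendor-file dialect quirks beyond the field-name mapping, or any
normalization/scoring correctness — scoring is explicitly out of scope
and imported as-is.

## Persistence and the CLI

The workspace store is JSON text (one `store.json` per workspace) with
explicitly typed nodes, so reconstruction is type-exact (integer vs
double, dates, empty tables). A relational embedded store would also
have been natural — the domain model is entity-relational — but a text
store keeps workspaces inspectable and diffable and avoids binary state
in tests. The CLI (`inst/cli/screenkit.R`, or `screenkitMain()`)
binds subcommands for every module and exits nonzero with a one-line
diagnostic on failure; the `demo` subcommand runs the whole workflow
end-to-end and is byte-reproducible under a fixed seed.

## Known limitations

* Plate numbers are treated as facility-global; two libraries declaring
  overlapping plate ranges will both answer a `plate:well` designation.
* Randomized layouts permute within plates only; a screener wanting
  cross-plate randomization would need to randomize the pick list.
* Rolling over a partially unfulfilled pool re-collapses to the screener
  pick, so a later request re-expands the full pool.
* The workbook text format does not escape embedded tabs (they are
  rejected at write time).
* No barcode, freezer-location or instrument integration, and no image
  data.
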