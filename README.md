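# screenkit

Lab information management for shared high-throughput screening (HTS)
facilities, as an R package. Facilities that run many interleaved
small-molecule and RNAi screens need careful book-keeping under physical
constraints: microplate libraries aliquoted into working copies whose
per-well reagent volumes are consumed over time; per-well screen results
with screener-called "positives"; follow-up cherry-pick requests that
turn positives into robot-plated custom plates; and an audit trail for
every consequential event. screenkit implements that core for both
reagent classes:

* **Libraries** — import from SD files (small molecule) or workbooks
  (RNAi, including pooled siRNA reagents with their duplex mappings),
  contents versioning with retained history, batch well/reagent search,
  deprecation, and round-trippable export.
* **Inventory** — library copies with an exact per-well volume ledger
  (integer nanoliters), uniform screening debits with freeze/thaw
  counting, manual corrections, plate retirement, remaining-volume
  reports.
* **Screen results** — raw/derived data columns with replicate and
  readout metadata, positives classification (boolean, partitioned
  strong/medium/weak, or strict threshold with direction), positives
  counts and percentages, cross-screen outer-join comparison tables,
  study annotations keyed by reagent, typed filtering, per-plate
  heat-map matrices.
* **Cherry picks** — pick validation with per-pick rejection reasons,
  siRNA pool deconvolution to duplexes, smallest-sufficient-copy volume
  reservation, constrained and optionally randomized (seeded,
  reproducible) plate mapping batched by source plate, liquid-handler
  mapping-file export, plated/failed/canceled plate transitions with
  exact refund-or-respawn ledger semantics, rollover of unfulfillable
  picks.
* **Access policy** — tiered reciprocity-based data sharing (level 0
  shares everything … 3 private): non-members see others' screens fully
  only when they share at least as much themselves, behind a pluggable
  policy hook; column-level visibility enforcement.
* **Activities** — an append-only, queryable audit log; every
  volume-mutating operation leaves exactly one activity.
* **Fixtures + CLI** — a deterministic synthetic-data generator
  (libraries, screen results, pick lists) and a command-line layer with
  a persistent JSON workspace store (`inst/cli/screenkit.R`).

## Worked example

```r
library(screenkit)

spec <- fixtureSpec(seed = 1, nPlates = 2)           # 384-well world
gen  <- generateLibrary(spec, "demo", "DEMO")        # writes an SD file
lib  <- importSmallMoleculeLibrary(gen$files[["library"]], "DEMO",
                                   384, 1, 2)
lib
#> ScreenLibrary 'DEMO' (small_molecule)
#>   plates 1-2 (384-well), version 1
#>   wells: 704 experimental / 768 total; 0 deprecated
```

704 experimental wells: 2 plates × (384 − 32 control wells). Screen it
and call positives:

```r
src <- createCopy(lib, "C", "cherry_pick_source", 10)   # 10 uL per well
generateScreenResult(lib, spec, "demo/result.txt")
screen <- newScreen("S-1", "small_molecule", "reporter assay",
                    labHead = "pi", dataSharingLevel = 1,
                    libraryNames = "DEMO")
screen <- importScreenResult(screen, "demo/result.txt", list(lib))
ps <- positivesSummary(screen, "PositiveScore")
sprintf("%d positives (%.3f%% of experimental wells)", ps$count, ps$percent)
#> "3 positives (0.426% of experimental wells)"
```

The count is over experimental wells only; 0.426% sits where the
generator's 0.5% positives rate should put it. Cherry-pick the hits onto
a randomized 384-well plate that keeps two control wells empty:

```r
pos <- classifyPositives(screen, "PositiveScore")
req <- createCherryPickRequest(screen, names(pos)[pos], 2, "pi",
                               libraries = list(lib),
                               randomizeLayout = TRUE, randomSeed = 1,
                               requiredEmptyWells = c("A01", "P24"))
req <- deconvolute(req, list(lib))
r   <- reserveReagent(req, list(src), "adm", newActivityLog())
req <- mapToPlates(r$request)
cat(exportPlateMapping(req)[1:4], sep = "\n")
#> source_plate,source_copy,source_well,destination_plate_ordinal,destination_well,volume_uL
#> 2,C,B14,1,N13,2
#> 2,C,G13,1,G24,2
#> 2,C,I02,1,F10,2
```

Each row programs one liquid-handler transfer: 2 µL from copy "C" of the
source well to the assigned destination well. Rows are batched by source
plate, destinations avoid the required-empty wells, and rerunning with
the same seed reproduces the file byte for byte.

The same workflow is available from a shell via the CLI wrapper
(`inst/cli/screenkit.R`), whose subcommands (`library`, `copy`, `screen`,
`cpr`, `access`, `activity`, `fixture`, `demo`) persist state in a JSON
workspace store.

## Acceptance script

`scripts/acceptance.R` re-runs the complete pipeline from scratch —
synthetic library generation, import, copy creation, library screening,
screen-result import, positives classification, cherry-pick request,
reservation, plate mapping and file export — seeded by `--seed`, and
writes its results JSON to `--out`:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Documentation

The methods vignette (`vignettes/screenkit-methods.Rmd`) describes the
domain model, the ledger arithmetic, the positives and sharing-policy
semantics, the cherry-pick state machine, what the synthetic generator
does and does not emulate, and known limitations.
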