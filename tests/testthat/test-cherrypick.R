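# standard small-molecule setup: library + cherry-pick-source copies
cpSetup <- function(nPlates = 1, format = 96, volumes = c(C = 10, D = 3)) {
  lib <- makeSmLibrary("CPL", nPlates = nPlates, format = format,
                       controls = c())
  copies <- list()
  for (nm in names(volumes))
    copies[[nm]] <- createCopy(lib, nm, "cherry_pick_source",
                               volumes[[nm]], existingCopies = copies)
  list(lib = lib, copies = unname(copies))
}

expKeys <- function(lib) {
  w <- libraryWells(lib)
  paste0(w$plate, ":", w$well)[w$well_type == "experimental"]
}

test_that("request creation validates picks and rejects bad volumes", {
  s <- cpSetup()
  picks <- expKeys(s$lib)[1:10]
  req <- createCherryPickRequest("S-1", picks, 2, "kim",
                                 libraries = list(s$lib))
  expect_identical(sum(req@screenerPicks$status == "accepted"), 10L)
  expect_equal(effectiveVolumeUl(req), 2)

  dupReq <- createCherryPickRequest("S-1", c("1:A02", "1:A03", "1:A02"),
                                    2, "kim", libraries = list(s$lib))
  expect_identical(dupReq@screenerPicks$status,
                   c("accepted", "accepted", "rejected"))
  expect_identical(dupReq@screenerPicks$rejection_reason[3], "duplicate")

  expect_error(createCherryPickRequest("S-1", "1:A02", 0, "kim"),
               "volume must be positive")
  # approved volume caps the effective volume
  appr <- createCherryPickRequest("S-1", "1:A02", 5, "kim",
                                  approvedVolumeUl = 3)
  expect_equal(effectiveVolumeUl(appr), 3)
})

test_that("pick validation applies every policy with its reason", {
  s <- cpSetup()
  log <- newActivityLog()
  lib <- deprecateWells(s$lib, "1:B01", "contamination", adminUser(),
                        log)$library
  # A01 is experimental here; make a control library with A01 dmso
  libC <- makeSmLibrary("CPC", format = 96,
                        controls = c(A01 = "dmso_control"))
  picks <- c("1:B01", "1:A02", "9:A01", "1:A01", "1:A03", "1:A04",
             "1:A05")
  req <- createCherryPickRequest("S-1", picks, 2, "kim", maxPicks = 3)
  res <- validatePicks(req, list(libC))
  # note 1:B01 is experimental in libC but deprecated in lib; use libC's
  # view first: B01 fine, A01 control, 9:A01 unknown
  sp <- res$request@screenerPicks
  expect_identical(sp$rejection_reason[sp$well == "A01" & sp$plate == 9],
                   "unknown_well")
  expect_identical(sp$rejection_reason[sp$well == "A01" & sp$plate == 1],
                   "non_experimental")
  # cap of 3: the 4th+ acceptable picks reject as over_limit
  expect_identical(sum(sp$status == "accepted"), 3L)
  expect_identical(sp$rejection_reason[sp$well == "A05"], "over_limit")

  # deprecated wells reject with their own reason
  res2 <- validatePicks(createCherryPickRequest("S-1",
                                                c("1:B01", "1:A02"), 2,
                                                "kim"),
                        list(lib))
  expect_identical(res2$request@screenerPicks$rejection_reason[1],
                   "deprecated")
  expect_identical(nrow(res2$rejections), 1L)
})

test_that("deconvolution expands pools by their duplex mapping", {
  pair <- makeRnaiPair(nPools = 3, perPool = 4)
  libs <- list(pair$pool, pair$duplex)

  # one pool -> 4 duplex-level lab picks
  req <- createCherryPickRequest("S-1", "1:A01", 2, "kim",
                                 libraries = libs)
  req <- deconvolute(req, libs)
  expect_identical(nrow(req@labPicks), 4L)
  expect_true(all(req@labPicks$source_plate == 2001L))
  expect_true(all(req@labPicks$status == "unfulfilled"))

  # 2 pools x 4 + 3 duplex picks = 11 lab picks (sum over the mapping)
  picks <- c("1:A01", "1:A02", "2001:A09", "2001:A10", "2001:A11")
  req2 <- createCherryPickRequest("S-1", picks, 2, "kim",
                                  libraries = libs)
  req2 <- deconvolute(req2, libs)
  w <- libraryWells(pair$pool)
  perPool <- vapply(c("A01", "A02"), function(wl)
    length(strsplit(w$duplex_wells[w$well == wl], ";")[[1]]), 1L)
  expect_identical(nrow(req2@labPicks), sum(perPool) + 3L)

  # small-molecule picks map 1:1
  s <- cpSetup()
  sm <- createCherryPickRequest("S-1", expKeys(s$lib)[1:10], 2, "kim",
                                libraries = list(s$lib))
  sm <- deconvolute(sm, list(s$lib))
  expect_identical(nrow(sm@labPicks), 10L)
  expect_identical(sm@labPicks$screener_key,
                   paste0(sm@labPicks$source_plate, ":",
                          sm@labPicks$source_well))

  # a pool whose duplexes are missing fails
  orphanRow <- rnaiRow(1, "H12", silencing = "pool",
                       vendor_id = "RP-999",
                       duplexWells = "2999:A01")
  w0 <- libraryWells(pair$pool)
  orphanLib <- importRnaiLibrary(
    list(Library = rbind(
      data.frame(Plate = 1, Well = "A01", Well_Type = "experimental",
                 Vendor = "A", Vendor_ID = "RP-001",
                 Silencing_Type = "pool", Entrez_Gene_ID = 1,
                 Gene_Symbol = "G", GenBank = NA, Species = NA,
                 Sequence = "ACGU", Duplex_Wells = "2999:A01",
                 stringsAsFactors = FALSE))),
    "ORPH", 96, 1, 1)
  reqO <- createCherryPickRequest("S-1", "1:A01", 2, "kim",
                                  libraries = list(orphanLib))
  expect_error(deconvolute(reqO, list(orphanLib)),
               "missing from the duplex library")
})

test_that("well-volume view reports each eligible copy with sufficiency", {
  s <- cpSetup(volumes = c(C = 10, D = 1))
  req <- createCherryPickRequest("S-1", "1:A02", 2, "kim",
                                 libraries = list(s$lib))
  req <- deconvolute(req, list(s$lib))
  tbl <- viewWellVolumes(req, s$copies)
  expect_identical(nrow(tbl), 2L)
  expect_identical(tbl$sufficient, c(TRUE, FALSE))

  # remaining exactly equal to the volume is sufficient
  s2 <- cpSetup(volumes = c(C = 2))
  req2 <- deconvolute(createCherryPickRequest("S-1", "1:A02", 2, "kim",
                                              libraries = list(s2$lib)),
                      list(s2$lib))
  expect_true(all(viewWellVolumes(req2, s2$copies)$sufficient))

  # retired plates leave no eligible rows
  retired <- lapply(s$copies, retirePlates, 1)
  expect_identical(nrow(viewWellVolumes(req, retired)), 0L)
})

test_that("reservation picks the smallest sufficient copy and debits it", {
  s <- cpSetup(volumes = c(C = 10, D = 3))
  log <- newActivityLog()
  req <- deconvolute(createCherryPickRequest("S-1", "1:A02", 2, "kim",
                                             libraries = list(s$lib)),
                     list(s$lib))
  res <- reserveReagent(req, s$copies, "adm", log)
  lp <- res$request@labPicks
  expect_identical(lp$status, "reserved")
  expect_identical(lp$source_copy, "D")  # nearly-empty copy first
  expect_equal(unname(remainingVolume(res$copies[[2]], "1:A02")), 1)
  expect_equal(unname(remainingVolume(res$copies[[1]], "1:A02")), 10)
  expect_identical(res$activity@kind, "cherry_pick_reservation")

  # no sufficient copy: pick stays unfulfilled, nothing debited
  s2 <- cpSetup(volumes = c(C = 1, D = 1))
  req2 <- deconvolute(createCherryPickRequest("S-1", "1:A02", 2, "kim",
                                              libraries = list(s2$lib)),
                      list(s2$lib))
  res2 <- reserveReagent(req2, s2$copies, "adm", log)
  expect_identical(res2$request@labPicks$status, "unfulfilled")
  expect_true(all(remainingVolume(res2$copies[[1]]) == 1))

  # ties break to the lexicographically smaller copy name
  s3 <- cpSetup(volumes = c(D = 5, C = 5))
  req3 <- deconvolute(createCherryPickRequest("S-1", "1:A02", 2, "kim",
                                              libraries = list(s3$lib)),
                      list(s3$lib))
  res3 <- reserveReagent(req3, s3$copies, "adm", log)
  expect_identical(res3$request@labPicks$source_copy, "C")
})

test_that("sequential reservations see earlier debits (shared well)", {
  # two pools sharing one duplex well -> two lab picks on one source well
  wn <- wellNamesRowMajor(96)
  dup <- importRnaiLibrary(list(Library = rnaiRow(2001, "A01")),
                           "DUP", 96, 2001, 2001)
  pools <- rbind(
    rnaiRow(1, "A01", silencing = "pool", vendor_id = "RP-1",
            duplexWells = "2001:A01"),
    rnaiRow(1, "A02", silencing = "pool", vendor_id = "RP-2",
            duplexWells = "2001:A01"))
  pool <- importRnaiLibrary(list(Library = pools), "POOL", 96, 1, 1)
  libs <- list(pool, dup)
  cp <- createCopy(dup, "C", "cherry_pick_source", 3)
  req <- deconvolute(createCherryPickRequest("S-1", c("1:A01", "1:A02"),
                                             2, "kim", libraries = libs),
                     libs)
  res <- reserveReagent(req, list(cp), "adm", newActivityLog())
  expect_identical(res$request@labPicks$status,
                   c("reserved", "unfulfilled"))
  expect_equal(unname(remainingVolume(res$copies[[1]], "2001:A01")), 1)
})

test_that("reservation agrees with a brute-force rule oracle", {
  withr::with_seed(99, {
    for (trial in 1:10) {
      nCopies <- sample(2:4, 1)
      vols <- stats::setNames(round(runif(nCopies, 0, 8), 1),
                              sample(LETTERS, nCopies))
      s <- cpSetup(volumes = vols)
      picks <- sample(expKeys(s$lib), 20)
      req <- deconvolute(createCherryPickRequest("S-1", picks, 2, "kim",
                                                 libraries = list(s$lib)),
                         list(s$lib))
      res <- reserveReagent(req, s$copies, "adm", newActivityLog())
      # oracle: replay the stated rule over a plain volume table
      tbl <- sapply(s$copies, function(cp) remainingVolume(cp))
      colnames(tbl) <- vapply(s$copies, copyName, "")
      expected <- character(nrow(req@labPicks))
      for (i in seq_len(nrow(req@labPicks))) {
        key <- paste0(req@labPicks$source_plate[i], ":",
                      req@labPicks$source_well[i])
        cand <- tbl[key, ]
        cand <- cand[cand >= 2]
        if (!length(cand)) { expected[i] <- NA_character_; next }
        nm <- names(cand)[order(cand, names(cand))][1]
        expected[i] <- nm
        tbl[key, nm] <- tbl[key, nm] - 2
      }
      expect_identical(res$request@labPicks$source_copy, expected)
      got <- sapply(res$copies, function(cp) remainingVolume(cp))
      colnames(got) <- vapply(res$copies, copyName, "")
      expect_equal(got[, colnames(tbl)], tbl)
    }
  })
})

# reserve `n` picks on a fresh 3-plate 384-well library
bigReserved <- function(n, empty = character(), randomize = FALSE,
                        seed = 7) {
  lib <- makeSmLibrary("BIG", nPlates = 3, format = 384, controls = c())
  cp <- createCopy(lib, "C", "cherry_pick_source", 100)
  picks <- expKeys(lib)[seq_len(n)]
  req <- createCherryPickRequest("S-1", picks, 2, "kim",
                                 libraries = list(lib),
                                 randomizeLayout = randomize,
                                 requiredEmptyWells = empty,
                                 randomSeed = seed)
  req <- deconvolute(req, list(lib))
  reserveReagent(req, list(cp), "adm", newActivityLog())$request
}

test_that("plate mapping batches, fills and overflows correctly", {
  empty24 <- wellNamesRowMajor(384)[1:24]
  req <- mapToPlates(bigReserved(800, empty = empty24))
  lp <- req@labPicks
  expect_identical(nrow(req@plates), 3L)  # ceil(800/360)
  expect_identical(as.vector(table(lp$dest_plate)), c(360L, 360L, 80L))
  # destinations unique per plate and never forbidden
  for (p in unique(lp$dest_plate)) {
    dests <- lp$dest_well[lp$dest_plate == p]
    expect_false(anyDuplicated(dests) > 0)
    expect_false(any(dests %in% empty24))
  }
  # source plates batched (non-decreasing within each destination plate)
  for (p in unique(lp$dest_plate)) {
    sub <- lp[lp$dest_plate == p, ]
    expect_false(is.unsorted(sub$source_plate))
  }
  expect_error(mapToPlates(req), "no reserved picks")  # all mapped now
})

test_that("row-major layout without randomization, reproducible with", {
  req <- mapToPlates(bigReserved(5))
  expect_identical(req@labPicks$dest_well,
                   wellNamesRowMajor(384)[1:5])

  r1 <- mapToPlates(bigReserved(50, randomize = TRUE, seed = 123))
  r2 <- mapToPlates(bigReserved(50, randomize = TRUE, seed = 123))
  expect_identical(r1@labPicks, r2@labPicks)
  r3 <- mapToPlates(bigReserved(50, randomize = TRUE, seed = 124))
  expect_false(identical(r1@labPicks$dest_well,
                         r3@labPicks$dest_well))
  # the whole-plate capacity degenerate case
  expect_error(
    mapToPlates(bigReserved(5, empty = wellNamesRowMajor(384))),
    "cover the whole destination plate")
})

test_that("the mapping file has one ordered row per mapped pick", {
  pair <- makeRnaiPair(nPools = 2, perPool = 4)
  libs <- list(pair$pool, pair$duplex)
  cp <- createCopy(pair$duplex, "C", "cherry_pick_source", 10)
  picks <- c("1:A01", "1:A02", "2001:A05", "2001:A06", "2001:A07")
  req <- deconvolute(createCherryPickRequest("S-1", picks, 2, "kim",
                                             libraries = libs), libs)
  req <- reserveReagent(req, list(cp), "adm", newActivityLog())$request
  req <- mapToPlates(req)
  lines <- exportPlateMapping(req)
  expect_length(lines, 12L)  # header + 11 mapped picks
  expect_match(lines[1], "^source_plate,source_copy")
  m <- utils::read.csv(textConnection(lines))
  expect_identical(nrow(m), sum(req@labPicks$status == "mapped"))
  expect_false(is.unsorted(m$source_plate))

  unmapped <- createCherryPickRequest("S-1", "1:A01", 2, "kim")
  expect_error(exportPlateMapping(unmapped), "no mapped picks")
})

test_that("byte-identical mapping files for identical request and seed", {
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  exportPlateMapping(mapToPlates(bigReserved(700, randomize = TRUE,
                                             seed = 31)), f1)
  exportPlateMapping(mapToPlates(bigReserved(700, randomize = TRUE,
                                             seed = 31)), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("plating confirms, canceling refunds exactly, failing respawns", {
  s <- cpSetup(volumes = c(C = 10))
  log <- newActivityLog()
  picks <- expKeys(s$lib)[1:6]
  req <- deconvolute(createCherryPickRequest("S-1", picks, 2, "kim",
                                             libraries = list(s$lib)),
                     list(s$lib))
  res <- reserveReagent(req, s$copies, "adm", log)
  req <- mapToPlates(res$request); copies <- res$copies; log <- res$log

  # cancel: every debit for the plate is exactly reversed
  cres <- updatePlateStatus(req, 1, "canceled", "adm", copies, log)
  expect_true(all(remainingVolume(cres$copies[[1]]) == 10))
  expect_identical(unique(cres$request@labPicks$status), "canceled")
  expect_identical(cres$activity@kind, "cherry_pick_cancellation")
  # a terminal plate refuses further transitions
  expect_error(updatePlateStatus(cres$request, 1, "plated", "adm",
                                 cres$copies, cres$log),
               "terminal")

  # plated: picks confirm and a liquid transfer activity is recorded
  res <- reserveReagent(deconvolute(
    createCherryPickRequest("S-1", picks, 2, "kim",
                            libraries = list(s$lib)), list(s$lib)),
    s$copies, "adm", newActivityLog())
  preq <- mapToPlates(res$request)
  pres <- updatePlateStatus(preq, 1, "plated", "adm", res$copies,
                            res$log)
  expect_identical(unique(pres$request@labPicks$status), "plated")
  expect_identical(pres$activity@kind, "cherry_pick_liquid_transfer")
  expect_length(exportPlateMapping(pres$request), 7L)
})

test_that("failure keeps the debit and yields an attempt-2 plate", {
  s <- cpSetup(volumes = c(C = 10))
  log <- newActivityLog()
  picks <- expKeys(s$lib)[1:4]
  res <- reserveReagent(deconvolute(
    createCherryPickRequest("S-1", picks, 2, "kim",
                            libraries = list(s$lib)), list(s$lib)),
    s$copies, "adm", log)
  req <- mapToPlates(res$request); copies <- res$copies; log <- res$log
  keys <- paste0(req@labPicks$source_plate, ":",
                 req@labPicks$source_well)
  expect_true(all(remainingVolume(copies[[1]], keys) == 8))

  fres <- updatePlateStatus(req, 1, "failed", "adm", copies, log)
  req <- fres$request; copies <- fres$copies; log <- fres$log
  # volumes stay debited; picks respawned as fresh unfulfilled
  expect_true(all(remainingVolume(copies[[1]], keys) == 8))
  expect_identical(sum(req@labPicks$status == "failed"), 4L)
  expect_identical(sum(req@labPicks$status == "unfulfilled"), 4L)

  # repeat the reservation and mapping workflow for the affected plate
  rres <- reserveReagent(req, copies, "adm", log)
  req <- mapToPlates(rres$request); copies <- rres$copies
  expect_true(all(remainingVolume(copies[[1]], keys) == 6))  # double debit
  succ <- req@plates[req@plates$status == "not_plated", ]
  expect_identical(succ$ordinal, 1L)
  expect_identical(succ$attempt, 2L)
})

test_that("unfulfilled picks roll over once into a new request", {
  # copy volume suffices for exactly 3 of 5 picks of the same well? no —
  # distinct wells, but shrink the copy so two specific wells run dry
  s <- cpSetup(volumes = c(C = 10))
  log <- newActivityLog()
  cp <- s$copies[[1]]
  adm <- adminUser()
  cp <- applyVolumeCorrection(cp, "1:A02", 1, "spill", adm, log)$copy
  cp <- applyVolumeCorrection(cp, "1:A03", 0, "dry", adm, log)$copy
  picks <- c("1:A02", "1:A03", "1:A04", "1:A05", "1:A06")
  res <- reserveReagent(deconvolute(
    createCherryPickRequest("S-1", picks, 2, "kim",
                            libraries = list(s$lib)), list(s$lib)),
    list(cp), "adm", log)
  req <- res$request
  expect_identical(sum(req@labPicks$status == "unfulfilled"), 2L)

  ro <- rolloverUnfulfilled(req, "CPR-2")
  expect_identical(nrow(ro$newRequest@screenerPicks), 2L)
  expect_setequal(paste0(ro$newRequest@screenerPicks$plate, ":",
                         ro$newRequest@screenerPicks$well),
                  c("1:A02", "1:A03"))
  # originals consumed: a second rollover errors
  expect_error(rolloverUnfulfilled(ro$request, "CPR-3"),
               "no unfulfilled")
  fully <- reserveReagent(deconvolute(
    createCherryPickRequest("S-1", "1:A04", 2, "kim",
                            libraries = list(s$lib)), list(s$lib)),
    list(cp), "adm", log)
  expect_error(rolloverUnfulfilled(fully$request, "X"), "no unfulfilled")
})

test_that("random workflows never leave the declared state machines", {
  withr::with_seed(17, {
    for (trial in 1:8) {
      s <- cpSetup(volumes = c(C = round(runif(1, 4, 10), 1)))
      picks <- sample(expKeys(s$lib), 15)
      log <- newActivityLog()
      res <- reserveReagent(deconvolute(
        createCherryPickRequest("S-1", picks, 2, "kim",
                                libraries = list(s$lib),
                                requiredEmptyWells =
                                  sample(wellNamesRowMajor(96), 5)),
        list(s$lib)), s$copies, "adm", log)
      req <- res$request; copies <- res$copies; log <- res$log
      for (step in 1:6) {
        op <- sample(c("map", "status", "reserve"), 1)
        ok <- tryCatch({
          if (op == "map") req <- mapToPlates(req)
          else if (op == "reserve") {
            r <- reserveReagent(req, copies, "adm", log)
            req <- r$request; copies <- r$copies; log <- r$log
          } else {
            open <- req@plates$ordinal[req@plates$status == "not_plated"]
            if (length(open)) {
              r <- updatePlateStatus(req, sample(open, 1),
                                     sample(c("plated", "failed",
                                              "canceled"), 1),
                                     "adm", copies, log)
              req <- r$request; copies <- r$copies; log <- r$log
            }
          }
          TRUE
        }, error = function(e) FALSE)
        lp <- req@labPicks
        expect_true(all(lp$status %in% c("unfulfilled", "reserved",
                                         "mapped", "plated", "failed",
                                         "canceled")))
        expect_true(all(!is.na(lp$source_copy[lp$status %in%
          c("reserved", "mapped", "plated")])))
        expect_true(all(!is.na(lp$dest_well[lp$status %in%
          c("mapped", "plated")])))
        expect_true(all(req@plates$status %in% c("not_plated", "plated",
                                                 "failed", "canceled")))
        # every mapped pick belongs to exactly one open plate
        mp <- lp[lp$status == "mapped", ]
        if (nrow(mp))
          expect_true(all(mp$dest_plate %in%
                            req@plates$ordinal[req@plates$status ==
                                                 "not_plated"]))
        # volumes never negative
        for (cp in copies)
          expect_true(all(remainingVolume(cp) >= 0))
      }
    }
  })
})
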