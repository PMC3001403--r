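# fixed set of valid SMILES used for synthetic compounds, so core tests
# carry no chemistry dependency; counters are appended in chemical names
.smilesTemplates <- c(
  "c1ccccc1", "CCO", "CC(=O)Oc1ccccc1C(=O)O",
  "CN1C=NC2=C1C(=O)N(C)C(=O)N2C", "CC(C)Cc1ccc(cc1)C(C)C(=O)O",
  "C1CCNCC1", "Clc1ccccc1", "OCC(O)CO", "NC(=O)c1ccccc1", "CC(=O)NC1CC1")

#' Specification for synthetic screening fixtures
#'
#' Holds the stated world the generator emulates: plate count and format,
#' the control-well layout, the expected positives rate and the fraction
#' of reagents typically cherry-picked in follow-up (around 0.3–0.5% of
#' compounds for small-molecule screens, 1–3% of genes for RNAi screens —
#' used as generator defaults only, never enforced).
#'
#' @param seed integer seed; the same seed yields byte-identical files.
#' @param libraryType `"small_molecule"` or `"rnai"`.
#' @param nPlates number of library plates.
#' @param plateFormat 96, 384 or 1536.
#' @param controlWells per-plate control layout: named character vector
#'   mapping well names to control well types. The default devotes
#'   column 1 to DMSO controls and the last column to library controls.
#' @param positivesRate expected fraction of experimental wells scoring
#'   positive.
#' @param cherryPickFraction fraction of experimental wells picked for
#'   follow-up.
#' @return a `FixtureSpec` list.
#' @export
fixtureSpec <- function(seed = 1, libraryType = "small_molecule",
                        nPlates = 2, plateFormat = 384,
                        controlWells = NULL,
                        positivesRate = if (libraryType == "rnai") 0.02
                                        else 0.005,
                        cherryPickFraction = if (libraryType == "rnai") 0.02
                                             else 0.005) {
  stopifnot(positivesRate >= 0, positivesRate <= 1,
            cherryPickFraction >= 0, cherryPickFraction <= 1)
  if (is.null(controlWells)) {
    dims <- plateDims(plateFormat)
    rows <- seq_len(dims[["rows"]]) - 1L
    dmso <- formatWellName(rows, 0L, plateFormat)
    libc <- formatWellName(rows, dims[["cols"]] - 1L, plateFormat)
    controlWells <- c(stats::setNames(rep("dmso_control", length(dmso)),
                                      dmso),
                      stats::setNames(rep("library_control", length(libc)),
                                      libc))
  }
  structure(list(seed = as.integer(seed), libraryType = libraryType,
                 nPlates = as.integer(nPlates),
                 plateFormat = as.integer(plateFormat),
                 controlWells = controlWells,
                 positivesRate = positivesRate,
                 cherryPickFraction = cherryPickFraction),
            class = "FixtureSpec")
}

.randSeq <- function(len) paste(sample(c("A", "C", "G", "U"), len,
                                       replace = TRUE), collapse = "")

#' Generate synthetic library content files
#'
#' Small-molecule specs produce one SD file with synthetic vendor ids and
#' valid SMILES drawn from a fixed template set; RNAi specs produce a
#' pooled library workbook plus the matching duplex library workbook
#' (4 duplexes per pool, plated row-major onto duplex plates numbered
#' from 2001). Control wells follow the spec's layout. Output is
#' deterministic under the spec seed.
#'
#' @param spec a [fixtureSpec()].
#' @param dir output directory.
#' @param name library short name (file basename).
#' @return list with `files` (paths written) and `meta` (importer
#'   arguments: screenType, plateFormat, startPlate, endPlate; for RNAi
#'   also the duplex library's meta).
#' @export
generateLibrary <- function(spec, dir, name = "SYNLIB") {
  stopifnot(inherits(spec, "FixtureSpec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wn <- wellNamesRowMajor(spec$plateFormat)
  ctrl <- spec$controlWells
  expWells <- setdiff(wn, names(ctrl))
  .withSeed(spec$seed, {
    if (spec$libraryType == "small_molecule") {
      recs <- list()
      k <- 0L
      for (p in seq_len(spec$nPlates)) {
        for (w in wn) {
          if (w %in% names(ctrl)) {
            recs[[length(recs) + 1L]] <- list(
              Plate = p, Well = w, Well_Type = ctrl[[w]])
          } else {
            k <- k + 1L
            recs[[length(recs) + 1L]] <- list(
              Plate = p, Well = w, Well_Type = "experimental",
              Vendor = "SynChem",
              Vendor_ID = sprintf("SC-%05d", k),
              SMILES = sample(.smilesTemplates, 1L),
              Molecular_Mass = round(stats::runif(1, 150, 650), 2),
              Chemical_Names = sprintf("compound-%d", k),
              PubChem_CIDs = sample.int(99999999, 1L),
              ChemBank_IDs = sprintf("cbk-%06d", k))
          }
        }
      }
      path <- file.path(dir, paste0(name, ".sdf"))
      writeSdf(lapply(recs, lapply, as.character), path)
      list(files = c(library = path),
           meta = list(screenType = "small_molecule",
                       plateFormat = spec$plateFormat, startPlate = 1L,
                       endPlate = spec$nPlates))
    } else {
      nPerPool <- 4L
      dupPerPlate <- spec$plateFormat
      poolRows <- list(); dupRows <- list()
      k <- 0L; d <- 0L
      for (p in seq_len(spec$nPlates)) {
        for (w in wn) {
          if (w %in% names(ctrl)) {
            poolRows[[length(poolRows) + 1L]] <- data.frame(
              Plate = p, Well = w, Well_Type = ctrl[[w]],
              Vendor = NA, Vendor_ID = NA, Silencing_Type = NA,
              Entrez_Gene_ID = NA, Gene_Symbol = NA, GenBank = NA,
              Species = NA, Sequence = NA, Duplex_Wells = NA,
              stringsAsFactors = FALSE)
            next
          }
          k <- k + 1L
          gene <- sample.int(999999, 1L)
          seqs <- vapply(seq_len(nPerPool),
                         function(i) .randSeq(sample(19:21, 1L)), "")
          dKeys <- character(nPerPool)
          for (i in seq_len(nPerPool)) {
            dPlate <- 2000L + (d %/% dupPerPlate) + 1L
            dWell <- wellNamesRowMajor(spec$plateFormat)[
              (d %% dupPerPlate) + 1L]
            d <- d + 1L
            dKeys[i] <- wellKey(dPlate, dWell)
            dupRows[[length(dupRows) + 1L]] <- data.frame(
              Plate = dPlate, Well = dWell, Well_Type = "experimental",
              Vendor = "SynRNAi",
              Vendor_ID = sprintf("SD-%05d-%d", k, i),
              Silencing_Type = "duplex", Entrez_Gene_ID = gene,
              Gene_Symbol = sprintf("GENE%d", gene),
              GenBank = sprintf("NM_%06d", gene),
              Species = "Homo sapiens", Sequence = seqs[i],
              Duplex_Wells = NA, stringsAsFactors = FALSE)
          }
          poolRows[[length(poolRows) + 1L]] <- data.frame(
            Plate = p, Well = w, Well_Type = "experimental",
            Vendor = "SynRNAi", Vendor_ID = sprintf("SP-%05d", k),
            Silencing_Type = "pool", Entrez_Gene_ID = gene,
            Gene_Symbol = sprintf("GENE%d", gene),
            GenBank = sprintf("NM_%06d", gene),
            Species = "Homo sapiens",
            Sequence = paste(seqs, collapse = ";"),
            Duplex_Wells = paste(dKeys, collapse = ";"),
            stringsAsFactors = FALSE)
        }
      }
      poolPath <- file.path(dir, paste0(name, "_pools.txt"))
      dupPath <- file.path(dir, paste0(name, "_duplexes.txt"))
      writeWorkbook(list(Library = do.call(rbind, poolRows)), poolPath)
      writeWorkbook(list(Library = do.call(rbind, dupRows)), dupPath)
      dupEnd <- 2000L + ((d - 1L) %/% dupPerPlate) + 1L
      list(files = c(library = poolPath, duplexes = dupPath),
           meta = list(screenType = "rnai",
                       plateFormat = spec$plateFormat, startPlate = 1L,
                       endPlate = spec$nPlates,
                       duplexMeta = list(startPlate = 2001L,
                                         endPlate = dupEnd)))
    }
  })
}

#' Generate a synthetic screen-result workbook for a library
#'
#' Produces two replicate raw columns of unit-scale noise, a derived
#' `Score` column (replicate mean) and a derived threshold positives
#' column `PositiveScore` (cutoff 2.5, direction above). True positives
#' are drawn per experimental well with probability `spec$positivesRate`
#' and receive a +5 activity shift, so the realised positive fraction
#' stays within binomial error of the rate. Control wells receive values
#' too, but never count as positives. The workbook conforms to the
#' screen-result import format and is deterministic under the seed.
#'
#' @param library a [ScreenLibrary] (the screened library).
#' @param spec a [fixtureSpec()] (seed and positives rate are used).
#' @param path output workbook path.
#' @return invisibly, the number of true positives drawn.
#' @export
generateScreenResult <- function(library, spec, path) {
  stopifnot(is(library, "ScreenLibrary"), inherits(spec, "FixtureSpec"))
  w <- library@wells
  rows <- which(w$well_type != "empty")
  n <- length(rows)
  .withSeed(spec$seed + 1L, {
    isExp <- w$well_type[rows] == "experimental"
    pos <- isExp & stats::runif(n) < spec$positivesRate
    rep1 <- round(stats::rnorm(n) + 5 * pos, 6)
    rep2 <- round(stats::rnorm(n) + 5 * pos, 6)
    score <- round((rep1 + rep2) / 2, 6)
    posScore <- ifelse(pos, score, 0)
    headers <- data.frame(
      Name = c("Rep1", "Rep2", "Score", "PositiveScore"),
      Kind = "numeric",
      Replicate = c(1L, 2L, NA, NA),
      Time_Point = NA, Readout_Technology = c("luminescence",
                                              "luminescence", NA, NA),
      Derived = c(FALSE, FALSE, TRUE, TRUE),
      Derived_From = c(NA, NA, "Rep1;Rep2", "Score"),
      Positive_Indicator = c(NA, NA, NA, "threshold"),
      Cutoff = c(NA, NA, NA, 2.5),
      Direction = c(NA, NA, NA, "above"),
      Description = c("raw replicate 1", "raw replicate 2",
                      "replicate mean", "screener positives call"),
      stringsAsFactors = FALSE)
    data <- data.frame(Plate = w$plate[rows], Well = w$well[rows],
                       Assay_Well_Type = w$well_type[rows],
                       Rep1 = rep1, Rep2 = rep2, Score = score,
                       PositiveScore = posScore, stringsAsFactors = FALSE)
    writeWorkbook(list(`Data Headers` = headers, Data = data), path)
    invisible(sum(pos))
  })
}

#' Draw a deterministic cherry-pick list from a library
#'
#' Samples `spec$cherryPickFraction` of the library's experimental wells
#' (at least one) under the spec seed, as `"plate:well"` designations.
#'
#' @param library a [ScreenLibrary].
#' @param spec a [fixtureSpec()].
#' @return character vector of well keys.
#' @export
generateCherryPickList <- function(library, spec) {
  stopifnot(is(library, "ScreenLibrary"))
  w <- library@wells
  keys <- wellKey(w$plate, w$well)[w$well_type == "experimental"]
  n <- max(1L, round(length(keys) * spec$cherryPickFraction))
  .withSeed(spec$seed + 2L, sample(keys, n))
}
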