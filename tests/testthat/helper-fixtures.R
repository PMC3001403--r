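# In-code fixture builders shared across the suite. Everything is
# generated programmatically; no files ship with the package.

# one SDF record as a named list of data fields
smRecord <- function(plate, well, type = "experimental",
                     vendor = "AcmeChem", vendor_id = NULL,
                     smiles = "CCO", inchi = NA, mass = 320.5,
                     names = NULL) {
  rec <- list(Plate = plate, Well = well, Well_Type = type)
  if (type == "experimental") {
    rec$Vendor <- vendor
    rec$Vendor_ID <- vendor_id %||% paste0("V-", plate, well)
    if (!is.na(smiles)) rec$SMILES <- smiles
    if (!is.na(inchi)) rec$InChI <- inchi
    rec$Molecular_Mass <- mass
    if (!is.null(names)) rec$Chemical_Names <- names
  }
  lapply(rec, as.character)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

sdfLinesFor <- function(records) screenkit:::writeSdf(records)

# a small-molecule library with every well of each plate filled
# (experimental except the listed control wells), built through the importer
makeSmLibrary <- function(shortName = "SML", nPlates = 1, format = 96,
                          controls = c(A01 = "dmso_control")) {
  wn <- wellNamesRowMajor(format)
  recs <- list()
  k <- 0L
  for (p in seq_len(nPlates)) for (w in wn) {
    if (w %in% names(controls))
      recs[[length(recs) + 1L]] <- smRecord(p, w, controls[[w]])
    else {
      k <- k + 1L
      recs[[length(recs) + 1L]] <- smRecord(p, w,
                                            vendor_id = sprintf("V-%04d", k))
    }
  }
  importSmallMoleculeLibrary(sdfLinesFor(recs), shortName, format, 1,
                             nPlates)
}

# rnai row for the workbook importer
rnaiRow <- function(plate, well, type = "experimental", silencing = "duplex",
                    vendor_id = paste0("R-", plate, well),
                    gene = 1234L, seqs = "ACGUACGUACGUACGUACGUA",
                    duplexWells = NA) {
  data.frame(Plate = plate, Well = well, Well_Type = type,
             Vendor = if (type == "experimental") "AcmeRNAi" else NA,
             Vendor_ID = if (type == "experimental") vendor_id else NA,
             Silencing_Type = if (type == "experimental") silencing else NA,
             Entrez_Gene_ID = if (type == "experimental") gene else NA,
             Gene_Symbol = if (type == "experimental")
               paste0("GENE", gene) else NA,
             GenBank = NA, Species = "Homo sapiens",
             Sequence = if (type == "experimental") seqs else NA,
             Duplex_Wells = duplexWells, stringsAsFactors = FALSE)
}

# pool library (plate 1) + duplex library (plate 2001), nPools pools of
# `perPool` duplexes each, laid row-major; returns list(pool, duplex)
makeRnaiPair <- function(nPools = 3, perPool = 4, format = 96) {
  wn <- wellNamesRowMajor(format)
  poolRows <- list(); dupRows <- list()
  d <- 0L
  for (k in seq_len(nPools)) {
    gene <- 1000L + k
    dKeys <- character(perPool)
    for (i in seq_len(perPool)) {
      d <- d + 1L
      dKeys[i] <- paste0("2001:", wn[d])
      dupRows[[d]] <- rnaiRow(2001L, wn[d], silencing = "duplex",
                              vendor_id = sprintf("RD-%03d-%d", k, i),
                              gene = gene)
    }
    poolRows[[k]] <- rnaiRow(1L, wn[k], silencing = "pool",
                             vendor_id = sprintf("RP-%03d", k),
                             gene = gene,
                             duplexWells = paste(dKeys, collapse = ";"))
  }
  dup <- importRnaiLibrary(list(Library = do.call(rbind, dupRows)),
                           "DUP", format, 2001, 2001)
  pool <- importRnaiLibrary(list(Library = do.call(rbind, poolRows)),
                            "POOL", format, 1, 1,
                            duplexLibraries = list(dup))
  list(pool = pool, duplex = dup)
}

# a minimal screen with an imported result built from explicit columns
makeScreenWithResult <- function(library, headers, data,
                                 facilityId = "S-1", level = 1) {
  sc <- newScreen(facilityId, screenType(library), labHead = "ph",
                  dataSharingLevel = level,
                  libraryNames = shortName(library))
  importScreenResult(sc, list(`Data Headers` = headers, Data = data),
                     list(library))
}

adminUser <- function(id = "adm")
  screenUser(id, "administrator",
             roles = c("login", "volume_admin", "read_everything"))

# independent ledger replay oracle: applies debits/credits/corrections to
# a plain named numeric vector in microliters, mirroring nothing of the
# package's internals
replayOracle <- function(keys, initialUl) {
  env <- new.env()
  env$vol <- stats::setNames(rep(initialUl, length(keys)), keys)
  list(
    debit = function(k, ul) env$vol[k] <- env$vol[k] - ul,
    credit = function(k, ul) env$vol[k] <- env$vol[k] + ul,
    set = function(k, ul) env$vol[k] <- ul,
    volumes = function() env$vol)
}
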