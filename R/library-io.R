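# default mapping from internal well-table columns to import-file field
# names; facilities with foreign SDF/workbook dialects can override via
# the `fieldMap` argument of the importers
.defaultFieldMap <- c(
  plate = "Plate", well = "Well", well_type = "Well_Type",
  vendor = "Vendor", vendor_id = "Vendor_ID",
  smiles = "SMILES", inchi = "InChI", molecular_mass = "Molecular_Mass",
  chemical_names = "Chemical_Names", pubchem_cids = "PubChem_CIDs",
  chembank_ids = "ChemBank_IDs",
  silencing_type = "Silencing_Type", entrez_gene_id = "Entrez_Gene_ID",
  gene_symbol = "Gene_Symbol", genbank_accessions = "GenBank",
  species = "Species", sequences = "Sequence",
  duplex_wells = "Duplex_Wells")

.resolveFieldMap <- function(fieldMap) {
  fm <- .defaultFieldMap
  if (!is.null(fieldMap)) fm[names(fieldMap)] <- fieldMap
  fm
}

# normalize a character data.frame of import rows to internal column names
.mapImportColumns <- function(df, fieldMap) {
  fm <- .resolveFieldMap(fieldMap)
  hit <- match(names(df), fm)
  names(df)[!is.na(hit)] <- names(fm)[hit[!is.na(hit)]]
  df
}

.trimOrNA <- function(v) {
  v <- trimws(as.character(v))
  ifelse(is.na(v) | !nzchar(v), NA_character_, v)
}

# fill a library's (empty) well table from normalized import rows; errors
# carry the 1-based record ordinal so files can be fixed
.fillWellTable <- function(library, rows) {
  schema <- wellTableSchema(library@screenType)
  wells <- .emptyWellTable(library@screenType, library@plateFormat,
                           library@startPlate, library@endPlate)
  n <- nrow(rows)
  if (!n) { library@wells <- wells; return(library) }
  for (req in c("plate", "well", "well_type"))
    if (!req %in% names(rows))
      stop("import file lacks required field '",
           .resolveFieldMap(NULL)[[req]], "'", call. = FALSE)

  plate <- suppressWarnings(as.integer(.trimOrNA(rows$plate)))
  if (anyNA(plate))
    stop("unparsable record ", which(is.na(plate))[1L],
         ": missing or non-numeric plate", call. = FALSE)
  outside <- plate < library@startPlate | plate > library@endPlate
  if (any(outside))
    stop("record ", which(outside)[1L], ": plate ", plate[which(outside)[1L]],
         " outside declared range ", library@startPlate, "-",
         library@endPlate, call. = FALSE)
  wn <- .trimOrNA(rows$well)
  if (anyNA(wn))
    stop("unparsable record ", which(is.na(wn))[1L], ": missing well",
         call. = FALSE)
  co <- tryCatch(parseWellName(wn, library@plateFormat), error = function(e)
    stop("unparsable well name in import: ", conditionMessage(e),
         call. = FALSE))
  wn <- formatWellName(co[, "row"], co[, "col"], library@plateFormat)
  keys <- wellKey(plate, wn)
  dup <- duplicated(keys)
  if (any(dup))
    stop("duplicate well in import file: record ", which(dup)[1L],
         " repeats ", keys[which(dup)[1L]], call. = FALSE)

  wtype <- .trimOrNA(rows$well_type)
  wtype[is.na(wtype)] <- "experimental"
  wtype <- tolower(wtype)
  if (!all(wtype %in% WELL_TYPES))
    stop("record ", which(!wtype %in% WELL_TYPES)[1L],
         ": invalid well type '", wtype[!wtype %in% WELL_TYPES][1L], "'",
         call. = FALSE)

  idx <- .wellRows(library, keys)  # all valid: table covers the range
  wells$well_type[idx] <- wtype
  for (col in setdiff(names(schema),
                      c("plate", "well", "well_type", "deprecated",
                        "deprecation_reason"))) {
    if (!col %in% names(rows)) next
    v <- .trimOrNA(rows[[col]])
    wells[[col]][idx] <- switch(schema[[col]],
      integer = suppressWarnings(as.integer(v)),
      numeric = suppressWarnings(as.numeric(v)),
      v)
  }

  expi <- idx[wtype == "experimental"]
  if (library@screenType == "small_molecule") {
    noStructure <- is.na(wells$smiles[expi]) & is.na(wells$inchi[expi])
    if (any(noStructure))
      stop("record ", which(wtype == "experimental")[noStructure][1L],
           ": experimental well lacks both SMILES and InChI", call. = FALSE)
    mm <- wells$molecular_mass[expi]
    if (any(!is.na(mm) & mm <= 0))
      stop("non-positive molecular mass in import", call. = FALSE)
  } else {
    st <- wells$silencing_type[expi]
    if (any(is.na(st) | !st %in% c("pool", "duplex")))
      stop("record ", which(wtype == "experimental")[
             is.na(st) | !st %in% c("pool", "duplex")][1L],
           ": silencing type must be 'pool' or 'duplex'", call. = FALSE)
    dw <- wells$duplex_wells[expi]
    poolNoDw <- st == "pool" & (is.na(dw) | !nzchar(dw))
    if (any(poolNoDw))
      stop("record ", which(wtype == "experimental")[poolNoDw][1L],
           ": pool reagent lacks Duplex_Wells", call. = FALSE)
    dupWithDw <- st == "duplex" & !is.na(dw) & nzchar(dw)
    if (any(dupWithDw))
      stop("record ", which(wtype == "experimental")[dupWithDw][1L],
           ": duplex reagent must not carry Duplex_Wells", call. = FALSE)
    # duplex tokens must parse as plate:well keys
    for (tok in unlist(strsplit(dw[st == "pool" & !is.na(dw)], ";",
                                fixed = TRUE)))
      splitWellKey(tok, library@plateFormat)
  }
  # empty/buffer wells never carry reagents
  blank <- wells$well_type %in% c("empty", "buffer")
  for (col in setdiff(names(schema), names(.wellColsCommon)))
    wells[[col]][blank] <- as.vector(NA, mode = schema[[col]])
  wells$vendor[blank] <- NA_character_
  wells$vendor_id[blank] <- NA_character_

  library@wells <- wells
  validObject(library)
  library
}

#' Import a small-molecule library from an SD file
#'
#' Each SDF record must carry `Plate`, `Well` and `Well_Type` data fields
#' (plus `Vendor`/`Vendor_ID` and structural fields for experimental
#' wells). Wells absent from the file become `well_type = "empty"`. Well
#' names are normalised to the zero-padded dialect ("a1" is stored as
#' "A01"). V2000 molblocks are tolerated and ignored; structures are taken
#' from the `SMILES`/`InChI` data fields.
#'
#' @param sdf path to an SD file, or its lines as a character vector.
#' @param shortName library name.
#' @param plateFormat 96, 384 or 1536.
#' @param startPlate,endPlate declared inclusive plate range.
#' @param fieldMap optional named character vector overriding the default
#'   data-field names (names are internal columns, values the foreign
#'   field names).
#' @return a [ScreenLibrary].
#' @export
importSmallMoleculeLibrary <- function(sdf, shortName, plateFormat = 384,
                                       startPlate = 1,
                                       endPlate = startPlate,
                                       fieldMap = NULL) {
  lib <- newScreenLibrary(shortName, "small_molecule", plateFormat,
                          startPlate, endPlate)
  parsed <- readSdf(sdf)
  rows <- .sdfRecordsToFrame(parsed$records)
  .fillWellTable(lib, .mapImportColumns(rows, fieldMap))
}

.sdfRecordsToFrame <- function(records) {
  if (!length(records)) return(data.frame(stringsAsFactors = FALSE))
  allNames <- unique(unlist(lapply(records, names)))
  cols <- lapply(allNames, function(nm)
    vapply(records, function(r)
      if (!is.null(r[[nm]])) r[[nm]] else NA_character_, ""))
  stats::setNames(as.data.frame(cols, stringsAsFactors = FALSE), allNames)
}

#' Import an RNAi library from a workbook
#'
#' The first sheet must carry columns `Plate`, `Well`, `Well_Type`,
#' `Vendor`, `Vendor_ID`, `Silencing_Type`, `Entrez_Gene_ID`,
#' `Gene_Symbol`, `GenBank`, `Species`, `Sequence` and `Duplex_Wells`
#' (semicolon-joined `plate:well` tokens, pool reagents only). Pool rows
#' must name their duplex wells; duplex rows must not.
#'
#' @param workbook path to a workbook file (plain-text format or `.xlsx`),
#'   or a named list of sheets as returned by [readWorkbook()].
#' @param duplexLibraries optional list of [ScreenLibrary] objects against
#'   which every pool's duplex well keys are resolved (pool-integrity
#'   check at import time).
#' @inheritParams importSmallMoleculeLibrary
#' @return a [ScreenLibrary].
#' @export
importRnaiLibrary <- function(workbook, shortName, plateFormat = 384,
                              startPlate = 1, endPlate = startPlate,
                              fieldMap = NULL, duplexLibraries = NULL) {
  sheets <- if (is.character(workbook)) readWorkbook(workbook) else workbook
  if (!length(sheets)) stop("workbook has no sheets", call. = FALSE)
  lib <- newScreenLibrary(shortName, "rnai", plateFormat, startPlate,
                          endPlate)
  lib <- .fillWellTable(lib, .mapImportColumns(sheets[[1L]], fieldMap))
  if (!is.null(duplexLibraries)) checkPoolIntegrity(lib, duplexLibraries)
  lib
}

#' Check that every pool reagent's duplex wells resolve
#'
#' @param library a pooled RNAi [ScreenLibrary].
#' @param duplexLibraries list of candidate duplex [ScreenLibrary] objects.
#' @return invisibly `TRUE`; errors on the first unresolvable duplex key.
#' @export
checkPoolIntegrity <- function(library, duplexLibraries) {
  stopifnot(is(library, "ScreenLibrary"), library@screenType == "rnai")
  if (is(duplexLibraries, "ScreenLibrary"))
    duplexLibraries <- list(duplexLibraries)
  w <- library@wells
  pools <- which(!is.na(w$silencing_type) & w$silencing_type == "pool")
  for (i in pools) {
    keys <- strsplit(w$duplex_wells[i], ";", fixed = TRUE)[[1L]]
    for (k in trimws(keys)) {
      found <- FALSE
      for (dl in duplexLibraries) {
        j <- .wellRows(dl, k)
        if (!is.na(j) && !is.na(dl@wells$silencing_type[j]) &&
            dl@wells$silencing_type[j] == "duplex") { found <- TRUE; break }
      }
      if (!found)
        stop("pool well ", wellKey(w$plate[i], w$well[i]),
             ": duplex well ", k, " not found in any duplex library",
             call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Import a new contents version of an existing library
#'
#' Parses the stream with the importer matching the library's reagent
#' class, increments the version and retains the previous well table in
#' `supersededVersions`, unmodified, for auditing. Volume ledgers of the
#' library's copies are untouched. The plate range must be unchanged.
#'
#' @param library the current [ScreenLibrary].
#' @param stream an SD file (small molecule) or workbook (RNAi), as
#'   accepted by the class importer.
#' @param fieldMap see [importSmallMoleculeLibrary()].
#' @return the updated [ScreenLibrary] (version incremented).
#' @export
importContentsVersion <- function(library, stream, fieldMap = NULL) {
  stopifnot(is(library, "ScreenLibrary"))
  fresh <- if (library@screenType == "small_molecule")
    importSmallMoleculeLibrary(stream, library@shortName,
                               library@plateFormat, library@startPlate,
                               library@endPlate, fieldMap)
  else
    importRnaiLibrary(stream, library@shortName, library@plateFormat,
                      library@startPlate, library@endPlate, fieldMap)
  prior <- library@wells
  library@supersededVersions <- c(library@supersededVersions, list(prior))
  library@wells <- fresh@wells
  library@version <- library@version + 1L
  validObject(library)
  library
}

#' Batch search for wells by plate/well designation or vendor reagent id
#'
#' Each query token is either a `"plate:well"` designation or a vendor
#' reagent id (which may match wells in several libraries — a given
#' reagent may exist in multiple libraries). Matches are returned in
#' input order with duplicates removed; unmatched tokens are reported
#' alongside the results, not raised as errors.
#'
#' @param libraries a [ScreenLibrary] or list of them.
#' @param query character vector of tokens.
#' @return list with `wells` (data.frame with a `library` column) and
#'   `unmatched` (character vector of tokens).
#' @export
batchWellSearch <- function(libraries, query) {
  if (is(libraries, "ScreenLibrary")) libraries <- list(libraries)
  out <- list(); unmatched <- character()
  for (tok in trimws(as.character(query))) {
    hits <- list()
    if (grepl(":", tok, fixed = TRUE)) {
      for (lib in libraries) {
        key <- tryCatch(
          do.call(wellKey, splitWellKey(tok, lib@plateFormat)),
          error = function(e) NA_character_)
        if (is.na(key)) next
        i <- .wellRows(lib, key)
        if (!is.na(i))
          hits <- c(hits, list(cbind(library = lib@shortName,
                                     lib@wells[i, , drop = FALSE])))
      }
    } else {
      for (lib in libraries) {
        i <- which(!is.na(lib@wells$vendor_id) & lib@wells$vendor_id == tok)
        if (length(i))
          hits <- c(hits, list(cbind(library = lib@shortName,
                                     lib@wells[i, , drop = FALSE])))
      }
    }
    if (length(hits)) out <- c(out, hits) else unmatched <- c(unmatched, tok)
  }
  wells <- if (length(out)) {
    common <- Reduce(intersect, lapply(out, names))
    res <- do.call(rbind, lapply(out, function(df) df[, common, drop = FALSE]))
    res[!duplicated(wellKey(paste(res$library, res$plate, sep = "/"),
                            res$well)), , drop = FALSE]
  } else data.frame(stringsAsFactors = FALSE)
  rownames(wells) <- NULL
  list(wells = wells, unmatched = unmatched)
}

#' Export library wells as an SD file or workbook
#'
#' Exports the filled (non-empty) wells of a library — or an explicit
#' subset — such that re-importing the exported stream reproduces the
#' well/reagent content exactly. SDF export is only available for
#' small-molecule libraries.
#'
#' @param library a [ScreenLibrary].
#' @param fmt `"sdf"` or `"workbook"`.
#' @param path output file path; when `NULL` the lines are returned.
#' @param keys optional `"plate:well"` keys restricting the export.
#' @param columns optional subset of reagent column names to include
#'   (plate/well/well type are always written).
#' @return invisibly, the written lines.
#' @export
exportWells <- function(library, fmt = c("workbook", "sdf"), path = NULL,
                        keys = NULL, columns = NULL) {
  stopifnot(is(library, "ScreenLibrary"))
  fmt <- match.arg(fmt)
  if (fmt == "sdf" && library@screenType != "small_molecule")
    stop("SD file export is unsupported for RNAi libraries", call. = FALSE)
  w <- library@wells
  rows <- if (is.null(keys)) which(w$well_type != "empty")
          else { i <- .wellRows(library, keys)
                 if (anyNA(i)) stop("unknown well key: ",
                                    keys[is.na(i)][1L], call. = FALSE)
                 i }
  schema <- wellTableSchema(library@screenType)
  cols <- setdiff(names(schema), c("plate", "well", "well_type",
                                   "deprecated", "deprecation_reason"))
  if (!is.null(columns)) cols <- intersect(cols, columns)
  fm <- .resolveFieldMap(NULL)
  sub <- w[rows, , drop = FALSE]
  if (fmt == "sdf") {
    records <- lapply(seq_len(nrow(sub)), function(i) {
      vals <- c(list(sub$plate[i], sub$well[i], sub$well_type[i]),
                as.list(sub[i, cols]))
      names(vals) <- fm[c("plate", "well", "well_type", cols)]
      vals <- vals[!vapply(vals, function(v) is.na(v[[1L]]), TRUE)]
      lapply(vals, as.character)
    })
    invisible(writeSdf(records, path))
  } else {
    out <- data.frame(sub$plate, sub$well, sub$well_type,
                      stringsAsFactors = FALSE)
    names(out) <- fm[c("plate", "well", "well_type")]
    for (cc in cols) out[[fm[[cc]]]] <- sub[[cc]]
    sheets <- list(Library = out)
    if (is.null(path)) return(invisible(sheets))
    invisible(writeWorkbook(sheets, path))
  }
}

#' Re-import an exported library stream
#'
#' Convenience dispatcher used in round-trip checks: imports `stream`
#' (SDF lines/path or workbook path/sheets) using the importer for
#' `screenType` with the same declared geometry.
#'
#' @inheritParams importSmallMoleculeLibrary
#' @param stream exported stream.
#' @param screenType reagent class of the stream.
#' @export
importLibrary <- function(stream, screenType, shortName, plateFormat = 384,
                          startPlate = 1, endPlate = startPlate,
                          fieldMap = NULL) {
  if (screenType == "small_molecule")
    importSmallMoleculeLibrary(stream, shortName, plateFormat, startPlate,
                               endPlate, fieldMap)
  else importRnaiLibrary(stream, shortName, plateFormat, startPlate,
                         endPlate, fieldMap)
}
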