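DATA_COLUMN_KINDS <- c("numeric", "text", "boolean", "partitioned")
POSITIVE_INDICATORS <- c("none", "boolean", "partition", "threshold")

# parse the "Data Headers" sheet into the typed columns table
.parseDataHeaders <- function(sheet) {
  need <- c("Name", "Kind")
  if (!all(need %in% names(sheet)))
    stop("Data Headers sheet must carry Name and Kind columns",
         call. = FALSE)
  get <- function(col) if (col %in% names(sheet)) .trimOrNA(sheet[[col]])
                       else rep(NA_character_, nrow(sheet))
  cols <- data.frame(
    name = .trimOrNA(sheet$Name),
    kind = tolower(.trimOrNA(sheet$Kind)),
    replicate = suppressWarnings(as.integer(get("Replicate"))),
    time_point = get("Time_Point"),
    readout_technology = get("Readout_Technology"),
    derived = toupper(get("Derived")) %in% c("TRUE", "YES", "1"),
    derived_from = get("Derived_From"),
    positive_indicator = tolower(get("Positive_Indicator")),
    cutoff = suppressWarnings(as.numeric(get("Cutoff"))),
    direction = tolower(get("Direction")),
    description = get("Description"),
    stringsAsFactors = FALSE)
  cols$positive_indicator[is.na(cols$positive_indicator)] <- "none"
  if (anyNA(cols$name) || anyDuplicated(cols$name))
    stop("data column names must be present and unique", call. = FALSE)
  bad <- !cols$kind %in% DATA_COLUMN_KINDS
  if (any(bad))
    stop("data column '", cols$name[bad][1L], "': invalid kind '",
         cols$kind[bad][1L], "'", call. = FALSE)
  bad <- !cols$positive_indicator %in% POSITIVE_INDICATORS
  if (any(bad))
    stop("data column '", cols$name[bad][1L],
         "': invalid positive indicator", call. = FALSE)
  for (i in seq_len(nrow(cols))) {
    if (cols$derived[i]) {
      refs <- trimws(strsplit(
        if (is.na(cols$derived_from[i])) "" else cols$derived_from[i],
        ";", fixed = TRUE)[[1L]])
      refs <- refs[nzchar(refs)]
      if (!length(refs))
        stop("derived column '", cols$name[i],
             "' must reference at least one earlier column", call. = FALSE)
      pos <- match(refs, cols$name)
      if (anyNA(pos))
        stop("derived column '", cols$name[i],
             "' references unknown column '", refs[is.na(pos)][1L], "'",
             call. = FALSE)
      if (any(pos >= i))
        stop("derived column '", cols$name[i],
             "' may only reference earlier columns (cycle or forward ",
             "reference via '", refs[pos >= i][1L], "')", call. = FALSE)
    }
    pi <- cols$positive_indicator[i]
    if (pi == "partition" && cols$kind[i] != "partitioned")
      stop("column '", cols$name[i],
           "': partition indicator requires partitioned values",
           call. = FALSE)
    if (pi == "boolean" && cols$kind[i] != "boolean")
      stop("column '", cols$name[i],
           "': boolean indicator requires boolean values", call. = FALSE)
    if (pi == "threshold") {
      if (cols$kind[i] != "numeric")
        stop("column '", cols$name[i],
             "': threshold indicator requires numeric values",
             call. = FALSE)
      if (is.na(cols$cutoff[i]) ||
          !cols$direction[i] %in% c("above", "below"))
        stop("column '", cols$name[i],
             "': threshold indicator requires a cutoff and a direction ",
             "(above/below)", call. = FALSE)
    }
  }
  cols
}

.typeResultColumn <- function(v, kind, sheet, colName) {
  raw <- .trimOrNA(v)
  filled <- which(!is.na(raw))
  switch(kind,
    numeric = {
      out <- suppressWarnings(as.numeric(raw))
      bad <- filled[is.na(out[filled])]
      if (length(bad))
        stop("sheet '", sheet, "' row ", bad[1L], " column '", colName,
             "': '", raw[bad[1L]], "' is not numeric", call. = FALSE)
      out
    },
    text = raw,
    boolean = {
      up <- toupper(raw)
      out <- rep(NA, length(raw))
      out[up %in% c("TRUE", "T", "1", "YES")] <- TRUE
      out[up %in% c("FALSE", "F", "0", "NO")] <- FALSE
      bad <- filled[is.na(out[filled])]
      if (length(bad))
        stop("sheet '", sheet, "' row ", bad[1L], " column '", colName,
             "': '", raw[bad[1L]], "' is not boolean", call. = FALSE)
      as.logical(out)
    },
    partitioned = {
      low <- tolower(raw)
      bad <- filled[!low[filled] %in% PARTITION_VALUES]
      if (length(bad))
        stop("sheet '", sheet, "' row ", bad[1L], " column '", colName,
             "': '", raw[bad[1L]],
             "' is not a partition value (strong/medium/weak/none)",
             call. = FALSE)
      low
    })
}

#' Import a screen result workbook into a screen
#'
#' The workbook must carry a `Data Headers` sheet (one row per data
#' column: name, value kind, replicate ordinal, time point, readout
#' technology, derived flag, semicolon-joined derived-from references and
#' the positives-indicator spec) and one or more data sheets with `Plate`,
#' `Well`, `Assay_Well_Type` and then one column per data header. Derived
#' column values are imported, not computed — analysis happens in external
#' software; only the derivation graph is validated (derived columns may
#' reference earlier columns only). Re-importing replaces all values and
#' updates the last-updated date while preserving the created date.
#'
#' @param screen a [Screen].
#' @param workbook path to a workbook (plain-text format or `.xlsx`) or a
#'   named list of sheets.
#' @param libraries list of [ScreenLibrary] objects the screen tested;
#'   every data row's well must exist in one of them.
#' @param date import date.
#' @return the updated [Screen] carrying a [ScreenResult].
#' @export
importScreenResult <- function(screen, workbook, libraries,
                               date = Sys.Date()) {
  stopifnot(is(screen, "Screen"))
  if (is(libraries, "ScreenLibrary")) libraries <- list(libraries)
  sheets <- if (is.character(workbook)) readWorkbook(workbook) else workbook
  if (!"Data Headers" %in% names(sheets))
    stop("workbook lacks a 'Data Headers' sheet", call. = FALSE)
  cols <- .parseDataHeaders(sheets[["Data Headers"]])
  dataSheets <- sheets[setdiff(names(sheets), "Data Headers")]
  if (!length(dataSheets))
    stop("workbook has no data sheets", call. = FALSE)

  fmt <- libraries[[1L]]@plateFormat
  parts <- lapply(names(dataSheets), function(sn) {
    sh <- dataSheets[[sn]]
    need <- c("Plate", "Well", "Assay_Well_Type", cols$name)
    if (!all(need %in% names(sh)))
      stop("data sheet '", sn, "' lacks columns: ",
           paste(setdiff(need, names(sh)), collapse = ", "), call. = FALSE)
    plate <- suppressWarnings(as.integer(.trimOrNA(sh$Plate)))
    if (anyNA(plate))
      stop("sheet '", sn, "' row ", which(is.na(plate))[1L],
           ": missing or non-numeric plate", call. = FALSE)
    co <- parseWellName(.trimOrNA(sh$Well), fmt)
    wellN <- formatWellName(co[, "row"], co[, "col"], fmt)
    awt <- tolower(.trimOrNA(sh$Assay_Well_Type))
    if (any(!awt %in% WELL_TYPES))
      stop("sheet '", sn, "' row ", which(!awt %in% WELL_TYPES)[1L],
           ": invalid assay well type", call. = FALSE)
    out <- data.frame(plate = plate, well = wellN, assay_well_type = awt,
                      stringsAsFactors = FALSE)
    for (i in seq_len(nrow(cols)))
      out[[cols$name[i]]] <- .typeResultColumn(sh[[cols$name[i]]],
                                               cols$kind[i], sn,
                                               cols$name[i])
    out
  })
  values <- do.call(rbind, parts)
  keys <- wellKey(values$plate, values$well)
  if (anyDuplicated(keys))
    stop("duplicate assay well across data sheets: ",
         keys[duplicated(keys)][1L], call. = FALSE)

  # validate wells against the screened libraries; pick up vendor ids
  relevant <- libraries
  if (length(screen@libraryNames)) {
    named <- vapply(libraries, shortName, "")
    sel <- named %in% screen@libraryNames
    if (any(sel)) relevant <- libraries[sel]
  }
  vendor <- rep(NA_character_, nrow(values))
  found <- rep(FALSE, nrow(values))
  for (lib in relevant) {
    i <- .wellRows(lib, keys)
    hit <- !is.na(i)
    vendor[hit & !found] <- lib@wells$vendor_id[i[hit & !found]]
    found <- found | hit
  }
  if (any(!found))
    stop("assay well ", keys[!found][1L],
         " is unknown to the screened libraries", call. = FALSE)
  values$vendor_id <- vendor
  values <- values[, c("plate", "well", "assay_well_type", "vendor_id",
                       cols$name)]

  created <- if (!is.null(screen@screenResult))
    screen@screenResult@dateCreated else as.Date(date)
  screen@screenResult <- new("ScreenResult", columns = cols,
                             values = values, plateFormat = fmt,
                             dateCreated = created,
                             dateUpdated = as.Date(date))
  validObject(screen)
  screen
}

.posColumn <- function(sr, column) {
  i <- match(column, sr@columns$name)
  if (is.na(i)) stop("unknown data column: ", column, call. = FALSE)
  if (sr@columns$positive_indicator[i] == "none")
    stop("column '", column, "' has no positive indicator", call. = FALSE)
  i
}

#' Classify positives for one data column
#'
#' Positives ("hits") are computed over experimental assay wells only:
#' boolean columns use the value itself; partitioned columns call any
#' non-`none` partition (strong/medium/weak) a positive; threshold columns
#' call values strictly exceeding the cutoff in the stated direction
#' (above or, for inhibition readouts, below).
#'
#' @param screenResult a [ScreenResult] (or a [Screen] carrying one).
#' @param column name of a positives column.
#' @return named logical vector keyed by `"plate:well"`, over experimental
#'   wells that carry a value in the column.
#' @export
classifyPositives <- function(screenResult, column) {
  sr <- if (is(screenResult, "Screen")) screenResult@screenResult
        else screenResult
  stopifnot(is(sr, "ScreenResult"))
  i <- .posColumn(sr, column)
  v <- sr@values
  vals <- v[[column]]
  keep <- which(v$assay_well_type == "experimental" & !is.na(vals))
  if (!length(keep))
    return(stats::setNames(logical(), character()))
  vals <- vals[keep]
  pos <- switch(sr@columns$positive_indicator[i],
    boolean = as.logical(vals),
    partition = vals != "none",
    threshold = if (sr@columns$direction[i] == "above")
                  vals > sr@columns$cutoff[i]
                else vals < sr@columns$cutoff[i])
  stats::setNames(pos, wellKey(v$plate[keep], v$well[keep]))
}

#' Count and percentage of positives in a column
#'
#' The percentage is taken over the experimental wells that carry a value
#' in this column (`100 * count / n_experimental`).
#'
#' @inheritParams classifyPositives
#' @return list with `count` and `percent`.
#' @export
positivesSummary <- function(screenResult, column) {
  pos <- classifyPositives(screenResult, column)
  if (!length(pos))
    stop("no experimental wells carry a value in column '", column,
         "'; percentage undefined", call. = FALSE)
  list(count = sum(pos), percent = 100 * sum(pos) / length(pos))
}

#' Per-plate heat-map matrix for a numeric data column
#'
#' Returns the plate's values laid out as an `n_rows x n_cols` matrix
#' (dimnames are row letters and column numbers); wells without a value
#' are `NA`. Callers wanting to compare alternate normalisations side by
#' side simply request several columns. Rendering is left to the caller
#' (e.g. `pheatmap` or `image()`).
#'
#' @inheritParams classifyPositives
#' @param plateNumber plate to lay out (must have been screened).
#' @return numeric matrix of the library's plate format.
#' @export
plateHeatmap <- function(screenResult, plateNumber, column) {
  sr <- if (is(screenResult, "Screen")) screenResult@screenResult
        else screenResult
  stopifnot(is(sr, "ScreenResult"))
  i <- match(column, sr@columns$name)
  if (is.na(i)) stop("unknown data column: ", column, call. = FALSE)
  if (sr@columns$kind[i] != "numeric")
    stop("heat maps require a numeric column; '", column, "' is ",
         sr@columns$kind[i], call. = FALSE)
  v <- sr@values[sr@values$plate == as.integer(plateNumber), , drop = FALSE]
  if (!nrow(v))
    stop("plate ", plateNumber, " was not screened", call. = FALSE)
  dims <- plateDims(sr@plateFormat)
  m <- matrix(NA_real_, dims[["rows"]], dims[["cols"]],
              dimnames = list(plateRowLabels(sr@plateFormat),
                              seq_len(dims[["cols"]])))
  co <- parseWellName(v$well, sr@plateFormat)
  m[cbind(co[, "row"] + 1L, co[, "col"] + 1L)] <- v[[column]]
  m
}
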