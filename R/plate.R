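#' Microplate formats and well coordinates
#'
#' Screening microplates come in 96-, 384- and 1536-well formats (8 x 12,
#' 16 x 24 and 32 x 48). Rows are labelled A..H, A..P and A..AF
#' respectively (after Z the labels continue AA..AF); columns are numbered
#' from 1. Internally all coordinates are 0-based; user-facing well names
#' use the letter + zero-padded 1-based column convention ("A01").
#'
#' @param format wells per plate: one of 96, 384, 1536.
#' @return `plateDims()` returns `c(rows, cols)`; `plateRowLabels()` the
#'   ordered row labels for the format.
#' @examples
#' plateDims(384)
#' plateRowLabels(96)
#' @export
plateDims <- function(format) {
  format <- as.integer(format)
  if (length(format) != 1L || is.na(format) || !format %in% c(96L, 384L, 1536L))
    stop("unsupported plate format: ", format,
         " (must be one of 96, 384, 1536)", call. = FALSE)
  switch(as.character(format),
         "96"   = c(rows = 8L,  cols = 12L),
         "384"  = c(rows = 16L, cols = 24L),
         "1536" = c(rows = 32L, cols = 48L))
}

# row labels A..Z then AA, AB, ... (32 rows for 1536)
.rowLabels <- function(n) {
  base <- LETTERS
  if (n <= 26L) return(base[seq_len(n)])
  extra <- paste0("A", LETTERS[seq_len(n - 26L)])
  c(base, extra)
}

#' @rdname plateDims
#' @export
plateRowLabels <- function(format) {
  .rowLabels(plateDims(format)[["rows"]])
}

#' Parse a well name into a 0-based (row, col) coordinate
#'
#' Accepts both the zero-padded ("A01") and unpadded ("A1") dialects,
#' case-insensitively. Vectorised over `name`.
#'
#' @param name character vector of well names.
#' @param format plate format (96/384/1536) governing the valid range.
#' @return integer matrix with columns `row` and `col`, 0-based.
#' @examples
#' parseWellName("A01", 384)
#' parseWellName(c("P24", "b3"), 384)
#' @export
parseWellName <- function(name, format) {
  dims <- plateDims(format)
  name <- toupper(trimws(as.character(name)))
  m <- regmatches(name, regexec("^([A-Z]{1,2})0*([0-9]{1,2})$", name))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad))
    stop("malformed well name: '", name[which(bad)[1L]], "'", call. = FALSE)
  letters_part <- vapply(m, `[`, "", 2L)
  col1 <- as.integer(vapply(m, `[`, "", 3L))
  labels <- .rowLabels(dims[["rows"]])
  row0 <- match(letters_part, labels) - 1L
  if (anyNA(row0))
    stop("row label out of range for ", format, "-well format: '",
         letters_part[which(is.na(row0))[1L]], "'", call. = FALSE)
  if (any(col1 < 1L | col1 > dims[["cols"]]))
    stop("column out of range for ", format, "-well format: '",
         col1[which(col1 < 1L | col1 > dims[["cols"]])[1L]], "'",
         call. = FALSE)
  cbind(row = row0, col = col1 - 1L)
}

#' Format a 0-based (row, col) coordinate as a canonical well name
#'
#' The inverse of [parseWellName()]; columns are zero-padded to two digits.
#' Vectorised over `row`/`col`.
#'
#' @param row,col 0-based integer coordinates.
#' @param format plate format (96/384/1536).
#' @return character vector of canonical well names ("A01", "AF48", ...).
#' @examples
#' formatWellName(15, 23, 384)
#' @export
formatWellName <- function(row, col, format) {
  dims <- plateDims(format)
  row <- as.integer(row); col <- as.integer(col)
  if (anyNA(row) || anyNA(col) ||
      any(row < 0L | row >= dims[["rows"]]) ||
      any(col < 0L | col >= dims[["cols"]]))
    stop("coordinate out of range for ", format, "-well format", call. = FALSE)
  paste0(.rowLabels(dims[["rows"]])[row + 1L],
         formatC(col + 1L, width = 2L, flag = "0"))
}

#' Well names of a plate in row-major order
#'
#' @param format plate format (96/384/1536).
#' @return character vector of length `format`: "A01", "A02", ..., row by row.
#' @export
wellNamesRowMajor <- function(format) {
  dims <- plateDims(format)
  rows <- rep(seq_len(dims[["rows"]]) - 1L, each = dims[["cols"]])
  cols <- rep(seq_len(dims[["cols"]]) - 1L, times = dims[["rows"]])
  formatWellName(rows, cols, format)
}

#' Enumerate the well keys of a plate in row-major order
#'
#' A well key is the canonical `"plate:well"` string ("7:B01") that
#' identifies a library well across plates.
#'
#' @param plateNumber positive integer plate number.
#' @param format plate format (96/384/1536).
#' @return character vector of `format` well keys, row-major.
#' @examples
#' wellsInRowMajor(7, 384)[25]  # "7:B01"
#' @export
wellsInRowMajor <- function(plateNumber, format) {
  plateNumber <- as.integer(plateNumber)
  if (length(plateNumber) != 1L || is.na(plateNumber) || plateNumber < 1L)
    stop("plateNumber must be a positive integer", call. = FALSE)
  paste0(plateNumber, ":", wellNamesRowMajor(format))
}

# -- well-key helpers (internal) ---------------------------------------------

wellKey <- function(plate, well) paste0(plate, ":", well)

# split "plate:well" keys; returns data.frame(plate, well) with canonical names
splitWellKey <- function(keys, format = 384L) {
  keys <- trimws(as.character(keys))
  parts <- strsplit(keys, ":", fixed = TRUE)
  ok <- vapply(parts, length, 1L) == 2L
  if (any(!ok))
    stop("malformed well key (expected 'plate:well'): '",
         keys[which(!ok)[1L]], "'", call. = FALSE)
  plate <- suppressWarnings(as.integer(vapply(parts, `[`, "", 1L)))
  if (anyNA(plate))
    stop("malformed plate number in well key: '",
         keys[which(is.na(plate))[1L]], "'", call. = FALSE)
  wn <- vapply(parts, `[`, "", 2L)
  co <- parseWellName(wn, format)
  data.frame(plate = plate,
             well = formatWellName(co[, "row"], co[, "col"], format),
             stringsAsFactors = FALSE)
}

# row-major index (0-based) of canonical well names, for ordering
rowMajorIndex <- function(well, format) {
  co <- parseWellName(well, format)
  co[, "row"] * plateDims(format)[["cols"]] + co[, "col"]
}

# microliter <-> integer nanoliter conversion: ledgers are exact in nL
ulToNl <- function(ul) {
  nl <- round(ul * 1000)
  if (any(abs(nl) >= .Machine$integer.max))
    stop("volume out of range", call. = FALSE)
  as.integer(nl)
}

nlToUl <- function(nl) nl / 1000
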