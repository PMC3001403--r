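#' Read and write multi-sheet workbooks
#'
#' Spreadsheet-style inputs (RNAi library contents, screen results, study
#' annotations) travel as multi-sheet workbooks. The native interchange
#' format is a plain-text one — tab-separated sheets introduced by
#' `#%sheet <name>` marker lines, with a `#%workbook` first line — so that
#' fixtures are diffable and byte-reproducible. Files ending in `.xlsx`
#' are also accepted on read when the readxl package is available.
#'
#' @param path file to read or write.
#' @param sheets named list of data.frames (all cells written as text).
#' @return `readWorkbook()` returns a named list of character
#'   data.frames; typing is applied downstream by the importers.
#' @export
readWorkbook <- function(path) {
  if (grepl("\\.xlsx$", path, ignore.case = TRUE)) {
    if (!requireNamespace("readxl", quietly = TRUE))
      stop("reading .xlsx workbooks requires the readxl package",
           call. = FALSE)
    nms <- readxl::excel_sheets(path)
    sheets <- lapply(nms, function(s) {
      df <- as.data.frame(readxl::read_excel(path, sheet = s,
                                             col_types = "text"),
                          stringsAsFactors = FALSE)
      df[] <- lapply(df, as.character)
      df
    })
    return(stats::setNames(sheets, nms))
  }
  if (!file.exists(path))
    stop("no such workbook file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !startsWith(lines[1L], "#%workbook"))
    stop("not a workbook file (missing '#%workbook' header): ", path,
         call. = FALSE)
  marks <- grep("^#%sheet\\s", lines)
  if (!length(marks)) return(list())
  nms <- sub("^#%sheet\\s+", "", lines[marks])
  ends <- c(marks[-1L] - 1L, length(lines))
  sheets <- lapply(seq_along(marks), function(i) {
    body <- lines[(marks[i] + 1L):ends[i]]
    body <- body[nzchar(body)]
    if (!length(body))
      return(data.frame(stringsAsFactors = FALSE))
    cells <- strsplit(body, "\t", fixed = TRUE)
    header <- cells[[1L]]
    rows <- cells[-1L]
    cols <- lapply(seq_along(header), function(j)
      vapply(rows, function(r) if (j <= length(r)) r[[j]] else "", ""))
    df <- stats::setNames(as.data.frame(cols, stringsAsFactors = FALSE),
                          header)
    df[] <- lapply(df, function(v) ifelse(v == "", NA_character_, v))
    df
  })
  stats::setNames(sheets, nms)
}

#' @rdname readWorkbook
#' @export
writeWorkbook <- function(sheets, path) {
  stopifnot(is.list(sheets), !is.null(names(sheets)))
  fmtCell <- function(v) {
    out <- if (is.numeric(v)) {
      vapply(v, function(x) if (is.na(x)) "" else format(x, digits = 15,
                                                         scientific = FALSE,
                                                         trim = TRUE), "")
    } else {
      v <- as.character(v)
      ifelse(is.na(v), "", v)
    }
    if (any(grepl("\t", out, fixed = TRUE)))
      stop("workbook cells must not contain tab characters", call. = FALSE)
    out
  }
  lines <- "#%workbook"
  for (nm in names(sheets)) {
    df <- sheets[[nm]]
    lines <- c(lines, paste("#%sheet", nm),
               paste(names(df), collapse = "\t"))
    if (nrow(df)) {
      cols <- lapply(df, fmtCell)
      lines <- c(lines, do.call(paste, c(cols, sep = "\t")))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
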