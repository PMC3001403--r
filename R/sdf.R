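# Minimal MDL SD file (SDF) reader/writer for library contents.
#
# Only the associated-data blocks are interpreted; V2000 molblocks are
# tolerated and ignored on read (structures travel as SMILES/InChI data
# fields). Records are separated by "$$$$".

# read an SD file into a data.frame of data fields (one row per record);
# `x` is a file path or a character vector of lines
readSdf <- function(x) {
  lines <- if (length(x) == 1L && file.exists(x)) readLines(x, warn = FALSE)
           else x
  # drop trailing blank lines, split on record terminators
  term <- which(trimws(lines) == "$$$$")
  if (!length(term)) {
    if (!any(nzchar(trimws(lines))))
      return(list(records = list()))
    stop("unparsable SD file: no '$$$$' record terminator", call. = FALSE)
  }
  starts <- c(1L, head(term, -1L) + 1L)
  records <- Map(function(s, e) lines[s:(e - 1L)], starts, term)
  fields <- lapply(seq_along(records), function(i) {
    rec <- records[[i]]
    tagIdx <- grep("^>\\s*<", rec)
    if (!length(tagIdx))
      stop("unparsable SD record ", i, ": no data fields", call. = FALSE)
    names <- sub("^>\\s*<([^>]+)>.*$", "\\1", rec[tagIdx])
    ends <- c(tagIdx[-1L] - 1L, length(rec))
    vals <- vapply(seq_along(tagIdx), function(j) {
      body <- rec[(tagIdx[j] + 1L):ends[j]]
      body <- body[cumsum(!nzchar(trimws(body))) == 0L]  # up to blank line
      paste(body, collapse = "\n")
    }, "")
    stats::setNames(as.list(vals), names)
  })
  list(records = fields)
}

# a placeholder no-structure V2000 molblock (three header lines, counts, end)
.emptyMolblock <- function(title = "") {
  c(title, "  screenkit", "",
    "  0  0  0  0  0  0  0  0  0  0999 V2000", "M  END")
}

# write records (list of named lists/char vectors) as an SD file; returns
# the lines invisibly, writing to `path` when given
writeSdf <- function(records, path = NULL) {
  lines <- unlist(lapply(records, function(rec) {
    fields <- unlist(lapply(names(rec), function(nm) {
      c(paste0("> <", nm, ">"), as.character(rec[[nm]]), "")
    }))
    c(.emptyMolblock(), fields, "$$$$")
  }), use.names = FALSE)
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}
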