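#' Merge screen results and studies into one comparison table
#'
#' Cross-screen comparison: rows are keyed by well (`"plate:well"`,
#' requires shared library plate numbering) or by reagent (vendor id), and
#' every key present in any source appears (outer join) — positives absent
#' from one screen remain visible, with empty (`NA`) cells, never zeros.
#' Columns carry provenance as `<source id>.<column name>`. Study
#' annotation columns always join by reagent, whatever the key mode.
#'
#' @param sources named list of [ScreenResult], [Screen] (carrying a
#'   result) and/or [Study] objects; names become the provenance prefix.
#' @param keyMode `"well"` or `"reagent"`.
#' @return data.frame with a `key` column plus one column per source data
#'   column.
#' @export
mergeComparisonTable <- function(sources, keyMode = c("well", "reagent")) {
  keyMode <- match.arg(keyMode)
  stopifnot(is.list(sources), !is.null(names(sources)),
            all(nzchar(names(sources))))
  sources <- lapply(sources, function(s)
    if (is(s, "Screen")) {
      if (is.null(s@screenResult))
        stop("screen ", s@facilityId, " has no screen result",
             call. = FALSE)
      s@screenResult
    } else s)

  isStudy <- vapply(sources, is, TRUE, "Study")
  screenFrames <- lapply(names(sources)[!isStudy], function(id) {
    sr <- sources[[id]]
    stopifnot(is(sr, "ScreenResult"))
    v <- sr@values
    key <- if (keyMode == "well") wellKey(v$plate, v$well) else v$vendor_id
    df <- v[, sr@columns$name, drop = FALSE]
    names(df) <- paste(id, names(df), sep = ".")
    df <- cbind(key = key, df, stringsAsFactors = FALSE)
    df <- df[!is.na(df$key), , drop = FALSE]
    # one row per key: keep the first occurrence (reagent mode may see a
    # reagent plated in several wells)
    df[!duplicated(df$key), , drop = FALSE]
  })

  # well mode needs a well -> reagent map to append study annotations
  vendorMap <- if (keyMode == "well" && any(isStudy)) {
    maps <- lapply(sources[!isStudy], function(sr) {
      v <- sr@values
      data.frame(key = wellKey(v$plate, v$well), vendor_id = v$vendor_id,
                 stringsAsFactors = FALSE)
    })
    mm <- do.call(rbind, maps)
    mm[!duplicated(mm$key), , drop = FALSE]
  } else NULL

  studyFrames <- lapply(names(sources)[isStudy], function(id) {
    st <- sources[[id]]
    df <- st@values
    ann <- setdiff(names(df), "vendor_id")
    out <- df[, ann, drop = FALSE]
    names(out) <- paste(id, names(out), sep = ".")
    if (keyMode == "reagent")
      cbind(key = df$vendor_id, out, stringsAsFactors = FALSE)
    else {
      # join annotations onto the wells that hold each reagent; reagents
      # not screened by any source contribute no rows in well mode
      i <- match(vendorMap$vendor_id, df$vendor_id)
      hit <- !is.na(i)
      cbind(key = vendorMap$key[hit],
            out[i[hit], , drop = FALSE], stringsAsFactors = FALSE)
    }
  })

  frames <- c(screenFrames, studyFrames)
  frames <- frames[vapply(frames, nrow, 1L) > 0L | !lengths(frames)]
  if (!length(frames)) return(data.frame(key = character(),
                                         stringsAsFactors = FALSE))
  merged <- Reduce(function(a, b) merge(a, b, by = "key", all = TRUE,
                                        sort = TRUE), frames)
  rownames(merged) <- NULL
  merged
}

#' Filter a comparison (or any) table by conjunctive criteria
#'
#' Operators: `eq`, `lt`, `le`, `gt`, `ge`, `between` (operand of length
#' 2, inclusive) and `contains` (case-insensitive substring, text columns
#' only). Ranking operators require numeric columns. Empty (`NA`) cells
#' never satisfy any criterion; row order is preserved.
#'
#' @param table a data.frame.
#' @param criteria list of criteria, each a list/vector with elements
#'   `column`, `op`, `operand`.
#' @return the filtered data.frame.
#' @export
filterTable <- function(table, criteria) {
  stopifnot(is.data.frame(table))
  keep <- rep(TRUE, nrow(table))
  for (cr in criteria) {
    col <- cr[["column"]]
    op <- cr[["op"]]
    operand <- cr[["operand"]]
    if (is.null(col) || !col %in% names(table))
      stop("unknown filter column: ", col, call. = FALSE)
    v <- table[[col]]
    if (op %in% c("lt", "le", "gt", "ge", "between") && !is.numeric(v))
      stop("operator '", op, "' requires a numeric column ('", col,
           "' is not)", call. = FALSE)
    if (op == "contains" && !is.character(v))
      stop("operator 'contains' requires a text column ('", col,
           "' is not)", call. = FALSE)
    m <- switch(op,
      eq = if (is.character(v)) tolower(v) == tolower(as.character(operand))
           else v == operand,
      lt = v < operand, le = v <= operand,
      gt = v > operand, ge = v >= operand,
      between = v >= operand[[1L]] & v <= operand[[2L]],
      contains = grepl(as.character(operand), v, fixed = FALSE,
                       ignore.case = TRUE),
      stop("unknown operator: ", op, call. = FALSE))
    m[is.na(m)] <- FALSE
    keep <- keep & m
  }
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export a table to CSV or a single-sheet workbook
#'
#' @param table a data.frame.
#' @param path output path.
#' @param fmt `"csv"` or `"workbook"`.
#' @export
exportTable <- function(table, path, fmt = c("csv", "workbook")) {
  fmt <- match.arg(fmt)
  if (fmt == "csv") utils::write.csv(table, path, row.names = FALSE,
                                     na = "")
  else writeWorkbook(list(Data = table), path)
  invisible(path)
}
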