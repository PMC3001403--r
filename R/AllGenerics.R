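#' Accessor generics
#'
#' Small accessor layer over the S4 entity classes so that callers never
#' reach into slots directly.
#'
#' @param x an entity object.
#' @param ... passed to methods.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("shortName", function(x) standardGeneric("shortName"))
#' @rdname accessors
#' @export
setGeneric("screenType", function(x) standardGeneric("screenType"))
#' @rdname accessors
#' @export
setGeneric("plateFormat", function(x) standardGeneric("plateFormat"))
#' @rdname accessors
#' @export
setGeneric("libraryWells", function(x) standardGeneric("libraryWells"))
#' @rdname accessors
#' @export
setGeneric("libraryVersion", function(x) standardGeneric("libraryVersion"))
#' @rdname accessors
#' @export
setGeneric("plateRange", function(x) standardGeneric("plateRange"))
#' @rdname accessors
#' @export
setGeneric("copyName", function(x) standardGeneric("copyName"))
#' @rdname accessors
#' @export
setGeneric("usageType", function(x) standardGeneric("usageType"))
#' @rdname accessors
#' @export
setGeneric("remainingVolume", function(x, ...) standardGeneric("remainingVolume"))
#' @rdname accessors
#' @export
setGeneric("freezeThawCount", function(x, ...) standardGeneric("freezeThawCount"))
#' @rdname accessors
#' @export
setGeneric("dataColumns", function(x) standardGeneric("dataColumns"))
#' @rdname accessors
#' @export
setGeneric("resultValues", function(x) standardGeneric("resultValues"))
#' @rdname accessors
#' @export
setGeneric("screenResult", function(x) standardGeneric("screenResult"))
#' @rdname accessors
#' @export
setGeneric("activities", function(x) standardGeneric("activities"))
#' @rdname accessors
#' @export
setGeneric("accessLevel", function(x) standardGeneric("accessLevel"))

#' @rdname accessors
setMethod("shortName", "ScreenLibrary", function(x) x@shortName)
#' @rdname accessors
setMethod("screenType", "ScreenLibrary", function(x) x@screenType)
#' @rdname accessors
setMethod("screenType", "Screen", function(x) x@screenType)
#' @rdname accessors
setMethod("plateFormat", "ScreenLibrary", function(x) x@plateFormat)
#' @rdname accessors
setMethod("plateFormat", "ScreenResult", function(x) x@plateFormat)
#' @rdname accessors
setMethod("libraryWells", "ScreenLibrary", function(x) x@wells)
#' @rdname accessors
setMethod("libraryVersion", "ScreenLibrary", function(x) x@version)
#' @rdname accessors
setMethod("plateRange", "ScreenLibrary",
          function(x) c(x@startPlate, x@endPlate))
#' @rdname accessors
setMethod("copyName", "LibraryCopy", function(x) x@name)
#' @rdname accessors
setMethod("usageType", "LibraryCopy", function(x) x@usageType)
#' @rdname accessors
setMethod("dataColumns", "ScreenResult", function(x) x@columns)
#' @rdname accessors
setMethod("resultValues", "ScreenResult", function(x) x@values)
#' @rdname accessors
setMethod("screenResult", "Screen", function(x) x@screenResult)
#' @rdname accessors
setMethod("activities", "ActivityLog", function(x) x@activities)
#' @rdname accessors
setMethod("accessLevel", "VisibilityDecision", function(x) x@access)

#' Remaining volume (µL) of one well or all wells of a copy
#'
#' @param x a [LibraryCopy].
#' @param well optional `"plate:well"` key; when omitted, the full named
#'   vector of remaining volumes is returned.
#' @return numeric µL (scalar or named vector).
#' @rdname accessors
setMethod("remainingVolume", "LibraryCopy", function(x, well = NULL) {
  if (is.null(well)) return(nlToUl(x@remainingNl))
  if (!all(well %in% names(x@remainingNl)))
    stop("unknown well key: ", well[!well %in% names(x@remainingNl)][1L],
         call. = FALSE)
  nlToUl(x@remainingNl[well])
})

#' Freeze/thaw count of a copy plate
#'
#' Materialised count of the library-screening activities that have touched
#' the plate (a reagent-quality proxy).
#'
#' @param x a [LibraryCopy].
#' @param plate plate number.
#' @rdname accessors
setMethod("freezeThawCount", "LibraryCopy", function(x, plate) {
  i <- match(as.integer(plate), x@plateInfo$plate)
  if (anyNA(i)) stop("plate not in copy: ", plate[is.na(i)][1L], call. = FALSE)
  x@plateInfo$freeze_thaw[i]
})

setMethod("show", "ScreenLibrary", function(object) {
  w <- object@wells
  cat("ScreenLibrary '", object@shortName, "' (", object@screenType, ")\n",
      "  plates ", object@startPlate, "-", object@endPlate, " (",
      object@plateFormat, "-well), version ", object@version, "\n",
      "  wells: ", sum(w$well_type == "experimental"), " experimental / ",
      nrow(w), " total; ", sum(w$deprecated), " deprecated\n", sep = "")
})

setMethod("show", "LibraryCopy", function(object) {
  cat("LibraryCopy '", object@name, "' of library '", object@libraryName,
      "' (", object@usageType, ")\n  ", nrow(object@plateInfo),
      " plates, total remaining ",
      format(sum(nlToUl(object@remainingNl))), " uL\n", sep = "")
})

setMethod("show", "Screen", function(object) {
  cat("Screen ", object@facilityId, " (", object@screenType, "): ",
      object@title, "\n  data sharing level ", object@dataSharingLevel,
      if (is.null(object@screenResult)) "; no screen result"
      else paste0("; result: ", nrow(object@screenResult@columns),
                  " data columns x ", nrow(object@screenResult@values),
                  " wells"),
      "\n", sep = "")
})

setMethod("show", "ScreenResult", function(object) {
  cat("ScreenResult: ", nrow(object@columns), " data columns x ",
      nrow(object@values), " assay wells (", object@plateFormat,
      "-well plates)\n  columns: ",
      paste(object@columns$name, collapse = ", "), "\n", sep = "")
})

setMethod("show", "CherryPickRequest", function(object) {
  sp <- object@screenerPicks; lp <- object@labPicks
  cat("CherryPickRequest ", object@id, " for screen ", object@screenId,
      "\n  ", nrow(sp), " screener picks (", sum(sp$status == "accepted"),
      " accepted), ", nrow(lp), " lab picks, ", nrow(object@plates),
      " plates\n  effective volume ", format(effectiveVolumeUl(object)),
      " uL\n", sep = "")
})

setMethod("show", "ActivityLog", function(object) {
  cat("ActivityLog with", length(object@activities), "activities\n")
})

setMethod("show", "Activity", function(object) {
  cat("Activity #", object@id, " [", object@kind, "/", object@category,
      "] by ", object@performedBy, " on ", format(object@date), "\n",
      sep = "")
})

setMethod("show", "ScreenUser", function(object) {
  cat("ScreenUser '", object@id, "' (", object@category, "), roles: ",
      paste(object@roles, collapse = ", "), "\n", sep = "")
})

setMethod("show", "VisibilityDecision", function(object) {
  cat("VisibilityDecision: user '", object@subject, "' on screen ",
      object@screenId, " -> ", object@access, "\n", sep = "")
})
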