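#' Create a physical copy of a library
#'
#' Aliquots the library's plates into a named working copy whose wells all
#' start at `initialWellVolumeUl`. Volumes are held internally as exact
#' integer nanoliters so the ledger never drifts.
#'
#' @param library a [ScreenLibrary].
#' @param name copy name, unique within the library (e.g. "C").
#' @param usageType `"library_screening"` or `"cherry_pick_source"`.
#' @param initialWellVolumeUl starting per-well volume in µL (> 0).
#' @param existingCopies list of the library's existing [LibraryCopy]
#'   objects, used to enforce name uniqueness.
#' @return a [LibraryCopy].
#' @examples
#' lib <- newScreenLibrary("L", "small_molecule", 96, 1, 3)
#' cp <- createCopy(lib, "C", "cherry_pick_source", 50)
#' remainingVolume(cp, "2:A01")  # 50
#' @export
createCopy <- function(library, name, usageType = "library_screening",
                       initialWellVolumeUl = 0, existingCopies = list()) {
  stopifnot(is(library, "ScreenLibrary"))
  if (initialWellVolumeUl <= 0)
    stop("initial well volume must be positive", call. = FALSE)
  taken <- vapply(existingCopies, copyName, "")
  if (name %in% taken)
    stop("copy name '", name, "' already used in library '",
         library@shortName, "'", call. = FALSE)
  plates <- seq.int(library@startPlate, library@endPlate)
  nl <- ulToNl(initialWellVolumeUl)
  keys <- unlist(lapply(plates, wellsInRowMajor, library@plateFormat))
  new("LibraryCopy", libraryName = library@shortName, name = name,
      usageType = usageType,
      plateInfo = data.frame(plate = plates, retired = FALSE,
                             freeze_thaw = 0L, initial_nl = nl,
                             stringsAsFactors = FALSE),
      remainingNl = stats::setNames(rep(nl, length(keys)), keys))
}

#' Retire or unretire a copy plate
#'
#' Retired plates accept no further debits and are excluded from
#' cherry-pick availability.
#'
#' @param copy a [LibraryCopy].
#' @param plateNumbers plates to flag.
#' @param retired logical flag.
#' @return the updated [LibraryCopy].
#' @export
retirePlates <- function(copy, plateNumbers, retired = TRUE) {
  stopifnot(is(copy, "LibraryCopy"))
  i <- match(as.integer(plateNumbers), copy@plateInfo$plate)
  if (anyNA(i))
    stop("plate not in copy: ", plateNumbers[is.na(i)][1L], call. = FALSE)
  copy@plateInfo$retired[i] <- retired
  copy
}

#' Record a library screening against a copy
#'
#' Screening a set of plates debits every well of each listed plate by
#' `volumePerWellUl * replicates`, increments each plate's freeze/thaw
#' count and records a `library_screening` lab activity. The debit is
#' atomic: if any well would go negative the whole operation is rejected
#' and no volume changes.
#'
#' @param copy a [LibraryCopy].
#' @param plateNumbers plates screened (must belong to the copy, not
#'   retired).
#' @param volumePerWellUl volume transferred per well per replicate (µL).
#' @param replicates number of replicate assay plates (>= 1).
#' @param performer the [ScreenUser] (or id) who screened.
#' @param log an [ActivityLog].
#' @param date event date.
#' @return list with the updated `copy`, `log` and the `activity`.
#' @export
recordLibraryScreening <- function(copy, plateNumbers, volumePerWellUl,
                                   replicates = 1, performer, log,
                                   date = Sys.Date()) {
  stopifnot(is(copy, "LibraryCopy"), is(log, "ActivityLog"))
  plateNumbers <- as.integer(plateNumbers)
  replicates <- as.integer(replicates)
  if (replicates < 1L) stop("replicates must be >= 1", call. = FALSE)
  i <- match(plateNumbers, copy@plateInfo$plate)
  if (anyNA(i))
    stop("plate not in copy: ", plateNumbers[is.na(i)][1L], call. = FALSE)
  if (any(copy@plateInfo$retired[i]))
    stop("plate ", plateNumbers[copy@plateInfo$retired[i]][1L],
         " is retired", call. = FALSE)
  debit <- ulToNl(volumePerWellUl) * replicates
  keyPlate <- as.integer(sub(":.*$", "", names(copy@remainingNl)))
  idx <- which(keyPlate %in% plateNumbers)
  short <- idx[copy@remainingNl[idx] < debit]
  if (length(short))
    stop("insufficient volume in well ", names(copy@remainingNl)[short[1L]],
         " (", nlToUl(copy@remainingNl[short[1L]]), " uL < ",
         nlToUl(debit), " uL); screening rejected", call. = FALSE)
  copy@remainingNl[idx] <- copy@remainingNl[idx] - debit
  copy@plateInfo$freeze_thaw[i] <- copy@plateInfo$freeze_thaw[i] + 1L
  rec <- recordActivity(
    log, "library_screening", performer, date,
    links = c(paste0("copy:", copy@libraryName, "/", copy@name),
              paste0("plate:", plateNumbers)),
    payload = list(plates = plateNumbers,
                   volume_per_well_ul = volumePerWellUl,
                   replicates = replicates,
                   total_debit_ul = nlToUl(debit)))
  list(copy = copy, log = rec$log, activity = rec$activity)
}

#' Manually correct a well's remaining volume
#'
#' Sets the remaining volume of one copy well to an observed value
#' (pipetting imprecision, evaporation, ...), recording a
#' `well_volume_correction` administrative activity holding the old and
#' new values. Requires the `"volume_admin"` role.
#'
#' @param copy a [LibraryCopy].
#' @param well `"plate:well"` key.
#' @param newVolumeUl observed volume (µL, >= 0).
#' @param reason free-text justification.
#' @param admin the administrator ([ScreenUser]) applying the correction.
#' @param log an [ActivityLog].
#' @param date event date.
#' @return list with the updated `copy`, `log` and the `activity`.
#' @export
applyVolumeCorrection <- function(copy, well, newVolumeUl, reason, admin,
                                  log, date = Sys.Date()) {
  stopifnot(is(copy, "LibraryCopy"), is(log, "ActivityLog"),
            is(admin, "ScreenUser"))
  if (!"volume_admin" %in% admin@roles)
    stop("user '", admin@id,
         "' lacks the volume_admin role required for corrections",
         call. = FALSE)
  if (newVolumeUl < 0)
    stop("corrected volume must be non-negative", call. = FALSE)
  if (!well %in% names(copy@remainingNl))
    stop("unknown well key: ", well, call. = FALSE)
  oldNl <- copy@remainingNl[[well]]
  newNl <- ulToNl(newVolumeUl)
  copy@remainingNl[[well]] <- newNl
  rec <- recordActivity(
    log, "well_volume_correction", admin, date,
    links = c(paste0("copy:", copy@libraryName, "/", copy@name),
              paste0("well:", well)),
    payload = list(well = well, old_ul = nlToUl(oldNl),
                   new_ul = nlToUl(newNl),
                   delta_ul = nlToUl(newNl - oldNl)),
    comments = reason)
  list(copy = copy, log = rec$log, activity = rec$activity)
}

#' Deprecate library wells
#'
#' Flags wells as no longer valid for screening (library creation errors,
#' contamination, ...). Deprecated wells are excluded from cherry-pick
#' availability. Re-deprecating a well is idempotent and updates the
#' reason. A `well_deprecation` administrative activity is recorded.
#'
#' @param library a [ScreenLibrary].
#' @param keys `"plate:well"` keys to deprecate.
#' @param reason non-empty justification.
#' @param admin the deciding administrator.
#' @param log an [ActivityLog].
#' @param date decision date.
#' @return list with the updated `library`, `log` and the `activity`.
#' @export
deprecateWells <- function(library, keys, reason, admin, log,
                           date = Sys.Date()) {
  stopifnot(is(library, "ScreenLibrary"), is(log, "ActivityLog"))
  if (!nzchar(trimws(reason)))
    stop("a deprecation reason is required", call. = FALSE)
  i <- .wellRows(library, keys)
  if (anyNA(i))
    stop("unknown well key: ", keys[is.na(i)][1L], call. = FALSE)
  library@wells$deprecated[i] <- TRUE
  library@wells$deprecation_reason[i] <- reason
  rec <- recordActivity(
    log, "well_deprecation", admin, date,
    links = c(paste0("library:", library@shortName),
              paste0("well:", keys)),
    payload = list(wells = keys, reason = reason))
  list(library = library, log = rec$log, activity = rec$activity)
}

#' Remaining-volume report for one library well across copies
#'
#' One row per copy; retired plates are flagged and excluded from the
#' cherry-pick-available total.
#'
#' @param copies list of the library's [LibraryCopy] objects.
#' @param well `"plate:well"` key.
#' @return data.frame with columns `copy`, `usage_type`, `retired`,
#'   `remaining_ul`.
#' @export
remainingVolumeReport <- function(copies, well) {
  if (is(copies, "LibraryCopy")) copies <- list(copies)
  rows <- lapply(copies, function(cp) {
    if (!well %in% names(cp@remainingNl))
      stop("unknown well key: ", well, call. = FALSE)
    plate <- as.integer(sub(":.*$", "", well))
    data.frame(copy = cp@name, usage_type = cp@usageType,
               retired = cp@plateInfo$retired[
                 match(plate, cp@plateInfo$plate)],
               remaining_ul = nlToUl(cp@remainingNl[[well]]),
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(copy = character(), usage_type = character(),
                         retired = logical(), remaining_ul = numeric(),
                         stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
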