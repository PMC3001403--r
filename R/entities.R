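#' Create a facility user
#'
#' @param id unique user id.
#' @param category `"screener"` or `"administrator"`.
#' @param roles character role names; the `"login"` role gates login.
#' @param classification free text ("Principal Investigator", ...).
#' @param labName lab affiliation.
#' @return a [ScreenUser].
#' @examples
#' screenUser("ada", "administrator", roles = c("login", "volume_admin"))
#' @export
screenUser <- function(id, category = "screener", roles = "login",
                       classification = "", labName = "") {
  new("ScreenUser", id = id, category = category, roles = roles,
      classification = classification, labName = labName)
}

#' Can a user log in?
#'
#' Login is permitted only when the user's roles contain the special
#' `"login"` role, which the facility grants or revokes.
#'
#' @param user a [ScreenUser].
#' @export
canLogin <- function(user) {
  stopifnot(is(user, "ScreenUser"))
  "login" %in% user@roles
}

#' Update a checklist item on a user
#'
#' Checklist items track administrative tasks (safety training, account
#' setup, mailing lists). Statuses are pending/completed/activated/
#' deactivated. This is normally driven through
#' [recordActivity()] with kind `"checklist_item_event"`.
#'
#' @param user a [ScreenUser].
#' @param name checklist item name.
#' @param status one of the checklist statuses.
#' @param date event date.
#' @return the updated [ScreenUser].
#' @export
setChecklistItem <- function(user, name, status, date = Sys.Date()) {
  stopifnot(is(user, "ScreenUser"))
  if (!status %in% CHECKLIST_STATUSES)
    stop("invalid checklist status: ", status, call. = FALSE)
  cl <- user@checklist
  i <- match(name, cl$name)
  if (is.na(i)) {
    cl <- rbind(cl, data.frame(name = name, status = status,
                               date = as.Date(date),
                               stringsAsFactors = FALSE))
  } else {
    cl$status[i] <- status
    cl$date[i] <- as.Date(date)
  }
  user@checklist <- cl
  validObject(user)
  user
}

# an empty well table covering the full plate range, row-major
.emptyWellTable <- function(screenType, plateFormat, startPlate, endPlate) {
  plates <- seq.int(startPlate, endPlate)
  wn <- wellNamesRowMajor(plateFormat)
  n <- length(plates) * length(wn)
  schema <- wellTableSchema(screenType)
  w <- emptyTypedFrame(schema, n)
  w$plate <- rep(plates, each = length(wn))
  w$well <- rep(wn, times = length(plates))
  w$well_type <- "empty"
  w$deprecated <- FALSE
  for (col in setdiff(names(schema), c("plate", "well", "well_type",
                                       "deprecated")))
    w[[col]] <- as.vector(NA, mode = schema[[col]])
  w
}

#' Create an empty screening library
#'
#' All wells start as `well_type = "empty"`; importers fill them in.
#'
#' @param shortName unique library name.
#' @param screenType `"small_molecule"` or `"rnai"`.
#' @param plateFormat 96, 384 or 1536.
#' @param startPlate,endPlate inclusive plate range.
#' @return a [ScreenLibrary].
#' @export
newScreenLibrary <- function(shortName, screenType, plateFormat = 384,
                             startPlate = 1, endPlate = startPlate) {
  new("ScreenLibrary", shortName = shortName, screenType = screenType,
      plateFormat = as.integer(plateFormat),
      startPlate = as.integer(startPlate), endPlate = as.integer(endPlate),
      version = 1L,
      wells = .emptyWellTable(screenType, as.integer(plateFormat),
                              as.integer(startPlate), as.integer(endPlate)))
}

#' Create a screen
#'
#' @param facilityId facility-assigned screen id.
#' @param screenType `"small_molecule"` or `"rnai"`.
#' @param title descriptive title.
#' @param labHead,leadScreener user ids.
#' @param collaborators user ids.
#' @param dataSharingLevel 0 (shared) .. 3 (private); see
#'   [effectiveAccess()].
#' @param libraryNames short names of screened libraries.
#' @param summary,assayProtocol descriptive text.
#' @return a [Screen].
#' @export
newScreen <- function(facilityId, screenType, title = "", labHead = "",
                      leadScreener = labHead, collaborators = character(),
                      dataSharingLevel = 3, libraryNames = character(),
                      summary = "", assayProtocol = "") {
  new("Screen", facilityId = as.character(facilityId),
      screenType = screenType, title = title, labHead = labHead,
      leadScreener = leadScreener, collaborators = collaborators,
      dataSharingLevel = as.integer(dataSharingLevel),
      libraryNames = libraryNames, summary = summary,
      assayProtocol = assayProtocol)
}

#' Append a dated status to a screen's history
#'
#' Statuses chart the progression of a screening effort (pending, accepted,
#' ongoing, completed, dropped); dates must be non-decreasing.
#'
#' @param screen a [Screen].
#' @param status new status.
#' @param date status date.
#' @return the updated [Screen].
#' @export
addScreenStatus <- function(screen, status, date = Sys.Date()) {
  stopifnot(is(screen, "Screen"))
  screen@statusHistory <- rbind(
    screen@statusHistory,
    data.frame(status = status, date = as.Date(date),
               stringsAsFactors = FALSE))
  validObject(screen)
  screen
}

#' Create a study of reagent annotations
#'
#' @param studyId facility-assigned study id.
#' @param title descriptive title.
#' @param annotations data.frame with a `vendor_id` column plus one column
#'   per annotation type (values keyed by reagent, not well).
#' @param columnInfo optional data.frame `name`, `kind`, `description`; by
#'   default inferred from `annotations`.
#' @return a [Study].
#' @export
newStudy <- function(studyId, title = "", annotations, columnInfo = NULL) {
  stopifnot(is.data.frame(annotations), "vendor_id" %in% names(annotations))
  if (anyDuplicated(annotations$vendor_id))
    stop("study annotations must have one row per reagent vendor_id",
         call. = FALSE)
  ann <- setdiff(names(annotations), "vendor_id")
  if (is.null(columnInfo))
    columnInfo <- data.frame(
      name = ann,
      kind = vapply(annotations[ann], function(v)
        if (is.numeric(v)) "numeric" else if (is.logical(v)) "boolean"
        else "text", ""),
      description = "", stringsAsFactors = FALSE)
  new("Study", studyId = as.character(studyId), title = title,
      annotationColumns = columnInfo, values = annotations)
}

# locate rows of a library well table by "plate:well" keys; NA where absent
.wellRows <- function(library, keys) {
  match(keys, wellKey(library@wells$plate, library@wells$well))
}
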