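# Activity kinds form an open registry: the five facility kinds are fixed
# with their lab/administrative categories; workflow steps that must leave
# an audit record (reservations, cancellation refunds, contents imports)
# are registered as additional kinds. The registry is validated at load.
.activityKinds <- new.env(parent = emptyenv())

.defaultActivityKinds <- c(
  library_screening = "lab",
  cherry_pick_liquid_transfer = "lab",
  well_deprecation = "administrative",
  well_volume_correction = "administrative",
  checklist_item_event = "administrative",
  # workflow extensions (open registry)
  cherry_pick_request_submission = "administrative",
  cherry_pick_reservation = "lab",
  cherry_pick_cancellation = "administrative",
  cherry_pick_plate_failure = "administrative",
  library_contents_import = "administrative")

.onLoad <- function(libname, pkgname) {
  for (k in names(.defaultActivityKinds))
    registerActivityKind(k, .defaultActivityKinds[[k]])
}

#' Register an activity kind
#'
#' The activity hierarchy is extensible: facilities may register further
#' kinds, each bound permanently to a `"lab"` or `"administrative"`
#' category. Re-registering a kind with a different category is an error.
#'
#' @param kind kind name.
#' @param category `"lab"` or `"administrative"`.
#' @export
registerActivityKind <- function(kind, category) {
  if (!category %in% c("lab", "administrative"))
    stop("category must be 'lab' or 'administrative'", call. = FALSE)
  existing <- .activityKinds[[kind]]
  if (!is.null(existing) && existing != category)
    stop("activity kind '", kind, "' already registered as ", existing,
         call. = FALSE)
  assign(kind, category, envir = .activityKinds)
  invisible(kind)
}

#' @rdname registerActivityKind
#' @export
activityKinds <- function() {
  kinds <- ls(.activityKinds)
  stats::setNames(vapply(kinds, function(k) .activityKinds[[k]], ""), kinds)
}

#' Create a new, empty activity log
#'
#' @return an [ActivityLog].
#' @export
newActivityLog <- function() new("ActivityLog")

#' Record an activity
#'
#' Appends an activity of a registered kind to the log, assigning the next
#' sequential id. The log is append-only: activities are never edited or
#' deleted, preserving the who/what/when/why of every event.
#'
#' @param log an [ActivityLog].
#' @param kind registered activity kind.
#' @param performer a [ScreenUser] or user id.
#' @param date event date (may precede the record date).
#' @param links character refs to the entities acted on (e.g.
#'   `"copy:LIB1/C"`, `"well:1:A01"`, `"user:ada"`).
#' @param payload kind-specific named list.
#' @param comments free text.
#' @return list with the updated `log` and the recorded `activity`.
#' @export
recordActivity <- function(log, kind, performer, date = Sys.Date(),
                           links = character(), payload = list(),
                           comments = "") {
  stopifnot(is(log, "ActivityLog"))
  category <- .activityKinds[[kind]]
  if (is.null(category))
    stop("unknown activity kind: '", kind, "'", call. = FALSE)
  if (kind == "well_volume_correction" &&
      !all(c("old_ul", "new_ul") %in% names(payload)))
    stop("well_volume_correction payload requires old_ul and new_ul",
         call. = FALSE)
  if (kind == "checklist_item_event" &&
      !all(c("item", "status") %in% names(payload)))
    stop("checklist_item_event payload requires item and status",
         call. = FALSE)
  performer <- if (is(performer, "ScreenUser")) performer@id
               else as.character(performer)
  act <- new("Activity", id = length(log@activities) + 1L, kind = kind,
             category = category, performedBy = performer,
             date = as.Date(date), comments = comments,
             links = as.character(links), payload = payload)
  log@activities <- c(log@activities, list(act))
  list(log = log, activity = act)
}

#' Query the activity log
#'
#' Filters are conjunctive; the result is ordered by (date, id).
#'
#' @param log an [ActivityLog].
#' @param kind,performer optional exact filters.
#' @param from,to optional inclusive date range.
#' @param entity optional entity ref that must appear among an activity's
#'   links.
#' @return list of matching [Activity] objects.
#' @export
queryActivities <- function(log, kind = NULL, performer = NULL, from = NULL,
                            to = NULL, entity = NULL) {
  stopifnot(is(log, "ActivityLog"))
  acts <- log@activities
  keep <- vapply(acts, function(a) {
    (is.null(kind) || a@kind %in% kind) &&
      (is.null(performer) || a@performedBy %in% performer) &&
      (is.null(from) || a@date >= as.Date(from)) &&
      (is.null(to) || a@date <= as.Date(to)) &&
      (is.null(entity) || any(entity %in% a@links))
  }, TRUE)
  acts <- acts[keep]
  ord <- order(as.numeric(vapply(acts, function(a) as.numeric(a@date), 0)),
               vapply(acts, function(a) a@id, 1L))
  acts[ord]
}

#' Activity log as a data table
#'
#' Flat view for en-masse browsing/reporting and CSV export.
#'
#' @param log an [ActivityLog].
#' @param path optional CSV output path.
#' @return data.frame with one row per activity.
#' @export
activitiesAsDataFrame <- function(log, path = NULL) {
  stopifnot(is(log, "ActivityLog"))
  acts <- log@activities
  df <- data.frame(
    id = vapply(acts, function(a) a@id, 1L),
    kind = vapply(acts, function(a) a@kind, ""),
    category = vapply(acts, function(a) a@category, ""),
    performed_by = vapply(acts, function(a) a@performedBy, ""),
    date = as.Date(vapply(acts, function(a) as.character(a@date), "")),
    comments = vapply(acts, function(a) a@comments, ""),
    links = vapply(acts, function(a) paste(a@links, collapse = ";"), ""),
    stringsAsFactors = FALSE)
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  df
}
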