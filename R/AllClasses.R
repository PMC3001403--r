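#' @import methods
NULL

WELL_TYPES <- c("experimental", "empty", "dmso_control", "library_control",
                "buffer")
SCREEN_TYPES <- c("small_molecule", "rnai")
CHECKLIST_STATUSES <- c("pending", "completed", "activated", "deactivated")
PARTITION_VALUES <- c("strong", "medium", "weak", "none")

# column schemas for the well table of each reagent class
.wellColsCommon <- c(plate = "integer", well = "character",
                     well_type = "character", deprecated = "logical",
                     deprecation_reason = "character",
                     vendor = "character", vendor_id = "character")
.wellColsSM <- c(smiles = "character", inchi = "character",
                 molecular_mass = "numeric", chemical_names = "character",
                 pubchem_cids = "character", chembank_ids = "character")
.wellColsRNAi <- c(silencing_type = "character", sequences = "character",
                   entrez_gene_id = "integer", gene_symbol = "character",
                   genbank_accessions = "character", species = "character",
                   duplex_wells = "character")

wellTableSchema <- function(screenType) {
  c(.wellColsCommon,
    if (screenType == "small_molecule") .wellColsSM else .wellColsRNAi)
}

emptyTypedFrame <- function(schema, n = 0L) {
  cols <- lapply(schema, function(tp) vector(tp, n))
  as.data.frame(cols, stringsAsFactors = FALSE)
}

#' A facility user (screener or administrator)
#'
#' Users carry a category, a set of role names controlling what they may do
#' (the special `"login"` role gates login; `"read_everything"` grants
#' administrators full data visibility; `"volume_admin"` gates ledger
#' corrections), a free-text classification, a lab affiliation and a
#' checklist of administrative tasks tracked by the facility.
#'
#' @slot id unique user id.
#' @slot category `"screener"` or `"administrator"`.
#' @slot roles character vector of role names.
#' @slot classification free text, e.g. "Principal Investigator".
#' @slot labName lab affiliation.
#' @slot checklist data.frame with columns `name`, `status`, `date`.
#' @export
setClass("ScreenUser",
  representation(id = "character", category = "character",
                 roles = "character", classification = "character",
                 labName = "character", checklist = "data.frame"),
  prototype(classification = "", labName = "",
            checklist = data.frame(name = character(), status = character(),
                                   date = as.Date(character()),
                                   stringsAsFactors = FALSE)))

setValidity("ScreenUser", function(object) {
  msg <- character()
  if (length(object@id) != 1L || !nzchar(object@id))
    msg <- c(msg, "id must be a non-empty string")
  if (length(object@category) != 1L ||
      !object@category %in% c("screener", "administrator"))
    msg <- c(msg, "category must be 'screener' or 'administrator'")
  if (nrow(object@checklist) &&
      !all(object@checklist$status %in% CHECKLIST_STATUSES))
    msg <- c(msg, "checklist statuses must be pending/completed/activated/deactivated")
  if (length(msg)) msg else TRUE
})

#' A versioned screening library
#'
#' A library is a cohesive, plated set of small-molecule or RNAi reagents
#' spanning a contiguous plate range. Its contents can be re-imported; each
#' import increments the version and the superseded well tables are retained
#' unmodified for auditing.
#'
#' @slot shortName unique library name.
#' @slot screenType `"small_molecule"` or `"rnai"`.
#' @slot plateFormat wells per plate (96/384/1536).
#' @slot startPlate,endPlate inclusive plate-number range.
#' @slot version contents version, starting at 1.
#' @slot wells data.frame, one row per well of every plate (row-major),
#'   with reagent columns for the library's reagent class.
#' @slot supersededVersions list of prior well tables (oldest first).
#' @export
setClass("ScreenLibrary",
  representation(shortName = "character", screenType = "character",
                 plateFormat = "integer", startPlate = "integer",
                 endPlate = "integer", version = "integer",
                 wells = "data.frame", supersededVersions = "list"),
  prototype(version = 1L, supersededVersions = list()))

setValidity("ScreenLibrary", function(object) {
  msg <- character()
  if (!object@screenType %in% SCREEN_TYPES)
    msg <- c(msg, "screenType must be 'small_molecule' or 'rnai'")
  if (!object@plateFormat %in% c(96L, 384L, 1536L))
    msg <- c(msg, "plateFormat must be 96, 384 or 1536")
  if (object@startPlate > object@endPlate)
    msg <- c(msg, "startPlate must be <= endPlate")
  if (object@version < 1L)
    msg <- c(msg, "version must be >= 1")
  w <- object@wells
  need <- names(wellTableSchema(object@screenType))
  if (!all(need %in% names(w)))
    msg <- c(msg, paste("wells table missing columns:",
                        paste(setdiff(need, names(w)), collapse = ", ")))
  else {
    if (nrow(w) && (any(w$plate < object@startPlate) ||
                    any(w$plate > object@endPlate)))
      msg <- c(msg, "well plate numbers outside declared plate range")
    if (nrow(w) && !all(w$well_type %in% WELL_TYPES))
      msg <- c(msg, "invalid well_type values")
    if (nrow(w) && any(w$deprecated & (is.na(w$deprecation_reason) |
                                       !nzchar(w$deprecation_reason))))
      msg <- c(msg, "deprecated wells must carry a deprecation_reason")
  }
  if (length(msg)) msg else TRUE
})

#' A physical copy of a library with a per-well volume ledger
#'
#' Copies are aliquoted working instances of a library's plates. Remaining
#' well volumes are held as exact integer nanoliters and are debited by
#' library screenings and cherry-pick reservations, and adjusted by manual
#' corrections. Individual plates can be retired.
#'
#' @slot libraryName short name of the parent library.
#' @slot name copy name, unique within the library (e.g. "C").
#' @slot usageType `"library_screening"` or `"cherry_pick_source"`.
#' @slot plateInfo data.frame: `plate`, `retired`, `freeze_thaw`,
#'   `initial_nl`.
#' @slot remainingNl named integer vector of remaining volume (nL) keyed by
#'   `"plate:well"`.
#' @export
setClass("LibraryCopy",
  representation(libraryName = "character", name = "character",
                 usageType = "character", plateInfo = "data.frame",
                 remainingNl = "integer"))

setValidity("LibraryCopy", function(object) {
  msg <- character()
  if (!object@usageType %in% c("library_screening", "cherry_pick_source"))
    msg <- c(msg, "usageType must be 'library_screening' or 'cherry_pick_source'")
  if (is.null(names(object@remainingNl)))
    msg <- c(msg, "remainingNl must be named by well key")
  if (length(object@remainingNl) && any(object@remainingNl < 0L))
    msg <- c(msg, "remaining volumes must be non-negative")
  if (length(msg)) msg else TRUE
})

#' An audit-trail activity record
#'
#' Activities capture the who/what/when/why of lab events (library
#' screenings, cherry-pick liquid transfers) and administrative decisions
#' (well deprecations, volume corrections, checklist events). They are
#' append-only.
#'
#' @slot id sequential integer assigned by the log at record time.
#' @slot kind registered activity kind.
#' @slot category `"lab"` or `"administrative"` (fixed per kind).
#' @slot performedBy user id.
#' @slot date event date (may precede the record date).
#' @slot comments free text.
#' @slot links character refs to the entities acted on.
#' @slot payload kind-specific named list (volumes, wells, old/new values).
#' @export
setClass("Activity",
  representation(id = "integer", kind = "character", category = "character",
                 performedBy = "character", date = "Date",
                 comments = "character", links = "character",
                 payload = "list"),
  prototype(comments = "", links = character(), payload = list()))

#' An append-only log of activities
#'
#' @slot activities list of [Activity] objects in record order; ids are
#'   monotonically increasing.
#' @export
setClass("ActivityLog", representation(activities = "list"),
         prototype(activities = list()))

#' A screen-result data set
#'
#' Imported per-well experimental values organised into raw and derived
#' data columns. Derived columns reference earlier columns only; positives
#' columns carry a boolean, partition or threshold indicator.
#'
#' @slot columns data.frame describing the data columns: `name`, `kind`
#'   (numeric/text/boolean/partitioned), `replicate`, `time_point`,
#'   `readout_technology`, `derived`, `derived_from` (semicolon-joined
#'   names), `positive_indicator` (none/boolean/partition/threshold),
#'   `cutoff`, `direction` (above/below), `description`.
#' @slot values wide data.frame: `plate`, `well`, `assay_well_type`,
#'   `vendor_id`, then one typed column per data column.
#' @slot plateFormat plate format of the screened library.
#' @slot dateCreated,dateUpdated import bookkeeping dates.
#' @export
setClass("ScreenResult",
  representation(columns = "data.frame", values = "data.frame",
                 plateFormat = "integer", dateCreated = "Date",
                 dateUpdated = "Date"))

#' A screen (screening project)
#'
#' @slot facilityId facility-assigned screen id.
#' @slot screenType `"small_molecule"` or `"rnai"`.
#' @slot title,summary,assayProtocol descriptive text.
#' @slot labHead,leadScreener user ids.
#' @slot collaborators user ids (no duplicates).
#' @slot statusHistory data.frame `status`, `date` with non-decreasing
#'   dates; statuses among pending/accepted/ongoing/completed/dropped.
#' @slot dataSharingLevel 0 (everything shared) .. 3 (private).
#' @slot libraryNames short names of the screened libraries.
#' @slot screenResult a [ScreenResult] or `NULL`.
#' @export
setClass("Screen",
  representation(facilityId = "character", screenType = "character",
                 title = "character", summary = "character",
                 assayProtocol = "character", labHead = "character",
                 leadScreener = "character", collaborators = "character",
                 statusHistory = "data.frame", dataSharingLevel = "integer",
                 libraryNames = "character", screenResult = "ANY"),
  prototype(title = "", summary = "", assayProtocol = "",
            collaborators = character(), libraryNames = character(),
            dataSharingLevel = 3L, screenResult = NULL,
            statusHistory = data.frame(status = character(),
                                       date = as.Date(character()),
                                       stringsAsFactors = FALSE)))

setValidity("Screen", function(object) {
  msg <- character()
  if (!object@screenType %in% SCREEN_TYPES)
    msg <- c(msg, "screenType must be 'small_molecule' or 'rnai'")
  if (!object@dataSharingLevel %in% 0:3)
    msg <- c(msg, "dataSharingLevel must be 0..3")
  sh <- object@statusHistory
  if (nrow(sh)) {
    if (!all(sh$status %in% c("pending", "accepted", "ongoing", "completed",
                              "dropped")))
      msg <- c(msg, "invalid status in statusHistory")
    if (is.unsorted(sh$date))
      msg <- c(msg, "statusHistory dates must be non-decreasing")
  }
  if (anyDuplicated(object@collaborators))
    msg <- c(msg, "collaborators must not contain duplicates")
  if (!is.null(object@screenResult) && !is(object@screenResult, "ScreenResult"))
    msg <- c(msg, "screenResult must be NULL or a ScreenResult")
  if (length(msg)) msg else TRUE
})

#' A study of reagent annotations
#'
#' Studies carry externally sourced, biologically relevant annotations
#' keyed by reagent (vendor id), not by well, so they can be appended to
#' any screen-result table that tested the reagent.
#'
#' @slot studyId facility-assigned study id.
#' @slot title descriptive text.
#' @slot annotationColumns data.frame `name`, `kind`, `description`.
#' @slot values data.frame with `vendor_id` plus one column per annotation.
#' @export
setClass("Study",
  representation(studyId = "character", title = "character",
                 annotationColumns = "data.frame", values = "data.frame"),
  prototype(title = ""))

CPR_REJECTION_REASONS <- c("duplicate", "deprecated", "non_experimental",
                           "over_limit", "unknown_well")
LCP_STATUSES <- c("unfulfilled", "reserved", "mapped", "plated", "failed",
                  "canceled")
PLATE_STATUSES <- c("not_plated", "plated", "failed", "canceled")

#' A cherry-pick request
#'
#' The follow-up workflow state for a screen: screener-submitted picks are
#' validated, deconvoluted to lab picks (pool siRNAs expand to their
#' duplexes), reserved against library-copy volumes, mapped onto
#' destination plates and exported as a liquid-handler mapping file.
#'
#' @slot id request id.
#' @slot screenId facility id of the screen.
#' @slot requestedBy screener user id.
#' @slot date request date.
#' @slot requestedVolumeUl requested per-well transfer volume (µL).
#' @slot approvedVolumeUl approved volume (µL) or `NA`; the effective
#'   volume is the approved volume when set, else the requested one.
#' @slot randomizeLayout permute destination wells within each plate?
#' @slot requiredEmptyWells destination well names kept empty.
#' @slot randomSeed persisted seed for the layout permutation.
#' @slot destFormat destination plate format (default 384).
#' @slot maxPicks facility policy cap on picks, or `NA`.
#' @slot screenerPicks data.frame: `plate`, `well`, `status`
#'   (accepted/rejected), `rejection_reason`.
#' @slot labPicks data.frame: `id`, `source_plate`, `source_well`,
#'   `screener_key`, `status`, `source_copy`, `dest_plate`, `dest_well`,
#'   `respawn_of`, `rolled_over`.
#' @slot plates data.frame: `ordinal`, `attempt`, `status`.
#' @export
setClass("CherryPickRequest",
  representation(id = "character", screenId = "character",
                 requestedBy = "character", date = "Date",
                 requestedVolumeUl = "numeric", approvedVolumeUl = "numeric",
                 randomizeLayout = "logical",
                 requiredEmptyWells = "character", randomSeed = "integer",
                 destFormat = "integer", maxPicks = "numeric",
                 screenerPicks = "data.frame", labPicks = "data.frame",
                 plates = "data.frame"),
  prototype(approvedVolumeUl = NA_real_, randomizeLayout = FALSE,
            requiredEmptyWells = character(), randomSeed = 0L,
            destFormat = 384L, maxPicks = NA_real_))

setValidity("CherryPickRequest", function(object) {
  msg <- character()
  if (length(object@requestedVolumeUl) != 1L || object@requestedVolumeUl <= 0)
    msg <- c(msg, "requestedVolumeUl must be positive")
  if (!is.na(object@approvedVolumeUl) &&
      object@approvedVolumeUl > object@requestedVolumeUl)
    msg <- c(msg, "approvedVolumeUl must be <= requestedVolumeUl")
  if (!object@destFormat %in% c(96L, 384L, 1536L))
    msg <- c(msg, "destFormat must be 96, 384 or 1536")
  if (length(object@requiredEmptyWells) &&
      !all(object@requiredEmptyWells %in% wellNamesRowMajor(object@destFormat)))
    msg <- c(msg, "requiredEmptyWells must be wells of the destination format")
  sp <- object@screenerPicks
  if (nrow(sp)) {
    if (!all(sp$status %in% c("accepted", "rejected")))
      msg <- c(msg, "screener pick statuses must be accepted/rejected")
    bad <- sp$status == "rejected" &
      !sp$rejection_reason %in% CPR_REJECTION_REASONS
    if (any(bad))
      msg <- c(msg, "rejected picks must carry a declared rejection reason")
  }
  lp <- object@labPicks
  if (nrow(lp)) {
    if (!all(lp$status %in% LCP_STATUSES))
      msg <- c(msg, "invalid lab pick status")
    withCopy <- lp$status %in% c("reserved", "mapped", "plated")
    if (any(withCopy & is.na(lp$source_copy)))
      msg <- c(msg, "reserved/mapped/plated picks must carry a source copy")
    withDest <- lp$status %in% c("mapped", "plated")
    if (any(withDest & (is.na(lp$dest_plate) | is.na(lp$dest_well))))
      msg <- c(msg, "mapped/plated picks must carry a destination")
  }
  if (nrow(object@plates) && !all(object@plates$status %in% PLATE_STATUSES))
    msg <- c(msg, "invalid cherry pick plate status")
  if (length(msg)) msg else TRUE
})

#' A visibility decision for a user on a screen
#'
#' @slot subject user id.
#' @slot screenId facility id of the screen.
#' @slot access one of `"none"`, `"metadata_only"`,
#'   `"positives_and_protocol"`, `"full"` (in increasing order).
#' @export
setClass("VisibilityDecision",
  representation(subject = "character", screenId = "character",
                 access = "character"))

ACCESS_LEVELS <- c("none", "metadata_only", "positives_and_protocol", "full")

setValidity("VisibilityDecision", function(object) {
  if (!object@access %in% ACCESS_LEVELS)
    "access must be one of none/metadata_only/positives_and_protocol/full"
  else TRUE
})
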