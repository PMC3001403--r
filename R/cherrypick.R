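# empty typed tables for the request state
.emptyScreenerPicks <- function() {
  data.frame(plate = integer(), well = character(), status = character(),
             rejection_reason = character(), stringsAsFactors = FALSE)
}

.emptyLabPicks <- function() {
  data.frame(id = integer(), source_plate = integer(),
             source_well = character(), screener_key = character(),
             status = character(), source_copy = character(),
             dest_plate = integer(), dest_well = character(),
             respawn_of = integer(), rolled_over = logical(),
             stringsAsFactors = FALSE)
}

.emptyCprPlates <- function() {
  data.frame(ordinal = integer(), attempt = integer(), status = character(),
             stringsAsFactors = FALSE)
}

# run expr with a fixed RNG seed, restoring the caller's RNG state
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  expr
}

#' Effective transfer volume of a cherry-pick request
#'
#' The approved volume when the facility has set one, else the requested
#' volume.
#'
#' @param request a [CherryPickRequest].
#' @return volume in µL.
#' @export
effectiveVolumeUl <- function(request) {
  stopifnot(is(request, "CherryPickRequest"))
  if (!is.na(request@approvedVolumeUl)) request@approvedVolumeUl
  else request@requestedVolumeUl
}

#' Create a cherry-pick request from a screener's pick list
#'
#' The screener submits follow-up picks as `"plate:well"` designations.
#' Picks are stored in submission order and validated immediately when
#' `libraries` are supplied (see [validatePicks()]); the submission is
#' recorded as an administrative activity when a log is given.
#'
#' @param screen a [Screen] (or its facility id).
#' @param picks character vector of `"plate:well"` designations.
#' @param requestedVolumeUl requested per-well transfer volume (µL, > 0).
#' @param requestedBy screener user id.
#' @param libraries optional libraries for immediate validation.
#' @param id request id.
#' @param approvedVolumeUl facility-approved volume (µL) or `NA`.
#' @param randomizeLayout permute destination wells within each plate?
#' @param requiredEmptyWells destination well names to keep empty (for
#'   controls or to avoid edge effects).
#' @param randomSeed persisted seed for the randomized layout.
#' @param destFormat destination plate format (default 384).
#' @param maxPicks facility policy cap on the number of picks, or `NA`.
#' @param sourceFormat plate format of the source libraries (for parsing
#'   the designations).
#' @param log optional [ActivityLog].
#' @param date request date.
#' @return the [CherryPickRequest] (or, with a log,
#'   `list(request, log, activity)`).
#' @export
createCherryPickRequest <- function(screen, picks, requestedVolumeUl,
                                    requestedBy, libraries = NULL,
                                    id = "CPR-1",
                                    approvedVolumeUl = NA_real_,
                                    randomizeLayout = FALSE,
                                    requiredEmptyWells = character(),
                                    randomSeed = 0,
                                    destFormat = 384,
                                    maxPicks = NA_real_,
                                    sourceFormat = 384,
                                    log = NULL, date = Sys.Date()) {
  if (requestedVolumeUl <= 0)
    stop("requested volume must be positive", call. = FALSE)
  screenId <- if (is(screen, "Screen")) screen@facilityId
              else as.character(screen)
  sp <- if (length(picks)) splitWellKey(picks, sourceFormat)
        else data.frame(plate = integer(), well = character(),
                        stringsAsFactors = FALSE)
  sp$status <- rep("accepted", nrow(sp))
  sp$rejection_reason <- rep(NA_character_, nrow(sp))
  req <- new("CherryPickRequest", id = as.character(id),
             screenId = screenId, requestedBy = requestedBy,
             date = as.Date(date),
             requestedVolumeUl = as.numeric(requestedVolumeUl),
             approvedVolumeUl = as.numeric(approvedVolumeUl),
             randomizeLayout = isTRUE(randomizeLayout),
             requiredEmptyWells = as.character(requiredEmptyWells),
             randomSeed = as.integer(randomSeed),
             destFormat = as.integer(destFormat),
             maxPicks = as.numeric(maxPicks),
             screenerPicks = sp, labPicks = .emptyLabPicks(),
             plates = .emptyCprPlates())
  if (!is.null(libraries)) req <- validatePicks(req, libraries)$request
  if (is.null(log)) return(req)
  rec <- recordActivity(log, "cherry_pick_request_submission", requestedBy,
                        date,
                        links = c(paste0("screen:", screenId),
                                  paste0("cpr:", id)),
                        payload = list(n_picks = nrow(sp),
                                       requested_volume_ul =
                                         requestedVolumeUl))
  list(request = req, log = rec$log, activity = rec$activity)
}

# locate a screener pick's well across the libraries; NULL when unknown
.findWell <- function(libraries, key) {
  for (lib in libraries) {
    i <- .wellRows(lib, key)
    if (!is.na(i)) return(list(library = lib, row = i))
  }
  NULL
}

#' Validate the screener picks of a request
#'
#' Facility policy review: every pick is marked accepted or rejected with
#' a reason — `unknown_well`, `non_experimental` (control/empty wells are
#' never cherry-pickable), `deprecated`, `duplicate` (a well may be picked
#' once), or `over_limit` for picks beyond the facility's pick cap, in
#' submission order. Rejections are per-pick conditions, not errors.
#'
#' @param request a [CherryPickRequest].
#' @param libraries list of [ScreenLibrary] objects holding the source
#'   wells.
#' @return list with the updated `request` and a `rejections` data.frame.
#' @export
validatePicks <- function(request, libraries) {
  stopifnot(is(request, "CherryPickRequest"))
  if (is(libraries, "ScreenLibrary")) libraries <- list(libraries)
  sp <- request@screenerPicks
  seen <- character()
  accepted <- 0L
  for (i in seq_len(nrow(sp))) {
    key <- wellKey(sp$plate[i], sp$well[i])
    hit <- .findWell(libraries, key)
    reason <- NA_character_
    if (is.null(hit)) reason <- "unknown_well"
    else {
      w <- hit$library@wells[hit$row, ]
      if (w$well_type != "experimental") reason <- "non_experimental"
      else if (w$deprecated) reason <- "deprecated"
      else if (key %in% seen) reason <- "duplicate"
      else if (!is.na(request@maxPicks) && accepted >= request@maxPicks)
        reason <- "over_limit"
    }
    if (is.na(reason)) {
      sp$status[i] <- "accepted"
      sp$rejection_reason[i] <- NA_character_
      accepted <- accepted + 1L
      seen <- c(seen, key)
    } else {
      sp$status[i] <- "rejected"
      sp$rejection_reason[i] <- reason
    }
  }
  request@screenerPicks <- sp
  validObject(request)
  rej <- sp[sp$status == "rejected", c("plate", "well",
                                       "rejection_reason")]
  rownames(rej) <- NULL
  list(request = request, rejections = rej)
}

#' Deconvolute screener picks into lab cherry picks
#'
#' Small-molecule and duplex RNAi picks map one-to-one onto lab picks.
#' Pool-based siRNA picks are automatically deconvoluted into their
#' constituent duplexes: one lab pick per duplex well of the pool reagent,
#' sourced from the duplex library. All lab picks start `unfulfilled`.
#'
#' @param request a [CherryPickRequest] with validated screener picks.
#' @param libraries list of [ScreenLibrary] objects (must include the
#'   duplex library for pooled picks).
#' @return the updated [CherryPickRequest].
#' @export
deconvolute <- function(request, libraries) {
  stopifnot(is(request, "CherryPickRequest"))
  if (is(libraries, "ScreenLibrary")) libraries <- list(libraries)
  sp <- request@screenerPicks
  acc <- which(sp$status == "accepted")
  rows <- list()
  nextId <- if (nrow(request@labPicks)) max(request@labPicks$id) else 0L
  for (i in acc) {
    key <- wellKey(sp$plate[i], sp$well[i])
    hit <- .findWell(libraries, key)
    if (is.null(hit))
      stop("pick ", key, " not found in the supplied libraries",
           call. = FALSE)
    w <- hit$library@wells[hit$row, ]
    srcKeys <- key
    if (hit$library@screenType == "rnai" &&
        !is.na(w$silencing_type) && w$silencing_type == "pool") {
      dk <- trimws(strsplit(w$duplex_wells, ";", fixed = TRUE)[[1L]])
      for (k in dk) {
        dh <- .findWell(libraries, k)
        if (is.null(dh) || is.na(dh$library@wells$silencing_type[dh$row]) ||
            dh$library@wells$silencing_type[dh$row] != "duplex")
          stop("pool ", key, ": duplex well ", k,
               " missing from the duplex library", call. = FALSE)
      }
      srcKeys <- dk
    }
    src <- splitWellKey(srcKeys, 1536L)
    rows[[length(rows) + 1L]] <- data.frame(
      id = nextId + seq_along(srcKeys), source_plate = src$plate,
      source_well = src$well, screener_key = key, status = "unfulfilled",
      source_copy = NA_character_, dest_plate = NA_integer_,
      dest_well = NA_character_, respawn_of = NA_integer_,
      rolled_over = FALSE, stringsAsFactors = FALSE)
    nextId <- nextId + length(srcKeys)
  }
  request@labPicks <- rbind(request@labPicks,
                            do.call(rbind, c(rows, list(.emptyLabPicks()))))
  validObject(request)
  request
}

# cherry-pick-eligible copies for a source plate: cherry-pick-source
# usage, plate present and not retired
.eligibleCopies <- function(copies, plate) {
  keep <- vapply(copies, function(cp) {
    if (cp@usageType != "cherry_pick_source") return(FALSE)
    i <- match(plate, cp@plateInfo$plate)
    !is.na(i) && !cp@plateInfo$retired[i]
  }, TRUE)
  copies[keep]
}

#' Tabulate available copy volumes for each lab pick
#'
#' One row per (lab pick, eligible cherry-pick-source copy); a copy is
#' sufficient when its remaining well volume is at least the request's
#' effective volume (boundary inclusive). Retired plates are excluded.
#'
#' @param request a [CherryPickRequest] with lab picks.
#' @param copies list of [LibraryCopy] objects.
#' @return data.frame `pick_id`, `source_plate`, `source_well`, `copy`,
#'   `remaining_ul`, `sufficient`.
#' @export
viewWellVolumes <- function(request, copies) {
  stopifnot(is(request, "CherryPickRequest"))
  if (is(copies, "LibraryCopy")) copies <- list(copies)
  volUl <- effectiveVolumeUl(request)
  lp <- request@labPicks
  rows <- list()
  for (i in seq_len(nrow(lp))) {
    key <- wellKey(lp$source_plate[i], lp$source_well[i])
    for (cp in .eligibleCopies(copies, lp$source_plate[i])) {
      rem <- nlToUl(cp@remainingNl[[key]])
      rows[[length(rows) + 1L]] <- data.frame(
        pick_id = lp$id[i], source_plate = lp$source_plate[i],
        source_well = lp$source_well[i], copy = cp@name,
        remaining_ul = rem, sufficient = rem >= volUl,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(pick_id = integer(), source_plate = integer(),
                         source_well = character(), copy = character(),
                         remaining_ul = numeric(), sufficient = logical(),
                         stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Reserve reagent volume for each unfulfilled lab pick
#'
#' For every unfulfilled pick, in pick order, the eligible copies holding
#' at least the effective volume in the source well are considered and
#' the copy with the smallest sufficient remaining volume is selected
#' (depleting nearly-empty copies first; ties break on the
#' lexicographically smallest copy name), and that well is debited. Picks
#' with no sufficient copy stay `unfulfilled` — insufficiency is per-pick,
#' never fatal. The operation is deterministic and records one
#' reservation activity.
#'
#' @param request a [CherryPickRequest] with lab picks.
#' @param copies list of [LibraryCopy] objects (modified copies are
#'   returned).
#' @param performer acting user (id or [ScreenUser]).
#' @param log an [ActivityLog].
#' @param date event date.
#' @return list with updated `request`, `copies`, `log` and the
#'   `activity`.
#' @export
reserveReagent <- function(request, copies, performer, log,
                           date = Sys.Date()) {
  stopifnot(is(request, "CherryPickRequest"), is(log, "ActivityLog"))
  if (is(copies, "LibraryCopy")) copies <- list(copies)
  volNl <- ulToNl(effectiveVolumeUl(request))
  lp <- request@labPicks
  todo <- which(lp$status == "unfulfilled" & !lp$rolled_over)
  nReserved <- 0L
  for (i in todo[order(lp$id[todo])]) {
    key <- wellKey(lp$source_plate[i], lp$source_well[i])
    elig <- .eligibleCopies(copies, lp$source_plate[i])
    if (!length(elig)) next
    rem <- vapply(elig, function(cp) cp@remainingNl[[key]], 1L)
    nms <- vapply(elig, copyName, "")
    ok <- rem >= volNl
    if (!any(ok)) next
    pick <- which(ok)[order(rem[ok], nms[ok])][1L]
    chosen <- nms[pick]
    j <- which(vapply(copies, copyName, "") == chosen &
                 vapply(copies, function(cp) cp@libraryName, "") ==
                   elig[[pick]]@libraryName)[1L]
    copies[[j]]@remainingNl[[key]] <-
      copies[[j]]@remainingNl[[key]] - volNl
    lp$status[i] <- "reserved"
    lp$source_copy[i] <- chosen
    nReserved <- nReserved + 1L
  }
  request@labPicks <- lp
  validObject(request)
  rec <- recordActivity(
    log, "cherry_pick_reservation", performer, date,
    links = paste0("cpr:", request@id),
    payload = list(n_reserved = nReserved,
                   n_unfulfilled = sum(lp$status == "unfulfilled" &
                                         !lp$rolled_over),
                   volume_ul = nlToUl(volNl)))
  list(request = request, copies = copies, log = rec$log,
       activity = rec$activity)
}

#' Map reserved picks onto cherry-pick destination plates
#'
#' Reserved picks are ordered by (source plate, source well row-major,
#' copy name) — keeping source plates batched together for the liquid
#' handler — and assigned to consecutive available destination wells,
#' overflowing onto further plates. Available wells are the destination
#' format's wells minus `requiredEmptyWells`, so the plate count is
#' `ceiling(n_reserved / n_available)`. With `randomizeLayout`, the
#' destination wells within each plate are permuted by a generator seeded
#' with the request's persisted seed, so a rerun reproduces the layout.
#' Picks respawned from a single failed plate are remapped onto a
#' successor plate carrying the same ordinal with attempt + 1.
#'
#' @param request a [CherryPickRequest] with reserved picks.
#' @return the updated [CherryPickRequest] (picks `mapped`, plates
#'   appended).
#' @export
mapToPlates <- function(request) {
  stopifnot(is(request, "CherryPickRequest"))
  available <- setdiff(wellNamesRowMajor(request@destFormat),
                       request@requiredEmptyWells)
  if (!length(available))
    stop("required empty wells cover the whole destination plate",
         call. = FALSE)
  lp <- request@labPicks
  res <- which(lp$status == "reserved")
  if (!length(res))
    stop("no reserved picks to map", call. = FALSE)
  ord <- res[order(lp$source_plate[res],
                   rowMajorIndex(lp$source_well[res], 1536L),
                   lp$source_copy[res])]
  nAvail <- length(available)
  plates <- request@plates
  nextOrdinal <- if (nrow(plates)) max(plates$ordinal) + 1L else 1L
  chunks <- split(ord, ceiling(seq_along(ord) / nAvail))
  .withSeed(request@randomSeed, {
    for (chunk in chunks) {
      rs <- unique(lp$respawn_of[chunk])
      if (length(rs) == 1L && !is.na(rs) &&
          any(plates$ordinal == rs & plates$status == "failed") &&
          !any(plates$ordinal == rs & plates$status == "not_plated")) {
        ordinal <- rs
        attempt <- max(plates$attempt[plates$ordinal == rs]) + 1L
      } else {
        ordinal <- nextOrdinal
        nextOrdinal <- nextOrdinal + 1L
        attempt <- 1L
      }
      dest <- if (request@randomizeLayout)
        sample(available)[seq_along(chunk)]
      else available[seq_along(chunk)]
      lp$status[chunk] <- "mapped"
      lp$dest_plate[chunk] <- ordinal
      lp$dest_well[chunk] <- dest
      plates <- rbind(plates,
                      data.frame(ordinal = ordinal, attempt = attempt,
                                 status = "not_plated",
                                 stringsAsFactors = FALSE))
    }
  })
  request@labPicks <- lp
  request@plates <- plates
  validObject(request)
  request
}

#' Export the liquid-handler plate-mapping file
#'
#' One CSV row per mapped pick: source plate, source copy, source well,
#' destination plate ordinal, destination well and transfer volume,
#' ordered by destination plate then source plate (reagents stay batched
#' by source plate for the automation).
#'
#' @param request a mapped [CherryPickRequest].
#' @param path optional output path.
#' @return the CSV lines, invisibly when writing to `path`.
#' @export
exportPlateMapping <- function(request, path = NULL) {
  stopifnot(is(request, "CherryPickRequest"))
  lp <- request@labPicks
  rows <- which(lp$status %in% c("mapped", "plated"))
  if (!length(rows))
    stop("request has no mapped picks; run reserveReagent/mapToPlates",
         call. = FALSE)
  ord <- rows[order(lp$dest_plate[rows], lp$source_plate[rows],
                    rowMajorIndex(lp$source_well[rows], 1536L),
                    lp$source_copy[rows])]
  volUl <- effectiveVolumeUl(request)
  lines <- c(
    "source_plate,source_copy,source_well,destination_plate_ordinal,destination_well,volume_uL",
    paste(lp$source_plate[ord], lp$source_copy[ord], lp$source_well[ord],
          lp$dest_plate[ord], lp$dest_well[ord],
          format(volUl, trim = TRUE, scientific = FALSE), sep = ","))
  if (!is.null(path)) { writeLines(lines, path); return(invisible(lines)) }
  lines
}

#' Update the plating status of a cherry-pick plate
#'
#' As plates are produced in the lab, each moves from `not_plated` to one
#' of the terminal statuses: `plated` confirms the reservation (picks
#' become plated; a cherry-pick liquid-transfer lab activity is
#' recorded); `canceled` reverses it (the reserved volume of every pick
#' on the plate is credited back to its source copy well); `failed`
#' records a physical plating failure — the reagent was consumed, so
#' volumes stay debited, and the plate's picks are respawned as fresh
#' unfulfilled picks so the reservation and mapping workflow can be
#' repeated, yielding a successor plate with attempt + 1.
#'
#' @param request a [CherryPickRequest].
#' @param plateOrdinal ordinal of the plate to update.
#' @param newStatus `"plated"`, `"failed"` or `"canceled"`.
#' @param performer acting user (id or [ScreenUser]).
#' @param copies list of [LibraryCopy] objects (credited on cancel).
#' @param log an [ActivityLog].
#' @param date event date.
#' @return list with updated `request`, `copies`, `log` and `activity`.
#' @export
updatePlateStatus <- function(request, plateOrdinal, newStatus, performer,
                              copies, log, date = Sys.Date()) {
  stopifnot(is(request, "CherryPickRequest"), is(log, "ActivityLog"))
  if (is(copies, "LibraryCopy")) copies <- list(copies)
  if (!newStatus %in% c("plated", "failed", "canceled"))
    stop("new status must be plated, failed or canceled", call. = FALSE)
  plates <- request@plates
  cand <- which(plates$ordinal == as.integer(plateOrdinal))
  if (!length(cand))
    stop("no such cherry pick plate: ", plateOrdinal, call. = FALSE)
  open <- cand[plates$status[cand] == "not_plated"]
  if (!length(open))
    stop("plate ", plateOrdinal, " is already in terminal status '",
         plates$status[cand[which.max(plates$attempt[cand])]], "'",
         call. = FALSE)
  row <- open[which.max(plates$attempt[open])]
  lp <- request@labPicks
  onPlate <- which(lp$status == "mapped" &
                     lp$dest_plate == plates$ordinal[row])
  volNl <- ulToNl(effectiveVolumeUl(request))

  if (newStatus == "plated") {
    lp$status[onPlate] <- "plated"
    act <- list(kind = "cherry_pick_liquid_transfer",
                payload = list(plate_ordinal = plates$ordinal[row],
                               n_picks = length(onPlate),
                               volume_ul = nlToUl(volNl)))
  } else if (newStatus == "canceled") {
    copyNames <- vapply(copies, copyName, "")
    for (i in onPlate) {
      key <- wellKey(lp$source_plate[i], lp$source_well[i])
      j <- which(copyNames == lp$source_copy[i])
      j <- j[vapply(copies[j], function(cp) key %in% names(cp@remainingNl),
                    TRUE)][1L]
      if (is.na(j))
        stop("cannot credit volume: copy '", lp$source_copy[i],
             "' not supplied", call. = FALSE)
      copies[[j]]@remainingNl[[key]] <- copies[[j]]@remainingNl[[key]] +
        volNl
    }
    lp$status[onPlate] <- "canceled"
    act <- list(kind = "cherry_pick_cancellation",
                payload = list(plate_ordinal = plates$ordinal[row],
                               n_picks = length(onPlate),
                               credited_ul = nlToUl(volNl) *
                                 length(onPlate)))
  } else {  # failed: reagent consumed; respawn picks for a new attempt
    lp$status[onPlate] <- "failed"
    nextId <- if (nrow(lp)) max(lp$id) else 0L
    respawn <- lp[onPlate, , drop = FALSE]
    respawn$id <- nextId + seq_len(nrow(respawn))
    respawn$status <- "unfulfilled"
    respawn$source_copy <- NA_character_
    respawn$dest_plate <- NA_integer_
    respawn$dest_well <- NA_character_
    respawn$respawn_of <- plates$ordinal[row]
    respawn$rolled_over <- FALSE
    lp <- rbind(lp, respawn)
    act <- list(kind = "cherry_pick_plate_failure",
                payload = list(plate_ordinal = plates$ordinal[row],
                               attempt = plates$attempt[row],
                               n_picks = length(onPlate)))
  }
  plates$status[row] <- newStatus
  request@labPicks <- lp
  request@plates <- plates
  validObject(request)
  rec <- recordActivity(log, act$kind, performer, date,
                        links = c(paste0("cpr:", request@id),
                                  paste0("cpr_plate:", request@id, "/",
                                         plates$ordinal[row])),
                        payload = act$payload)
  list(request = request, copies = copies, log = rec$log,
       activity = rec$activity)
}

#' Roll unfulfillable picks over into a new request
#'
#' Picks left unfulfilled after reservation (no copy held sufficient
#' volume) can be rolled over into a fresh cherry-pick request on the
#' same screen for later processing. The unfulfilled lab picks are
#' re-collapsed to screener-pick level; the originals are marked rolled
#' over and are not processed (or rolled over) again.
#'
#' @param request a [CherryPickRequest] with unfulfilled picks.
#' @param newId id for the new request.
#' @param date request date of the new request.
#' @return list with the updated original `request` and the `newRequest`.
#' @export
rolloverUnfulfilled <- function(request, newId, date = Sys.Date()) {
  stopifnot(is(request, "CherryPickRequest"))
  lp <- request@labPicks
  un <- which(lp$status == "unfulfilled" & !lp$rolled_over)
  if (!length(un))
    stop("request has no unfulfilled picks to roll over", call. = FALSE)
  keys <- unique(lp$screener_key[un])
  sp <- splitWellKey(keys, 1536L)
  sp$status <- "accepted"
  sp$rejection_reason <- NA_character_
  newReq <- new("CherryPickRequest", id = as.character(newId),
                screenId = request@screenId,
                requestedBy = request@requestedBy, date = as.Date(date),
                requestedVolumeUl = request@requestedVolumeUl,
                approvedVolumeUl = request@approvedVolumeUl,
                randomizeLayout = request@randomizeLayout,
                requiredEmptyWells = request@requiredEmptyWells,
                randomSeed = request@randomSeed,
                destFormat = request@destFormat,
                maxPicks = request@maxPicks,
                screenerPicks = sp, labPicks = .emptyLabPicks(),
                plates = .emptyCprPlates())
  lp$rolled_over[un] <- TRUE
  request@labPicks <- lp
  list(request = request, newRequest = newReq)
}
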