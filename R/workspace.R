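# -- entity (de)serialization ------------------------------------------------
#
# The workspace store is JSON text: every persisted object is encoded as
# explicit tagged nodes so reconstruction is type-exact (integer vs
# double, Date, named vectors, empty data.frames). The schema mirrors the
# domain model one-to-one.

serializeEntity <- function(x) {
  if (is.null(x)) return(list(.t = "null"))
  if (isS4(x)) {
    sl <- methods::slotNames(class(x))
    return(list(.t = "s4", class = as.character(class(x)),
                slots = stats::setNames(
                  lapply(sl, function(s) serializeEntity(methods::slot(x, s))),
                  sl)))
  }
  if (inherits(x, "Date"))
    return(list(.t = "date", v = as.list(as.character(x))))
  if (is.data.frame(x))
    return(list(.t = "df", n = nrow(x),
                cols = lapply(x, serializeEntity)))
  if (is.list(x))
    return(list(.t = "list", names = as.list(names(x)),
                items = lapply(unname(x), serializeEntity)))
  # atomic vector
  list(.t = "atomic", mode = storage.mode(x),
       names = as.list(names(x)),
       v = lapply(unname(as.vector(x)), function(e)
         if (is.na(e)) NULL else e))
}

deserializeEntity <- function(x) {
  switch(x$.t,
    null = NULL,
    s4 = {
      slots <- lapply(x$slots, deserializeEntity)
      do.call(methods::new, c(list(Class = x$class), slots))
    },
    date = as.Date(unlist(x$v, use.names = FALSE) %||% character()),
    df = {
      cols <- lapply(x$cols, deserializeEntity)
      if (!length(cols)) return(data.frame(stringsAsFactors = FALSE))
      df <- as.data.frame(cols, stringsAsFactors = FALSE, optional = TRUE)
      names(df) <- names(x$cols)
      df
    },
    list = {
      items <- lapply(x$items, deserializeEntity)
      nms <- unlist(x$names, use.names = FALSE)
      if (length(nms)) names(items) <- nms
      items
    },
    atomic = {
      v <- vector(x$mode, length(x$v))
      filled <- !vapply(x$v, is.null, TRUE)
      v[!filled] <- NA
      v[filled] <- unlist(x$v[filled], use.names = FALSE)
      storage.mode(v) <- x$mode
      nms <- unlist(x$names, use.names = FALSE)
      if (length(nms)) names(v) <- nms
      v
    },
    stop("unknown store node type: ", x$.t, call. = FALSE))
}

#' A persistent workspace binding all entities to a directory
#'
#' All command-line operations act on one workspace: a directory holding
#' a JSON entity store (`store.json`) plus a config (policy vocabulary,
#' default plate format, import field mappings). The store survives
#' process restarts.
#'
#' @slot root workspace directory.
#' @slot env environment holding `users`, `libraries`, `copies`,
#'   `screens`, `studies`, `requests` (named lists), `log` (an
#'   [ActivityLog]) and `config`.
#' @export
setClass("Workspace", representation(root = "character",
                                     env = "environment"))

.defaultConfig <- function() {
  list(plate_format = 384L,
       access_levels = list(`0` = "shared", `1` = "non-positives withheld",
                            `2` = "positives and protocol", `3` = "private"),
       field_map = as.list(.defaultFieldMap))
}

#' Create or open a workspace
#'
#' @param root workspace directory (created if missing).
#' @return a [Workspace]; an existing `store.json` is loaded.
#' @export
openWorkspace <- function(root) {
  dir.create(root, showWarnings = FALSE, recursive = TRUE)
  env <- new.env(parent = emptyenv())
  env$users <- list(); env$libraries <- list(); env$copies <- list()
  env$screens <- list(); env$studies <- list(); env$requests <- list()
  env$log <- newActivityLog()
  env$config <- .defaultConfig()
  ws <- new("Workspace", root = normalizePath(root), env = env)
  storePath <- file.path(ws@root, "store.json")
  if (file.exists(storePath)) {
    raw <- jsonlite::read_json(storePath, simplifyVector = FALSE)
    for (section in c("users", "libraries", "copies", "screens", "studies",
                      "requests"))
      env[[section]] <- lapply(raw[[section]] %||% list(),
                               deserializeEntity)
    if (!is.null(raw$log)) env$log <- deserializeEntity(raw$log)
    if (!is.null(raw$config)) env$config <- raw$config
  }
  ws
}

#' @rdname openWorkspace
#' @param ws a [Workspace].
#' @export
saveWorkspace <- function(ws) {
  stopifnot(is(ws, "Workspace"))
  env <- ws@env
  out <- list(
    users = lapply(env$users, serializeEntity),
    libraries = lapply(env$libraries, serializeEntity),
    copies = lapply(env$copies, serializeEntity),
    screens = lapply(env$screens, serializeEntity),
    studies = lapply(env$studies, serializeEntity),
    requests = lapply(env$requests, serializeEntity),
    log = serializeEntity(env$log),
    config = env$config)
  jsonlite::write_json(out, file.path(ws@root, "store.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  invisible(ws)
}

setMethod("show", "Workspace", function(object) {
  env <- object@env
  cat("Workspace at ", object@root, "\n  ",
      length(env$libraries), " libraries, ", length(env$copies),
      " copies, ", length(env$screens), " screens, ",
      length(env$requests), " cherry pick requests, ",
      length(env$log@activities), " activities\n", sep = "")
})

# convenience store accessors used by the CLI
wsGet <- function(ws, section, id) {
  obj <- ws@env[[section]][[id]]
  if (is.null(obj))
    stop("no ", sub("s$", "", section), " named '", id,
         "' in the workspace", call. = FALSE)
  obj
}

wsSet <- function(ws, section, id, obj) {
  ws@env[[section]][[id]] <- obj
  invisible(ws)
}

# copies are stored under "library/copyName"
copyStoreKey <- function(libraryName, copyName)
  paste(libraryName, copyName, sep = "/")

wsLibraryCopies <- function(ws, libraryName) {
  keys <- grep(paste0("^", libraryName, "/"), names(ws@env$copies),
               value = TRUE)
  ws@env$copies[keys]
}
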