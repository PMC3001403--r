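#' Data sharing levels and the reciprocity rule
#'
#' Screens carry a data sharing level from 0 to 3: 0 shares everything,
#' 1 shares but withholds non-positive detail, 2 shares positives and
#' protocol, 3 is private. Access is reciprocal — screeners willing to
#' share more of their own data are allowed similar levels of others'
#' data. The default concrete policy is:
#'
#' * lab head, lead screener, collaborators, and administrators holding
#'   the `"read_everything"` role always get `full` access;
#' * otherwise, with the user's own level `u` and the screen's level `s`:
#'   `none` when either is 3 (private screens are invisible and private
#'   users see nothing of others), `full` when `u <= s` (the user shares
#'   at least as much as the target), and `metadata_only` when `u > s`.
#'
#' A user's own level is the minimum sharing level over the screens they
#' are a member of *in the same reagent-class domain* — small-molecule
#' sharing does not unlock RNAi screens or vice versa — defaulting to 3
#' (private) for users with no screens. The whole rule is pluggable via
#' the `policy` argument, so facilities can substitute their own.
#'
#' @param user a [ScreenUser].
#' @param screen the target [Screen].
#' @param screens list of all screens, used to derive the user's own
#'   sharing level (ignored when `userLevel` is given).
#' @param userLevel override for the user's own sharing level (0-3).
#' @param policy optional function `(user, screen, userLevel)` returning
#'   an access string, replacing the level rule after the
#'   membership/admin overrides.
#' @return a [VisibilityDecision].
#' @examples
#' s <- newScreen("S1", "small_molecule", labHead = "pi",
#'                dataSharingLevel = 1)
#' u <- screenUser("guest")
#' accessLevel(effectiveAccess(u, s, userLevel = 1))  # "full"
#' accessLevel(effectiveAccess(u, s, userLevel = 2))  # "metadata_only"
#' @export
effectiveAccess <- function(user, screen, screens = list(),
                            userLevel = NULL, policy = NULL) {
  stopifnot(is(user, "ScreenUser"), is(screen, "Screen"))
  decide <- function(access)
    new("VisibilityDecision", subject = user@id,
        screenId = screen@facilityId, access = access)
  member <- user@id %in% c(screen@labHead, screen@leadScreener,
                           screen@collaborators)
  if (member) return(decide("full"))
  if (user@category == "administrator" && "read_everything" %in% user@roles)
    return(decide("full"))
  u <- if (!is.null(userLevel)) as.integer(userLevel)
       else userSharingLevel(user, screens, screen@screenType)
  if (!is.null(policy)) return(decide(policy(user, screen, u)))
  s <- screen@dataSharingLevel
  access <- if (s == 3L || u == 3L) "none"
            else if (u <= s) "full"
            else "metadata_only"
  decide(access)
}

#' @rdname effectiveAccess
#' @param screenType reagent-class domain in which to compute the level.
#' @export
userSharingLevel <- function(user, screens, screenType) {
  stopifnot(is(user, "ScreenUser"))
  levels <- vapply(screens, function(sc) {
    if (sc@screenType == screenType &&
        user@id %in% c(sc@labHead, sc@leadScreener, sc@collaborators))
      sc@dataSharingLevel else NA_integer_
  }, 1L)
  levels <- levels[!is.na(levels)]
  if (length(levels)) min(levels) else 3L
}

#' Columns of a screen result visible under an access decision
#'
#' `full` exposes every data column; `positives_and_protocol` exposes
#' only the positives-indicator columns; `metadata_only` and `none`
#' expose no columns.
#'
#' @param decision a [VisibilityDecision].
#' @param screenResult a [ScreenResult].
#' @return character vector of visible column names.
#' @export
visibleColumns <- function(decision, screenResult) {
  stopifnot(is(decision, "VisibilityDecision"),
            is(screenResult, "ScreenResult"))
  cols <- screenResult@columns
  switch(decision@access,
         full = cols$name,
         positives_and_protocol =
           cols$name[cols$positive_indicator != "none"],
         character(0))
}
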