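#' A single rater's scoring of one foot in one session
#'
#' A `score_grid` holds the rows x cols matrix of ordinal wear levels (or
#' `NA` for cells outside the foot) that one rater assigned to one foot in
#' one scoring session. Row 1 is at the toe, column 1 at the medial edge of
#' a left foot; cells are addressed "RxCy" (e.g. `"R5C7"` = row 5, column 7).
#' Right feet are scored from mirrored images, recorded via
#' `side = "mirrored_right"`.
#'
#' @param cells Integer matrix (rows x cols) of levels or `NA`.
#' @param foot_id,rater_id Identifier strings.
#' @param session Session index (>= 1); repeat sessions support
#'   intraobserver analysis.
#' @param scale A [wear_scale()] or its name.
#' @param side `"left"` or `"mirrored_right"`.
#' @param used Has the foot been worn? Used feet cannot legitimately score 0
#'   in any cell. Defaults to `TRUE` (wear studies concern replaced feet).
#' @return A `score_grid` object.
#' @seealso [validate_grid()], [collapse_grid()], [rating_panel()]
#' @export
score_grid <- function(cells, foot_id, rater_id, session = 1L,
                       scale = "original", side = c("left", "mirrored_right"),
                       used = TRUE) {
  scale <- as_wear_scale(scale)
  side <- match.arg(side)
  if (!is.matrix(cells)) stop("`cells` must be a matrix")
  storage.mode(cells) <- "integer"
  stopifnot(length(foot_id) == 1L, length(rater_id) == 1L)
  session <- as.integer(session)
  if (is.na(session) || session < 1L) stop("`session` must be an integer >= 1")
  structure(
    list(foot_id = as.character(foot_id), rater_id = as.character(rater_id),
         session = session, scale = scale,
         rows = nrow(cells), cols = ncol(cells), cells = cells,
         side = side, used = isTRUE(used)),
    class = "score_grid"
  )
}

#' @export
print.score_grid <- function(x, ...) {
  cat(sprintf("<score_grid %s / %s / session %d: %dx%d, %s scale, %d NA cells>\n",
              x$foot_id, x$rater_id, x$session, x$rows, x$cols,
              x$scale$name, sum(is.na(x$cells))))
  invisible(x)
}

#' Validate a score grid against the rubric's rules
#'
#' Violations are returned as data, not raised as errors, so that incoming
#' score sheets can be triaged in bulk. Checked rules: every numeric cell is
#' a level of the grid's scale; a used foot has no 0 cells (score 0 means
#' "newly manufactured, not yet used"); the standard grid is 20x10 = 200
#' cells (non-standard dimensions are reported as a note-level violation
#' only when `require_standard = TRUE`).
#'
#' @param g A [score_grid()].
#' @param require_standard Flag non-20x10 grids? Default `FALSE` (the grid
#'   is configurable, e.g. 10x5).
#' @return Data frame with columns `cell` (label "RxCy" or `""` for
#'   grid-level violations), `rule`, `message`; zero rows iff valid.
#' @export
validate_grid <- function(g, require_standard = FALSE) {
  stopifnot(inherits(g, "score_grid"))
  viol <- list()
  add <- function(cell, rule, message) {
    viol[[length(viol) + 1L]] <<- data.frame(
      cell = cell, rule = rule, message = message, stringsAsFactors = FALSE)
  }
  idx <- which(!is.na(g$cells) & !(g$cells %in% g$scale$levels), arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) {
    r <- idx[k, 1]; c <- idx[k, 2]
    add(cell_label(r, c), "out_of_range",
        sprintf("value %d is not a level of the %s scale",
                g$cells[r, c], g$scale$name))
  }
  if (g$used) {
    idx0 <- which(!is.na(g$cells) & g$cells == 0L, arr.ind = TRUE)
    for (k in seq_len(nrow(idx0))) {
      add(cell_label(idx0[k, 1], idx0[k, 2]), "zero_on_used_foot",
          "a used foot cannot score 0 (0 = newly manufactured)")
    }
  }
  if (require_standard && g$rows * g$cols != 200L) {
    add("", "nonstandard_grid",
        sprintf("grid is %dx%d, standard is 20x10 (200 cells)", g$rows, g$cols))
  }
  if (length(viol) == 0L) {
    return(data.frame(cell = character(0), rule = character(0),
                      message = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, viol)
}

#' Collapse a grid from the original to the modified scale
#'
#' Applies [collapse_score()] elementwise; all metadata (foot, rater,
#' session, side, used) is preserved and the result is tagged with the
#' modified scale.
#'
#' @param g A [score_grid()] on the original scale.
#' @return A `score_grid` on the modified scale.
#' @export
collapse_grid <- function(g) {
  stopifnot(inherits(g, "score_grid"))
  if (g$scale$name != "original") {
    stop("wrong scale: grid is already on the modified scale")
  }
  out <- g
  cc <- collapse_score(as.vector(g$cells))
  out$cells <- matrix(cc, nrow = g$rows, ncol = g$cols)
  out$scale <- wear_scale("modified")
  out
}

grid_key <- function(foot_id, rater_id, session) {
  paste(foot_id, rater_id, session, sep = "\r")
}

#' An aligned panel of score grids across feet, raters and sessions
#'
#' The unit of reliability analysis: a collection of [score_grid()]s sharing
#' one scale and grid size, with at most one grid per (foot, rater, session)
#' triple. Rater "groups" that score jointly are treated as single raters.
#'
#' @param grids List of `score_grid` objects.
#' @return A `rating_panel` with ordered `feet`, `raters`, `sessions`.
#' @export
rating_panel <- function(grids) {
  if (length(grids) == 0L) stop("a rating panel needs at least one grid")
  stopifnot(all(vapply(grids, inherits, logical(1), "score_grid")))
  sc <- vapply(grids, function(g) g$scale$name, character(1))
  rw <- vapply(grids, function(g) g$rows, numeric(1))
  cl <- vapply(grids, function(g) g$cols, numeric(1))
  if (length(unique(sc)) > 1L) stop("all grids in a panel must share one scale")
  if (length(unique(rw)) > 1L || length(unique(cl)) > 1L) {
    stop("all grids in a panel must share the same grid dimensions")
  }
  keys <- vapply(grids, function(g) grid_key(g$foot_id, g$rater_id, g$session),
                 character(1))
  if (anyDuplicated(keys)) {
    d <- grids[[which(duplicated(keys))[1]]]
    stop(sprintf("duplicate grid for foot %s, rater %s, session %d",
                 d$foot_id, d$rater_id, d$session))
  }
  names(grids) <- keys
  structure(
    list(grids = grids,
         feet = unique(vapply(grids, `[[`, character(1), "foot_id")),
         raters = unique(vapply(grids, `[[`, character(1), "rater_id")),
         sessions = sort(unique(vapply(grids, function(g) g$session, integer(1)))),
         scale = grids[[1]]$scale, rows = grids[[1]]$rows, cols = grids[[1]]$cols),
    class = "rating_panel"
  )
}

#' @export
print.rating_panel <- function(x, ...) {
  cat(sprintf("<rating_panel: %d feet x %d raters x %d session(s), %dx%d grid, %s scale>\n",
              length(x$feet), length(x$raters), length(x$sessions),
              x$rows, x$cols, x$scale$name))
  invisible(x)
}

#' Fetch one grid from a panel
#'
#' @param panel A [rating_panel()].
#' @param foot_id,rater_id,session Triple identifying the grid.
#' @return The `score_grid`, or `NULL` if absent.
#' @export
panel_grid <- function(panel, foot_id, rater_id, session = 1L) {
  stopifnot(inherits(panel, "rating_panel"))
  panel$grids[[grid_key(foot_id, rater_id, as.integer(session))]]
}

#' Collapse every grid in a panel to the modified scale
#'
#' @param panel A [rating_panel()] on the original scale.
#' @return A `rating_panel` on the modified scale.
#' @export
collapse_panel <- function(panel) {
  stopifnot(inherits(panel, "rating_panel"))
  rating_panel(lapply(panel$grids, collapse_grid))
}
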